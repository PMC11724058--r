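#' Cell-by-feature expression matrix
#'
#' Thin container for a sparse cells x features matrix of (possibly
#' fractional) UMI masses, tracking which library it came from and its
#' normalization state. The state is checked before downstream operations,
#' so a matrix cannot be normalized twice.
#'
#' @param values a matrix or sparse Matrix, cells in rows, features in
#'   columns, with dimnames.
#' @param library_kind `"smallRNA"` or `"mRNA"`.
#' @param normalization `"raw"`, `"lognorm"` or `"log2rpm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, library_kind = c("smallRNA", "mRNA"),
                              normalization = c("raw", "lognorm", "log2rpm")) {
  library_kind <- match.arg(library_kind)
  normalization <- match.arg(normalization)
  values <- methods::as(methods::as(methods::as(
    Matrix::Matrix(values, sparse = TRUE), "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs cell and feature names")
  if (any(values@x < 0)) stop("expression values must be nonnegative")
  structure(list(values = values, library_kind = library_kind,
                 normalization = normalization),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s, %s): %d cells x %d features\n",
              x$library_kind, x$normalization, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a mature-miRNA reference FASTA
#'
#' Accepts DNA or RNA alphabets (U is converted to T). Duplicate ids are a
#' format error; distinct ids may share a sequence (miRNA families), which
#' is how multimapping arises for the small-RNA matcher.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case DNA sequences.
#' @export
read_mirna_reference <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate ids in miRNA reference: ", ids[duplicated(ids)][1])
  seqs <- chartr("Uu", "Tt", as.character(x))
  stats::setNames(toupper(seqs), ids)
}

#' Match trimmed small-RNA inserts against a mature-miRNA reference
#'
#' An insert matches a reference entry when it equals a prefix of the
#' mature sequence (or the full sequence) with at most `max_mismatch`
#' substitutions. All matching entries are reported; the number of matches
#' becomes the read's mapped-location count used for multimapper weighting.
#'
#' @param tagged a tagged-read data frame (only `assigned` rows are used).
#' @param reference named character vector from [read_mirna_reference()].
#' @param max_mismatch substitutions tolerated (default 1).
#' @return A feature-assignment data frame with columns `read_id`, `cell`,
#'   `umi`, `features` (comma-joined sorted ids), `n_locations`.
#' @export
assign_smallrna_features <- function(tagged, reference, max_mismatch = 1) {
  if (anyDuplicated(names(reference)))
    stop("duplicate ids in miRNA reference")
  use <- tagged[tagged$status == "assigned", , drop = FALSE]
  if (nrow(use) == 0)
    return(data.frame(read_id = character(), cell = character(),
                      umi = character(), features = character(),
                      n_locations = integer()))
  uins <- unique(use$insert)
  hits <- cpp_prefix_match(uins, unname(reference), as.integer(max_mismatch))
  feat_key <- vapply(hits, function(ix) {
    if (length(ix) == 0) return(NA_character_)
    paste(sort(names(reference)[ix]), collapse = ",")
  }, character(1))
  nloc <- lengths(hits)
  m <- match(use$insert, uins)
  out <- data.frame(read_id = use$read_id, cell = use$cell, umi = use$umi,
                    features = feat_key[m], n_locations = as.integer(nloc[m]),
                    row.names = NULL)
  dropped <- is.na(out$features)
  if (any(dropped))
    message(sprintf("assign_smallrna_features: %d/%d reads unassigned",
                    sum(dropped), nrow(out)))
  out[!dropped, , drop = FALSE]
}

#' Join external alignments with the tagged-read table
#'
#' Consumes genome-alignment results (produced outside this package) as a
#' tabular file with one row per aligned read, and attaches the cell and
#' UMI recovered at demultiplexing. Reads aligned but absent from the
#' tagged table are a consistency error; tagged reads without an alignment
#' are dropped with a counted log line.
#'
#' @param alignments data frame with columns `read_id`, `features`
#'   (comma-joined feature ids) and `n_locations`.
#' @param tagged a tagged-read data frame (only `assigned` rows are used).
#' @return A feature-assignment data frame (see
#'   [assign_smallrna_features()]).
#' @export
ingest_alignments <- function(alignments, tagged) {
  stopifnot(all(c("read_id", "features", "n_locations") %in% names(alignments)))
  use <- tagged[tagged$status == "assigned", , drop = FALSE]
  orphan <- !(alignments$read_id %in% tagged$read_id)
  if (any(orphan))
    stop("alignment read_id absent from tagged table: ",
         alignments$read_id[which(orphan)[1]])
  m <- match(use$read_id, alignments$read_id)
  unaligned <- is.na(m)
  if (any(unaligned))
    message(sprintf("ingest_alignments: %d/%d assigned reads unaligned, dropped",
                    sum(unaligned), nrow(use)))
  use <- use[!unaligned, , drop = FALSE]
  m <- m[!unaligned]
  feats <- vapply(strsplit(alignments$features[m], ","),
                  function(f) paste(sort(unique(f)), collapse = ","),
                  character(1))
  data.frame(read_id = use$read_id, cell = use$cell, umi = use$umi,
             features = feats,
             n_locations = as.integer(alignments$n_locations[m]),
             row.names = NULL)
}

#' Read an alignment table from TSV
#'
#' Expected columns: `read_id`, `features` (comma-joined), `n_locations`.
#' @param path file path.
#' @export
read_alignment_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character", features = "character"))
}

#' Read alignments from a SAM or BAM file
#'
#' Builds the tabular alignment format consumed by [ingest_alignments()]
#' from a coordinate-style alignment file: one row per aligned read, with
#' `features` the sorted distinct reference names the read hit and
#' `n_locations` the reported mapped-location count (the `NH` tag when
#' present, else the number of alignment records). Requires the Rsamtools
#' package; SAM input is converted on the fly.
#'
#' @param path SAM or BAM file path.
#' @return Data frame with columns `read_id`, `features`, `n_locations`.
#' @export
read_alignments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM alignments requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname"), tag = "NH"))[[1]]
  keep <- !is.na(b$rname)
  dt <- data.table::data.table(read_id = b$qname[keep],
                               rname = as.character(b$rname[keep]),
                               nh = if (is.null(b$tag$NH)) NA_integer_
                                    else b$tag$NH[keep])
  if (nrow(dt) == 0)
    return(data.frame(read_id = character(), features = character(),
                      n_locations = integer()))
  out <- dt[, .(features = paste(sort(unique(rname)), collapse = ","),
                n_locations = if (all(is.na(nh))) .N else max(nh, na.rm = TRUE)),
            by = "read_id"]
  as.data.frame(out)
}

#' Collapse UMIs with one-mismatch adjacency
#'
#' Builds a graph with an edge between observed UMIs at Hamming distance
#' at most `max_dist` and collapses each connected component into one
#' molecule. This implements the symmetric ("cluster") reading of
#' adjacency-based deduplication.
#'
#' @param umis character vector (multiset) of equal-length UMIs.
#' @param max_dist maximum Hamming distance for an edge (default 1; 0
#'   collapses only identical UMIs).
#' @return A list with `n` (number of components) and `representative`, a
#'   named character vector mapping each observed UMI to the
#'   lexicographically smallest member of its component.
#' @export
collapse_umis <- function(umis, max_dist = 1) {
  if (length(umis) == 0)
    return(list(n = 0L, representative = stats::setNames(character(), character())))
  if (length(unique(nchar(umis))) != 1) stop("mixed UMI lengths")
  uu <- sort(unique(umis))
  comp <- cpp_umi_components(uu, as.integer(max_dist))
  # uu is sorted, so the first member seen per component is the smallest
  rep_of_comp <- uu[!duplicated(comp)][order(unique(comp))]
  rep_map <- stats::setNames(rep_of_comp[comp], uu)
  list(n = max(comp), representative = rep_map)
}

# number of UMI components in one group (fast path for grouped counting)
n_umi_components <- function(umis, max_dist) {
  uu <- unique(umis)
  if (length(uu) <= 1L) return(length(uu))
  max(cpp_umi_components(uu, as.integer(max_dist)))
}

#' Build a raw expression matrix from feature assignments
#'
#' UMIs are collapsed within each (cell, feature-set) group with
#' [collapse_umis()]; each collapsed UMI then contributes unit mass split
#' equally across the distinct features it maps to (`weighting =
#' "fractional"`, the default), so total matrix mass equals the number of
#' collapsed UMIs. `weighting = "multiply"` instead weights each UMI by its
#' mapped-location count, the literal reading of location-weighted counts.
#'
#' @param assignments a feature-assignment data frame.
#' @param library_kind `"smallRNA"` or `"mRNA"`.
#' @param weighting `"fractional"` or `"multiply"`.
#' @param collapse_max_dist Hamming radius for UMI collapsing (default 1).
#' @return An [expression_matrix()] with `normalization = "raw"`.
#' @export
count_expression <- function(assignments,
                             library_kind = c("smallRNA", "mRNA"),
                             weighting = c("fractional", "multiply"),
                             collapse_max_dist = 1) {
  library_kind <- match.arg(library_kind)
  weighting <- match.arg(weighting)
  if (nrow(assignments) == 0) stop("no feature assignments to count")
  dt <- data.table::as.data.table(assignments)
  md <- as.integer(collapse_max_dist)
  grp <- dt[, .(n_comp = n_umi_components(umi, md),
                k = n_locations[1L]),
            by = c("cell", "features")]
  feat_lists <- strsplit(grp$features, ",", fixed = TRUE)
  nf <- lengths(feat_lists)
  w <- if (weighting == "fractional") 1 else grp$k
  mass <- rep(grp$n_comp * w / nf, nf)
  trip <- data.table::data.table(
    cell = rep(grp$cell, nf),
    feature = unlist(feat_lists),
    mass = mass)
  trip <- trip[, .(mass = sum(mass)), by = c("cell", "feature")]
  cells <- sort(unique(assignments$cell))
  features <- sort(unique(trip$feature))
  values <- Matrix::sparseMatrix(
    i = match(trip$cell, cells), j = match(trip$feature, features),
    x = trip$mass, dims = c(length(cells), length(features)),
    dimnames = list(cells, features))
  expression_matrix(values, library_kind = library_kind, normalization = "raw")
}

#' Per-cell quality summary
#'
#' @param x an [expression_matrix()] (raw).
#' @param tagged optional tagged-read data frame to add per-cell read
#'   counts.
#' @return Data frame with columns `cell`, `umi_mass`, `n_features` and,
#'   when `tagged` is given, `n_reads`.
#' @export
cell_qc <- function(x, tagged = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  out <- data.frame(cell = rownames(x$values),
                    umi_mass = Matrix::rowSums(x$values),
                    n_features = Matrix::rowSums(x$values > 0),
                    row.names = NULL)
  if (!is.null(tagged)) {
    reads <- table(tagged$cell[tagged$status == "assigned"])
    out$n_reads <- as.integer(reads[out$cell])
    out$n_reads[is.na(out$n_reads)] <- 0L
  }
  out
}

#' Log-normalize a raw matrix per cell
#'
#' Each value v in a cell with raw total T becomes `ln(1 + v * scale / T)`.
#' Zero stays zero, and scaling all counts of a cell by a constant leaves
#' the result unchanged. Cells with zero total are dropped with a warning
#' (an error in strict mode). Re-normalizing is rejected.
#'
#' @param x an [expression_matrix()] with `normalization = "raw"`.
#' @param scale_factor library-size scale (default 10000).
#' @param strict error instead of dropping zero-total cells.
#' @return An [expression_matrix()] with `normalization = "lognorm"`.
#' @export
normalize_lognorm <- function(x, scale_factor = 1e4, strict = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$normalization != "raw")
    stop("matrix is already normalized (", x$normalization, ")")
  totals <- Matrix::rowSums(x$values)
  zero <- totals == 0
  if (any(zero)) {
    if (strict) stop("cells with zero total: ",
                     paste(utils::head(rownames(x$values)[zero], 3), collapse = ", "))
    warning(sprintf("dropping %d cells with zero total", sum(zero)))
  }
  v <- x$values[!zero, , drop = FALSE]
  totals <- totals[!zero]
  v <- Matrix::Diagonal(x = scale_factor / totals) %*% v
  v <- methods::as(methods::as(v, "generalMatrix"), "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- list(rownames(x$values)[!zero], colnames(x$values))
  out <- expression_matrix(v, library_kind = x$library_kind,
                           normalization = "raw")
  out$normalization <- "lognorm"
  out
}

#' Log2 reads-per-million transform of an aggregated profile
#'
#' `v -> log2(1 + v * 1e6 / sum(v))`; the pseudocount keeps zeros at zero
#' and the per-million scaling makes the result invariant to global depth.
#'
#' @param profile nonnegative numeric vector of aggregated counts.
#' @return Numeric vector of log2-RPM values.
#' @export
normalize_log2rpm <- function(profile) {
  total <- sum(profile)
  if (total <= 0) stop("profile total must be positive")
  log2(1 + profile * 1e6 / total)
}

#' Average expression profiles within groups
#'
#' @param x an [expression_matrix()] (any normalization).
#' @param labels named character vector mapping every cell in `x` to a
#'   group label.
#' @return A dense group x feature matrix with groups in sorted order.
#' @export
aggregate_by_group <- function(x, labels) {
  stopifnot(inherits(x, "expression_matrix"))
  cells <- rownames(x$values)
  miss <- setdiff(cells, names(labels))
  if (length(miss))
    stop("label map missing cells: ", paste(utils::head(miss, 3), collapse = ", "))
  lab <- labels[cells]
  groups <- sort(unique(lab))
  empty <- setdiff(unique(labels), lab)
  if (length(empty))
    stop("empty group: ", empty[1])
  out <- matrix(0, length(groups), ncol(x$values),
                dimnames = list(groups, colnames(x$values)))
  for (g in groups) {
    rows <- which(lab == g)
    out[g, ] <- Matrix::colMeans(x$values[rows, , drop = FALSE])
  }
  out
}

#' Keep the most highly expressed features of a group profile matrix
#'
#' Features are ranked by total expression summed across groups; ties at
#' the rank boundary are broken lexicographically by feature id.
#'
#' @param m group x feature matrix.
#' @param n number of features to keep (all features if `n` exceeds the
#'   feature count). Conventional defaults are 200 for miRNA and 2500 for
#'   mRNA profiles.
#' @return The reduced matrix, original column order preserved.
#' @export
select_top_expressed <- function(m, n) {
  stopifnot(n >= 1)
  totals <- colSums(m)
  ord <- order(-totals, colnames(m))
  keep <- sort(ord[seq_len(min(n, ncol(m)))])
  m[, keep, drop = FALSE]
}

#' Write / read an expression matrix as MatrixMarket plus sidecars
#'
#' Writes `matrix.mtx` (cells x features), `cells.tsv`, `features.tsv` and
#' `meta.json` (library kind and normalization state) under `dir`.
#'
#' @param x an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @export
write_expression_matrix <- function(x, dir) {
  stopifnot(inherits(x, "expression_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$values, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$values), file.path(dir, "cells.tsv"))
  writeLines(colnames(x$values), file.path(dir, "features.tsv"))
  jsonlite::write_json(list(library_kind = x$library_kind,
                            normalization = x$normalization),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(dir) {
  v <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  dimnames(v) <- list(readLines(file.path(dir, "cells.tsv")),
                      readLines(file.path(dir, "features.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  out <- expression_matrix(v, library_kind = meta$library_kind,
                           normalization = "raw")
  out$normalization <- meta$normalization
  out
}
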