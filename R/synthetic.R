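# Seeded synthetic data: expression matrices and raw reads with the
# structural assumptions the pipeline relies on (dual-index barcodes, UMIs,
# adapter-flanked small-RNA inserts, sequencing errors, multimapping, and
# planted miRNA -> target repression), plus ground truth for every stage.

random_seqs <- function(n, len) {
  if (n == 0) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, split(m, col(m)))
}

# n sequences with pairwise Hamming distance >= min_dist (rejection sampling)
distant_seqs <- function(n, len, min_dist) {
  repeat {
    s <- unique(random_seqs(n * 2, len))
    keep <- character(0)
    for (x in s) {
      if (length(keep) == 0 ||
          all(cpp_assign_barcodes(x, keep, min_dist - 1L) == 0L))
        keep <- c(keep, x)
      if (length(keep) == n) return(keep)
    }
  }
}

#' Define a synthetic co-profiling scenario
#'
#' A scenario fixes everything the simulator needs: per-type expression
#' programs for miRNA and mRNA, planted repression links, dual-index
#' barcodes, reference sequences, read layouts, library-size and error
#' parameters, and a seed. The same scenario always generates identical
#' data.
#'
#' Defaults emulate a four-type mixture profiled at roughly 100K small-RNA
#' and 200K mRNA reads: 4 x 100 cells, 96 eight-nt indices combined into
#' dual-index barcodes, 8-nt UMIs, negative-binomial counts around
#' per-type programs, 0.5% per-base substitution error, a handful of
#' miRNA family members sharing a mature sequence (multimapping), and one
#' planted miRNA whose targets are repressed to 0.25x in the miRNA-high
#' cell type.
#'
#' @param n_types number of cell types.
#' @param n_cells_per_type cells per type.
#' @param type_names type labels.
#' @param n_mirna,n_mrna feature counts per modality.
#' @param n_signature_mirna,n_signature_mrna per-type signature feature
#'   counts (disjoint blocks).
#' @param signature_fold per-type expression fold-up of signature features
#'   in their own type, recycled over types. The unequal defaults mirror
#'   real mixtures, where cell types differ in distinctiveness, and keep
#'   the leading ordination axes from being rotationally degenerate.
#' @param repression list with `n_targets` and `factor` (strictly in
#'   (0,1)); the planted miRNA is the first signature miRNA of the first
#'   type, its targets drawn from well-expressed non-signature mRNAs, and
#'   target means in that type are multiplied by `factor`. `NULL` plants
#'   nothing.
#' @param libsize_mirna,libsize_mrna log-normal (meanlog, sdlog) of
#'   per-cell molecule counts.
#' @param dispersion negative-binomial size parameter.
#' @param error_rate per-base substitution probability in simulated reads.
#' @param n_indices,index_length dual-index pool (pairwise Hamming >= 3).
#' @param umi_length UMI length (nt).
#' @param mirna_length mature miRNA reference length (nt).
#' @param n_multimap_pairs miRNA id pairs sharing one mature sequence.
#' @param mrna_multimap_rate fraction of mRNA reads reported at multiple
#'   genomic locations (two genes, three locations).
#' @param distinct_umis draw UMIs pairwise Hamming >= 2 within each
#'   (cell, feature) group, making collapse lossless.
#' @param adapter3 small-RNA 3' adapter.
#' @param mirna_names,programs optional overrides: custom miRNA ids and a
#'   list with `mirna` / `mrna` per-type program weight matrices.
#' @param seed integer seed; all generation is deterministic given it.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_types = 4,
                               n_cells_per_type = 100,
                               type_names = paste0("type", seq_len(n_types)),
                               n_mirna = 220, n_mrna = 2600,
                               n_signature_mirna = 25, n_signature_mrna = 300,
                               signature_fold = c(8, 6, 5, 4),
                               repression = list(n_targets = 40, factor = 0.25),
                               libsize_mirna = c(meanlog = log(250), sdlog = 0.3),
                               libsize_mrna = c(meanlog = log(500), sdlog = 0.3),
                               dispersion = 2,
                               error_rate = 0.005,
                               n_indices = 96, index_length = 8,
                               umi_length = 8,
                               mirna_length = 22,
                               n_multimap_pairs = 8,
                               mrna_multimap_rate = 0.05,
                               distinct_umis = FALSE,
                               adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                               mirna_names = NULL,
                               programs = NULL,
                               seed = 1L) {
  stopifnot(n_types >= 2, n_cells_per_type >= 1,
            length(type_names) == n_types)
  if (!is.null(repression))
    stopifnot(repression$factor > 0, repression$factor < 1)
  n_cells <- n_types * n_cells_per_type
  mirna_ids <- mirna_names %||% sprintf("miR-s%03d", seq_len(n_mirna))
  stopifnot(length(mirna_ids) == n_mirna)
  mrna_ids <- sprintf("gene%04d", seq_len(n_mrna))

  with_seed(seed, {
    # dual-index pool and per-cell barcodes (index pair concatenated)
    idx <- distant_seqs(n_indices, index_length, 3L)
    combos <- expand.grid(i1 = seq_len(n_indices), i2 = seq_len(n_indices))
    if (n_cells > nrow(combos)) stop("too many cells for the index pool")
    combos <- combos[seq_len(n_cells), ]
    cell_barcodes <- paste0(idx[combos$i1], idx[combos$i2])

    # mature miRNA reference; multimap pairs share a sequence
    ref <- stats::setNames(random_seqs(n_mirna, mirna_length), mirna_ids)
    if (n_multimap_pairs > 0) {
      # pair up trailing non-signature miRNAs so planted structure is intact
      pool <- seq(n_mirna - 2 * n_multimap_pairs + 1, n_mirna)
      for (p in seq_len(n_multimap_pairs)) {
        a <- pool[2 * p - 1]; b <- pool[2 * p]
        ref[b] <- ref[a]
      }
    }
    mrna_seqs <- stats::setNames(random_seqs(n_mrna, 36L), mrna_ids)

    # per-type expression programs (weights; rows normalized at simulation)
    if (is.null(programs)) {
      base_mirna <- stats::rgamma(n_mirna, shape = 0.6, rate = 1) + 0.02
      base_mrna <- stats::rgamma(n_mrna, shape = 0.6, rate = 1) + 0.02
      prog_mirna <- matrix(rep(base_mirna, each = n_types), n_types,
                           dimnames = list(type_names, mirna_ids))
      prog_mrna <- matrix(rep(base_mrna, each = n_types), n_types,
                          dimnames = list(type_names, mrna_ids))
      fold <- rep_len(signature_fold, n_types)
      for (t in seq_len(n_types)) {
        sig_mi <- seq((t - 1) * n_signature_mirna + 1, t * n_signature_mirna)
        sig_mr <- seq((t - 1) * n_signature_mrna + 1, t * n_signature_mrna)
        prog_mirna[t, sig_mi] <- prog_mirna[t, sig_mi] * fold[t]
        prog_mrna[t, sig_mr] <- prog_mrna[t, sig_mr] * fold[t]
      }
    } else {
      prog_mirna <- programs$mirna
      prog_mrna <- programs$mrna
      stopifnot(all(dim(prog_mirna) == c(n_types, n_mirna)),
                all(dim(prog_mrna) == c(n_types, n_mrna)))
      dimnames(prog_mirna) <- list(type_names, mirna_ids)
      dimnames(prog_mrna) <- list(type_names, mrna_ids)
    }

    links <- NULL
    if (!is.null(repression)) {
      # plant on the most expressed type-1 signature miRNA so the link sits
      # among the highest-expressed features used for ordination
      sig1 <- seq_len(min(n_signature_mirna, n_mirna))
      planted_mirna <- mirna_ids[sig1[which.max(prog_mirna[1, sig1])]]
      nonsig <- setdiff(seq_len(n_mrna),
                        seq_len(min(n_types * n_signature_mrna, n_mrna)))
      expressed <- nonsig[prog_mrna[1, nonsig] >=
                            stats::median(prog_mrna[1, nonsig])]
      tgt <- sort(sample(expressed, min(repression$n_targets,
                                        length(expressed))))
      prog_mrna[1, tgt] <- prog_mrna[1, tgt] * repression$factor
      links <- data.frame(mirna = planted_mirna,
                          target = mrna_ids[tgt],
                          factor = repression$factor,
                          high_type = type_names[1])
    }

    structure(list(
      n_types = n_types, n_cells_per_type = n_cells_per_type,
      type_names = type_names,
      cells = data.frame(cell = cell_barcodes,
                         type = rep(type_names, each = n_cells_per_type)),
      whitelist = barcode_whitelist(cell_barcodes),
      index_pool = idx,
      mirna_ids = mirna_ids, mrna_ids = mrna_ids,
      reference = ref, mrna_seqs = mrna_seqs,
      prog_mirna = prog_mirna, prog_mrna = prog_mrna,
      links = links,
      libsize_mirna = libsize_mirna, libsize_mrna = libsize_mrna,
      dispersion = dispersion, error_rate = error_rate,
      umi_length = as.integer(umi_length),
      mirna_length = as.integer(mirna_length),
      mrna_multimap_rate = mrna_multimap_rate,
      distinct_umis = distinct_umis,
      adapter3 = adapter3,
      layout_smallrna = read_layout(
        barcode_start = 0, barcode_length = 2L * index_length,
        umi_start = 2L * index_length, umi_length = umi_length,
        adapter3 = adapter3, library_kind = "smallRNA",
        min_insert_length = 15),
      layout_mrna = read_layout(
        barcode_start = 0, barcode_length = 2L * index_length,
        umi_start = 2L * index_length, umi_length = umi_length,
        adapter3 = NULL, library_kind = "mRNA",
        min_insert_length = 15),
      seed = as.integer(seed)),
      class = "synthetic_scenario")
  })
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scenario: %d types x %d cells, %d miRNAs, ",
                     "%d mRNAs, error %.3g, seed %d\n"),
              x$n_types, x$n_cells_per_type, length(x$mirna_ids),
              length(x$mrna_ids), x$error_rate, x$seed))
  invisible(x)
}

#' Marker-panel scenario for classifier tests
#'
#' Six subpopulations carrying the conserved marker panel (lymphoid,
#' myeloid, endothelial, stromal, epithelial, alveolar) plus a tumor
#' population expressing the exclusion marker miR-135b, which no other
#' type expresses at all.
#'
#' @param n_cells_per_type cells per subpopulation.
#' @param n_mirna total miRNA features (markers plus filler).
#' @param seed integer seed.
#' @param ... passed on to [synthetic_scenario()].
#' @return A `synthetic_scenario` whose `cells$type` holds the true labels.
#' @export
marker_scenario <- function(n_cells_per_type = 60, n_mirna = 60, seed = 1L,
                            ...) {
  markers <- c("miR-142", "miR-150", "miR-223", "miR-126", "miR-199",
               "miR-200", "miR-375", "miR-135b")
  types <- c("lymphoid", "myeloid", "endothelial", "stromal", "epithelial",
             "alveolar", "tumor")
  rules <- default_marker_rules()
  stopifnot(n_mirna > length(markers))
  filler <- sprintf("miR-f%03d", seq_len(n_mirna - length(markers)))
  mirna_ids <- c(markers, filler)
  n_types <- length(types)

  prog <- matrix(0.05, n_types, n_mirna, dimnames = list(types, mirna_ids))
  prog[, "miR-135b"] <- 0                       # exclusion marker: tumor only
  for (t in names(rules)) prog[t, rules[[t]]] <- 12
  prog["tumor", "miR-135b"] <- 12
  n_mrna <- 400
  prog_mrna <- matrix(1, n_types, n_mrna)

  synthetic_scenario(n_types = n_types, n_cells_per_type = n_cells_per_type,
                     type_names = types, n_mirna = n_mirna, n_mrna = n_mrna,
                     mirna_names = mirna_ids,
                     programs = list(mirna = prog, mrna = prog_mrna),
                     repression = NULL, n_multimap_pairs = 0,
                     seed = seed, ...)
}

#' Draw ground-truth expression matrices for a scenario
#'
#' Per-cell counts are negative-binomial around the cell type's program
#' scaled to a log-normal library size; planted repression is part of the
#' program. Deterministic given the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return List with `mirna` and `mrna` raw [expression_matrix()] objects,
#'   `labels` (cell -> true type), `links` (planted repression table) and
#'   `libsizes`.
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed + 1000L, {
    cells <- scenario$cells
    n <- nrow(cells)
    draw <- function(prog, libsize, ids) {
      p <- prog / rowSums(prog)                  # per-type proportions
      ls <- pmax(10, round(stats::rlnorm(n, libsize[["meanlog"]],
                                         libsize[["sdlog"]])))
      mu <- p[cells$type, , drop = FALSE] * ls
      cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                   size = scenario$dispersion),
                    nrow = n, dimnames = list(cells$cell, ids))
      list(counts = cnt, libsizes = ls)
    }
    mi <- draw(scenario$prog_mirna, scenario$libsize_mirna, scenario$mirna_ids)
    mr <- draw(scenario$prog_mrna, scenario$libsize_mrna, scenario$mrna_ids)
    list(mirna = expression_matrix(mi$counts, "smallRNA", "raw"),
         mrna = expression_matrix(mr$counts, "mRNA", "raw"),
         labels = stats::setNames(cells$type, cells$cell),
         links = scenario$links,
         libsizes = list(mirna = mi$libsizes, mrna = mr$libsizes))
  })
}

# UMIs for one (cell, feature) group; pairwise Hamming >= 2 when distinct
draw_group_umis <- function(g, len, distinct) {
  if (!distinct) return(random_seqs(g, len))
  repeat {
    u <- random_seqs(g, len)
    uu <- unique(u)
    if (length(uu) == g && max(cpp_umi_components(uu, 1L)) == g) return(u)
  }
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs[1])
  N <- length(seqs)
  k <- stats::rbinom(1, N * L, rate)
  if (k == 0) return(seqs)
  pos <- sample.int(N * L, k)
  ri <- (pos - 1L) %/% L + 1L
  pp <- (pos - 1L) %% L + 1L
  bases <- c("A", "C", "G", "T")
  for (t in seq_len(k)) {
    cur <- substr(seqs[ri[t]], pp[t], pp[t])
    substr(seqs[ri[t]], pp[t], pp[t]) <- sample(setdiff(bases, cur), 1)
  }
  seqs
}

#' Emit raw reads (and truth tables) for simulated expression
#'
#' Every truth count becomes one molecule with a random UMI and one read
#' laid out as barcode + UMI + insert per the scenario's read layouts.
#' Small-RNA inserts are the mature reference sequence followed by the 3'
#' adapter; mRNA inserts are transcript prefixes, with a truth alignment
#' table recording feature and mapped-location count per read (a
#' `mrna_multimap_rate` fraction is reported at three locations covering
#' two genes). Substitution errors hit every base at the scenario rate.
#'
#' @param truth output of [simulate_expression()].
#' @param scenario the same [synthetic_scenario()].
#' @param dir if non-`NULL`, write `smallrna.fastq.gz`, `mrna.fastq.gz`
#'   and truth TSVs there.
#' @return List with `reads_smallrna`, `reads_mrna` (read data frames),
#'   `truth_smallrna`, `truth_mrna` (read_id, cell, umi, feature),
#'   `alignments` (mRNA truth alignment table), and `paths` when `dir` is
#'   given.
#' @export
simulate_reads <- function(truth, scenario, dir = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed + 2000L, {
    mk_molecules <- function(em) {
      tr <- Matrix::summary(em$values)
      cells <- rownames(em$values)[tr$i]
      feats <- colnames(em$values)[tr$j]
      n <- as.integer(tr$x)
      dt <- data.table::data.table(cell = rep(cells, n),
                                   feature = rep(feats, n))
      dt[, umi := draw_group_umis(.N, scenario$umi_length,
                                  scenario$distinct_umis),
         by = c("cell", "feature")]
      dt
    }

    # small RNA library
    mol_s <- mk_molecules(truth$mirna)
    mol_s <- mol_s[sample.int(nrow(mol_s))]       # shuffle read order
    mol_s[, read_id := sprintf("sr%08d", .I)]
    seq_s <- paste0(mol_s$cell, mol_s$umi,
                    scenario$reference[mol_s$feature], scenario$adapter3)
    seq_s <- inject_errors(seq_s, scenario$error_rate)
    reads_s <- data.frame(read_id = mol_s$read_id, seq = seq_s,
                          qual = strrep("I", nchar(seq_s)))
    truth_s <- data.frame(read_id = mol_s$read_id, cell = mol_s$cell,
                          umi = mol_s$umi, feature = mol_s$feature)

    # mRNA library
    mol_m <- mk_molecules(truth$mrna)
    mol_m <- mol_m[sample.int(nrow(mol_m))]
    mol_m[, read_id := sprintf("mr%08d", .I)]
    seq_m <- paste0(mol_m$cell, mol_m$umi, scenario$mrna_seqs[mol_m$feature])
    seq_m <- inject_errors(seq_m, scenario$error_rate)
    reads_m <- data.frame(read_id = mol_m$read_id, seq = seq_m,
                          qual = strrep("I", nchar(seq_m)))
    truth_m <- data.frame(read_id = mol_m$read_id, cell = mol_m$cell,
                          umi = mol_m$umi, feature = mol_m$feature)

    multi <- stats::runif(nrow(mol_m)) < scenario$mrna_multimap_rate
    partner_idx <- match(mol_m$feature, scenario$mrna_ids) %%
      length(scenario$mrna_ids) + 1L
    partner <- scenario$mrna_ids[partner_idx]
    feats <- mol_m$feature
    if (any(multi)) {
      a <- mol_m$feature[multi]; b <- partner[multi]
      feats[multi] <- ifelse(a < b, paste(a, b, sep = ","),
                             paste(b, a, sep = ","))
    }
    alignments <- data.frame(read_id = mol_m$read_id, features = feats,
                             n_locations = ifelse(multi, 3L, 1L))

    out <- list(reads_smallrna = reads_s, reads_mrna = reads_m,
                truth_smallrna = truth_s, truth_mrna = truth_m,
                alignments = alignments)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        smallrna_fastq = file.path(dir, "smallrna.fastq.gz"),
        mrna_fastq = file.path(dir, "mrna.fastq.gz"),
        truth_smallrna = file.path(dir, "truth_smallrna.tsv"),
        truth_mrna = file.path(dir, "truth_mrna.tsv"),
        alignments = file.path(dir, "alignments.tsv"),
        whitelist = file.path(dir, "whitelist.txt"))
      write_fastq(reads_s, paths$smallrna_fastq)
      write_fastq(reads_m, paths$mrna_fastq)
      utils::write.table(truth_s, paths$truth_smallrna, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(truth_m, paths$truth_mrna, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(alignments, paths$alignments, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_barcode_whitelist(scenario$whitelist, paths$whitelist)
      out$paths <- paths
    }
    out
  })
}

#' Run the full pipeline on a synthetic scenario and score it
#'
#' Simulates expression and reads, demultiplexes both libraries, matches
#' small-RNA inserts against the scenario's reference, ingests the truth
#' alignment table for the mRNA library, builds raw matrices, and compares
#' everything against ground truth.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir optional directory for FASTQ round-tripping; default a
#'   temporary directory (reads are always written and re-read, so the
#'   FASTQ path is exercised end to end).
#' @param max_mismatch barcode correction tolerance.
#' @return List with the recovered matrices (`mirna`, `mrna`), `truth`,
#'   `tagged` (per-library tagged-read tables), and `report`, a list of
#'   truth-comparison metrics: `barcode_accuracy` (fraction of uniquely
#'   correctable reads assigned to the true cell), `ambiguous_assigned`
#'   (must be 0), `cor_mirna` / `cor_mrna` (truth-vs-recovered count
#'   correlations over matched cells and features), and
#'   `max_abs_diff_mirna` / `max_abs_diff_mrna`.
#' @export
run_end_to_end <- function(scenario, dir = NULL, max_mismatch = 1) {
  truth <- simulate_expression(scenario)
  dir <- dir %||% file.path(tempfile("comir_sim_"))
  sim <- simulate_reads(truth, scenario, dir = dir)

  reads_s <- read_fastq(sim$paths$smallrna_fastq)
  reads_m <- read_fastq(sim$paths$mrna_fastq)
  tagged_s <- demux_reads(reads_s, scenario$layout_smallrna,
                          scenario$whitelist, max_mismatch = max_mismatch)
  tagged_m <- demux_reads(reads_m, scenario$layout_mrna,
                          scenario$whitelist, max_mismatch = max_mismatch)

  asg_s <- assign_smallrna_features(tagged_s, scenario$reference)
  em_s <- count_expression(asg_s, library_kind = "smallRNA")
  asg_m <- ingest_alignments(sim$alignments, tagged_m)
  em_m <- count_expression(asg_m, library_kind = "mRNA")

  report <- c(
    score_demux(rbind(cbind(tagged_s, true_cell = sim$truth_smallrna$cell[
                        match(tagged_s$read_id, sim$truth_smallrna$read_id)]),
                      cbind(tagged_m, true_cell = sim$truth_mrna$cell[
                        match(tagged_m$read_id, sim$truth_mrna$read_id)]))),
    list(cor_mirna = matrix_recovery(em_s, truth$mirna)$cor,
         cor_mrna = matrix_recovery(em_m, truth$mrna)$cor,
         max_abs_diff_mirna = matrix_recovery(em_s, truth$mirna)$max_abs_diff,
         max_abs_diff_mrna = matrix_recovery(em_m, truth$mrna)$max_abs_diff))
  list(mirna = em_s, mrna = em_m, truth = truth,
       tagged = list(smallrna = tagged_s, mrna = tagged_m),
       assignments = list(smallrna = asg_s, mrna = asg_m),
       report = report)
}

# demux scoring: barcode-correctable reads must land in the true cell
score_demux <- function(tagged) {
  structural <- tagged$status %in% c("assigned", "unassigned_barcode",
                                     "ambiguous_barcode")
  t2 <- tagged[structural, ]
  d <- cpp_hamming_to(t2$cell_barcode, t2$true_cell)
  correctable <- d <= 1 & t2$status != "ambiguous_barcode"
  acc <- mean(t2$cell[correctable] == t2$true_cell[correctable])
  list(barcode_accuracy = acc,
       n_correctable = sum(correctable),
       ambiguous_assigned = sum(t2$status == "ambiguous_barcode" &
                                  !is.na(t2$cell)))
}

# align recovered matrix to truth and compare entries
matrix_recovery <- function(recovered, truth) {
  cells <- intersect(rownames(truth$values), rownames(recovered$values))
  feats <- intersect(colnames(truth$values), colnames(recovered$values))
  a <- as.matrix(truth$values[cells, feats, drop = FALSE])
  b <- matrix(0, length(cells), length(feats), dimnames = list(cells, feats))
  b[, ] <- as.matrix(recovered$values[cells, feats, drop = FALSE])
  # cells or features lost entirely count as zeros in the recovered matrix
  full_b <- matrix(0, nrow(truth$values), ncol(truth$values),
                   dimnames = dimnames(truth$values))
  full_b[cells, feats] <- b
  a_full <- as.matrix(truth$values)
  list(cor = stats::cor(as.vector(a_full), as.vector(full_b)),
       max_abs_diff = max(abs(a_full - full_b)))
}
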