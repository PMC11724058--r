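#' Read a FASTQ file into a data frame
#'
#' Uses Biostrings for parsing; gzip-compressed files are handled
#' transparently.
#'
#' @param path path to a FASTQ (or FASTQ.gz) file.
#' @return A data frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL)
}

#' Write reads to a FASTQ file
#'
#' @param reads data frame with columns `read_id`, `seq`, `qual`.
#' @param path output path; a `.gz` suffix triggers compression.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Slice raw reads into cell barcode, UMI and insert
#'
#' Decomposes each read according to a [read_layout()]. Reads too short to
#' contain the structural segments, or whose insert is shorter than the
#' layout's `min_insert_length`, get status `too_short`; all others get the
#' intermediate status `parsed` (finalized by [demux_reads()]).
#'
#' @param reads data frame with columns `read_id`, `seq`, `qual`.
#' @param layout a [read_layout()].
#' @return A tagged-read data frame with columns `read_id`, `cell_barcode`,
#'   `umi`, `insert`, `insert_quality`, `status`.
#' @export
parse_reads <- function(reads, layout) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq", "qual") %in% names(reads)))
  bad_len <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad_len))
    stop("malformed FASTQ record (sequence/quality length mismatch): ",
         reads$read_id[which(bad_len)[1]])
  bad_id <- is.na(reads$read_id) | !nzchar(reads$read_id)
  if (any(bad_id))
    stop("malformed FASTQ record: empty read id at position ", which(bad_id)[1])

  n <- nrow(reads)
  len <- nchar(reads$seq)
  need <- max(layout$barcode_start + layout$barcode_length,
              layout$umi_start + layout$umi_length)
  ins_from <- insert_start(layout) + 1L

  barcode <- substr(reads$seq, layout$barcode_start + 1L,
                    layout$barcode_start + layout$barcode_length)
  umi <- substr(reads$seq, layout$umi_start + 1L,
                layout$umi_start + layout$umi_length)
  insert <- substr(reads$seq, ins_from, len)
  insert_quality <- substr(reads$qual, ins_from, len)

  status <- rep("parsed", n)
  status[len < need] <- "too_short"
  status[status == "parsed" & nchar(insert) < layout$min_insert_length] <- "too_short"

  data.frame(read_id = reads$read_id, cell_barcode = barcode, umi = umi,
             insert = insert, insert_quality = insert_quality,
             status = status, row.names = NULL)
}

#' Assign observed barcodes to whitelist entries with mismatch correction
#'
#' An exact match wins immediately; otherwise the unique whitelist entry
#' within Hamming distance `max_mismatch` is taken. No entry in range gives
#' `NA` with status `unassigned_barcode`; two or more equidistant minima
#' give `NA` with status `ambiguous_barcode`.
#'
#' @param observed character vector of observed barcodes (all of whitelist
#'   length).
#' @param whitelist a [barcode_whitelist()].
#' @param max_mismatch 0 or 1 tolerated substitutions.
#' @return A data frame with columns `cell` (matched barcode or `NA`) and
#'   `status` (`assigned`, `unassigned_barcode`, `ambiguous_barcode`).
#' @export
assign_barcodes <- function(observed, whitelist, max_mismatch = 1) {
  stopifnot(inherits(whitelist, "barcode_whitelist"), max_mismatch %in% 0:1)
  if (length(observed) == 0)
    return(data.frame(cell = character(), status = character()))
  if (any(nchar(observed) != whitelist$length))
    stop("observed barcode length differs from whitelist length ",
         whitelist$length)
  idx <- cpp_assign_barcodes(observed, whitelist$barcodes, as.integer(max_mismatch))
  cell <- ifelse(idx > 0, whitelist$barcodes[pmax(idx, 1L)], NA_character_)
  status <- rep("assigned", length(idx))
  status[idx == 0L] <- "unassigned_barcode"
  status[idx == -1L] <- "ambiguous_barcode"
  data.frame(cell = cell, status = status, row.names = NULL)
}

#' Trim the 3' adapter from small-RNA inserts
#'
#' Removes the suffix starting at the leftmost occurrence of an adapter
#' prefix of length at least `min_overlap` with at most `max_err`
#' mismatches. Inserts without an adapter occurrence are returned unchanged
#' and flagged `untrimmed`.
#'
#' @param inserts character vector of insert sequences.
#' @param adapter3 adapter sequence.
#' @param min_overlap minimum adapter-prefix overlap (nt).
#' @param max_err maximum substitutions tolerated in the overlap.
#' @return A data frame with columns `insert` (trimmed) and `trimmed`
#'   (logical).
#' @export
trim_adapter3 <- function(inserts, adapter3, min_overlap = 5, max_err = 1) {
  stopifnot(is.character(adapter3), nzchar(adapter3), min_overlap >= 1)
  if (length(inserts) == 0)
    return(data.frame(insert = character(), trimmed = logical()))
  pos <- cpp_trim_positions(inserts, adapter3, as.integer(min_overlap),
                            as.integer(max_err))
  trimmed <- pos >= 0L
  out <- inserts
  out[trimmed] <- substr(inserts[trimmed], 1L, pos[trimmed])
  data.frame(insert = out, trimmed = trimmed, row.names = NULL)
}

#' Demultiplex parsed reads against a whitelist
#'
#' Runs the full per-read preprocessing chain: structural slicing
#' ([parse_reads()]), 3' adapter trimming for small-RNA layouts
#' ([trim_adapter3()]), and barcode assignment ([assign_barcodes()]).
#' Every read ends in exactly one status class:
#' `assigned`, `unassigned_barcode`, `ambiguous_barcode`, `too_short`,
#' or `untrimmed` (small-RNA reads without an adapter occurrence).
#'
#' @param reads data frame with columns `read_id`, `seq`, `qual`.
#' @param layout a [read_layout()].
#' @param whitelist a [barcode_whitelist()].
#' @param max_mismatch barcode correction tolerance (0 or 1).
#' @param trim_min_overlap,trim_max_err adapter trimming parameters.
#' @param require_trimmed if `TRUE` (default for small-RNA layouts with an
#'   adapter), untrimmed reads are excluded from assignment.
#' @return A tagged-read data frame with columns `read_id`, `cell_barcode`,
#'   `umi`, `insert`, `insert_quality`, `cell`, `status`.
#' @export
demux_reads <- function(reads, layout, whitelist, max_mismatch = 1,
                        trim_min_overlap = 5, trim_max_err = 1,
                        require_trimmed = !is.null(layout$adapter3)) {
  tagged <- parse_reads(reads, layout)
  tagged$cell <- NA_character_

  ok <- tagged$status == "parsed"
  if (!is.null(layout$adapter3) && any(ok)) {
    tr <- trim_adapter3(tagged$insert[ok], layout$adapter3,
                        min_overlap = trim_min_overlap, max_err = trim_max_err)
    tagged$insert[ok] <- tr$insert
    tagged$insert_quality[ok] <- substr(tagged$insert_quality[ok], 1L,
                                        nchar(tr$insert))
    idx <- which(ok)
    if (require_trimmed)
      tagged$status[idx[!tr$trimmed]] <- "untrimmed"
    short <- nchar(tagged$insert[idx]) < layout$min_insert_length &
      tagged$status[idx] == "parsed"
    tagged$status[idx[short]] <- "too_short"
    ok <- tagged$status == "parsed"
  }

  if (any(ok)) {
    asg <- assign_barcodes(tagged$cell_barcode[ok], whitelist, max_mismatch)
    tagged$cell[ok] <- asg$cell
    tagged$status[ok] <- asg$status
  }
  n_stat <- table(tagged$status)
  message(sprintf("demux: %d reads; %s", nrow(tagged),
                  paste(sprintf("%s=%d", names(n_stat), n_stat), collapse = " ")))
  tagged
}

#' Uniformly subsample tagged reads
#'
#' Samples exactly `min(n, nrow(tagged))` reads without replacement,
#' deterministically for a given seed and input order; the caller's RNG
#' stream is left untouched.
#'
#' @param tagged a tagged-read data frame.
#' @param n number of reads to keep.
#' @param seed integer seed for this draw.
#' @return A subset of `tagged` in original row order.
#' @export
downsample_reads <- function(tagged, n, seed = 1L) {
  stopifnot(n >= 0)
  m <- nrow(tagged)
  if (n >= m) return(tagged)
  keep <- with_seed(seed, sort(sample.int(m, n)))
  tagged[keep, , drop = FALSE]
}

#' Per-status read counts
#' @param tagged a tagged-read data frame.
#' @return A data frame with columns `status` and `n`.
#' @export
status_summary <- function(tagged) {
  tab <- table(factor(tagged$status,
                      levels = c("assigned", "unassigned_barcode",
                                 "ambiguous_barcode", "too_short",
                                 "untrimmed")))
  data.frame(status = names(tab), n = as.integer(tab), row.names = NULL)
}

#' Write / read a tagged-read table as TSV
#' @param tagged a tagged-read data frame.
#' @param path file path.
#' @export
write_tagged_reads <- function(tagged, path) {
  utils::write.table(tagged, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tagged_reads
#' @export
read_tagged_reads <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
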