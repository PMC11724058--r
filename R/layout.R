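#' Describe where the cell barcode, UMI and insert live in a read
#'
#' A read layout declares the structural segments of a raw read: the cell
#' barcode (for dual-indexed designs, the two index segments concatenated
#' into one logical barcode), the UMI ("index tag"), and the insert, which
#' is everything after the last structural segment. Coordinates are 0-based
#' half-open.
#'
#' @param barcode_start 0-based offset of the cell barcode (nt).
#' @param barcode_length barcode length (nt).
#' @param umi_start 0-based offset of the UMI (nt).
#' @param umi_length UMI length (nt).
#' @param adapter3 3' adapter sequence to trim from small-RNA inserts;
#'   `NULL` for libraries without one (e.g. mRNA).
#' @param library_kind `"smallRNA"` or `"mRNA"`.
#' @param min_insert_length minimum usable insert length (nt) after slicing
#'   and adapter trimming; shorter reads are flagged `too_short`.
#' @return An object of class `read_layout`.
#' @examples
#' read_layout(barcode_length = 16, umi_start = 16, umi_length = 8,
#'             adapter3 = "TGGAATTCTCGGGTGCCAAGG", library_kind = "smallRNA")
#' @export
read_layout <- function(barcode_start = 0, barcode_length = 16,
                        umi_start = 16, umi_length = 8,
                        adapter3 = NULL,
                        library_kind = c("smallRNA", "mRNA"),
                        min_insert_length = 15) {
  library_kind <- match.arg(library_kind)
  stopifnot(barcode_length > 0, umi_length > 0,
            barcode_start >= 0, umi_start >= 0,
            min_insert_length >= 1)
  bc <- c(barcode_start, barcode_start + barcode_length)
  um <- c(umi_start, umi_start + umi_length)
  if (max(bc[1], um[1]) < min(bc[2], um[2]))
    stop("barcode and UMI segments overlap")
  if (!is.null(adapter3)) {
    adapter3 <- toupper(adapter3)
    if (!grepl("^[ACGT]+$", adapter3)) stop("adapter3 must be an ACGT string")
  }
  structure(
    list(barcode_start = as.integer(barcode_start),
         barcode_length = as.integer(barcode_length),
         umi_start = as.integer(umi_start),
         umi_length = as.integer(umi_length),
         adapter3 = adapter3,
         library_kind = library_kind,
         min_insert_length = as.integer(min_insert_length)),
    class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf("read_layout (%s): barcode [%d,%d), UMI [%d,%d), insert from %d",
              x$library_kind,
              x$barcode_start, x$barcode_start + x$barcode_length,
              x$umi_start, x$umi_start + x$umi_length, insert_start(x)))
  if (!is.null(x$adapter3)) cat(", adapter3", x$adapter3)
  cat("\n")
  invisible(x)
}

insert_start <- function(layout) {
  max(layout$barcode_start + layout$barcode_length,
      layout$umi_start + layout$umi_length)
}

#' Construct a cell-barcode whitelist
#'
#' @param barcodes character vector of equal-length ACGT barcodes.
#' @return An object of class `barcode_whitelist`.
#' @export
barcode_whitelist <- function(barcodes) {
  barcodes <- toupper(as.character(barcodes))
  if (length(barcodes) == 0) stop("empty whitelist")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in whitelist")
  lens <- unique(nchar(barcodes))
  if (length(lens) != 1) stop("whitelist barcodes differ in length")
  if (!all(grepl("^[ACGT]+$", barcodes))) stop("whitelist alphabet must be {A,C,G,T}")
  structure(list(barcodes = barcodes, length = as.integer(lens)),
            class = "barcode_whitelist")
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat(sprintf("barcode_whitelist: %d barcodes of length %d\n",
              length(x$barcodes), x$length))
  invisible(x)
}

#' Read a barcode whitelist from a plain-text file
#'
#' One barcode per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return A [barcode_whitelist()].
#' @export
read_barcode_whitelist <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  barcode_whitelist(lines)
}

#' Write a barcode whitelist
#' @param whitelist a [barcode_whitelist()].
#' @param path output file path.
#' @export
write_barcode_whitelist <- function(whitelist, path) {
  writeLines(whitelist$barcodes, path)
  invisible(path)
}
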