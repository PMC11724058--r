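#' Co-inertia analysis of paired group profiles
#'
#' Two-table ordination of miRNA and mRNA profiles measured on the same
#' groups (cell types or subpopulations). Columns of both tables are
#' centered (optionally scaled to unit variance), and the axes come from
#' the singular decomposition of the cross-product of the centered tables:
#' eigenvalues are the squared singular values, and each table's rows are
#' projected onto the common axes, giving a pair of coordinates per group.
#' The RV coefficient summarizes the global similarity of the two tables.
#'
#' Axis signs are fixed by making the largest-magnitude miRNA loading on
#' each axis positive, so results are reproducible across SVD backends.
#'
#' @param X group x miRNA matrix (rows aligned with `Y`).
#' @param Y group x mRNA matrix.
#' @param k number of axes to return (default 2).
#' @param preprocessing `"center"` (default) or `"center_scale"` for
#'   unit-variance columns; constant columns are left at zero when scaling.
#' @return An object of class `coinertia_result` with elements
#'   `eigenvalues` (all, nonincreasing), `row_scores_X`, `row_scores_Y`
#'   (group x k), `col_loadings_X` (miRNA x k), `col_loadings_Y`
#'   (mRNA x k), `rv`, `k`, `preprocessing`.
#' @export
coinertia_fit <- function(X, Y, k = 2,
                          preprocessing = c("center", "center_scale")) {
  preprocessing <- match.arg(preprocessing)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same groups (rows)")
  if (nrow(X) < 2) stop("need at least 2 groups")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("X and Y rows are not aligned")
  Xc <- center_table(X, preprocessing)
  Yc <- center_table(Y, preprocessing)
  C <- crossprod(Xc, Yc)                       # miRNA x mRNA cross-product
  s <- svd(C)
  eig <- s$d^2
  k <- min(k, sum(s$d > max(s$d[1], .Machine$double.eps) * 1e-12), ncol(X), ncol(Y))
  if (k < 1) stop("cross-product has no positive singular value")
  u <- s$u[, seq_len(k), drop = FALSE]
  v <- s$v[, seq_len(k), drop = FALSE]
  # sign convention: dominant miRNA loading positive on each axis
  for (a in seq_len(k)) {
    j <- which.max(abs(u[, a]))
    if (u[j, a] < 0) { u[, a] <- -u[, a]; v[, a] <- -v[, a] }
  }
  dimnames(u) <- list(colnames(X), paste0("Axis", seq_len(k)))
  dimnames(v) <- list(colnames(Y), paste0("Axis", seq_len(k)))
  rsx <- Xc %*% u
  rsy <- Yc %*% v
  structure(list(k = k, eigenvalues = eig,
                 row_scores_X = rsx, row_scores_Y = rsy,
                 col_loadings_X = u, col_loadings_Y = v,
                 rv = rv_coefficient(X, Y, preprocessing = preprocessing),
                 preprocessing = preprocessing),
            class = "coinertia_result")
}

#' @export
print.coinertia_result <- function(x, ...) {
  cat(sprintf(paste0("coinertia_result: %d axes, %d x %d features, RV = %.4f\n",
                     "eigenvalues: %s\n"),
              x$k, nrow(x$col_loadings_X), nrow(x$col_loadings_Y), x$rv,
              paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = " ")))
  invisible(x)
}

center_table <- function(M, preprocessing) {
  Mc <- sweep(M, 2, colMeans(M))
  if (preprocessing == "center_scale") {
    sdv <- sqrt(colSums(Mc^2) / nrow(Mc))
    sdv[sdv == 0] <- 1
    Mc <- sweep(Mc, 2, sdv, "/")
  }
  Mc
}

#' RV coefficient between two tables on the same groups
#'
#' Matrix correlation in \[0, 1\] between column-centered tables:
#' `RV = ||Yc'Xc||_F^2 / (||Xc'Xc||_F * ||Yc'Yc||_F)`. The numerator is
#' the total co-inertia (sum of co-inertia eigenvalues); the denominator
#' normalizes by each table's own total squared inertia.
#'
#' @param X,Y group x feature matrices with aligned rows.
#' @param preprocessing as in [coinertia_fit()].
#' @return Scalar in \[0, 1\].
#' @export
rv_coefficient <- function(X, Y, preprocessing = c("center", "center_scale")) {
  preprocessing <- match.arg(preprocessing)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same groups (rows)")
  Xc <- center_table(X, preprocessing)
  Yc <- center_table(Y, preprocessing)
  nx <- sum(crossprod(Xc)^2)
  ny <- sum(crossprod(Yc)^2)
  if (nx == 0) stop("X is constant after centering; RV undefined")
  if (ny == 0) stop("Y is constant after centering; RV undefined")
  sum(crossprod(Yc, Xc)^2) / sqrt(nx * ny)
}

#' Assign 2D coordinates to quadrants
#'
#' Sign pattern (+,+) is Q1, (-,+) Q2, (-,-) Q3, (+,-) Q4; zero counts as
#' positive. When each of four group centroids occupies its own quadrant,
#' `relabel_centroids` renames the quadrants after the groups.
#'
#' @param scores n x 2 coordinate matrix.
#' @param relabel_centroids optional 4 x 2 matrix of group centroids with
#'   rownames; quadrants are renamed by the group whose centroid falls in
#'   each (requires a bijection, else an error).
#' @return Character vector of quadrant (or group) labels.
#' @export
quadrant_assign <- function(scores, relabel_centroids = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("quadrant assignment needs exactly 2 axes")
  qx <- scores[, 1] >= 0
  qy <- scores[, 2] >= 0
  q <- ifelse(qx & qy, "Q1", ifelse(!qx & qy, "Q2", ifelse(!qx, "Q3", "Q4")))
  names(q) <- rownames(scores)
  if (!is.null(relabel_centroids)) {
    cq <- quadrant_assign(relabel_centroids)
    if (anyDuplicated(cq))
      stop("group centroids do not occupy distinct quadrants")
    map <- stats::setNames(rownames(relabel_centroids), cq)
    q <- stats::setNames(unname(map[q]), names(q))
  }
  q
}

#' Locate a miRNA's predicted targets in the co-inertia plane
#'
#' Restricts the mRNA loadings of a fitted ordination to the given
#' miRNA's predicted targets and tabulates which quadrant each falls in.
#' Targets absent from the fitted matrix are counted as missing, not an
#' error.
#'
#' @param fit a [coinertia_fit()] result with `k >= 2`.
#' @param targets a target map from [consensus_targets()].
#' @param mirna miRNA id to look up (must be present in the map).
#' @return A list with `coordinates` (target x 2), `quadrant` per target,
#'   `counts` and `fraction` per quadrant, and `missing` (number of
#'   predicted targets absent from the matrix).
#' @export
target_overlay <- function(fit, targets, mirna) {
  stopifnot(inherits(fit, "coinertia_result"))
  if (fit$k < 2) stop("overlay needs at least 2 fitted axes")
  tset <- targets$map[[mirna]]
  if (is.null(tset)) stop("miRNA not in target map: ", mirna)
  present <- intersect(tset, rownames(fit$col_loadings_Y))
  coords <- fit$col_loadings_Y[present, 1:2, drop = FALSE]
  q <- quadrant_assign(coords)
  counts <- table(factor(q, levels = c("Q1", "Q2", "Q3", "Q4")))
  list(coordinates = coords,
       quadrant = q,
       counts = stats::setNames(as.integer(counts), names(counts)),
       fraction = stats::setNames(as.numeric(counts) / max(1, length(q)),
                                  names(counts)),
       missing = length(tset) - length(present))
}

#' Consensus miRNA target map across prediction algorithms
#'
#' Keeps (miRNA, gene) pairs predicted by at least `min_algorithms` of the
#' supplied per-algorithm tables (default 3, the usual multi-algorithm
#' consensus rule).
#'
#' @param predictions either a list of data frames with columns `mirna`
#'   and `gene` (one per algorithm), or a single data frame with columns
#'   `mirna`, `gene`, `algorithm`.
#' @param min_algorithms minimum number of agreeing algorithms.
#' @return An object of class `target_map`: list with `table` (data frame
#'   `mirna`, `gene`, `support`) and `map` (miRNA id -> character vector
#'   of targets).
#' @export
consensus_targets <- function(predictions, min_algorithms = 3) {
  stopifnot(min_algorithms >= 1)
  if (is.data.frame(predictions)) {
    stopifnot(all(c("mirna", "gene", "algorithm") %in% names(predictions)))
    predictions <- split(predictions[c("mirna", "gene")],
                         predictions$algorithm)
  }
  pairs <- unique(data.table::rbindlist(lapply(predictions, function(p) {
    data.table::data.table(mirna = as.character(p$mirna),
                           gene = as.character(p$gene))
  }), idcol = "src"))
  if (nrow(pairs) == 0) {
    tab <- data.frame(mirna = character(), gene = character(),
                      support = integer())
    return(structure(list(table = tab, map = list()), class = "target_map"))
  }
  sup <- pairs[, .(support = length(unique(src))), by = c("mirna", "gene")]
  sup <- sup[sup$support >= min_algorithms, ]
  tab <- as.data.frame(sup[order(sup$mirna, sup$gene)])
  structure(list(table = tab,
                 map = split(tab$gene, tab$mirna)),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d miRNAs, %d (miRNA, target) pairs\n",
              length(x$map), nrow(x$table)))
  invisible(x)
}

#' Read per-algorithm miRNA target predictions from TSV
#'
#' Expected columns: `mirna`, `gene`, `algorithm`.
#' @param path file path.
#' @export
read_target_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
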