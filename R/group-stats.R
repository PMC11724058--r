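#' Marker rules for subpopulation classification
#'
#' An ordered set of (label, marker miRNA set) rules plus an exclusion
#' marker. Cells expressing the exclusion marker above its threshold are
#' removed; remaining cells take the label whose markers have the highest
#' mean normalized expression, provided it exceeds the assignment
#' threshold.
#'
#' The default rules are the conserved lung marker panel: miR-142/miR-150
#' for lymphoid cells, miR-142/miR-223 for myeloid cells, miR-126 for
#' endothelial cells, miR-199 for stromal cells, miR-200 for general
#' epithelial cells and miR-375 for alveolar cells, with miR-135b-positive
#' (tumor) cells removed.
#'
#' @param rules named list: label -> character vector of marker miRNAs.
#' @param exclusion_marker miRNA whose expression flags cells for removal
#'   (`NULL` disables exclusion).
#' @param exclusion_threshold normalized expression above which a cell is
#'   removed (default 0: any expression).
#' @param assignment_threshold minimum mean marker expression required to
#'   assign a label; below it a cell is `unassigned`.
#' @return An object of class `marker_rule_set`.
#' @export
marker_rule_set <- function(rules = default_marker_rules(),
                            exclusion_marker = "miR-135b",
                            exclusion_threshold = 0,
                            assignment_threshold = 0) {
  stopifnot(is.list(rules), length(rules) > 0)
  if (is.null(names(rules)) || anyDuplicated(names(rules)))
    stop("rule labels must be unique and named")
  if (any(lengths(rules) == 0)) stop("marker sets must be non-empty")
  structure(list(rules = rules,
                 exclusion_marker = exclusion_marker,
                 exclusion_threshold = exclusion_threshold,
                 assignment_threshold = assignment_threshold),
            class = "marker_rule_set")
}

#' @rdname marker_rule_set
#' @export
default_marker_rules <- function() {
  list(lymphoid = c("miR-142", "miR-150"),
       myeloid = c("miR-142", "miR-223"),
       endothelial = "miR-126",
       stromal = "miR-199",
       epithelial = "miR-200",
       alveolar = "miR-375")
}

#' Classify cells by marker rules
#'
#' @param x an [expression_matrix()] with `normalization = "lognorm"`.
#' @param rules a [marker_rule_set()].
#' @return Named character vector: cell -> label, `"removed"` or
#'   `"unassigned"`. Invariant to cell and feature ordering.
#' @export
classify_by_markers <- function(x, rules) {
  stopifnot(inherits(x, "expression_matrix"), inherits(rules, "marker_rule_set"))
  if (x$normalization != "lognorm")
    stop("classification expects a log-normalized matrix")
  feats <- colnames(x$values)
  need <- unique(c(unlist(rules$rules), rules$exclusion_marker))
  miss <- setdiff(need, feats)
  if (length(miss))
    stop("marker rule references absent feature(s): ",
         paste(miss, collapse = ", "))
  score <- sapply(rules$rules, function(mk)
    Matrix::rowMeans(x$values[, mk, drop = FALSE]))
  score <- matrix(score, nrow = nrow(x$values),
                  dimnames = list(rownames(x$values), names(rules$rules)))
  best <- max.col(score, ties.method = "first")
  best_score <- score[cbind(seq_len(nrow(score)), best)]
  label <- colnames(score)[best]
  label[best_score <= rules$assignment_threshold] <- "unassigned"
  if (!is.null(rules$exclusion_marker)) {
    excl <- x$values[, rules$exclusion_marker] > rules$exclusion_threshold
    label[as.vector(excl)] <- "removed"
  }
  stats::setNames(label, rownames(x$values))
}

#' Wilcoxon rank-sum test with exact small-sample path
#'
#' Two-sided rank-sum test with midrank tie handling. The p-value is exact
#' (full enumeration of rank arrangements) when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return List with `statistic` (Mann-Whitney U for `a`), `p_value`, and
#'   `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 12
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Star label for an adjusted p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.1, empty otherwise.
#' @param p_adj adjusted p-value(s).
#' @return Character vector of star labels.
#' @export
star_label <- function(p_adj) {
  ifelse(p_adj < 0.001, "***",
         ifelse(p_adj < 0.01, "**",
                ifelse(p_adj < 0.1, "*", "")))
}

#' Compare miRNA expression between conditions within subpopulations
#'
#' One Wilcoxon rank-sum test per (subpopulation, miRNA), comparing the
#' two condition groups, with Bonferroni correction over all tests
#' actually performed and star labels from [star_label()]. Subpopulations
#' present in only one condition (or below `min_cells` in either) are
#' skipped with a warning.
#'
#' @param x an [expression_matrix()] with `normalization = "lognorm"`.
#' @param labels named character vector: cell -> subpopulation. Cells
#'   labeled `"removed"` or `"unassigned"` are ignored.
#' @param condition named character vector: cell -> condition, two levels
#'   (e.g. `old` / `young`).
#' @param features miRNAs to test (default: all features of `x`).
#' @param min_cells minimum cells per (subpopulation, condition) group.
#' @return Data frame with one row per performed test: `subpopulation`,
#'   `feature`, per-condition means, `direction`, `p`, `p_adj`, `stars`.
#' @export
compare_groups <- function(x, labels, condition, features = NULL,
                           min_cells = 3) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$normalization != "lognorm")
    stop("comparison expects a log-normalized matrix")
  features <- features %||% colnames(x$values)
  cells <- rownames(x$values)
  lab <- labels[cells]
  cond <- condition[cells]
  keep <- !is.na(lab) & !is.na(cond) & !(lab %in% c("removed", "unassigned"))
  lab <- lab[keep]; cond <- cond[keep]
  v <- x$values[keep, features, drop = FALSE]
  lev <- sort(unique(cond))
  if (length(lev) != 2) stop("condition must have exactly two levels")
  rows <- list()
  for (sp in sort(unique(lab))) {
    in_sp <- lab == sp
    n1 <- sum(in_sp & cond == lev[1]); n2 <- sum(in_sp & cond == lev[2])
    if (n1 < min_cells || n2 < min_cells) {
      warning(sprintf("subpopulation %s skipped (%s: %d, %s: %d cells)",
                      sp, lev[1], n1, lev[2], n2))
      next
    }
    for (f in features) {
      va <- v[in_sp & cond == lev[1], f]
      vb <- v[in_sp & cond == lev[2], f]
      if (all(va == va[1]) && all(vb == vb[1]) && va[1] == vb[1]) {
        p <- 1
      } else {
        p <- wilcoxon_rank_sum(va, vb)$p_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subpopulation = sp, feature = f,
        mean_1 = mean(va), mean_2 = mean(vb), p = p)
    }
  }
  if (length(rows) == 0)
    stop("no testable (subpopulation, condition) groups")
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lev[2])
  out$direction <- ifelse(out[[3]] > out[[4]], paste0("up_", lev[1]),
                          ifelse(out[[3]] < out[[4]], paste0("up_", lev[2]),
                                 "equal"))
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  out$stars <- star_label(out$p_adj)
  out
}

#' Split samples into old and young by median age
#'
#' Samples above the median age are `old`, below are `young`; a sample at
#' exactly the median is sent to `old` (deterministic tie rule).
#'
#' @param ages named numeric vector: sample -> age.
#' @return Named character vector: sample -> `"old"` or `"young"`.
#' @export
split_by_median_age <- function(ages) {
  if (length(ages) < 2) stop("need at least 2 samples")
  if (!is.numeric(ages) || any(is.na(ages))) stop("ages must be numeric")
  med <- stats::median(ages)
  stats::setNames(ifelse(ages >= med, "old", "young"), names(ages))
}
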