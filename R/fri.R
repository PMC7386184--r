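#' Fail-point set
#'
#' The set of point identifiers (linear indices on a shared layout) that
#' failed a comparison criterion, together with the number of evaluated
#' points it was drawn from.
#'
#' @param indices integer vector of failing point indices (deduplicated).
#' @param n_evaluated number of evaluated points the comparison considered.
#' @param criteria the [comparison_criteria()] that produced the set
#'   (optional).
#' @param layout_dim dimensions of the shared point layout (optional).
#' @return object of class `fail_point_set`.
#' @export
fail_point_set <- function(indices, n_evaluated, criteria = NULL,
                           layout_dim = NULL) {
  indices <- sort(unique(as.integer(indices)))
  n_evaluated <- as.integer(n_evaluated)
  if (length(indices) > n_evaluated)
    stop("more fail points than evaluated points")
  structure(list(indices = indices, n_evaluated = n_evaluated,
                 criteria = criteria, layout_dim = layout_dim),
            class = "fail_point_set")
}

#' @export
print.fail_point_set <- function(x, ...) {
  cat(sprintf("<fail_point_set  %d of %d evaluated>\n",
              length(x$indices), x$n_evaluated))
  invisible(x)
}

#' Simpson's Faunal Resemblance Index of two fail-point sets
#'
#' `FRI = |X intersect Y| / min(|X|, |Y|)`, in `[0, 1]`; 1 when either set
#' contains the other, 0 when they are disjoint.  Because it is scaled by
#' the smaller set, it is the overlap statistic least influenced by unequal
#' set sizes.  Comparisons in which either operand is empty (a 100% passing
#' rate) are not numbers but an explicit *excluded* marker, and are omitted
#' from cohort summaries.
#'
#' @param X,Y [fail_point_set()]s on the same point layout.
#' @param pair_label optional label (e.g. `"pattern1-vs-pattern3"`).
#' @return object of class `fri_result` with fields `value`,
#'   `n_intersection`, `n_min`, `excluded`, `pair_label`.
#' @export
simpson_fri <- function(X, Y, pair_label = NULL) {
  stopifnot(inherits(X, "fail_point_set"), inherits(Y, "fail_point_set"))
  if (!is.null(X$layout_dim) && !is.null(Y$layout_dim) &&
      !identical(X$layout_dim, Y$layout_dim))
    stop("fail-point sets live on different layouts")
  nx <- length(X$indices); ny <- length(Y$indices)
  if (nx == 0L || ny == 0L) {
    return(structure(list(value = NA_real_, n_intersection = NA_integer_,
                          n_min = min(nx, ny), excluded = TRUE,
                          pair_label = pair_label), class = "fri_result"))
  }
  ni <- length(intersect(X$indices, Y$indices))
  nm <- min(nx, ny)
  structure(list(value = ni / nm, n_intersection = ni, n_min = nm,
                 excluded = FALSE, pair_label = pair_label),
            class = "fri_result")
}

#' @export
print.fri_result <- function(x, ...) {
  if (x$excluded)
    cat(sprintf("<fri %s: excluded (empty fail set)>\n",
                if (is.null(x$pair_label)) "" else x$pair_label))
  else
    cat(sprintf("<fri %s: %.3f (= %d / %d)>\n",
                if (is.null(x$pair_label)) "" else x$pair_label,
                x$value, x$n_intersection, x$n_min))
  invisible(x)
}

#' FRI table across criteria for the three comparison patterns
#'
#' Computes, per criterion, the resemblance of pattern 1 (pTPS vs sTPS) fail
#' points with pattern 2 (pTPS vs measurement) and with pattern 3 (sTPS vs
#' measurement) fail points.  Cells where either operand set is empty are
#' flagged excluded.
#'
#' @param pattern1_fails,pattern2_fails,pattern3_fails named lists of
#'   [fail_point_set()]s, one per criterion label.
#' @param criteria_labels criteria labels to tabulate; default the names of
#'   `pattern1_fails`.
#' @return data.frame with one row per criterion and columns
#'   `fri_12`, `fri_13`, exclusion flags and set sizes.
#' @export
fri_table <- function(pattern1_fails, pattern2_fails, pattern3_fails,
                      criteria_labels = names(pattern1_fails)) {
  rows <- lapply(criteria_labels, function(lb) {
    f12 <- simpson_fri(pattern1_fails[[lb]], pattern2_fails[[lb]],
                       paste0(lb, ":pattern1-vs-pattern2"))
    f13 <- simpson_fri(pattern1_fails[[lb]], pattern3_fails[[lb]],
                       paste0(lb, ":pattern1-vs-pattern3"))
    data.frame(criterion = lb,
               fri_12 = f12$value, excluded_12 = f12$excluded,
               fri_13 = f13$value, excluded_13 = f13$excluded,
               n_fail_1 = length(pattern1_fails[[lb]]$indices),
               n_fail_2 = length(pattern2_fails[[lb]]$indices),
               n_fail_3 = length(pattern3_fails[[lb]]$indices))
  })
  do.call(rbind, rows)
}

#' Cohort summary of FRI values
#'
#' Mean, sample SD, max and min of the non-excluded FRI values per criterion
#' and pattern pair, plus the count of excluded cases — mirroring how 100%
#' passing plans are left out of cohort resemblance summaries.
#'
#' @param fri_tables list of per-case [fri_table()] data frames.
#' @return data.frame with one row per (criterion, pair).
#' @export
summarize_fri <- function(fri_tables) {
  all <- do.call(rbind, fri_tables)
  out <- list()
  for (lb in unique(all$criterion)) {
    sub <- all[all$criterion == lb, ]
    for (pair in c("12", "13")) {
      v <- sub[[paste0("fri_", pair)]]
      ex <- sub[[paste0("excluded_", pair)]]
      keep <- !ex & !is.na(v)
      out[[length(out) + 1L]] <- data.frame(
        criterion = lb, pair = paste0("pattern1-vs-pattern", substring(pair, 2)),
        n = sum(keep), n_excluded = sum(!keep),
        mean = if (any(keep)) mean(v[keep]) else NA_real_,
        sd = if (sum(keep) > 1) stats::sd(v[keep]) else NA_real_,
        max = if (any(keep)) max(v[keep]) else NA_real_,
        min = if (any(keep)) min(v[keep]) else NA_real_)
    }
  }
  do.call(rbind, out)
}
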