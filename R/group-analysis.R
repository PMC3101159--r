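#' Welch t-test of one item between two groups
#'
#' Compares raw category scores on a single item between two groups with the
#' unequal-variance (Welch) t-test and Satterthwaite degrees of freedom.
#' Raw scores, not logits, are compared: item-by-item analyses ask whether
#' the perception expressed on this item changed, holding the item fixed.
#'
#' @param responses_a,responses_b numeric vectors of category scores
#'   (NA dropped); each group needs at least 2 observations.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return one-row data.frame (`n_a`, `n_b`, `mean_diff` = a - b, `se`,
#'   `ci_lower`, `ci_upper`, `df`, `t`, `p`).
#' @export
item_t_test <- function(responses_a, responses_b, conf_level = 0.95) {
  a <- responses_a[!is.na(responses_a)]
  b <- responses_b[!is.na(responses_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    if (d != 0)
      stop("zero variance in both groups with unequal means: t undefined",
           call. = FALSE)
    return(data.frame(n_a = length(a), n_b = length(b), mean_diff = 0,
                      se = 0, ci_lower = 0, ci_upper = 0,
                      df = length(a) + length(b) - 2, t = 0, p = 1))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  data.frame(n_a = length(a), n_b = length(b),
             mean_diff = unname(diff(rev(tt$estimate))),
             se = unname(tt$stderr),
             ci_lower = tt$conf.int[1L], ci_upper = tt$conf.int[2L],
             df = unname(tt$parameter), t = unname(tt$statistic),
             p = tt$p.value)
}

#' Chi-square comparison of demographic composition
#'
#' Pearson chi-square test of a contingency table of group counts (e.g.
#' gender by survey year). Yates continuity correction is applied exactly
#' when the table is 2x2, the convention under which small two-by-two
#' demographic tables are conventionally reported.
#'
#' @param contingency matrix (or table) of non-negative integer counts,
#'   at least 2x2.
#' @return list with `statistic`, `df`, `p`, `corrected`.
#' @examples
#' demographic_chi_square(matrix(c(236, 61, 228, 63), 2, byrow = TRUE))
#' @export
demographic_chi_square <- function(contingency) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in contingency table", call. = FALSE)
  correct <- nrow(m) == 2L && ncol(m) == 2L
  ct <- stats::chisq.test(m, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, corrected = correct)
}

#' Item-by-item group comparison report
#'
#' For every item shared by the two response matrices (e.g. two survey
#' years), runs [item_t_test()] on the whole groups and within each stratum
#' of an optional demographic partition. Rows are ordered by item, then
#' stratum. Strata present in the labels but empty in either matrix are
#' omitted with a warning. No multiple-testing correction is applied; the
#' number of tests is recorded in the `n_tests` attribute.
#'
#' @param matrix_a,matrix_b response matrices (persons x items, shared item
#'   colnames).
#' @param strata_a,strata_b optional vectors of stratum labels, one per row
#'   of the corresponding matrix.
#' @param items optional subset of item ids to report (default: all shared).
#' @return data.frame of comparison rows (`item_id`, `stratum`, then the
#'   [item_t_test()] columns), difference oriented as group A minus group B.
#' @export
itemwise_report <- function(matrix_a, matrix_b, strata_a = NULL,
                            strata_b = NULL, items = NULL) {
  A <- validate_response_matrix(matrix_a)
  B <- validate_response_matrix(matrix_b)
  shared <- intersect(colnames(A), colnames(B))
  if (!is.null(items)) shared <- intersect(shared, as.character(items))
  if (length(shared) == 0L) stop("matrices share no items", call. = FALSE)
  if (is.null(strata_a) != is.null(strata_b))
    stop("supply strata for both matrices or neither", call. = FALSE)
  strata <- if (is.null(strata_a)) "All" else
    sort(unique(c(as.character(strata_a), as.character(strata_b))))

  rows <- list()
  for (it in shared) {
    for (s in strata) {
      sel_a <- if (is.null(strata_a)) rep(TRUE, nrow(A)) else as.character(strata_a) == s
      sel_b <- if (is.null(strata_b)) rep(TRUE, nrow(B)) else as.character(strata_b) == s
      a <- A[sel_a, it]; b <- B[sel_b, it]
      if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) {
        warning("stratum '", s, "' too small for item ", it, "; row omitted",
                call. = FALSE)
        next
      }
      row <- item_t_test(a, b)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(item_id = as.integer(it), stratum = s,
                         stringsAsFactors = FALSE), row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  out
}
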