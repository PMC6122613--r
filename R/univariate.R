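#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. The Welch variant is used throughout because the
#' group variances of the discriminating regions differ by more than
#' two-fold, making the pooled-variance test indefensible.
#'
#' @param x,y Numeric sample vectors, each with at least two values.
#' @return List with `t_statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (stats::var(x) + stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t_statistic = 0, df = length(x) + length(y) - 2, p_value = 1))
    stop("zero variance in both samples with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Univariate screen of all integration regions
#'
#' Welch t-test per IR between two groups of a normalized cohort, with
#' Benjamini-Hochberg correction applied jointly across all regions. Fold
#' change is `mean(group_b) / mean(group_a)`; with the conventional
#' `(cancer, inflammation)` ordering a fold change above one means the
#' region is elevated in inflammation.
#'
#' @param cohort Normalized `"cohort"` containing both groups.
#' @param group_a,group_b Group labels to compare.
#' @return Data frame of class `"univariate_screen"`, one row per IR:
#'   `ir_index`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `fold_change`,
#'   `log2_fc`, `t`, `p`, `p_adj`, sorted by `ir_index`.
#' @export
univariate_screen <- function(cohort, group_a = "cancer",
                              group_b = "inflammation") {
  stopifnot(inherits(cohort, "cohort"))
  if (!isTRUE(attr(cohort, "normalized")))
    stop("cohort must be normalized", call. = FALSE)
  for (g in c(group_a, group_b))
    if (!g %in% cohort$group)
      stop("group '", g, "' absent from cohort", call. = FALSE)
  m <- .ir_matrix(cohort)
  a <- m[cohort$group == group_a, , drop = FALSE]
  b <- m[cohort$group == group_b, , drop = FALSE]
  res <- lapply(seq_len(ncol(m)), function(j) {
    ht <- welch_t_test(a[, j], b[, j])
    data.frame(ir_index = j,
               mean_a = mean(a[, j]), sd_a = stats::sd(a[, j]),
               mean_b = mean(b[, j]), sd_b = stats::sd(b[, j]),
               t = ht$t_statistic, p = ht$p_value)
  })
  res <- do.call(rbind, res)
  res$fold_change <- res$mean_b / res$mean_a
  res$log2_fc <- log2(res$fold_change)
  res$p_adj <- bh_adjust(res$p)
  res <- res[, c("ir_index", "mean_a", "sd_a", "mean_b", "sd_b",
                 "fold_change", "log2_fc", "t", "p", "p_adj")]
  class(res) <- c("univariate_screen", "data.frame")
  res
}

#' Volcano classification of screened regions
#'
#' Labels every region into one of three classes: `"significant"`
#' (`p_adj < alpha`), `"high_fc"` (non-significant but
#' `|log2 fold change| >= lfc`), and `"negligible"`. The classes partition
#' the regions.
#'
#' @param results A [univariate_screen()] table.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold for the high-fold-change
#'   class (default 1).
#' @return Data frame with `ir_index`, `log2_fc`, `neg_log10_p_adj`,
#'   `class`.
#' @export
volcano_table <- function(results, alpha = 0.05, lfc = 1) {
  stopifnot(inherits(results, "univariate_screen"))
  cls <- ifelse(results$p_adj < alpha, "significant",
                ifelse(abs(results$log2_fc) >= lfc, "high_fc", "negligible"))
  data.frame(ir_index = results$ir_index,
             log2_fc = results$log2_fc,
             neg_log10_p_adj = -log10(pmax(results$p_adj, .Machine$double.xmin)),
             class = factor(cls, levels = c("significant", "high_fc",
                                            "negligible")),
             stringsAsFactors = FALSE)
}
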