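#' ROC curve for a continuous marker
#'
#' Builds the full threshold sweep for a single marker. With
#' `direction = "lower"` (the convention for relative glutamate, where low
#' values suggest cancer) a subject is called positive when
#' `value <= threshold`; with `direction = "higher"` when
#' `value >= threshold`. Thresholds are the midpoints between consecutive
#' distinct observed values plus infinite sentinels, so every achievable
#' (sensitivity, specificity) pair appears exactly once.
#'
#' @param values Numeric marker vector.
#' @param labels Logical or two-class labels; `positive` names the disease
#'   class when labels are not logical.
#' @param direction `"lower"` (low marker = positive call) or `"higher"`.
#' @param positive Label counted as positive when `labels` is not logical.
#' @return Object of class `"roc_curve"`: data frame with `threshold`,
#'   `sensitivity`, `specificity`, plus `direction` attribute.
#' @export
roc_curve <- function(values, labels, direction = c("lower", "higher"),
                      positive = NULL) {
  direction <- match.arg(direction)
  pos <- .as_positive(labels, positive)
  if (all(pos) || all(!pos))
    stop("both classes must be present", call. = FALSE)
  if (anyNA(values)) stop("marker values must be complete", call. = FALSE)
  v <- sort(unique(values))
  thr <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  thr <- c(-Inf, v, thr, Inf)   # include observed values: <=/>= are inclusive
  thr <- sort(unique(thr))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  call_pos <- if (direction == "lower")
    function(t) values <= t else function(t) values >= t
  sens <- vapply(thr, function(t) sum(call_pos(t) & pos) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(!call_pos(t) & !pos) / n_neg, numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  structure(out, direction = direction,
            class = c("roc_curve", "data.frame"))
}

.as_positive <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes",
                             call. = FALSE)
  if (is.null(positive))
    positive <- if ("cancer" %in% levels(f)) "cancer" else levels(f)[1]
  if (!positive %in% levels(f))
    stop("'positive' is not a label level", call. = FALSE)
  f == positive
}

#' Empirical AUC
#'
#' Trapezoidal area under the ROC curve; numerically identical to the
#' Mann-Whitney probability that a random positive subject's marker is more
#' disease-like than a random negative's, counting ties one half.
#'
#' @param x A `"roc_curve"`, or raw marker values (then `labels` etc. as in
#'   [roc_curve()]).
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_empirical <- function(x, labels = NULL, direction = c("lower", "higher"),
                          positive = NULL) {
  if (!inherits(x, "roc_curve"))
    x <- roc_curve(x, labels, direction, positive)
  fpr <- 1 - x$specificity
  ord <- order(fpr, x$sensitivity)
  fpr <- fpr[ord]; tpr <- x$sensitivity[ord]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Binormal AUC
#'
#' Closed-form ROC area when both classes' marker values are normal:
#' `pnorm(|mean_pos - mean_neg| / sqrt(sd_pos^2 + sd_neg^2))`. With the
#' published glutamate moments (inflammation 0.485 +/- 0.237 as the
#' high-marker class against cancer 0.159 +/- 0.156) this reproduces the
#' reported discrimination of the glutamate region.
#'
#' @param mean_pos,sd_pos Moments of the positive class.
#' @param mean_neg,sd_neg Moments of the negative class.
#' @return AUC in `[0.5, 1]` (degenerate 0.5 or 1 when both SDs are zero).
#' @examples
#' auc_binormal(0.485, 0.237, 0.159, 0.156)  # ~ 0.875
#' @export
auc_binormal <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (sd_pos < 0 || sd_neg < 0) stop("SDs must be non-negative", call. = FALSE)
  s <- sqrt(sd_pos^2 + sd_neg^2)
  if (s == 0) return(if (mean_pos == mean_neg) 0.5 else 1)
  stats::pnorm(abs(mean_pos - mean_neg) / s)
}

#' Youden-optimal cutoff
#'
#' Threshold maximizing Youden's J = sensitivity + specificity - 1 along a
#' ROC curve; ties break toward the smaller threshold.
#'
#' @param curve A `"roc_curve"`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.min(curve$threshold[best])]
  list(threshold = curve$threshold[pick],
       sensitivity = curve$sensitivity[pick],
       specificity = curve$specificity[pick],
       j = j[pick])
}

#' Diagnostic metrics from a 2x2 confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative cell counts (fractional expected counts
#'   are accepted).
#' @return Object of class `"diagnostic_metrics"`: sensitivity,
#'   specificity, PPV, NPV and MCE; a metric whose denominator is zero is
#'   `NA` (flagged, never 0/0).
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all-zero confusion matrix", call. = FALSE)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp),
         ppv = rate(tp, tp + fp),
         npv = rate(tn, tn + fn),
         mce = (fp + fn) / total,
         counts = counts),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("sensitivity %s | specificity %s | PPV %s | NPV %s | MCE %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$ppv),
              pct(x$npv), pct(x$mce)))
  invisible(x)
}

#' Diagnostic metrics from printed rates and cohort sizes
#'
#' Reconstructs the expected 2x2 cell counts from a sensitivity,
#' specificity and the class sizes, keeping fractional cells (no integer
#' rounding), and derives PPV, NPV and MCE. This is the arithmetic that
#' links a test's published sensitivity/specificity to its predictive
#' values at the study prevalence.
#'
#' @param sens,spec Rates in `[0, 1]`.
#' @param n_pos,n_neg Positive/negative class sizes.
#' @return A `"diagnostic_metrics"` object.
#' @examples
#' metrics_from_rates(0.96, 0.23, 269, 108)  # PET-CT at SUVmax >= 2.5
#' metrics_from_rates(0.85, 0.81, 269, 108)  # glutamate at cutoff 0.31
#' @export
metrics_from_rates <- function(sens, spec, n_pos, n_neg) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (n_pos <= 0 || n_neg <= 0) stop("counts must be positive", call. = FALSE)
  metrics_from_confusion(tp = sens * n_pos, fn = (1 - sens) * n_pos,
                         tn = spec * n_neg, fp = (1 - spec) * n_neg)
}

#' Combined SUVmax / glutamate decision rule
#'
#' Categorizes a subject by the two binary calls: PET positive iff
#' `suvmax >= suv_cutoff` (default 2.5), glutamate positive-for-cancer iff
#' `value <= glutamate_cutoff` (default 0.31). Both boundaries are
#' inclusive for the cancer call; the complements are strict.
#'
#' @param suvmax,glutamate Non-negative marker values (vectorized).
#' @param suv_cutoff,glutamate_cutoff Positive cutoffs.
#' @return Factor with levels `"both-cancer"` (PET+ and low glutamate),
#'   `"both-benign"`, `"discordant-PET+"` (PET+ but high glutamate),
#'   `"discordant-PET-"` (PET- but low glutamate).
#' @export
combined_rule <- function(suvmax, glutamate, suv_cutoff = 2.5,
                          glutamate_cutoff = 0.31) {
  if (suv_cutoff <= 0 || glutamate_cutoff <= 0)
    stop("cutoffs must be positive", call. = FALSE)
  if (anyNA(suvmax) || anyNA(glutamate))
    stop("missing marker value(s); the rule does not impute", call. = FALSE)
  if (any(suvmax < 0) || any(glutamate < 0))
    stop("marker values must be non-negative", call. = FALSE)
  pet <- suvmax >= suv_cutoff
  glu <- glutamate <= glutamate_cutoff
  lev <- c("both-cancer", "both-benign", "discordant-PET+", "discordant-PET-")
  out <- ifelse(pet & glu, lev[1],
         ifelse(!pet & !glu, lev[2],
         ifelse(pet, lev[3], lev[4])))
  factor(out, levels = lev)
}

#' Stratified metrics of the combined rule
#'
#' Applies [combined_rule()] to every subject carrying both markers and
#' tallies the cancer-call correctness within each category. In the
#' concordant categories the rule's call is unambiguous; in the discordant
#' categories a cancer subject is "missed" when the final call is benign
#' under the stated tie-handling (`discordant_call`, default `"benign"`,
#' i.e. a discordant profile is not called cancer).
#'
#' @param cohort Normalized `"cohort"` (or data frame) with `group` and
#'   `suvmax` columns.
#' @param glutamate_ir IR index of the glutamate region (default 89).
#' @param suv_cutoff,glutamate_cutoff Cutoffs as in [combined_rule()].
#' @param groups Labels of the disease/benign groups considered.
#' @param discordant_call How a discordant profile is resolved into a final
#'   call: follow the `"glutamate"` test (default: PET+ with high glutamate
#'   is called benign, PET- with low glutamate is called cancer), follow
#'   `"pet"`, or force `"benign"`/`"cancer"`.
#' @return List of class `"combined_metrics"`: `category_counts`,
#'   `per_category` (per-category cancer counts and call correctness),
#'   `discordant_miss_fraction` (cancer subjects in discordant categories
#'   whose final call is benign, over all discordant cancer subjects; `NA`
#'   when no cancer subject is discordant), and the concordant-category
#'   metrics.
#' @export
stratified_metrics <- function(cohort, glutamate_ir = 89L, suv_cutoff = 2.5,
                               glutamate_cutoff = 0.31,
                               groups = c("cancer", "inflammation"),
                               discordant_call = c("glutamate", "pet",
                                                   "benign", "cancer")) {
  discordant_call <- match.arg(discordant_call)
  stopifnot(inherits(cohort, "cohort"))
  marker <- extract_marker(cohort, glutamate_ir)
  sub <- cohort$group %in% groups & !is.na(cohort$suvmax)
  truth <- cohort$group[sub] == groups[1]
  cat4 <- combined_rule(cohort$suvmax[sub], marker$value[sub],
                        suv_cutoff, glutamate_cutoff)
  disc_cancer_call <- switch(discordant_call,
    glutamate = cat4 == "discordant-PET-",   # low glutamate drives the call
    pet       = cat4 == "discordant-PET+",
    benign    = rep(FALSE, length(cat4)),
    cancer    = rep(TRUE, length(cat4)))
  call_cancer <- cat4 == "both-cancer" |
    (startsWith(as.character(cat4), "discordant") & disc_cancer_call)

  per_category <- do.call(rbind, lapply(levels(cat4), function(cl) {
    i <- cat4 == cl
    data.frame(category = cl, n = sum(i), n_cancer = sum(truth[i]),
               n_called_cancer = sum(call_cancer[i]),
               correct = if (sum(i)) mean((call_cancer[i]) == truth[i])
                         else NA_real_)
  }))

  disc <- startsWith(as.character(cat4), "discordant")
  n_disc_cancer <- sum(truth & disc)
  miss <- if (n_disc_cancer > 0)
    sum(truth & disc & !call_cancer) / n_disc_cancer else NA_real_

  conc <- !disc
  metrics <- if (any(conc)) {
    metrics_from_confusion(tp = sum(conc & truth & call_cancer),
                           fp = sum(conc & !truth & call_cancer),
                           tn = sum(conc & !truth & !call_cancer),
                           fn = sum(conc & truth & !call_cancer))
  } else NULL

  structure(list(category_counts = table(cat4),
                 per_category = per_category,
                 discordant_miss_fraction = miss,
                 concordant_metrics = metrics,
                 n = sum(sub)),
            class = "combined_metrics")
}

#' @export
print.combined_metrics <- function(x, ...) {
  cat("Combined SUVmax/glutamate rule on", x$n, "subjects\n")
  print(x$category_counts)
  if (!is.null(x$concordant_metrics)) {
    cat("Concordant-category performance: ")
    print(x$concordant_metrics)
  }
  cat(sprintf("Discordant cancer subjects missed: %s\n",
              if (is.na(x$discordant_miss_fraction)) "not applicable"
              else sprintf("%.1f%%", 100 * x$discordant_miss_fraction)))
  invisible(x)
}
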