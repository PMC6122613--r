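#' Cross-validation configuration
#'
#' Defaults follow the study design: 250 repeats of a stratified four-fold
#' cross-validation on a class-balanced subsample (majority class randomly
#' downsampled to the minority size in every repeat), with a LASSO top-16
#' signature, giving 1000 fold evaluations per run.
#'
#' @param n_repeats Balanced-subsample repeats (default 250).
#' @param n_folds Folds per repeat (default 4).
#' @param K Signature size passed to [plslda()] (default 16).
#' @param ncomp PLS component count or `"auto"` (see [plslda()]).
#' @param balance Subsample the majority class to the minority size each
#'   repeat (default `TRUE`).
#' @param seed Master seed; every subsample and fold assignment derives
#'   from it, so a fixed seed reproduces the full result.
#' @return An object of class `"cv_config"`.
#' @export
cv_config <- function(n_repeats = 250L, n_folds = 4L, K = 16L,
                      ncomp = "auto", balance = TRUE, seed = 1L) {
  stopifnot(n_repeats >= 1L, n_folds >= 2L, K >= 1L)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds), K = as.integer(K),
                 ncomp = ncomp, balance = isTRUE(balance),
                 seed = as.integer(seed)),
            class = "cv_config")
}

## One master seed -> one sub-seed per repeat (subsampling + folds).
.repeat_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## Stratified fold assignment: permute within class, deal round-robin.
.stratified_folds <- function(f, n_folds) {
  folds <- integer(length(f))
  for (lev in levels(f)) {
    i <- which(f == lev)
    folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  folds
}

.rates <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  c(mce = (fp + fn) / length(truth),
    sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Balanced repeated cross-validation of the PLS-LDA classifier
#'
#' For each repeat, the majority class is randomly downsampled to the
#' minority-class size, the balanced set is split into stratified folds,
#' and within every fold a full nested fit (autoscaling, LASSO top-K
#' selection, PLS, LDA) is computed on the training three-quarters and
#' evaluated on the held-out quarter. Misclassification error, sensitivity
#' and specificity are recorded per fold evaluation; feature selection
#' frequencies are counted over all evaluations.
#'
#' @param x Feature matrix or data frame (subjects x features), e.g.
#'   the IR columns of a normalized cohort.
#' @param y Two-class labels.
#' @param positive Label treated as the positive (disease) class for
#'   sensitivity/specificity; defaults to `"cancer"` when present, else the
#'   first class level.
#' @param config A [cv_config()].
#' @return An object of class `"cv_plslda"`: per-evaluation rates, their
#'   means, per-feature selection frequencies, and the per-repeat balanced
#'   class counts.
#' @export
balanced_repeated_cv <- function(x, y, positive = NULL,
                                 config = cv_config()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  f <- factor(y)
  if (nlevels(f) != 2L) stop("exactly two classes required", call. = FALSE)
  if (is.null(positive))
    positive <- if ("cancer" %in% levels(f)) "cancer" else levels(f)[1]
  if (!positive %in% levels(f))
    stop("'positive' is not a class label", call. = FALSE)
  tab <- table(f)
  n_min <- min(tab)
  if (n_min < config$n_folds)
    stop("minority class smaller than the number of folds", call. = FALSE)
  minority <- names(tab)[which.min(tab)]

  seeds <- .repeat_seeds(config$seed, config$n_repeats)
  n_eval <- config$n_repeats * config$n_folds
  per_eval <- matrix(NA_real_, n_eval, 3,
                     dimnames = list(NULL, c("mce", "sens", "spec")))
  sel_counts <- stats::setNames(numeric(ncol(x)), colnames(x))
  class_counts <- matrix(NA_integer_, config$n_repeats, 2,
                         dimnames = list(NULL, levels(f)))
  eval_meta <- data.frame(repeat_id = rep(seq_len(config$n_repeats),
                                          each = config$n_folds),
                          fold = rep(seq_len(config$n_folds),
                                     config$n_repeats))

  e <- 0L
  for (r in seq_len(config$n_repeats)) {
    set.seed(seeds[r])
    if (config$balance) {
      keep <- unlist(lapply(levels(f), function(lev) {
        i <- which(f == lev)
        if (lev == minority) i else sample(i, n_min)
      }))
    } else keep <- seq_along(f)
    xb <- x[keep, , drop = FALSE]
    fb <- droplevels(f[keep])
    class_counts[r, ] <- as.integer(table(fb)[levels(f)])
    folds <- .stratified_folds(fb, config$n_folds)
    for (k in seq_len(config$n_folds)) {
      tr <- folds != k
      fit <- plslda(xb[tr, , drop = FALSE], fb[tr],
                    K = config$K, ncomp = config$ncomp)
      pred <- predict(fit, xb[!tr, , drop = FALSE])
      e <- e + 1L
      per_eval[e, ] <- .rates(fb[!tr], pred, positive)
      sel_counts[fit$selected] <- sel_counts[fit$selected] + 1
    }
  }

  structure(
    list(per_eval = cbind(eval_meta, as.data.frame(per_eval)),
         mce_mean = mean(per_eval[, "mce"]),
         sens_mean = mean(per_eval[, "sens"], na.rm = TRUE),
         spec_mean = mean(per_eval[, "spec"], na.rm = TRUE),
         selection_frequency = sel_counts / n_eval,
         class_counts = class_counts,
         positive = positive, config = config,
         features = colnames(x)),
    class = "cv_plslda"
  )
}

#' @export
print.cv_plslda <- function(x, ...) {
  cfg <- x$config
  cat("Balanced repeated CV of PLS-LDA:", cfg$n_repeats, "repeats x",
      cfg$n_folds, "folds =", nrow(x$per_eval), "evaluations\n")
  cat(sprintf("Mean MCE %.3f | sensitivity %.3f | specificity %.3f (positive = %s)\n",
              x$mce_mean, x$sens_mean, x$spec_mean, x$positive))
  top <- sort(x$selection_frequency, decreasing = TRUE)
  top <- top[top > 0]
  cat("Most frequently selected features:\n")
  print(round(utils::head(top, 10), 3))
  invisible(x)
}

#' @export
summary.cv_plslda <- function(object, ...) {
  print(object)
  cat("\nPer-evaluation MCE quartiles:\n")
  print(stats::quantile(object$per_eval$mce))
  invisible(object)
}

#' Ablation cross-validation
#'
#' Runs the identical balanced repeated CV after deleting the named feature
#' columns. Under the same master seed the subsample and fold schedule is
#' identical to the unablated run, so results are directly comparable
#' (paired by repeat and fold).
#'
#' @inheritParams balanced_repeated_cv
#' @param remove Feature columns to delete: integer indices or column names
#'   (e.g. `"IR89"`). An empty set reproduces [balanced_repeated_cv()]
#'   exactly.
#' @return A `"cv_plslda"` object on the reduced feature table.
#' @export
ablation_cv <- function(x, y, remove, positive = NULL,
                        config = cv_config()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.character(remove)) {
    bad <- setdiff(remove, colnames(x))
    if (length(bad)) stop("unknown feature(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    remove <- match(remove, colnames(x))
  }
  if (length(remove) >= ncol(x))
    stop("cannot remove every feature", call. = FALSE)
  keep <- if (length(remove)) setdiff(seq_len(ncol(x)), remove)
          else seq_len(ncol(x))
  balanced_repeated_cv(x[, keep, drop = FALSE], y, positive, config)
}

#' Leave-one-out cross-validation with per-stage error attribution
#'
#' Downsamples the majority class once to the minority size (seeded), then
#' leaves each subject of the balanced set out in turn, refitting the whole
#' nested pipeline (selection, scaling, PLS, LDA) without it and predicting
#' it. Each held-out cancer subject's error is attributed to its TNM stage.
#'
#' @inheritParams balanced_repeated_cv
#' @param stage Character vector of TNM stages, `NA` for non-cancer
#'   subjects; required for every cancer subject.
#' @param K Signature size.
#' @param ncomp PLS components (fixed count recommended; default 2).
#' @param seed Seed for the single balancing subsample.
#' @param balance Downsample the majority class first (default `TRUE`).
#' @return List of class `"loocv_stage"`: `overall` (MCE, sensitivity,
#'   specificity), `per_stage` (data frame with stage, n, errors, mce; `NA`
#'   mce for empty stages), and `n_eval`.
#' @export
loocv_per_stage <- function(x, y, stage, positive = NULL, K = 16L,
                            ncomp = 2L, seed = 1L, balance = TRUE) {
  x <- as.matrix(x)
  f <- factor(y)
  if (nlevels(f) != 2L) stop("exactly two classes required", call. = FALSE)
  if (is.null(positive))
    positive <- if ("cancer" %in% levels(f)) "cancer" else levels(f)[1]
  if (length(stage) != length(f))
    stop("one stage entry per subject required (NA outside cancer)",
         call. = FALSE)
  if (any(f == positive & is.na(stage)))
    stop("stage labels required for all '", positive, "' subjects",
         call. = FALSE)

  set.seed(seed)
  tab <- table(f)
  n_min <- min(tab)
  minority <- names(tab)[which.min(tab)]
  keep <- if (balance) {
    unlist(lapply(levels(f), function(lev) {
      i <- which(f == lev)
      if (lev == minority) i else sample(i, n_min)
    }))
  } else seq_along(f)
  xb <- x[keep, , drop = FALSE]
  fb <- droplevels(f[keep])
  sb <- stage[keep]

  n <- nrow(xb)
  pred <- factor(rep(NA_character_, n), levels = levels(fb))
  for (i in seq_len(n)) {
    fit <- plslda(xb[-i, , drop = FALSE], fb[-i], K = K, ncomp = ncomp)
    pred[i] <- predict(fit, xb[i, , drop = FALSE])
  }
  err <- pred != fb
  overall <- .rates(fb, pred, positive)

  stages <- sort(unique(stats::na.omit(stage)))
  per_stage <- do.call(rbind, lapply(stages, function(s) {
    i <- which(!is.na(sb) & sb == s & fb == positive)
    data.frame(stage = s, n = length(i), errors = sum(err[i]),
               mce = if (length(i)) mean(err[i]) else NA_real_)
  }))
  structure(list(overall = overall, per_stage = per_stage, n_eval = n,
                 positive = positive),
            class = "loocv_stage")
}

#' @export
print.loocv_stage <- function(x, ...) {
  cat("Leave-one-out CV on the balanced set (", x$n_eval, " fits)\n",
      sep = "")
  cat(sprintf("Overall MCE %.3f | sensitivity %.3f | specificity %.3f\n",
              x$overall["mce"], x$overall["sens"], x$overall["spec"]))
  cat("Per-stage misclassification (", x$positive, " subjects):\n", sep = "")
  print(x$per_stage, row.names = FALSE)
  invisible(x)
}

#' Assemble the feature table of a cohort pair
#'
#' Convenience accessor: subsets a normalized cohort to two groups and
#' returns the IR matrix, labels, stages, and (optionally) the table with
#' SUVmax appended via [augment_with_suvmax()].
#'
#' @param cohort Normalized `"cohort"`.
#' @param groups Two group labels (default cancer vs inflammation).
#' @param use_suvmax Append the SUVmax column (default `FALSE`).
#' @return List with `x`, `y`, `stage`, `subject_id`.
#' @export
cohort_features <- function(cohort, groups = c("cancer", "inflammation"),
                            use_suvmax = FALSE) {
  stopifnot(inherits(cohort, "cohort"), length(groups) == 2L)
  if (!isTRUE(attr(cohort, "normalized")))
    stop("cohort must be normalized", call. = FALSE)
  sub <- cohort[cohort$group %in% groups, , drop = FALSE]
  if (!all(groups %in% sub$group))
    stop("group absent from cohort: ",
         paste(setdiff(groups, sub$group), collapse = ", "), call. = FALSE)
  x <- .ir_matrix(sub)
  if (use_suvmax) x <- augment_with_suvmax(x, sub$suvmax, sub$subject_id)
  list(x = x, y = sub$group, stage = sub$stage, subject_id = sub$subject_id)
}
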