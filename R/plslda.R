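#' LASSO top-K feature selection by path entry order
#'
#' Ranks features by the order in which they first enter the active set
#' along the decreasing-penalty L1 path of a least-squares fit to the
#' +/-1-coded response, and returns the first `K`. Realizes "top K" without
#' committing to a single penalty value. Features that never enter the
#' computed path are ranked after all entrants by descending absolute inner
#' product with the response. All ties break toward the smaller column
#' index.
#'
#' @param x Numeric matrix (autoscaled columns expected; no intercept is
#'   fitted).
#' @param y Two-class labels (factor, character, or +/-1 numeric).
#' @param K Number of features to return; `K = 0` returns an empty set.
#' @return Integer vector of `K` column indices, in selection order.
#' @export
lasso_top_k <- function(x, y, K) {
  x <- as.matrix(x)
  if (K > ncol(x)) stop("K exceeds the number of features", call. = FALSE)
  yc <- .code_pm1(y)
  if (length(unique(yc)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (K == 0L) return(integer(0))
  if (ncol(x) == 1L) return(1L)
  fit <- glmnet::glmnet(x, yc, family = "gaussian", alpha = 1,
                        standardize = FALSE, intercept = FALSE,
                        nlambda = 200, lambda.min.ratio = 1e-4)
  beta <- fit$beta  # p x nlambda, lambda decreasing
  entry <- apply(beta != 0, 1, function(nz) {
    w <- which(nz)
    if (length(w)) w[1] else Inf
  })
  ## fallback ranking for features the path never activates
  score <- abs(drop(crossprod(x, yc)))
  ord <- order(entry, -score, seq_along(entry))
  ## exact duplicate columns enter the path together; keep only the
  ## smallest-index representative of each duplicate group
  taken <- integer(0)
  for (j in ord) {
    dup <- FALSE
    for (t in taken) {
      if (identical(x[, j], x[, t])) { dup <- TRUE; break }
    }
    if (!dup) taken <- c(taken, j)
    if (length(taken) == K) break
  }
  taken
}

.code_pm1 <- function(y) {
  if (is.numeric(y) && all(y %in% c(-1, 1))) return(as.numeric(y))
  f <- factor(y)
  if (nlevels(f) != 2L) stop("response must have exactly two classes",
                             call. = FALSE)
  ifelse(f == levels(f)[1], 1, -1)
}

#' Partial least squares (NIPALS, single response)
#'
#' Successive weight vectors maximize covariance between the deflated
#' predictor block and the response; scores are mutually orthogonal. At
#' `A = rank(X)` the fitted response equals the ordinary least-squares fit.
#'
#' @param x Centered/scaled predictor matrix.
#' @param y Numeric response (+/-1 coding for classification use).
#' @param ncomp Number of latent components, `1 <= ncomp <= min(p, n-1)`.
#' @return List with weights `W`, loadings `P`, y-loadings `q`, scores `T`,
#'   the projection matrix `R = W (P'W)^{-1}` (so new scores are `X R`),
#'   and `y_mean`.
#' @export
fit_pls <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (ncomp < 1 || ncomp > min(p, n - 1))
    stop("'ncomp' must lie in 1..min(p, n-1)", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance feature column", call. = FALSE)
  y_mean <- mean(y)
  E <- x; f <- y - y_mean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("response variance exhausted before component ", a, call. = FALSE)
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q[a] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q[a] * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
  }
  R <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, q = q, T = Tm, R = R, y_mean = y_mean, ncomp = ncomp)
}

## Linear discriminant with equal priors on a low-dimensional score matrix.
## Returns the discriminant direction and midpoint offset; d(x) >= 0 assigns
## the first (sorted) class level.
.fit_lda_scores <- function(scores, f) {
  scores <- as.matrix(scores)
  lev <- levels(f)
  m1 <- colMeans(scores[f == lev[1], , drop = FALSE])
  m2 <- colMeans(scores[f == lev[2], , drop = FALSE])
  d1 <- sweep(scores[f == lev[1], , drop = FALSE], 2, m1)
  d2 <- sweep(scores[f == lev[2], , drop = FALSE], 2, m2)
  S <- (crossprod(d1) + crossprod(d2)) / (nrow(scores) - 2)
  delta <- tryCatch(solve(S, m1 - m2), error = function(e)
    solve(S + diag(1e-8 * mean(diag(S)), ncol(S)), m1 - m2))
  list(delta = delta, offset = sum((m1 + m2) / 2 * delta), levels = lev)
}

#' Fit a PLS-LDA classifier with nested LASSO feature selection
#'
#' The estimator at the heart of the pipeline: features are autoscaled on
#' the training data, the top `K` are selected by LASSO path entry order,
#' `ncomp` PLS components are extracted against the +/-1-coded class label,
#' and a linear discriminant with equal class priors is fitted on the
#' component scores. Selection, scaling and projection are all computed
#' from the training data only, so the fitted object can be applied to new
#' subjects without leakage.
#'
#' @param x Numeric feature matrix or data frame (subjects x features).
#' @param y Two-class response (factor or character).
#' @param K Signature size: number of features retained by the LASSO
#'   ranking (default 16).
#' @param ncomp Number of PLS components, or `"auto"` to pick the
#'   `ncomp` in `1..min(8, K)` minimizing a deterministic stratified
#'   four-fold misclassification error on the training set.
#' @return An object of class `"plslda"`.
#' @seealso [predict.plslda()], [balanced_repeated_cv()]
#' @examples
#' set.seed(42)
#' x <- matrix(rnorm(60 * 5), 60, 5)
#' y <- rep(c("case", "ctrl"), each = 30)
#' x[y == "case", 1] <- x[y == "case", 1] + 3
#' fit <- plslda(x, y, K = 3, ncomp = 2)
#' table(predict(fit, x), y)
#' @export
plslda <- function(x, y, K = 16L, ncomp = "auto") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  f <- factor(y)
  if (nlevels(f) != 2L) stop("'y' must have exactly two classes", call. = FALSE)
  if (nrow(x) != length(f)) stop("x and y sizes differ", call. = FALSE)
  if (K < 1) stop("K must be >= 1 to fit a classifier", call. = FALSE)
  K <- min(as.integer(K), ncol(x))

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance feature column(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
  xs <- scale(x, center = ctr, scale = scl)

  sel <- lasso_top_k(xs, f, K)
  xsel <- xs[, sel, drop = FALSE]
  ycode <- .code_pm1(f)

  a_max <- min(8L, K, nrow(x) - 1L)
  if (identical(ncomp, "auto")) {
    ncomp <- .choose_ncomp(xsel, f, a_max)
  } else {
    ncomp <- as.integer(ncomp)
    if (ncomp < 1 || ncomp > min(K, nrow(x) - 1L))
      stop("'ncomp' out of range", call. = FALSE)
  }
  pls <- fit_pls(xsel, ycode, ncomp)
  lda <- .fit_lda_scores(pls$T, f)

  structure(
    list(selected = sel, feature_names = colnames(x)[sel],
         center = ctr, scale = scl, pls = pls, lda = lda,
         levels = levels(f), K = K, ncomp = ncomp, n = nrow(x)),
    class = "plslda"
  )
}

## Deterministic stratified 4-fold CV over candidate component counts:
## fit once per fold at a_max, evaluate truncations.
.choose_ncomp <- function(xsel, f, a_max) {
  n <- nrow(xsel)
  folds <- integer(n)
  for (lev in levels(f)) {
    i <- which(f == lev)
    folds[i] <- rep_len(seq_len(4L), length(i))
  }
  err <- matrix(NA_real_, 4L, a_max)
  ycode <- .code_pm1(f)
  for (k in seq_len(4L)) {
    tr <- folds != k
    if (length(unique(f[tr])) < 2L) next
    a_fit <- min(a_max, sum(tr) - 1L)
    pls <- tryCatch(fit_pls(xsel[tr, , drop = FALSE], ycode[tr], a_fit),
                    error = function(e) NULL)
    if (is.null(pls)) next
    te_scores <- xsel[!tr, , drop = FALSE] %*% pls$R
    for (a in seq_len(a_fit)) {
      lda <- .fit_lda_scores(pls$T[, seq_len(a), drop = FALSE], factor(f[tr]))
      d <- drop(te_scores[, seq_len(a), drop = FALSE] %*% lda$delta) - lda$offset
      pred <- ifelse(d >= 0, lda$levels[1], lda$levels[2])
      err[k, a] <- mean(pred != f[!tr])
    }
  }
  mce <- colMeans(err, na.rm = TRUE)
  which.min(mce)  # ties -> fewer components
}

#' Predict method for PLS-LDA fits
#'
#' Applies the stored feature selection, scaling, PLS projection and LDA
#' rule. A subject exactly on the decision boundary is assigned the first
#' class level in sort order.
#'
#' @param object A `"plslda"` fit.
#' @param newdata Matrix or data frame with the training feature dimension.
#' @param type `"class"` for labels, `"score"` for the signed LDA
#'   discriminant (positive toward the first class level).
#' @param ... Unused.
#' @return Factor of predicted labels, or numeric discriminant scores.
#' @export
predict.plslda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object$center), call. = FALSE)
  xs <- scale(newdata, center = object$center, scale = object$scale)
  scores <- xs[, object$selected, drop = FALSE] %*% object$pls$R
  d <- drop(scores %*% object$lda$delta) - object$lda$offset
  if (type == "score") return(d)
  factor(ifelse(d >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' @export
print.plslda <- function(x, ...) {
  cat("PLS-LDA classifier (LASSO top-", x$K, " selection, ", x$ncomp,
      " latent component", if (x$ncomp > 1) "s", ")\n", sep = "")
  cat("Classes:", paste(x$levels, collapse = " vs "),
      " |  n =", x$n, "\n")
  cat("Selected features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.plslda <- function(object, ...) {
  ## discriminant expressed on the scaled selected features:
  ## d(x) = x_s[, sel] %*% (R delta) - offset
  b <- drop(object$pls$R %*% object$lda$delta)
  stats::setNames(b, object$feature_names)
}

#' @export
summary.plslda <- function(object, ...) {
  cat("PLS-LDA fit summary\n")
  print(object)
  cat("\nDiscriminant weights on scaled selected features:\n")
  print(round(coef(object), 4))
  invisible(object)
}

#' Append SUVmax as an additional predictor column
#'
#' @param x Feature matrix or data frame.
#' @param suvmax Numeric SUVmax per subject; must be complete.
#' @param ids Optional subject identifiers used in the error message.
#' @return Matrix with one appended `SUVmax` column, which participates in
#'   scaling and selection like any integration region.
#' @export
augment_with_suvmax <- function(x, suvmax, ids = rownames(x)) {
  x <- as.matrix(x)
  if (length(suvmax) != nrow(x))
    stop("one SUVmax value per subject required", call. = FALSE)
  if (anyNA(suvmax)) {
    miss <- which(is.na(suvmax))
    lab <- if (!is.null(ids)) ids[miss] else miss
    stop("missing SUVmax for subject(s): ",
         paste(utils::head(lab, 10), collapse = ", "), call. = FALSE)
  }
  cbind(x, SUVmax = suvmax)
}
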