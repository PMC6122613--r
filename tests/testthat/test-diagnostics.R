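test_that("ROC curve covers both endpoints and handles separable data", {
  r <- roc_curve(c(0.1, 0.2, 0.3, 0.4), c(TRUE, TRUE, FALSE, FALSE),
                 direction = "lower")
  expect_true(any(r$sensitivity == 1 & r$specificity == 0))
  expect_true(any(r$sensitivity == 0 & r$specificity == 1))
  expect_true(any(r$sensitivity == 1 & r$specificity == 1))  # separable
  # all-equal marker values: diagonal curve
  r0 <- roc_curve(rep(1, 10), rep(c(TRUE, FALSE), 5), direction = "lower")
  expect_equal(auc_empirical(r0), 0.5)
  # direction symmetry: negated values with flipped direction
  set.seed(40)
  v <- rnorm(30); lab <- rep(c(TRUE, FALSE), 15)
  r1 <- roc_curve(v, lab, "lower")
  r2 <- roc_curve(-v, lab, "higher")
  expect_equal(sort(r1$sensitivity), sort(r2$sensitivity))
  expect_equal(auc_empirical(r1), auc_empirical(r2))
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("empirical AUC equals the Mann-Whitney probability", {
  # worked four-pair example: positives {0.1, 0.35}, negatives {0.3, 0.4},
  # lower => positive: 3 concordant pairs of 4
  expect_equal(auc_empirical(c(0.1, 0.35, 0.3, 0.4),
                             c(TRUE, TRUE, FALSE, FALSE), "lower"), 0.75)
  # brute-force pairwise oracle on 100 random instances, with ties
  set.seed(41)
  for (i in 1:100) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    pos <- sample(seq(0, 1, by = 0.1), n1, replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), n2, replace = TRUE)
    # lower => positive: a pair is concordant when pos < neg
    grid <- expand.grid(p = pos, n = neg)
    oracle <- mean(ifelse(grid$p < grid$n, 1, ifelse(grid$p == grid$n, 0.5, 0)))
    got <- auc_empirical(c(pos, neg), rep(c(TRUE, FALSE), c(n1, n2)), "lower")
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly monotone marker transforms", {
  set.seed(42)
  v <- runif(40); lab <- rep(c(TRUE, FALSE), 20)
  a0 <- auc_empirical(v, lab, "lower")
  expect_equal(auc_empirical(exp(v), lab, "lower"), a0)
  expect_equal(auc_empirical(v^3 + 2 * v, lab, "lower"), a0)
})

test_that("binormal AUC matches quadrature and its degenerate limits", {
  # numeric integration oracle: P(X_pos > X_neg) for two normals
  quad_auc <- function(m1, s1, m2, s2) {
    stats::integrate(function(x) dnorm(x, m1, s1) * pnorm(x, m2, s2),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }
  set.seed(43)
  for (i in 1:10) {
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.2, 2); s2 <- runif(1, 0.2, 2)
    hi <- max(m1, m2); lo <- min(m1, m2)
    shi <- if (m1 >= m2) s1 else s2
    slo <- if (m1 >= m2) s2 else s1
    expect_equal(auc_binormal(hi, shi, lo, slo), quad_auc(hi, shi, lo, slo),
                 tolerance = 1e-6)
  }
  expect_equal(auc_binormal(1, 0.5, 1, 0.5), 0.5)
  expect_equal(auc_binormal(1, 0, 0, 0), 1)
  expect_equal(auc_binormal(1, 0, 1, 0), 0.5)
})

test_that("binormal AUC agrees with empirical AUC on sampled normals", {
  set.seed(44)
  n <- 4000
  pos <- rnorm(n, 0.485, 0.237)   # high-marker class
  neg <- rnorm(n, 0.159, 0.156)
  emp <- auc_empirical(c(pos, neg), rep(c(TRUE, FALSE), each = n), "higher")
  theo <- auc_binormal(0.485, 0.237, 0.159, 0.156)
  # Monte-Carlo SE of the AUC (conservative bound)
  se <- sqrt(theo * (1 - theo) / n)
  expect_lt(abs(emp - theo), 3 * se)
})

test_that("Youden cutoff equals the brute-force sweep", {
  set.seed(45)
  for (i in 1:100) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    v <- c(rnorm(n1, 0.3, 0.15), rnorm(n2, 0.5, 0.2))
    lab <- rep(c(TRUE, FALSE), c(n1, n2))
    curve <- roc_curve(v, lab, "lower")
    got <- youden_cutoff(curve)
    j_all <- curve$sensitivity + curve$specificity - 1
    expect_equal(got$j, max(j_all), tolerance = 1e-12)
    # tie rule: smallest threshold among maximizers
    best <- which(j_all == max(j_all))
    expect_equal(got$threshold, min(curve$threshold[best]))
  }
  # diagonal curve: J = 0
  r0 <- roc_curve(rep(1, 10), rep(c(TRUE, FALSE), 5), "lower")
  expect_equal(youden_cutoff(r0)$j, 0)
})

test_that("confusion-matrix metrics follow their definitions", {
  m <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  expect_equal(m$mce, 0)
  m2 <- metrics_from_confusion(1, 1, 1, 1)
  expect_equal(unlist(m2[c("sensitivity", "specificity", "ppv", "npv", "mce")]),
               c(sensitivity = .5, specificity = .5, ppv = .5, npv = .5,
                 mce = .5))
  # zero denominators flagged, not 0/0
  m3 <- metrics_from_confusion(0, 0, 5, 5)
  expect_true(is.na(m3$ppv))
  expect_error(metrics_from_confusion(0, 0, 0, 0), "all-zero")
  # round-trip: counts -> metrics -> counts
  set.seed(46)
  for (i in 1:20) {
    cm <- sample(0:30, 4)
    if (sum(cm) == 0 || cm[1] + cm[4] == 0 || cm[3] + cm[2] == 0) next
    m <- metrics_from_confusion(cm[1], cm[2], cm[3], cm[4])
    n_pos <- cm[1] + cm[4]; n_neg <- cm[3] + cm[2]
    expect_equal(unname(m$sensitivity * n_pos), cm[1])
    expect_equal(unname(m$specificity * n_neg), cm[3])
  }
})

test_that("rate-based metrics reproduce printed predictive values", {
  # PET-CT at SUVmax >= 2.5 in 269 cancer vs 108 inflammation subjects
  pet <- metrics_from_rates(0.96, 0.23, 269, 108)
  expect_equal(round(100 * pet$ppv), 76)
  expect_lt(abs(pet$npv - 0.71), 0.02)
  # glutamate cutoff 0.31
  glu <- metrics_from_rates(0.85, 0.81, 269, 108)
  expect_equal(round(100 * glu$ppv), 92)
  expect_lt(abs(glu$npv - 0.69), 0.02)
  # consistency with integer-count confusion arithmetic at the same rates
  m1 <- metrics_from_rates(0.8, 0.6, 10, 20)
  m2 <- metrics_from_confusion(8, 8, 12, 2)
  expect_equal(m1$ppv, m2$ppv)
  expect_equal(m1$npv, m2$npv)
  expect_equal(metrics_from_rates(1, 1, 7, 9)$ppv, 1)
  expect_equal(metrics_from_rates(1, 1, 7, 9)$npv, 1)
  expect_error(metrics_from_rates(1.2, 0.5, 10, 10), "\\[0, 1\\]")
})

test_that("combined rule categorizes by the stated inclusive boundaries", {
  expect_equal(as.character(combined_rule(12.1, 0.159)), "both-cancer")
  expect_equal(as.character(combined_rule(2.5, 0.31)), "both-cancer")
  expect_equal(as.character(combined_rule(2.49, 0.32)), "both-benign")
  expect_equal(as.character(combined_rule(3.0, 0.5)), "discordant-PET+")
  expect_equal(as.character(combined_rule(1.0, 0.2)), "discordant-PET-")
  expect_error(combined_rule(NA, 0.2), "missing")
  expect_error(combined_rule(3, 0.2, suv_cutoff = 0), "positive")
})

test_that("stratified combined metrics partition the cohort", {
  co <- normalize_total_area(generate_cohort(small_config(seed = 30)))
  sm <- stratified_metrics(co)
  expect_equal(sum(sm$category_counts), sm$n)
  expect_equal(sm$n, sum(co$group %in% c("cancer", "inflammation")))
  expect_true(is.na(sm$discordant_miss_fraction) ||
                (sm$discordant_miss_fraction >= 0 &&
                   sm$discordant_miss_fraction <= 1))
  # markers that agree perfectly leave discordant categories empty
  co2 <- co[co$group %in% c("cancer", "inflammation"), ]
  co2$suvmax <- ifelse(co2$IR89 <= 0.31, 10, 1)
  attr(co2, "normalized") <- TRUE
  attr(co2, "n_ir") <- 110L
  class(co2) <- class(co)
  sm2 <- stratified_metrics(co2)
  expect_equal(unname(sm2$category_counts["discordant-PET+"]), 0L,
               ignore_attr = TRUE)
  expect_equal(unname(sm2$category_counts["discordant-PET-"]), 0L,
               ignore_attr = TRUE)
})
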