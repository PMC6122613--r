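# Small cohort configurations used across test files. Fixtures are always
# built in code; nothing is read from disk.

# Downscaled three-group cohort with the default marker structure.
small_config <- function(seed = 1L, n_cancer = 60L, n_inflam = 24L,
                         n_control = 40L) {
  stages <- c(IA = 15L, IIA = 10L, IIIA = 20L, IV = 15L)
  stopifnot(sum(stages) == n_cancer)
  cohort_config(
    groups = list(
      group_spec("cancer", n_cancer, 0.159, 0.156,
                 suvmax_mean = 12.1, suvmax_sd = 7.6,
                 stage_distribution = stages),
      group_spec("inflammation", n_inflam, 0.485, 0.237,
                 suvmax_mean = 4.3, suvmax_sd = 2.8),
      group_spec("control", n_control, 0.152, 0.113)
    ),
    effects = default_effects(),
    seed = seed
  )
}

# Cohort in which one region is, by construction, the only discriminating
# feature after normalization. The marker share is kept at the background
# scale so compositional closure (the common 1 - marker factor applied to
# the other regions) is negligible; at the printed glutamate shares the
# closure factor itself would make every region informative.
one_signal_config <- function(seed = 1L, n_cancer = 40L, n_inflam = 24L,
                              n_ir = 30L) {
  cohort_config(
    groups = list(
      group_spec("cancer", n_cancer, 0.010, 0.003,
                 suvmax_mean = 12.1, suvmax_sd = 7.6,
                 stage_distribution = NULL),
      group_spec("inflammation", n_inflam, 0.022, 0.005,
                 suvmax_mean = 4.3, suvmax_sd = 2.8)
    ),
    effects = list(),
    n_ir = n_ir,
    seed = seed
  )
}

one_signal_features <- function(seed = 1L, glutamate_ir = 20L, ...) {
  co <- generate_cohort(one_signal_config(seed = seed, ...),
                        glutamate_ir = glutamate_ir)
  cohort_features(normalize_total_area(co))
}

# Two separable clouds with a guaranteed margin: bounded uniform noise on
# every feature, classes offset by `shift` (> 2) on feature 1, so the gap
# between classes on feature 1 is at least shift - 2.
toy_clouds <- function(n = 20L, p = 4L, shift = 4, seed = 99L) {
  set.seed(seed)
  x <- matrix(runif(2 * n * p, -1, 1), 2 * n, p)
  x[seq_len(n), 1] <- x[seq_len(n), 1] + shift / 2
  x[n + seq_len(n), 1] <- x[n + seq_len(n), 1] - shift / 2
  list(x = x, y = rep(c("case", "ctrl"), each = n))
}
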