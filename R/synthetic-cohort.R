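#' Moment-matched positive sampler
#'
#' Draws non-negative values from a gamma distribution parameterized by its
#' mean and standard deviation: shape = (mean/sd)^2, scale = sd^2/mean.
#' Relative NMR concentrations are non-negative with coefficients of
#' variation close to 1 in some groups, so a normal model would put
#' substantial mass below zero; the gamma preserves the first two moments
#' exactly on positive support. `sd = 0` returns the constant `mean`.
#'
#' @param mean Positive target mean.
#' @param sd Non-negative target standard deviation.
#' @param n Number of draws (>= 1).
#' @return Numeric vector of `n` non-negative values.
#' @examples
#' set.seed(1)
#' x <- rpositive(0.159, 0.156, 269)
#' c(mean(x), sd(x))
#' @export
rpositive <- function(mean, sd, n) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("'mean' must be a single positive number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("'sd' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  n <- as.integer(n)
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Group specification for the synthetic cohort generator
#'
#' Describes one subject group by its size, its glutamate (IR89)
#' relative-concentration moments, optionally its SUVmax moments (PET-imaged
#' groups only), and optionally a TNM stage distribution (cancer only).
#'
#' @param name Group label, one of `"cancer"`, `"inflammation"`, `"control"`.
#' @param n Subject count.
#' @param glutamate_mean,glutamate_sd Moments of the relative glutamate
#'   concentration (dimensionless fraction of total spectral area).
#' @param suvmax_mean,suvmax_sd Moments of SUVmax, or `NULL` for groups that
#'   were not PET-imaged.
#' @param stage_distribution Named integer vector of TNM stage counts summing
#'   to `n`, or `NULL`.
#' @return An object of class `"group_spec"`.
#' @export
group_spec <- function(name, n, glutamate_mean, glutamate_sd,
                       suvmax_mean = NULL, suvmax_sd = NULL,
                       stage_distribution = NULL) {
  name <- match.arg(name, c("cancer", "inflammation", "control"))
  if (n <= 0) stop("group size must be positive", call. = FALSE)
  if (glutamate_mean <= 0 || glutamate_sd < 0)
    stop("glutamate moments invalid: mean must be > 0, sd >= 0", call. = FALSE)
  if (!is.null(suvmax_mean)) {
    if (suvmax_mean <= 0 || suvmax_sd < 0)
      stop("SUVmax moments invalid: mean must be > 0, sd >= 0", call. = FALSE)
  }
  if (!is.null(stage_distribution)) {
    if (is.null(names(stage_distribution)) || any(!nzchar(names(stage_distribution))))
      stop("stage_distribution must be a named count vector", call. = FALSE)
    if (any(stage_distribution < 0) || sum(stage_distribution) != n)
      stop("stage counts must be non-negative and sum to the group size",
           call. = FALSE)
  }
  structure(
    list(name = name, n = as.integer(n),
         glutamate_mean = glutamate_mean, glutamate_sd = glutamate_sd,
         suvmax_mean = suvmax_mean, suvmax_sd = suvmax_sd,
         stage_distribution = stage_distribution),
    class = "group_spec"
  )
}

#' Effect specification: one IR carrying group-dependent signal
#'
#' @param ir_index Integer in 1..n_ir naming the integration region.
#' @param means,sds Named numeric vectors (names = group labels) giving that
#'   IR's relative-concentration moments per group.
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(ir_index, means, sds) {
  if (length(ir_index) != 1L || ir_index < 1)
    stop("'ir_index' must be a single positive integer", call. = FALSE)
  if (is.null(names(means)) || is.null(names(sds)) ||
      !identical(sort(names(means)), sort(names(sds))))
    stop("'means' and 'sds' must be named per group, with matching names",
         call. = FALSE)
  if (any(means <= 0) || any(sds < 0))
    stop("effect moments invalid: means must be > 0, sds >= 0", call. = FALSE)
  structure(list(ir_index = as.integer(ir_index),
                 means = means, sds = sds[names(means)]),
            class = "effect_spec")
}

## Table of published cancer stage counts (sums to 269)
.default_stages <- c(IA = 53L, IB = 22L, IIA = 16L, IIB = 16L,
                     IIIA = 63L, IIIB = 28L, IV = 71L)

#' Cohort configuration
#'
#' Bundles group specifications, effect specifications, the IR count, the
#' background noise model for non-effect IRs, the SUVmax-marker dependence
#' structure and the seed. The default configuration reproduces the study
#' conditions: 269 cancer / 108 inflammation / 347 control subjects, the
#' published TNM stage counts, glutamate (IR89) relative concentrations of
#' 0.159 +/- 0.156 (cancer), 0.485 +/- 0.237 (inflammation) and
#' 0.152 +/- 0.113 (controls), SUVmax 12.1 +/- 7.6 (cancer) and
#' 4.3 +/- 2.8 (inflammation), and secondary discriminating effects in
#' IR15 and IR96.
#'
#' @param groups List of [group_spec()] objects.
#' @param effects List of [effect_spec()] objects; indices must be distinct.
#' @param n_ir Total number of integration regions (default 110).
#' @param background_mean,background_cv Gamma moments shared by all
#'   non-effect IRs in every group (relative-concentration scale before the
#'   per-subject renormalization described in [generate_cohort()]).
#' @param suvmax_glutamate_rho Gaussian-copula rank correlation between
#'   SUVmax and the glutamate IR within a class; default 0 (conditional
#'   independence given class).
#' @param total_area_mean,total_area_cv Moments of the per-subject total
#'   integrated area used to de-normalize relative values into raw integrals.
#' @param seed Integer seed making generation fully reproducible.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(groups = default_groups(),
                          effects = default_effects(),
                          n_ir = 110L,
                          background_mean = 0.01, background_cv = 0.4,
                          suvmax_glutamate_rho = 0,
                          total_area_mean = 100, total_area_cv = 0.2,
                          seed = 1L) {
  stopifnot(length(groups) >= 1L, n_ir >= 1L)
  if (!all(vapply(groups, inherits, logical(1), "group_spec")))
    stop("'groups' must be a list of group_spec objects", call. = FALSE)
  if (!all(vapply(effects, inherits, logical(1), "effect_spec")))
    stop("'effects' must be a list of effect_spec objects", call. = FALSE)
  idx <- vapply(effects, `[[`, integer(1), "ir_index")
  if (anyDuplicated(idx))
    stop("effect ir indices must be distinct", call. = FALSE)
  if (any(idx > n_ir))
    stop("effect ir_index outside 1..n_ir", call. = FALSE)
  if (abs(suvmax_glutamate_rho) >= 1)
    stop("'suvmax_glutamate_rho' must lie in (-1, 1)", call. = FALSE)
  structure(
    list(groups = groups, effects = effects, n_ir = as.integer(n_ir),
         background_mean = background_mean, background_cv = background_cv,
         suvmax_glutamate_rho = suvmax_glutamate_rho,
         total_area_mean = total_area_mean, total_area_cv = total_area_cv,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_groups <- function() {
  list(
    group_spec("cancer", 269, 0.159, 0.156,
               suvmax_mean = 12.1, suvmax_sd = 7.6,
               stage_distribution = .default_stages),
    group_spec("inflammation", 108, 0.485, 0.237,
               suvmax_mean = 4.3, suvmax_sd = 2.8),
    group_spec("control", 347, 0.152, 0.113)
  )
}

#' @rdname cohort_config
#' @export
default_effects <- function(glutamate_ir = 89L) {
  ## IR89 moments come from the group specs; IR15 (tyrosine) and IR96
  ## (alanine/isoleucine/lysine) carry smaller configurable separations.
  list(
    effect_spec(15L,
                means = c(cancer = 0.008, inflammation = 0.012, control = 0.010),
                sds = c(cancer = 0.003, inflammation = 0.004, control = 0.003)),
    effect_spec(96L,
                means = c(cancer = 0.020, inflammation = 0.028, control = 0.024),
                sds = c(cancer = 0.006, inflammation = 0.008, control = 0.007))
  )
}

#' Generate a synthetic cohort
#'
#' Draws a cohort whose group sizes, stage counts, SUVmax distributions and
#' effect-IR relative concentrations match the configuration. Effect IRs
#' (including the glutamate IR, taken from each group's glutamate moments)
#' are sampled as target relative concentrations; the remaining background
#' IRs are sampled from a shared gamma and rescaled within each subject to
#' fill the remaining probability mass, so that total-area normalization
#' recovers the configured relative values exactly. The emitted table holds
#' raw integrals (relative values multiplied by a per-subject total area);
#' `normalized` is `FALSE`.
#'
#' Relative concentrations live on the simplex, so subjects whose summed
#' effect values reach the compositional bound (0.999) are resampled. The
#' realized effect-IR moments are therefore those of the configured gamma
#' truncated at that bound. For the default cancer and control groups the
#' truncated mass is below 0.3%; for the inflammation group the configured
#' gamma places about 3% of its mass above 1, so its realized relative
#' glutamate mean is about 0.46 rather than 0.485 --- an intrinsic
#' consequence of imposing printed unbounded moments on bounded
#' compositional data, about one within-group standard error at n = 108.
#'
#' @param config A [cohort_config()].
#' @param glutamate_ir IR index that carries the glutamate signal
#'   (default 89).
#' @return An object of class `"cohort"`: a data frame with columns
#'   `subject_id`, `group`, `stage`, `suvmax`, `IR1` ... `IRn`, plus a
#'   `normalized` attribute.
#' @export
generate_cohort <- function(config = cohort_config(), glutamate_ir = 89L) {
  stopifnot(inherits(config, "cohort_config"))
  if (glutamate_ir < 1 || glutamate_ir > config$n_ir)
    stop("'glutamate_ir' outside 1..n_ir", call. = FALSE)
  eff_idx <- vapply(config$effects, `[[`, integer(1), "ir_index")
  if (glutamate_ir %in% eff_idx)
    stop("glutamate IR must not also appear in 'effects'", call. = FALSE)
  set.seed(config$seed)

  rows <- lapply(config$groups, function(g)
    .generate_group(g, config, glutamate_ir))
  out <- do.call(rbind, rows)
  out$subject_id <- sprintf("S%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[, c("subject_id", "group", "stage", "suvmax",
                 paste0("IR", seq_len(config$n_ir)))]
  structure(out, normalized = FALSE, n_ir = config$n_ir,
            class = c("cohort", "data.frame"))
}

.generate_group <- function(g, config, glutamate_ir) {
  n <- g$n
  n_ir <- config$n_ir
  eff_idx <- c(glutamate_ir, vapply(config$effects, `[[`, integer(1), "ir_index"))
  eff_mean <- c(g$glutamate_mean,
                vapply(config$effects, function(e) unname(e$means[g$name]),
                       numeric(1)))
  eff_sd <- c(g$glutamate_sd,
              vapply(config$effects, function(e) unname(e$sds[g$name]),
                     numeric(1)))
  if (anyNA(eff_mean) || anyNA(eff_sd))
    stop("effect_spec missing moments for group '", g$name, "'", call. = FALSE)

  ## Effect IRs on the relative-concentration scale, with rejection of the
  ## (rare) draws whose sum leaves no mass for the background regions.
  eff <- matrix(0, n, length(eff_idx))
  for (j in seq_along(eff_idx))
    eff[, j] <- rpositive(eff_mean[j], eff_sd[j], n)
  bad <- rowSums(eff) >= 0.999
  while (any(bad)) {
    for (j in seq_along(eff_idx))
      eff[bad, j] <- rpositive(eff_mean[j], eff_sd[j], sum(bad))
    bad <- rowSums(eff) >= 0.999
  }

  ## Background IRs: iid gamma, identical across groups, rescaled per
  ## subject so the full relative vector sums to one.
  bg_idx <- setdiff(seq_len(n_ir), eff_idx)
  bg_sd <- config$background_mean * config$background_cv
  bg <- matrix(rpositive(config$background_mean, bg_sd, n * length(bg_idx)),
               n, length(bg_idx))
  bg <- bg * (1 - rowSums(eff)) / rowSums(bg)

  rel <- matrix(0, n, n_ir)
  rel[, eff_idx] <- eff
  rel[, bg_idx] <- bg

  ## De-normalize into raw integrals with a per-subject total area.
  area <- rpositive(config$total_area_mean,
                    config$total_area_mean * config$total_area_cv, n)
  raw <- rel * area

  suv <- rep(NA_real_, n)
  if (!is.null(g$suvmax_mean)) {
    rho <- config$suvmax_glutamate_rho
    if (rho == 0) {
      suv <- rpositive(g$suvmax_mean, g$suvmax_sd, n)
    } else {
      ## Gaussian copula: couple the SUVmax quantile to the glutamate
      ## quantile with the configured rank correlation.
      shape_g <- (g$glutamate_mean / g$glutamate_sd)^2
      u_glu <- stats::pgamma(eff[, 1], shape = shape_g,
                             scale = g$glutamate_sd^2 / g$glutamate_mean)
      z <- rho * stats::qnorm(pmin(pmax(u_glu, 1e-12), 1 - 1e-12)) +
        sqrt(1 - rho^2) * stats::rnorm(n)
      shape_s <- (g$suvmax_mean / g$suvmax_sd)^2
      suv <- stats::qgamma(stats::pnorm(z), shape = shape_s,
                           scale = g$suvmax_sd^2 / g$suvmax_mean)
    }
  }

  stage <- rep(NA_character_, n)
  if (!is.null(g$stage_distribution))
    stage <- rep(names(g$stage_distribution), times = g$stage_distribution)

  df <- data.frame(subject_id = NA_character_, group = g$name, stage = stage,
                   suvmax = suv, stringsAsFactors = FALSE)
  raw <- as.data.frame(raw)
  names(raw) <- paste0("IR", seq_len(n_ir))
  cbind(df, raw)
}

#' @export
print.cohort <- function(x, ...) {
  n_ir <- attr(x, "n_ir")
  cat("Synthetic plasma NMR cohort:", nrow(x), "subjects,",
      n_ir, "integration regions\n")
  print(table(x$group))
  cat("Values are",
      if (isTRUE(attr(x, "normalized"))) "relative concentrations (sum 1)"
      else "raw integrals", "\n")
  invisible(x)
}

.ir_cols <- function(cohort) grep("^IR[0-9]+$", names(cohort), value = TRUE)

.ir_matrix <- function(cohort) {
  as.matrix(cohort[, .ir_cols(cohort), drop = FALSE])
}

#' Write / read a cohort as CSV
#'
#' Layout: header `subject_id,group,stage,suvmax,IR1,...,IRn`; empty cells
#' for inapplicable stage/SUVmax; UTF-8; decimal point. Numeric values are
#' written with 17 significant digits so a round trip preserves them to
#' full double precision.
#'
#' @param cohort A `"cohort"` object.
#' @param path Destination / source file path.
#' @return `read_cohort()` returns a `"cohort"`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  df$stage[is.na(cohort$stage)] <- ""
  header <- paste0("# normalized=", tolower(as.character(isTRUE(attr(cohort, "normalized")))))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param n_ir Expected IR column count; `NULL` accepts whatever the file
#'   carries.
#' @export
read_cohort <- function(path, n_ir = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  normalized <- identical(first, "# normalized=true")
  skip <- if (startsWith(first, "# normalized=")) 1L else 0L
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = NA)
  required <- c("subject_id", "group", "stage", "suvmax")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty subject table", call. = FALSE)
  ir <- grep("^IR[0-9]+$", names(df), value = TRUE)
  if (length(ir) == 0L) stop("no IR columns found", call. = FALSE)
  if (!is.null(n_ir) && length(ir) != n_ir)
    stop("expected ", n_ir, " IR columns, found ", length(ir), call. = FALSE)
  n_ir <- length(ir)
  if (!identical(ir, paste0("IR", seq_len(n_ir))))
    stop("IR columns must be IR1..IR", n_ir, " in order", call. = FALSE)
  for (col in ir) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("non-numeric IR cell at row ", bad, ", column ", col, call. = FALSE)
    }
  }
  unknown <- setdiff(unique(df$group), c("cancer", "inflammation", "control"))
  if (length(unknown))
    stop("unknown group label at row ", which(df$group %in% unknown)[1],
         ", column group: ", unknown[1], call. = FALSE)
  df$stage <- as.character(df$stage)
  structure(df, normalized = normalized, n_ir = n_ir,
            class = c("cohort", "data.frame"))
}
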