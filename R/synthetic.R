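# Synthetic two-phenotype cohorts with the statistical structure the
# analysis assumes: a ferroptosis-like panel in which a planted fraction of
# driver genes is up-shifted and a planted fraction of suppressor genes is
# down-shifted in cases, Gaussian noise, nuisance background genes, and
# survival times whose hazard rises with the latent (planted) score.

#' Configuration for a synthetic cohort
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 40 cases vs 40 controls, a 150-gene panel (60 drivers, 60
#' suppressors, 30 markers) plus 500 background genes, a 1.0 log2-unit
#' shift planted on half of the drivers (up in cases) and half of the
#' suppressors (down in cases), residual SD 0.7, and a hazard ratio of 2
#' per SD of the latent score over a 3-year (1095-day) horizon.
#'
#' @param n_case,n_control sample counts per phenotype.
#' @param n_driver,n_suppressor,n_marker,n_background gene counts.
#' @param delta_driver mean log2 up-shift of planted driver genes in cases.
#' @param delta_suppressor mean log2 down-shift of planted suppressor genes.
#' @param planted_fraction fraction of drivers/suppressors carrying a shift.
#' @param sigma residual (within-group) SD on the log2 scale.
#' @param baseline_mean mean of per-gene baselines (log2 units).
#' @param hazard_ratio_per_sd multiplicative hazard per 1 SD of latent score.
#' @param censor_rate expected censored fraction for an average sample.
#' @param horizon follow-up horizon in days.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_case = 40, n_control = 40,
                          n_driver = 60, n_suppressor = 60, n_marker = 30,
                          n_background = 500,
                          delta_driver = 1.0, delta_suppressor = 1.0,
                          planted_fraction = 0.5, sigma = 0.7,
                          baseline_mean = 6.0,
                          hazard_ratio_per_sd = 2.0, censor_rate = 0.5,
                          horizon = 1095, seed = 1L) {
  cfg <- list(n_case = n_case, n_control = n_control, n_driver = n_driver,
              n_suppressor = n_suppressor, n_marker = n_marker,
              n_background = n_background, delta_driver = delta_driver,
              delta_suppressor = delta_suppressor,
              planted_fraction = planted_fraction, sigma = sigma,
              baseline_mean = baseline_mean,
              hazard_ratio_per_sd = hazard_ratio_per_sd,
              censor_rate = censor_rate, horizon = horizon,
              seed = as.integer(seed))
  counts <- c("n_case", "n_control", "n_driver", "n_suppressor",
              "n_marker", "n_background")
  for (nm in counts) {
    if (nm == "n_background") next
    if (cfg[[nm]] < 1) stop(nm, " must be a positive count")
  }
  if (cfg$n_background < 0) stop("n_background must be non-negative")
  if (cfg$planted_fraction <= 0 || cfg$planted_fraction > 1) {
    stop("planted_fraction must lie in (0, 1]")
  }
  if (cfg$sigma <= 0) stop("sigma must be positive")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)")
  }
  if (cfg$hazard_ratio_per_sd <= 0) stop("hazard_ratio_per_sd must be positive")
  if (cfg$horizon <= 0) stop("horizon must be positive")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate the gene universe for a synthetic cohort
#'
#' Deterministic given the config seed; symbol sets are disjoint across
#' categories by construction (`DRV*`, `SUP*`, `MRK*`, `BG*`).
#'
#' @param config a [cohort_config()].
#' @return list with `panel` (a `ferro_gene_set`) and `background`
#'   (character vector of background gene symbols).
#' @export
generate_gene_universe <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sym <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  panel <- data.frame(
    symbol = c(sym("DRV", config$n_driver), sym("SUP", config$n_suppressor),
               sym("MRK", config$n_marker)),
    category = rep(c("driver", "suppressor", "marker"),
                   c(config$n_driver, config$n_suppressor, config$n_marker)),
    stringsAsFactors = FALSE)
  class(panel) <- c("ferro_gene_set", "data.frame")
  list(panel = panel, background = sym("BG", config$n_background))
}

#' Generate a synthetic expression cohort
#'
#' Expression follows `x[g, s] = baseline_g + shift_g * 1[s is case] +
#' N(0, sigma^2)` with `baseline_g ~ N(baseline_mean, 1)`; `shift_g` is
#' `+delta_driver` for a planted subset of drivers, `-delta_suppressor`
#' for a planted subset of suppressors, 0 otherwise. The latent score per
#' sample is the standardized difference between mean planted-driver and
#' mean planted-suppressor expression; it drives the optional survival
#' layer ([attach_survival()]).
#'
#' @param config a [cohort_config()].
#' @return list with `expression` (matrix), `phenotypes` (data.frame),
#'   `panel`, and `truth` (planted gene sets + latent scores).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  uni <- generate_gene_universe(config)
  panel <- uni$panel
  genes <- c(panel$symbol, uni$background)
  n <- config$n_case + config$n_control
  samples <- sprintf("S%03d", seq_len(n))
  is_case <- c(rep(TRUE, config$n_case), rep(FALSE, config$n_control))

  drivers <- panel$symbol[panel$category == "driver"]
  suppressors <- panel$symbol[panel$category == "suppressor"]
  n_pd <- max(1L, round(config$planted_fraction * length(drivers)))
  n_ps <- max(1L, round(config$planted_fraction * length(suppressors)))
  planted_up <- sort(sample(drivers, n_pd))
  planted_down <- sort(sample(suppressors, n_ps))

  shift <- setNames(numeric(length(genes)), genes)
  shift[planted_up] <- config$delta_driver
  shift[planted_down] <- -config$delta_suppressor

  baseline <- rnorm(length(genes), config$baseline_mean, 1)
  expr <- baseline + outer(shift, as.numeric(is_case)) +
    matrix(rnorm(length(genes) * n, 0, config$sigma),
           nrow = length(genes))
  dimnames(expr) <- list(genes, samples)

  latent <- colMeans(expr[planted_up, , drop = FALSE]) -
    colMeans(expr[planted_down, , drop = FALSE])
  latent <- as.numeric(scale(latent))

  pheno <- data.frame(
    sample_id = samples,
    diagnosis = ifelse(is_case, "TCMR", "non_rejection"),
    stringsAsFactors = FALSE)

  list(expression = expr, phenotypes = pheno, panel = panel,
       truth = list(planted_up = planted_up, planted_down = planted_down,
                    latent_scores = setNames(latent, samples)),
       config = config)
}

#' Attach survival outcomes driven by the latent score
#'
#' Failure times are exponential with hazard `h0 * HR^z` where `z` is the
#' standardized latent score, `HR = hazard_ratio_per_sd` and
#' `h0 = log(2) / horizon` (median survival at the horizon for an average
#' sample). Censoring is independent exponential with rate chosen so the
#' expected censored fraction at `z = 0` equals `censor_rate`;
#' `censor_rate = 0` means no censoring.
#'
#' @param phenotypes phenotype data.frame with `sample_id`.
#' @param latent_scores named numeric vector, standardized (mean 0, SD 1).
#' @param config a [cohort_config()].
#' @return phenotypes with `time` and `event` columns added.
#' @export
attach_survival <- function(phenotypes, latent_scores, config) {
  stopifnot(inherits(config, "cohort_config"))
  z <- latent_scores[phenotypes$sample_id]
  if (any(is.na(z))) {
    stop("missing latent score for sample(s): ",
         paste(phenotypes$sample_id[is.na(z)], collapse = ", "))
  }
  set.seed(config$seed + 77003L)
  h0 <- log(2) / config$horizon
  haz <- h0 * config$hazard_ratio_per_sd^z
  t_fail <- rexp(length(z), rate = haz)
  if (config$censor_rate > 0) {
    mu <- h0 * config$censor_rate / (1 - config$censor_rate)
    t_cens <- rexp(length(z), rate = mu)
  } else {
    t_cens <- rep(Inf, length(z))
  }
  phenotypes$time <- pmin(t_fail, t_cens)
  phenotypes$event <- as.numeric(t_fail <= t_cens)
  phenotypes
}

#' Simulate a cohort and write its artifacts to disk
#'
#' Writes `expression.tsv`, `phenotypes.csv`, `panel.tsv` and `truth.json`
#' under `out_dir`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if absent).
#' @param survival attach survival outcomes.
#' @return the cohort list from [generate_cohort()], invisibly.
#' @export
simulate_cohort <- function(config, out_dir, survival = TRUE) {
  cohort <- generate_cohort(config)
  if (survival) {
    cohort$phenotypes <- attach_survival(cohort$phenotypes,
                                         cohort$truth$latent_scores, config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(out_dir, "expression.tsv"))
  utils::write.csv(cohort$phenotypes, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  write_gene_set(cohort$panel, file.path(out_dir, "panel.tsv"))
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}
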