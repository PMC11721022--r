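# Synthetic retention-data generator. Emulates the statistical structure the
# pipeline assumes: per compound x system, the retention index is linear in
# the modifier fraction (index = X_true - S * phi) with Gaussian noise on the
# index scale, measured in triplicate over the system's phi grid; each
# system maps true log P to the true intercept through the inverse of its
# calibration line, X_true = (logP - b)/a.

#' The twelve default chromatographic systems
#'
#' TLC and HPLC on RP18, RP8 and CN phases with methanol or acetonitrile,
#' with the modifier concentration windows used in practice for the gliflozin
#' series (TLC: RP 35-60% ACN / 60-85% MeOH, CN 40-60% ACN / 45-65% MeOH;
#' HPLC: RP 35-60% ACN / 55-80% MeOH, CN 30-55% ACN / 45-70% MeOH), stepped
#' at 5%.
#'
#' @param n_phi Optional number of equally spaced grid points per system; the
#'   default `NULL` uses the 5% step grids.
#' @return Tibble: `method`, `technique`, `phase`, `modifier`, `phi_grid`
#'   (list-column of fractions).
#' @export
default_systems <- function(n_phi = NULL) {
  ranges <- tibble::tribble(
    ~technique, ~phase, ~modifier,      ~phi_min, ~phi_max,
    "TLC",  "RP18", "acetonitrile", 0.35, 0.60,
    "TLC",  "RP18", "methanol",     0.60, 0.85,
    "TLC",  "RP8",  "acetonitrile", 0.35, 0.60,
    "TLC",  "RP8",  "methanol",     0.60, 0.85,
    "TLC",  "CN",   "acetonitrile", 0.40, 0.60,
    "TLC",  "CN",   "methanol",     0.45, 0.65,
    "HPLC", "RP18", "acetonitrile", 0.35, 0.60,
    "HPLC", "RP18", "methanol",     0.55, 0.80,
    "HPLC", "RP8",  "acetonitrile", 0.35, 0.60,
    "HPLC", "RP8",  "methanol",     0.55, 0.80,
    "HPLC", "CN",   "acetonitrile", 0.30, 0.55,
    "HPLC", "CN",   "methanol",     0.45, 0.70
  )
  ranges$method <- system_label(ranges$technique, ranges$phase, ranges$modifier)
  ranges$phi_grid <- lapply(seq_len(nrow(ranges)), function(i) {
    if (is.null(n_phi)) {
      seq(ranges$phi_min[i], ranges$phi_max[i], by = 0.05)
    } else {
      seq(ranges$phi_min[i], ranges$phi_max[i], length.out = n_phi)
    }
  })
  ranges[c("method", "technique", "phase", "modifier", "phi_grid")]
}

#' Default test-compound set for the generator
#'
#' The five gliflozins with true log P set to their published mean
#' experimental values (2-decimal precision).
#'
#' @return Tibble: `compound`, `logp_true`.
#' @export
default_drugs <- function() {
  tibble::tibble(
    compound = c("CANA", "DAPA", "EMPA", "ERTU", "SOTA"),
    logp_true = c(3.99, 2.83, 2.29, 3.04, 3.94)
  )
}

#' Configuration of the synthetic retention-data generator
#'
#' Collects everything the generator needs: the chromatographic systems with
#' their \eqn{\varphi} grids, the reference standards and test drugs with
#' their true log P, the per-system calibration map (true intercept
#' \eqn{X_{true} = (\log P - b)/a}), the slope rule, the noise level, the
#' replicate count, the HPLC dead time and the mandatory seed.
#'
#' True slopes are tied to the true intercept through the grid midpoint,
#' \eqn{S = X_{true}/\bar{\varphi}} with a seeded multiplicative jitter
#' (`slope_jitter`, default +/-10%), so every compound elutes inside the
#' measured window — mirroring the slope-intercept collinearity typical of a
#' congeneric series.
#'
#' @param systems Systems tibble as from [default_systems()].
#' @param standards Standards tibble (`compound`, `logp_lit`); default
#'   [gliflozin_standards()].
#' @param drugs Drugs tibble (`compound`, `logp_true`); default
#'   [default_drugs()].
#' @param coefs Per-system calibration coefficients (`method`, `slope_a`,
#'   `intercept_b`); default [calibration_coefficients()].
#' @param noise_sd Gaussian standard deviation on the retention index
#'   (default 0.02).
#' @param replicates Replicate measurements per point (default 3).
#' @param t0 HPLC dead time in minutes (default 1.0).
#' @param slope_jitter Length-2 range of the multiplicative slope jitter
#'   (default `c(0.9, 1.1)`).
#' @param seed Integer seed; mandatory for any stochastic run.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(systems = default_systems(),
                             standards = gliflozin_standards(),
                             drugs = default_drugs(),
                             coefs = calibration_coefficients(),
                             noise_sd = 0.02,
                             replicates = 3,
                             t0 = 1.0,
                             slope_jitter = c(0.9, 1.1),
                             seed) {
  if (missing(seed) || !is.finite(seed)) abort("A `seed` is mandatory.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (t0 <= 0) abort("`t0` must be > 0.")
  if (any(coefs$slope_a == 0)) abort("Calibration slope a must be nonzero.")
  missing_sys <- setdiff(systems$method, coefs$method)
  if (length(missing_sys)) {
    abort(paste0("No calibration coefficients for system(s): ",
                 paste(missing_sys, collapse = ", ")))
  }
  structure(
    list(systems = systems, standards = standards, drugs = drugs,
         coefs = coefs, noise_sd = noise_sd, replicates = as.integer(replicates),
         t0 = t0, slope_jitter = slope_jitter, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# one row per compound x system with true intercept and slope; consumes the
# first length(compounds)*length(systems) uniforms of the active RNG stream
.draw_truth <- function(config) {
  compounds <- dplyr::bind_rows(
    tibble::tibble(compound = config$standards$compound, role = "standard",
                   logp_true = config$standards$logp_lit),
    tibble::tibble(compound = config$drugs$compound, role = "drug",
                   logp_true = config$drugs$logp_true)
  )
  grid <- tidyr::crossing(compounds, method = config$systems$method)
  grid <- dplyr::inner_join(grid, config$coefs[c("method", "slope_a", "intercept_b")],
                            by = "method")
  phi_mid <- vapply(config$systems$phi_grid, function(g) mean(range(g)), numeric(1))
  grid <- dplyr::inner_join(
    grid, tibble::tibble(method = config$systems$method, phi_mid = phi_mid),
    by = "method"
  )
  grid <- grid[order(grid$compound, grid$method), ]
  grid$x_true <- (grid$logp_true - grid$intercept_b) / grid$slope_a
  jitter <- runif(nrow(grid), config$slope_jitter[1], config$slope_jitter[2])
  grid$slope_S <- grid$x_true / grid$phi_mid * jitter
  grid[c("compound", "role", "logp_true", "method", "x_true", "slope_S")]
}

#' True parameter table of a generator configuration
#'
#' The per-compound, per-system ground truth implied by a configuration and
#' its seed: true log P, true intercept \eqn{X_{true}} and true slope
#' \eqn{S}. Matches exactly the truth used by [generate_dataset()] for the
#' same config.
#'
#' @param config A `generator_config`.
#' @return Tibble: `compound`, `role`, `logp_true`, `method`, `x_true`,
#'   `slope_S`.
#' @export
truth_table <- function(config) {
  withr::with_seed(config$seed, .draw_truth(config))
}

#' Generate a synthetic retention dataset
#'
#' Draws, for every compound x system x \eqn{\varphi} x replicate, a
#' retention index \eqn{X_{true} - S\varphi + N(0, \sigma)} and converts it
#' to the raw observable: TLC records invert the \eqn{R_M} transform to an
#' \eqn{R_F}; HPLC records produce \eqn{t_R = t_0 (1 + 10^{\log k})}. TLC
#' indices whose \eqn{R_F} falls outside (0.01, 0.99) are redrawn (at most
#' 100 times each, counted in the `redraws` attribute) rather than truncated,
#' so the index distribution stays unbiased. Fully reproducible from the
#' config seed.
#'
#' @param config A `generator_config`.
#' @return Validated retention record tibble (schema of [read_retention()])
#'   with attribute `redraws` (total redrawn observations).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must be a generator_config.")
  }
  withr::with_seed(config$seed, {
    truth <- .draw_truth(config)
    sys_tbl <- tibble::tibble(
      method = config$systems$method,
      technique = config$systems$technique,
      phase = config$systems$phase,
      modifier = config$systems$modifier,
      phi_grid = config$systems$phi_grid
    )
    design <- dplyr::inner_join(truth, sys_tbl, by = "method")
    design <- tidyr::unnest(
      dplyr::mutate(design, phi = .data$phi_grid), "phi"
    )
    design$phi_grid <- NULL
    design <- tidyr::crossing(design, replicate = seq_len(config$replicates))
    design <- design[order(design$compound, design$method, design$phi,
                           design$replicate), ]
    mu <- design$x_true - design$slope_S * design$phi
    value <- mu + rnorm(nrow(design), 0, config$noise_sd)
    redraws <- 0L
    tlc <- design$technique == "TLC"
    bad <- tlc & (rf_from_rm(value) <= 0.01 | rf_from_rm(value) >= 0.99)
    attempts <- 0L
    while (any(bad)) {
      attempts <- attempts + 1L
      if (attempts > 100L) {
        abort(sprintf(
          "Generation failed: %d TLC observation(s) persistently give R_F outside (0.01, 0.99); first offender %s / %s at phi = %.2f",
          sum(bad), design$compound[which(bad)[1]],
          design$method[which(bad)[1]], design$phi[which(bad)[1]]
        ))
      }
      redraws <- redraws + sum(bad)
      value[bad] <- mu[bad] + rnorm(sum(bad), 0, config$noise_sd)
      bad <- tlc & (rf_from_rm(value) <= 0.01 | rf_from_rm(value) >= 0.99)
    }
    design$rf <- ifelse(tlc, rf_from_rm(value), NA_real_)
    design$tr <- ifelse(tlc, NA_real_, config$t0 * (1 + 10^value))
    design$t0 <- ifelse(tlc, NA_real_, config$t0)
    out <- validate_retention(design[c(
      "compound", "role", "technique", "phase", "modifier", "phi",
      "replicate", "rf", "tr", "t0"
    )])
    attr(out, "redraws") <- redraws
    out
  })
}

#' Recover drug log P from one synthetic dataset
#'
#' Runs the full analysis chain — generate, aggregate replicates,
#' extrapolate to 100% water, calibrate on the standards, predict — and
#' joins the per-drug, per-system predictions with the generator truth.
#'
#' @param config A `generator_config`.
#' @param min_r2 Extrapolation quality threshold (warnings only).
#' @return Tibble: `drug`, `method`, `logp_hat`, `logp_true`, `error`.
#' @export
recover_logp <- function(config, min_r2 = 0.9) {
  records <- generate_dataset(config)
  indices <- aggregate_replicates(records)
  extrap <- extrapolate_dataset(indices, min_r2 = min_r2)
  models <- calibrate_dataset(extrap, config$standards)
  pred <- predict_dataset(models, extrap)
  long <- tidyr::pivot_longer(pred, -"drug", names_to = "method",
                              values_to = "logp_hat")
  long <- dplyr::inner_join(
    long,
    tibble::tibble(drug = config$drugs$compound,
                   logp_true = config$drugs$logp_true),
    by = "drug"
  )
  long$error <- long$logp_hat - long$logp_true
  long
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeats [recover_logp()] over `n_reps` seeded replications (seeds
#' `seed + 1, ..., seed + n_reps`) and summarizes the bias and RMSE of the
#' recovered log P per drug and per system.
#'
#' @param config A `generator_config`; its seed anchors the replication
#'   seeds.
#' @param n_reps Number of replications (>= 1).
#' @param min_r2 Extrapolation quality threshold.
#' @return List with `per_drug` and `per_system` tibbles (`bias`, `rmse`,
#'   `n`) and the raw `errors` tibble.
#' @export
recovery_experiment <- function(config, n_reps, min_r2 = 0.9) {
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  runs <- lapply(seq_len(n_reps), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    res <- tryCatch(
      recover_logp(cfg, min_r2 = min_r2),
      error = function(e) abort(sprintf("Recovery run %d failed: %s", i,
                                        conditionMessage(e)))
    )
    res$rep <- i
    res
  })
  errors <- dplyr::bind_rows(runs)
  summarize_err <- function(df, key) {
    out <- dplyr::summarise(
      dplyr::group_by(df, .data[[key]]),
      bias = mean(.data$error),
      rmse = sqrt(mean(.data$error^2)),
      n = dplyr::n(),
      .groups = "drop"
    )
    out
  }
  list(
    per_drug = summarize_err(errors, "drug"),
    per_system = summarize_err(errors, "method"),
    errors = errors
  )
}
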