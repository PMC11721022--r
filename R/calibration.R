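#' Calibrate a chromatographic lipophilicity scale against standards
#'
#' Regresses the literature log P of a set of reference standards on their
#' extrapolated retention index (\eqn{R_{MW}} or \eqn{\log k_W}) for one
#' chromatographic system, giving the calibration line
#' \deqn{\log P_{EXP} = a X + b}
#' together with the Pearson correlation \eqn{r}, the standard error of
#' estimate \eqn{s = \sqrt{SSE/(n-2)}}, the Fisher statistic
#' \eqn{F = (n-2)\, r^2 / (1-r^2)} and its upper-tail p-value on
#' \eqn{F(1, n-2)} (equivalent to a two-sided t-test on \eqn{r}).
#'
#' @param x Extrapolated retention index of each standard.
#' @param logp Literature log P of each standard (same order).
#' @param system Optional method label carried into the model object.
#' @param compound Optional standard identifiers (for residual reporting).
#' @return An object of class `calibration_model`: list with `a`, `b`, `r`,
#'   `p`, `s`, `F`, `n`, `fitted`, `system`, `compound`, `x`, `logp`. For an
#'   exact fit (\eqn{|r| = 1}) `F` is `Inf` and `p` is 0.
#' @examples
#' m <- fit_calibration(x = c(1, 2, 3, 4, 5, 6) / 2,
#'                      logp = c(0.62, 1.28, 1.81, 2.27, 2.70, 3.5))
#' predict_logp(m, 4.0)
#' @export
fit_calibration <- function(x, logp, system = NULL, compound = NULL) {
  if (length(x) != length(logp)) abort("`x` and `logp` lengths differ.")
  keep <- is.finite(x) & is.finite(logp)
  if (!all(keep)) abort("Calibration inputs must be finite.")
  n <- length(x)
  if (n < 3) abort("Calibration needs at least 3 standards.")
  if (var(x) == 0) abort("Degenerate calibration: retention indices all equal.")
  fit <- lm(logp ~ x)
  sse <- sum(fit$residuals^2)
  syy <- sum((logp - mean(logp))^2)
  r <- cor(x, logp)
  Fstat <- if (abs(r) >= 1 - 1e-15) Inf else (n - 2) * r^2 / (1 - r^2)
  structure(
    list(
      a = unname(coef(fit)[2]),
      b = unname(coef(fit)[1]),
      r = r,
      p = pf(Fstat, 1, n - 2, lower.tail = FALSE),
      s = sqrt(sse / (n - 2)),
      F = Fstat,
      n = n,
      fitted = unname(fit$fitted.values),
      system = system,
      compound = compound,
      x = x,
      logp = logp
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model>%s log P_EXP = %.4f x + %.4f  (n = %d, r = %.4f, s = %.4f, F = %.4g, p = %.2g)\n",
    if (is.null(x$system)) "" else paste0(" ", x$system, ":"),
    x$a, x$b, x$n, x$r, x$s, x$F, x$p
  ))
  invisible(x)
}

#' Predict experimental log P from a calibration model
#'
#' Applies the calibration line \eqn{\log P_{EXP} = a X + b} to extrapolated
#' retention indices of test compounds. Predictions outside the standards'
#' calibrated index range are returned (lipophilic drugs routinely exceed the
#' standards' log P span) but can be identified with the `extrapolated`
#' attribute when `flag_range = TRUE`.
#'
#' @param model A `calibration_model`.
#' @param x Retention index (scalar or vector).
#' @param flag_range If `TRUE`, attach a logical attribute `extrapolated`
#'   marking predictions outside the standards' index range.
#' @return Numeric vector of predicted log P values.
#' @export
predict_logp <- function(model, x, flag_range = FALSE) {
  if (!inherits(model, "calibration_model")) {
    abort("`model` must be a fitted calibration_model.")
  }
  out <- model$a * x + model$b
  if (flag_range) {
    attr(out, "extrapolated") <- x < min(model$x) | x > max(model$x)
  }
  out
}

#' Back-fit residuals of a calibration
#'
#' Re-predicts the calibration standards with their own fitted model and
#' reports the residual \eqn{\log P_{EXP}(X_i) - \log P_{lit,i}} per
#' standard. These residuals are the OLS residuals with the sign flipped, so
#' they sum to zero; their spread across systems measures how faithfully a
#' chromatographic scale reproduces known lipophilicities.
#'
#' @param model A `calibration_model` fitted with `compound` identifiers.
#' @param standards Optional tibble with columns `compound` and `logp_lit`;
#'   defaults to the standards stored in the model.
#' @return Tibble with `compound`, `logp_lit`, `logp_exp`, `residual`.
#' @export
backfit_residuals <- function(model, standards = NULL) {
  if (!inherits(model, "calibration_model")) {
    abort("`model` must be a fitted calibration_model.")
  }
  compound <- model$compound %||% paste0("std", seq_len(model$n))
  if (!is.null(standards)) {
    idx <- match(standards$compound, compound)
    if (anyNA(idx)) {
      abort(paste0("Standard(s) not in the model: ",
                   paste(standards$compound[is.na(idx)], collapse = ", ")))
    }
    compound <- compound[idx]
    lit <- model$logp[idx]
    pred <- model$fitted[idx]
  } else {
    lit <- model$logp
    pred <- model$fitted
  }
  tibble::tibble(
    compound = compound,
    logp_lit = lit,
    logp_exp = pred,
    residual = pred - lit
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit one calibration model per chromatographic system
#'
#' Joins an extrapolation result table (standards only) with a standards
#' table of literature log P and fits [fit_calibration()] per system.
#'
#' @param extrap Extrapolation results from [extrapolate_dataset()]; rows
#'   with `role == "standard"` are used.
#' @param standards Tibble with columns `compound`, `logp_lit` (see
#'   [gliflozin_standards()] for the packaged default set).
#' @return Named list of `calibration_model` objects, one per `method` label.
#' @export
calibrate_dataset <- function(extrap, standards) {
  std <- dplyr::filter(extrap, .data$role == "standard", .data$flags != "unfit")
  std <- dplyr::inner_join(std, standards[c("compound", "logp_lit")],
                           by = "compound")
  if (nrow(std) == 0) abort("No standard compounds found in the extrapolation table.")
  methods <- sort(unique(std$method))
  models <- lapply(methods, function(m) {
    g <- std[std$method == m, ]
    fit_calibration(g$intercept, g$logp_lit, system = m, compound = g$compound)
  })
  setNames(models, methods)
}

#' Tidy coefficient table of per-system calibrations
#'
#' @param models Named list of `calibration_model` objects from
#'   [calibrate_dataset()].
#' @return Tibble with one row per system: `method`, `a`, `b`, `r`, `p`, `s`,
#'   `F`, `n`.
#' @export
calibration_table <- function(models) {
  dplyr::bind_rows(lapply(models, function(m) {
    tibble::tibble(method = m$system %||% NA_character_, a = m$a, b = m$b,
                   r = m$r, p = m$p, s = m$s, F = m$F, n = m$n)
  }))
}

#' Predict experimental log P for test compounds across systems
#'
#' Applies each system's calibration model to the extrapolated retention
#' indices of the test (drug) compounds and assembles the drugs x methods
#' experimental log P table.
#'
#' @param models Named list of `calibration_model` objects.
#' @param extrap Extrapolation results; rows with `role == "drug"` are used.
#' @return A lipophilicity table: tibble with a `drug` column and one numeric
#'   column per chromatographic method.
#' @export
predict_dataset <- function(models, extrap) {
  drugs <- dplyr::filter(extrap, .data$role == "drug", .data$flags != "unfit")
  if (nrow(drugs) == 0) abort("No drug compounds found in the extrapolation table.")
  missing <- setdiff(unique(drugs$method), names(models))
  if (length(missing)) {
    abort(paste0("No calibration model for system(s): ",
                 paste(missing, collapse = ", ")))
  }
  drugs$logp_exp <- vapply(seq_len(nrow(drugs)), function(i) {
    predict_logp(models[[drugs$method[i]]], drugs$intercept[i])
  }, numeric(1))
  wide <- tidyr::pivot_wider(
    drugs[c("compound", "method", "logp_exp")],
    names_from = "method", values_from = "logp_exp"
  )
  names(wide)[1] <- "drug"
  wide <- wide[order(wide$drug), c("drug", sort(setdiff(names(wide), "drug")))]
  wide
}
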