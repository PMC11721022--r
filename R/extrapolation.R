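#' Extrapolate a retention index to a fully aqueous mobile phase
#'
#' Fits the linear solvent-strength relation
#' \deqn{R_M = R_{MW} - S \varphi \qquad \log k = \log k_W - S \varphi}
#' by ordinary least squares of the retention index on the modifier volume
#' fraction \eqn{\varphi}, and reports the intercept at \eqn{\varphi = 0}
#' (\eqn{R_{MW}} or \eqn{\log k_W}) together with the slope magnitude
#' \eqn{S} (the negative of the fitted OLS slope), the determination
#' coefficient and the residual standard error.
#'
#' A fit with \eqn{r^2} below `min_r2` is flagged (`"low_r2"`) and a warning
#' is emitted, but the result is still returned: the threshold is a data
#' quality statement, not a gate. A perfectly constant response has no
#' defined \eqn{r^2}; it is reported as 0 with a `"degenerate"` flag.
#'
#' @param phi Numeric vector of modifier volume fractions (>= 3 distinct
#'   values).
#' @param value Retention index (\eqn{R_M} or \eqn{\log k}) at each `phi`.
#' @param min_r2 Quality threshold on \eqn{r^2} (default 0.9).
#' @return One-row tibble: `intercept`, `slope_S`, `r2`, `n_points`,
#'   `residual_se`, `flags` (`""`, `"low_r2"` or `"degenerate"`).
#' @examples
#' phi <- seq(0.35, 0.60, by = 0.05)
#' fit_extrapolation(phi, 2.0 - 3.0 * phi)
#' @export
fit_extrapolation <- function(phi, value, min_r2 = 0.9) {
  if (length(phi) != length(value)) abort("`phi` and `value` lengths differ.")
  keep <- is.finite(phi) & is.finite(value)
  phi <- phi[keep]
  value <- value[keep]
  if (length(unique(phi)) < 3) {
    abort("Extrapolation needs >= 3 distinct modifier fractions.")
  }
  if (var(phi) == 0) abort("Zero variance in `phi`.")
  fit <- lm(value ~ phi)
  n <- length(value)
  sse <- sum(fit$residuals^2)
  syy <- sum((value - mean(value))^2)
  flags <- character()
  if (syy == 0) {
    r2 <- 0
    flags <- c(flags, "degenerate")
  } else {
    r2 <- 1 - sse / syy
  }
  residual_se <- sqrt(sse / (n - 2))
  if (r2 < min_r2 && !"degenerate" %in% flags) {
    flags <- c(flags, "low_r2")
    warn(sprintf("Extrapolation r2 = %.4f below min_r2 = %.2f", r2, min_r2))
  }
  tibble::tibble(
    intercept = unname(coef(fit)[1]),
    slope_S = -unname(coef(fit)[2]),
    r2 = r2,
    n_points = n,
    residual_se = residual_se,
    flags = paste(flags, collapse = ";")
  )
}

#' Extrapolate every compound x system group of a retention index table
#'
#' Applies [fit_extrapolation()] to each compound x system group of an
#' aggregated retention index table (see [aggregate_replicates()]). Groups
#' with fewer than 3 distinct modifier fractions cannot be fit; they are
#' returned with `NA` estimates and an `"unfit"` flag (and a warning), never
#' silently dropped.
#'
#' @param indices Retention index tibble with columns `compound`, `role`,
#'   `technique`, `phase`, `modifier`, `method`, `phi`, `value`.
#' @param min_r2 Quality threshold passed to [fit_extrapolation()].
#' @return Tibble with one row per compound x system: identification columns
#'   plus `intercept`, `slope_S`, `r2`, `n_points`, `residual_se`, `flags`.
#' @export
extrapolate_dataset <- function(indices, min_r2 = 0.9) {
  empty <- tibble::tibble(
    compound = character(), role = character(), technique = character(),
    phase = character(), modifier = character(), method = character(),
    intercept = double(), slope_S = double(), r2 = double(),
    n_points = integer(), residual_se = double(), flags = character()
  )
  if (is.null(indices) || nrow(indices) == 0) {
    warn("Empty retention index table: nothing to extrapolate.")
    return(empty)
  }
  groups <- dplyr::group_by(
    indices, .data$compound, .data$role, .data$technique,
    .data$phase, .data$modifier, .data$method
  )
  out <- dplyr::group_modify(groups, function(g, key) {
    if (length(unique(g$phi)) < 3) {
      return(tibble::tibble(
        intercept = NA_real_, slope_S = NA_real_, r2 = NA_real_,
        n_points = nrow(g), residual_se = NA_real_, flags = "unfit"
      ))
    }
    fit_extrapolation(g$phi, g$value, min_r2 = min_r2)
  })
  out <- dplyr::ungroup(out)
  n_unfit <- sum(out$flags == "unfit")
  if (n_unfit > 0) {
    warn(sprintf(
      "%d compound x system group(s) had < 3 distinct phi points and were flagged 'unfit'.",
      n_unfit
    ))
  }
  out[names(empty)]
}
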