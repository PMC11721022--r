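#' TLC lipophilicity index from the retardation factor
#'
#' Computes \eqn{R_M = \log_{10}(1/R_F - 1)}, the lipophilicity index used in
#' reversed-phase TLC. The transform is the (base-10) logit of \eqn{1 - R_F}:
#' a compound that migrates half-way with the solvent front (\eqn{R_F = 0.5})
#' has \eqn{R_M = 0}, stronger retention gives positive values.
#'
#' @param rf Numeric vector of retardation factors, strictly inside (0, 1).
#' @return Numeric vector of \eqn{R_M} values.
#' @examples
#' rm_from_rf(c(0.25, 0.5, 0.75))
#' @seealso [logk_from_times()] for the HPLC analogue, [rf_from_rm()] for the
#'   inverse.
#' @export
rm_from_rf <- function(rf) {
  if (!is.numeric(rf)) abort("`rf` must be numeric.")
  bad <- which(!is.finite(rf) | rf <= 0 | rf >= 1)
  if (length(bad)) {
    abort(sprintf(
      "R_F values must lie strictly in (0, 1); offending record(s) %s: %s",
      paste(bad, collapse = ", "),
      paste(signif(rf[bad], 4), collapse = ", ")
    ))
  }
  log10(1 / rf - 1)
}

#' Retardation factor from the TLC lipophilicity index
#'
#' Inverse of [rm_from_rf()]: \eqn{R_F = 1/(1 + 10^{R_M})}. Used by the
#' synthetic-data generator to turn model retention indices back into raw
#' TLC observables.
#'
#' @param rm Numeric vector of \eqn{R_M} values.
#' @return Numeric vector of retardation factors in (0, 1).
#' @export
rf_from_rm <- function(rm) {
  if (!is.numeric(rm)) abort("`rm` must be numeric.")
  1 / (1 + 10^rm)
}

#' HPLC retention coefficient from retention and dead time
#'
#' Computes \eqn{\log k = \log_{10}((t_R - t_0)/t_0)} from the retention time
#' of the analyte and the dead (hold-up) time of the column. Only the ratio of
#' the two times matters, so any common time unit can be used.
#'
#' @param tr Numeric vector of retention times; must exceed `t0`.
#' @param t0 Numeric vector (or scalar) of dead times, > 0.
#' @return Numeric vector of \eqn{\log k} values.
#' @examples
#' logk_from_times(tr = c(2, 11), t0 = 1)
#' @export
logk_from_times <- function(tr, t0) {
  if (!is.numeric(tr) || !is.numeric(t0)) abort("`tr` and `t0` must be numeric.")
  n <- max(length(tr), length(t0))
  tr <- rep_len(tr, n)
  t0 <- rep_len(t0, n)
  bad <- which(!is.finite(tr) | !is.finite(t0) | t0 <= 0 | tr <= t0)
  if (length(bad)) {
    abort(sprintf(
      "Retention times must satisfy t_R > t_0 > 0; offending record(s) %s (t_R = %s, t_0 = %s)",
      paste(bad, collapse = ", "),
      paste(signif(tr[bad], 4), collapse = ", "),
      paste(signif(t0[bad], 4), collapse = ", ")
    ))
  }
  log10((tr - t0) / t0)
}

# canonical modifier abbreviations used in method labels
.modifier_abbrev <- c(methanol = "MeOH", acetonitrile = "ACN")

#' Chromatographic system descriptor
#'
#' Describes one chromatographic system: the technique (TLC or HPLC), the
#' stationary-phase chemistry (RP18, RP8 or CN), the organic modifier
#' (methanol or acetonitrile) and the grid of modifier volume fractions
#' \eqn{\varphi} at which retention is measured.
#'
#' @param technique `"TLC"` or `"HPLC"`.
#' @param phase Stationary phase: `"RP18"`, `"RP8"` or `"CN"`.
#' @param modifier Organic modifier: `"methanol"` or `"acetonitrile"`.
#' @param phi_grid Strictly increasing vector of modifier volume fractions,
#'   each in (0, 1), with at least 3 points (a linear extrapolation needs
#'   residual degrees of freedom).
#' @return An object of class `chrom_system`: a list with the four fields plus
#'   a `label` such as `"TLC.RP18.MeOH"`.
#' @examples
#' chrom_system("TLC", "RP18", "methanol", seq(0.60, 0.85, by = 0.05))
#' @export
chrom_system <- function(technique = c("TLC", "HPLC"),
                         phase = c("RP18", "RP8", "CN"),
                         modifier = c("methanol", "acetonitrile"),
                         phi_grid) {
  technique <- match.arg(technique)
  phase <- match.arg(phase)
  modifier <- match.arg(modifier)
  if (!is.numeric(phi_grid) || length(phi_grid) < 3) {
    abort("`phi_grid` needs at least 3 modifier fractions.")
  }
  if (any(phi_grid <= 0 | phi_grid >= 1)) {
    abort("`phi_grid` fractions must lie strictly in (0, 1).")
  }
  if (any(diff(phi_grid) <= 0)) {
    abort("`phi_grid` must be strictly increasing.")
  }
  structure(
    list(
      technique = technique, phase = phase, modifier = modifier,
      phi_grid = phi_grid,
      label = system_label(technique, phase, modifier)
    ),
    class = "chrom_system"
  )
}

#' @export
print.chrom_system <- function(x, ...) {
  cat(sprintf(
    "<chrom_system> %s: phi = %s\n", x$label,
    paste(format(x$phi_grid), collapse = ", ")
  ))
  invisible(x)
}

#' Canonical method label for a chromatographic system
#'
#' @param technique,phase,modifier Character vectors (recycled).
#' @return Labels such as `"HPLC.CN.ACN"` used throughout output tables.
#' @export
system_label <- function(technique, phase, modifier) {
  abbrev <- unname(.modifier_abbrev[as.character(modifier)])
  if (anyNA(abbrev)) abort("`modifier` must be 'methanol' or 'acetonitrile'.")
  paste(technique, phase, abbrev, sep = ".")
}

#' Read a raw retention table
#'
#' Reads a CSV of raw retention observations, one row per replicate
#' measurement. Expected columns: `compound`, `role` (`"standard"` or
#' `"drug"`), `technique`, `phase`, `modifier`, `phi_percent` (modifier
#' concentration in percent, converted to a fraction on read), `replicate`,
#' and exactly one observable per row: `rf` for TLC rows, `tr` and `t0`
#' (minutes) for HPLC rows.
#'
#' Schema violations are reported with the offending data row numbers; rows
#' are never silently dropped or clipped (an out-of-range \eqn{R_F} would bias
#' the extrapolated intercept).
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated retention records with `phi` as a fraction
#'   and a `method` label column.
#' @export
read_retention <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_retention(df)
}

#' Validate a retention record table
#'
#' Checks the retention schema (see [read_retention()]) on an in-memory data
#' frame, converts `phi_percent` to the `phi` fraction and attaches the
#' canonical `method` label. Used by [read_retention()] and directly on
#' generated datasets.
#'
#' @param df Data frame of raw retention records.
#' @return A validated tibble with columns `compound`, `role`, `technique`,
#'   `phase`, `modifier`, `method`, `phi`, `replicate`, `rf`, `tr`, `t0`.
#' @export
validate_retention <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("compound", "role", "technique", "phase", "modifier", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("Retention table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"phi" %in% names(df)) {
    if (!"phi_percent" %in% names(df)) {
      abort("Retention table needs a `phi` (fraction) or `phi_percent` column.")
    }
    df$phi <- df$phi_percent / 100
    df$phi_percent <- NULL
  }
  for (col in c("rf", "tr", "t0")) if (!col %in% names(df)) df[[col]] <- NA_real_
  .row_err <- function(idx, msg) {
    if (length(idx)) {
      abort(sprintf("%s (row%s %s)", msg, if (length(idx) > 1) "s" else "",
                    paste(head(idx, 10), collapse = ", ")))
    }
  }
  .row_err(which(!df$technique %in% c("TLC", "HPLC")),
           "`technique` must be TLC or HPLC")
  .row_err(which(!df$phase %in% c("RP18", "RP8", "CN")),
           "`phase` must be RP18, RP8 or CN")
  .row_err(which(!df$modifier %in% names(.modifier_abbrev)),
           "`modifier` must be methanol or acetonitrile")
  .row_err(which(!df$role %in% c("standard", "drug")),
           "`role` must be standard or drug")
  .row_err(which(!is.finite(df$phi) | df$phi <= 0 | df$phi >= 1),
           "`phi` must be a fraction strictly in (0, 1)")
  .row_err(which(!is.finite(df$replicate) | df$replicate < 1),
           "`replicate` must be a positive integer")
  tlc <- df$technique == "TLC"
  .row_err(which(tlc & (is.na(df$rf) | !is.na(df$tr) | !is.na(df$t0))),
           "TLC rows must have `rf` and no `tr`/`t0`")
  .row_err(which(!tlc & (is.na(df$tr) | is.na(df$t0) | !is.na(df$rf))),
           "HPLC rows must have `tr` and `t0` and no `rf`")
  .row_err(which(tlc & !is.na(df$rf) & (df$rf <= 0 | df$rf >= 1)),
           "`rf` must lie strictly in (0, 1)")
  .row_err(which(!tlc & !is.na(df$t0) & df$t0 <= 0),
           "`t0` must be > 0")
  .row_err(which(!tlc & !is.na(df$tr) & !is.na(df$t0) & df$tr <= df$t0),
           "`tr` must exceed `t0`")
  df$method <- system_label(df$technique, df$phase, df$modifier)
  df[c("compound", "role", "technique", "phase", "modifier", "method",
       "phi", "replicate", "rf", "tr", "t0")]
}

#' Average replicates and transform to retention indices
#'
#' Collapses replicate measurements for each compound x system x modifier
#' fraction, averaging the raw observable (\eqn{R_F} or \eqn{t_R}) across
#' replicates and then applying the index transform ([rm_from_rf()] or
#' [logk_from_times()]). Averaging happens on the raw, measured scale because
#' the index transforms are nonlinear.
#'
#' @param records Validated retention record tibble (see
#'   [validate_retention()]).
#' @return A tibble of retention indices: one row per compound x system x phi
#'   with columns `value` (\eqn{R_M} or \eqn{\log k}) and `n_replicates`.
#' @export
aggregate_replicates <- function(records) {
  records <- validate_retention(records)
  if (nrow(records) == 0) {
    warn("No retention records to aggregate.")
  }
  grouped <- dplyr::group_by(
    records,
    .data$compound, .data$role, .data$technique, .data$phase,
    .data$modifier, .data$method, .data$phi
  )
  out <- dplyr::summarise(
    grouped,
    mean_rf = mean(.data$rf),
    mean_tr = mean(.data$tr),
    mean_t0 = mean(.data$t0),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  out$value <- ifelse(
    out$technique == "TLC",
    ifelse(is.na(out$mean_rf), NA_real_, log10(1 / out$mean_rf - 1)),
    ifelse(is.na(out$mean_tr), NA_real_,
           log10((out$mean_tr - out$mean_t0) / out$mean_t0))
  )
  # mean of valid replicates can still stray out of domain only if inputs did,
  # which validate_retention already excludes; guard anyway
  if (any(!is.finite(out$value))) {
    abort("Aggregated observable fell outside the transform domain.")
  }
  out[c("compound", "role", "technique", "phase", "modifier", "method",
        "phi", "value", "n_replicates")]
}
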