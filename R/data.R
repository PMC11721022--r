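# Loaders for the packaged gliflozin example data: published experimental and
# computational log P tables, calibration coefficients, reference standards
# and pharmacology records for the five SGLT-inhibitor drugs CANA, DAPA,
# EMPA, ERTU and SOTA.

chromlip_extdata <- function(file) {
  path <- system.file("extdata", file, package = "chromlip")
  if (path == "") abort(paste0("Packaged data file not found: ", file))
  path
}

.read_method_table <- function(file) {
  df <- readr::read_csv(chromlip_extdata(file), show_col_types = FALSE,
                        progress = FALSE)
  long <- tidyr::pivot_longer(df, -"method", names_to = "drug",
                              values_to = "logp")
  wide <- tidyr::pivot_wider(long, names_from = "method",
                             values_from = "logp")
  wide[order(wide$drug), c("drug", sort(setdiff(names(wide), "drug")))]
}

#' Published experimental log P table for the gliflozins
#'
#' Experimental log P (log P_EXP) of the five gliflozin drugs from twelve
#' standardized chromatographic systems (TLC and HPLC; RP18, RP8 and CN
#' phases; methanol and acetonitrile modifiers), as published. Values are
#' calibrated predictions at the 2-decimal reporting precision.
#'
#' @return Lipophilicity table: tibble with `drug` and 12 method columns.
#' @export
gliflozin_logp_exp <- function() .read_method_table("gliflozin_logp_exp.csv")

#' Published computational log P table for the gliflozins
#'
#' log P of the five gliflozin drugs from seven computational models (iLOGP,
#' XLOGP3, WLOGP, MLOGP, SILICOS-IT, Consensus.LogP, ALOGP), as published.
#' These values are consumed as given; the algorithms themselves are not
#' implemented here.
#'
#' @return Lipophilicity table: tibble with `drug` and 7 method columns.
#' @export
gliflozin_logp_comp <- function() .read_method_table("gliflozin_logp_comp.csv")

#' Combined experimental + computational lipophilicity table
#'
#' @return Tibble with `drug` and 19 method columns (12 chromatographic + 7
#'   computational), the input for the chemometric comparisons.
#' @export
gliflozin_logp_all <- function() {
  dplyr::inner_join(gliflozin_logp_exp(), gliflozin_logp_comp(), by = "drug")
}

#' Reference standards for log P calibration
#'
#' Six reference compounds with established literature log P spanning
#' 0.62-3.5: 2-aminophenol (S1, 0.62), salicylamide (S2, 1.28),
#' 4-dimethylaminobenzaldehyde (S3, 1.81), eugenol (S4, 2.27), 2-naphthol
#' (S5, 2.70) and diphenylamine (S6, 3.5).
#'
#' @return Tibble: `compound`, `name`, `logp_lit`.
#' @export
gliflozin_standards <- function() {
  readr::read_csv(chromlip_extdata("gliflozin_standards.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published per-system calibration coefficients
#'
#' Slope and intercept of the published calibration lines
#' \eqn{\log P_{EXP} = a X + b} (X = \eqn{R_{MW}} for TLC, \eqn{\log k_W}
#' for HPLC) for the twelve chromatographic systems. Used as the default
#' system maps of the synthetic-data generator and for worked prediction
#' examples; the underlying raw retention data are not published, so these
#' coefficients are inputs, not something the package refits.
#'
#' @return Tibble: `method`, `technique`, `phase`, `modifier`, `slope_a`,
#'   `intercept_b`.
#' @export
calibration_coefficients <- function() {
  readr::read_csv(chromlip_extdata("calibration_coefficients.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published pharmacology records for the gliflozins
#'
#' IC50 against SGLT2 and SGLT1 (nM) plus protein binding, clearance, volume
#' of distribution, half-life and dose-range metadata for the five drugs.
#'
#' @return Tibble: `drug`, `ic50_sglt2_nm`, `ic50_sglt1_nm`, `pb_percent`,
#'   `cl_l_per_h`, `vd_l`, `t05_h`, `dose_mg`.
#' @export
gliflozin_pharmacology <- function() {
  readr::read_csv(chromlip_extdata("gliflozin_pharmacology.csv"),
                  show_col_types = FALSE, progress = FALSE)
}
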