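#' pIC50 from an IC50 in nanomolar units
#'
#' \eqn{pIC_{50} = -\log_{10}(IC_{50} \times 10^{-9})}: the negative base-10
#' logarithm of the half-maximal inhibitory concentration in molar units.
#' An IC50 of 1 nM corresponds to a pIC50 of 9.
#'
#' @param ic50_nm Positive IC50 value(s) in nM.
#' @return pIC50 value(s).
#' @examples
#' pic50(c(1, 2.2, 1000))
#' @export
pic50 <- function(ic50_nm) {
  if (!is.numeric(ic50_nm)) abort("`ic50_nm` must be numeric.")
  bad <- which(!is.finite(ic50_nm) | ic50_nm <= 0)
  if (length(bad)) {
    abort(sprintf("IC50 must be positive; offending value(s) %s",
                  paste(bad, collapse = ", ")))
  }
  -log10(ic50_nm * 1e-9)
}

#' Lipophilic ligand efficiency
#'
#' \eqn{LLE = pIC_{50} - \log P}: potency normalized for lipophilicity. A
#' constant LLE along a series of increasingly potent, increasingly
#' lipophilic analogues indicates the potency gain is bought with
#' lipophilicity; an LLE increase at constant log P indicates a specific
#' potency gain.
#'
#' @param pic50_value pIC50 value(s).
#' @param logp_value log P value(s) on the same compounds.
#' @return LLE value(s).
#' @examples
#' lle(pic50(2.2), 3.99)
#' @export
lle <- function(pic50_value, logp_value) {
  if (any(!is.finite(pic50_value)) || any(!is.finite(logp_value))) {
    abort("pIC50 and log P must be finite.")
  }
  pic50_value - logp_value
}

#' Per-drug summary of experimental lipophilicity
#'
#' Mean and sample standard deviation (divisor \eqn{n-1}) of log P across the
#' experimental chromatographic scales for each drug. Computational columns
#' should not be in `table`; pass the experimental table only.
#'
#' @param table Lipophilicity table of experimental columns.
#' @return Tibble: `drug`, `logp_mean`, `logp_sd`, `n_methods`.
#' @export
summarize_lipophilicity <- function(table) {
  m <- as_logp_matrix(table)
  if (ncol(m) < 2) abort("Need at least 2 experimental methods for a summary.")
  tibble::tibble(
    drug = rownames(m),
    logp_mean = unname(rowMeans(m)),
    logp_sd = unname(apply(m, 1, sd)),
    n_methods = ncol(m)
  )
}

#' Pharmacology summary table with pIC50 and LLE
#'
#' Combines a pharmacology record table (IC50s against SGLT2 and SGLT1 plus
#' ADME metadata) with the per-drug experimental lipophilicity summary, and
#' derives pIC50 and LLE for both targets. LLE is computed against the mean
#' experimental log P of each drug.
#'
#' @param pharm Tibble with columns `drug`, `ic50_sglt2_nm`, `ic50_sglt1_nm`
#'   (see [gliflozin_pharmacology()]).
#' @param lipo_summary Output of [summarize_lipophilicity()].
#' @return Tibble with one row per drug: lipophilicity summary, pIC50 and
#'   LLE for both targets, plus any ADME metadata columns carried through.
#' @export
lle_table <- function(pharm, lipo_summary) {
  missing <- setdiff(pharm$drug, lipo_summary$drug)
  if (length(missing)) {
    abort(paste0("No lipophilicity summary for drug(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- dplyr::inner_join(pharm, lipo_summary, by = "drug")
  out$pic50_sglt2 <- pic50(out$ic50_sglt2_nm)
  out$pic50_sglt1 <- pic50(out$ic50_sglt1_nm)
  out$lle_sglt2 <- lle(out$pic50_sglt2, out$logp_mean)
  out$lle_sglt1 <- lle(out$pic50_sglt1, out$logp_mean)
  out[order(-out$logp_mean), ]
}
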