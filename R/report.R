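# Pipeline stages and report assembly. Each stage reads/writes plain CSV
# (plus Newick for the tree) so runs are reproducible and diffable; reporting
# precision follows the field's tables: log P 2 decimals, r 4 decimals,
# LLE 2 decimals.

.write_csv <- function(df, path, verbose = FALSE) {
  readr::write_csv(df, path, progress = FALSE)
  if (verbose) message("wrote ", path)
  path
}

#' Run the retention-to-log P stage
#'
#' Aggregates a raw retention table, extrapolates every compound x system to
#' 100% water, calibrates each system on the standards and predicts
#' experimental log P for the drugs. This is the core standardized
#' chromatographic lipophilicity chain.
#'
#' @param records Validated retention records (from [read_retention()] or
#'   [generate_dataset()]).
#' @param standards Standards tibble (`compound`, `logp_lit`).
#' @param min_r2 Extrapolation quality threshold.
#' @return List: `indices`, `extrapolation`, `models`, `calibration`
#'   (coefficient table), `logp_exp` (drugs x methods lipophilicity table).
#' @export
run_calibration_pipeline <- function(records, standards, min_r2 = 0.9) {
  indices <- aggregate_replicates(records)
  extrap <- extrapolate_dataset(indices, min_r2 = min_r2)
  models <- calibrate_dataset(extrap, standards)
  list(
    indices = indices,
    extrapolation = extrap,
    models = models,
    calibration = calibration_table(models),
    logp_exp = predict_dataset(models, extrap)
  )
}

#' Chemometric comparison of lipophilicity scales
#'
#' Correlation matrix, pairwise regression statistics for the best-correlated
#' pairs, hierarchical clustering and PCA, on a combined lipophilicity table.
#'
#' @param table Lipophilicity table (experimental and/or computational
#'   columns).
#' @param distance,linkage Clustering options (see [cluster_methods()]).
#' @param pca_scale Standardize variables in the PCA?
#' @param r_min Report pairwise statistics for pairs with `|r| >= r_min`
#'   (default 0.97, the conventional "best correlated" cut).
#' @return List: `correlation` (matrix), `pairs` (tibble), `clustering`
#'   (`method_clustering`), `pca` (`lipo_pca`).
#' @export
run_chemometrics <- function(table, distance = "euclidean",
                             linkage = "ward.D2", pca_scale = TRUE,
                             r_min = 0.97) {
  cormat <- correlation_matrix(table)
  all_pairs <- pairwise_stats_table(table)
  list(
    correlation = cormat,
    pairs = all_pairs[abs(all_pairs$r) >= r_min, ],
    clustering = cluster_methods(table, distance = distance, linkage = linkage),
    pca = pca_methods(table, scale = pca_scale)
  )
}

#' Assemble the full lipophilicity report
#'
#' Chains prediction, chemometrics and pharmacology: takes an experimental
#' lipophilicity table (either computed by [run_calibration_pipeline()] or
#' loaded), joins the computational log P table, and writes the full artifact
#' set — experimental log P, correlation matrix, pairwise statistics, Newick
#' dendrogram, PCA scores/loadings/variance, and the pharmacology summary
#' with pIC50 and LLE.
#'
#' @param logp_exp Experimental lipophilicity table (tibble with `drug`
#'   column).
#' @param logp_comp Computational lipophilicity table; `NULL` to skip.
#' @param pharm Pharmacology records; `NULL` to skip the LLE table.
#' @param out_dir Output directory (created if needed).
#' @param distance,linkage,pca_scale Chemometric options.
#' @param verbose Print each artifact path as it is written.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_report <- function(logp_exp, logp_comp = NULL, pharm = NULL, out_dir,
                       distance = "euclidean", linkage = "ward.D2",
                       pca_scale = TRUE, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  round_tbl <- function(df, digits) {
    df[-1] <- lapply(df[-1], round, digits)
    df
  }
  paths$logp_exp <- .write_csv(round_tbl(logp_exp, 2),
                               file.path(out_dir, "logp_experimental.csv"),
                               verbose)
  combined <- if (is.null(logp_comp)) logp_exp else {
    dplyr::inner_join(logp_exp, logp_comp, by = "drug")
  }
  chem <- run_chemometrics(combined, distance = distance, linkage = linkage,
                           pca_scale = pca_scale)
  cor_df <- tibble::as_tibble(round(chem$correlation, 4), rownames = "method")
  paths$correlation <- .write_csv(cor_df,
                                  file.path(out_dir, "correlation_matrix.csv"),
                                  verbose)
  pairs <- chem$pairs
  pairs$r <- round(pairs$r, 4)
  paths$pairwise <- .write_csv(pairs, file.path(out_dir, "pairwise_stats.csv"),
                               verbose)
  paths$newick <- file.path(out_dir, "method_clustering.nwk")
  newick_tree(chem$clustering, paths$newick)
  if (verbose) message("wrote ", paths$newick)
  paths$pca_variance <- .write_csv(
    tibble::tibble(component = paste0("PC", seq_along(chem$pca$eigenvalues)),
                   eigenvalue = chem$pca$eigenvalues,
                   proportion = chem$pca$proportion),
    file.path(out_dir, "pca_variance.csv"), verbose
  )
  paths$pca_scores <- .write_csv(
    tibble::as_tibble(chem$pca$scores, rownames = "observation"),
    file.path(out_dir, "pca_scores.csv"), verbose
  )
  paths$pca_loadings <- .write_csv(
    tibble::as_tibble(chem$pca$loadings, rownames = "variable"),
    file.path(out_dir, "pca_loadings.csv"), verbose
  )
  if (!is.null(pharm)) {
    summ <- summarize_lipophilicity(logp_exp)
    lt <- lle_table(pharm, summ)
    num <- vapply(lt, is.numeric, logical(1))
    lt[num] <- lapply(lt[num], round, 2)
    paths$lle <- .write_csv(lt, file.path(out_dir, "pharmacology_lle.csv"),
                            verbose)
  }
  invisible(paths)
}
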