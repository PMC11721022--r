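#' Convert a lipophilicity table to a drugs x methods matrix
#'
#' A lipophilicity table holds one log P scale per column (chromatographic
#' systems and/or computational models) over a common set of compounds held
#' in the `drug` column.
#'
#' @param table Tibble with a `drug` identifier column and numeric method
#'   columns, or an already-formed numeric matrix with row names.
#' @return Numeric matrix, drugs as rows, methods as columns.
#' @export
as_logp_matrix <- function(table) {
  if (is.matrix(table)) {
    storage.mode(table) <- "double"
    return(table)
  }
  table <- tibble::as_tibble(table)
  if (!"drug" %in% names(table)) {
    abort("Lipophilicity table needs a `drug` column.")
  }
  m <- as.matrix(table[setdiff(names(table), "drug")])
  rownames(m) <- table$drug
  if (!is.numeric(m)) abort("Method columns must all be numeric.")
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0]
    abort(paste0("Missing log P cells in column(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) abort("Method names must be unique.")
  m
}

#' Correlation matrix of lipophilicity scales
#'
#' Pearson correlations between all pairs of method columns of a
#' lipophilicity table, computed over the common compound set. Entries are
#' carried at full precision; use `round(., 4)` for reporting at the usual
#' table precision.
#'
#' @param table Lipophilicity table (see [as_logp_matrix()]).
#' @return Symmetric correlation matrix with unit diagonal. Columns with zero
#'   variance give `NA` rows/columns with a warning rather than an error.
#' @export
correlation_matrix <- function(table) {
  m <- as_logp_matrix(table)
  if (nrow(m) < 3) abort("Correlation needs at least 3 compounds.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Zero-variance column(s) flagged as NA: ",
                paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  suppressWarnings(r <- cor(m))
  diag(r) <- 1
  r
}

#' Pairwise regression statistics for two lipophilicity scales
#'
#' Descriptive statistics for the linear relation between two log P scales:
#' Pearson `r`, Fisher statistic \eqn{F = (n-2) r^2/(1-r^2)} with its
#' upper-tail p-value on \eqn{F(1, n-2)}, and the standard error of estimate
#' `s` from the OLS regression of `y` on `x` (so `r`, `F` and `p` are
#' symmetric in the pair while `s` follows the stated regression direction).
#'
#' @param x,y Numeric vectors of equal length (>= 3), one log P value per
#'   compound.
#' @param labels Optional character pair naming the two scales.
#' @return One-row tibble: `pair`, `r`, `F`, `p`, `s`, `n`.
#' @export
pairwise_stats <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) abort("`x` and `y` lengths differ.")
  n <- length(x)
  if (n < 3) abort("Pairwise statistics need at least 3 compounds.")
  if (var(x) == 0 || var(y) == 0) abort("Zero-variance scale in pair.")
  m <- fit_calibration(x, y)
  tibble::tibble(
    pair = paste(labels[2], labels[1], sep = "~"),
    r = m$r, F = m$F, p = m$p, s = m$s, n = n
  )
}

#' Pairwise regression statistics for selected method pairs
#'
#' @param table Lipophilicity table.
#' @param pairs Two-column character matrix or data frame of method pairs
#'   (`x`, `y`); defaults to all unordered pairs.
#' @return Tibble of [pairwise_stats()] rows.
#' @export
pairwise_stats_table <- function(table, pairs = NULL) {
  m <- as_logp_matrix(table)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(colnames(m), 2))
  }
  pairs <- as.matrix(pairs)
  dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]
    b <- pairs[i, 2]
    pairwise_stats(m[, a], m[, b], labels = c(a, b))
  }))
}

#' Hierarchical clustering of lipophilicity scales
#'
#' Agglomerative clustering of the method columns of a lipophilicity table,
#' each method represented by its per-drug log P vector. Columns are ordered
#' lexicographically (C locale) before clustering so the merge order — and
#' hence the tree — is reproducible regardless of input column order; exact
#' distance ties then resolve to the pair with the lexicographically smallest
#' labels.
#'
#' @param table Lipophilicity table.
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (\eqn{d = 1 - r}).
#' @param linkage Agglomeration rule passed to [stats::hclust()]; default
#'   `"ward.D2"`.
#' @return Object of class `method_clustering`: list with the `hclust` tree,
#'   `labels`, `distance`, `linkage`.
#' @export
cluster_methods <- function(table, distance = c("euclidean", "correlation"),
                            linkage = "ward.D2") {
  distance <- match.arg(distance)
  m <- as_logp_matrix(table)
  if (ncol(m) < 2) {
    return(structure(
      list(hclust = NULL, labels = colnames(m), distance = distance,
           linkage = linkage),
      class = "method_clustering"
    ))
  }
  m <- m[, order(colnames(m), method = "radix"), drop = FALSE]
  d <- switch(distance,
    euclidean = dist(t(m)),
    correlation = as.dist(1 - cor(m))
  )
  structure(
    list(hclust = hclust(d, method = linkage), labels = colnames(m),
         distance = distance, linkage = linkage),
    class = "method_clustering"
  )
}

#' @export
print.method_clustering <- function(x, ...) {
  cat(sprintf("<method_clustering> %d methods, %s distance, %s linkage\n",
              length(x$labels), x$distance, x$linkage))
  invisible(x)
}

#' Cut a method clustering into groups
#'
#' @param clustering A `method_clustering`.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_methods <- function(clustering, k) {
  if (is.null(clustering$hclust)) {
    return(setNames(rep(1L, length(clustering$labels)), clustering$labels))
  }
  cutree(clustering$hclust, k = k)
}

#' Export a method clustering as a Newick tree
#'
#' Converts the dendrogram to a `phylo` object and writes Newick with branch
#' lengths derived from merge heights.
#'
#' @param clustering A `method_clustering`.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `file`).
#' @export
newick_tree <- function(clustering, file = NULL) {
  if (is.null(clustering$hclust)) {
    nwk <- paste0("(", clustering$labels, ");")
  } else {
    phy <- ape::as.phylo(clustering$hclust)
    nwk <- ape::write.tree(phy)
  }
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}

#' Principal component analysis of lipophilicity scales
#'
#' PCA of a lipophilicity table with drugs as observations and methods as
#' variables (the default), or transposed. With `scale = TRUE` (the default)
#' the decomposition is of the correlation matrix of the variables, i.e.
#' every scale contributes equally regardless of its spread. Component signs
#' follow a fixed convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param table Lipophilicity table.
#' @param scale Standardize variables (correlation PCA)? Default `TRUE`.
#' @param observations `"drugs"` (rows of the table, default) or `"methods"`.
#' @return Object of class `lipo_pca`: list with `eigenvalues`, `proportion`
#'   (of total variance, over all non-null components), `scores`
#'   (observations x components) and `loadings` (variables x components).
#' @export
pca_methods <- function(table, scale = TRUE,
                        observations = c("drugs", "methods")) {
  observations <- match.arg(observations)
  m <- as_logp_matrix(table)
  if (observations == "methods") m <- t(m)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("PCA needs at least 2 observations and 2 variables.")
  }
  if (scale) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(paste0("Constant variable(s) cannot be scaled: ",
                   paste(colnames(m)[sds == 0], collapse = ", ")))
    }
  }
  p <- prcomp(m, center = TRUE, scale. = scale)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  ev <- p$sdev^2
  structure(
    list(
      eigenvalues = ev,
      proportion = ev / sum(ev),
      scores = scores,
      loadings = loadings,
      scale = scale,
      observations = observations
    ),
    class = "lipo_pca"
  )
}

#' @export
print.lipo_pca <- function(x, ...) {
  cat(sprintf(
    "<lipo_pca> %s as observations; PC proportions: %s\n", x$observations,
    paste(sprintf("%.1f%%", 100 * x$proportion[seq_len(min(4, length(x$proportion)))]),
          collapse = ", ")
  ))
  invisible(x)
}
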