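# standardize a numeric matrix column-wise on complete values, then
# mean-impute missing entries (0 after centering); used by PCA and clustering
standardize_impute <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  const <- apply(x, 2, function(col) {
    v <- var(col, na.rm = TRUE)
    is.na(v) || v < .Machine$double.eps
  })
  if (any(const)) {
    abort(paste0("Constant (or all-missing) column(s): ",
                 toString(colnames(x)[const])))
  }
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- if (scale) apply(x, 2, sd, na.rm = TRUE) else rep(1, ncol(x))
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  n_imputed <- sum(is.na(z))
  if (n_imputed > 0) {
    inform(paste0("Mean-imputing ", n_imputed, " missing value(s)."))
    z[is.na(z)] <- 0
  }
  attr(z, "n_imputed") <- n_imputed
  z
}

numeric_feature_matrix <- function(data, id_col = "accession") {
  if (is.matrix(data)) {
    rn <- rownames(data)
    if (is.null(rn)) rn <- as.character(seq_len(nrow(data)))
    return(list(x = data, id = rn))
  }
  id <- if (id_col %in% names(data)) as.character(data[[id_col]])
        else as.character(seq_len(nrow(data)))
  num <- data %>% select(dplyr::where(is.numeric))
  list(x = as.matrix(num), id = id)
}

#' Principal component analysis of a stress-tolerance-index matrix
#'
#' Eigen-decomposes the (by default standardized) accession x index matrix.
#' Missing index values (e.g. an undefined synchrony index) are
#' mean-imputed after standardization, with a message. Component signs are
#' fixed so that each component's largest-magnitude loading is positive,
#' making outputs stable across platforms.
#'
#' @param sti A tibble with an `accession` column and numeric index
#'   columns (e.g. from [sti_profiles()]), or a plain numeric matrix.
#' @param scale Standardize columns to unit variance (recommended: the
#'   indices live on different scales).
#' @return An object of class `sti_pca` with elements `scores` (tibble),
#'   `loadings` (tibble), `var_explained`, `sdev`, `n_imputed`.
#'   `tidy()` returns scores, loadings or eigenvalues; `autoplot()` draws
#'   the score plot.
#' @export
pca_sti <- function(sti, scale = TRUE) {
  fm <- numeric_feature_matrix(sti)
  if (nrow(fm$x) < 3) abort("Need at least 3 rows for a PCA.")
  if (ncol(fm$x) < 2) abort("Need at least 2 numeric columns for a PCA.")
  z <- standardize_impute(fm$x, scale = scale)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  # sign convention: largest |loading| positive per component
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x) %>% mutate(accession = fm$id, .before = 1)
  loadings <- as_tibble(pc$rotation) %>%
    mutate(index = colnames(fm$x), .before = 1)
  out <- list(
    scores = scores, loadings = loadings, var_explained = ve,
    sdev = pc$sdev, n_imputed = attr(z, "n_imputed")
  )
  class(out) <- "sti_pca"
  out
}

#' @export
print.sti_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "rows x", nrow(x$loadings), "indices\n")
  ve <- round(100 * x$var_explained, 1)
  cat("variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_sti
#' @param x An `sti_pca` object.
#' @param matrix Which component to return: `"scores"`, `"loadings"` or
#'   `"eigenvalues"`.
#' @param ... Unused.
#' @method tidy sti_pca
#' @export
tidy.sti_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                         ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble(
      component = seq_along(x$var_explained),
      std_dev = x$sdev,
      var_explained = x$var_explained,
      cumulative = cumsum(x$var_explained)
    )
  )
}

#' @rdname pca_sti
#' @method glance sti_pca
#' @export
glance.sti_pca <- function(x, ...) {
  tibble(
    n = nrow(x$scores), n_indices = nrow(x$loadings),
    var_pc1 = x$var_explained[1],
    var_pc2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_,
    n_imputed = x$n_imputed
  )
}

#' Hierarchical k-means clustering of accessions
#'
#' Reproducible k-means: a Ward-linkage agglomerative clustering of the
#' (standardized, mean-imputed) feature matrix is cut at `k`, the cut's
#' cluster means seed a Lloyd k-means refinement, and the final labels are
#' renumbered by decreasing cluster size. The refinement can only decrease
#' the total within-cluster sum of squares relative to the hierarchical
#' cut, and the whole procedure is deterministic given its inputs.
#'
#' @param features A tibble with an `accession` column plus numeric feature
#'   columns (e.g. an STI profile table), or a numeric matrix.
#' @param k Number of clusters (>= 2; `n > k` required).
#' @param seed Optional integer seed (the procedure is deterministic, but
#'   the seed is honoured and recorded for provenance).
#' @param scale Standardize features before clustering.
#' @return An object of class `germ_hkmeans` with elements `clusters`
#'   (tibble of `accession`, `cluster`), `centroids` (matrix, standardized
#'   space), `tot_withinss`, `hclust_withinss`, `k`, `seed`.
#' @export
hkmeans <- function(features, k = 3, seed = NULL, scale = TRUE) {
  if (k < 2) abort("`k` must be >= 2.")
  fm <- numeric_feature_matrix(features)
  if (nrow(fm$x) <= k) abort("Need more rows than clusters.")
  if (!is.null(seed)) set.seed(seed)
  z <- standardize_impute(fm$x, scale = scale)
  hc <- hclust(dist(z), method = "ward.D2")
  init <- cutree(hc, k = k)
  centers <- rowsum(z, init) / as.vector(table(init))
  wss0 <- sum(purrr::map_dbl(seq_len(k), function(g) {
    sum(sweep(z[init == g, , drop = FALSE], 2, centers[g, ], "-")^2)
  }))
  km <- kmeans(z, centers = centers, iter.max = 100, algorithm = "Lloyd")
  # renumber clusters by decreasing size for stable output
  sizes <- tabulate(km$cluster, k)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  clusters <- tibble(accession = fm$id,
                     cluster = relabel[km$cluster])
  out <- list(
    clusters = clusters,
    features = z,
    centroids = km$centers[ord, , drop = FALSE],
    tot_withinss = km$tot.withinss,
    hclust_withinss = wss0,
    k = k,
    seed = seed
  )
  class(out) <- "germ_hkmeans"
  out
}

#' @export
print.germ_hkmeans <- function(x, ...) {
  cat("Hierarchical k-means,", x$k, "clusters; sizes:",
      paste(table(x$clusters$cluster), collapse = "/"), "\n")
  cat("total within-cluster SS:", format(x$tot_withinss),
      "(hierarchical cut:", format(x$hclust_withinss), ")\n")
  invisible(x)
}

#' @rdname hkmeans
#' @param x A `germ_hkmeans` object.
#' @param ... Unused.
#' @method tidy germ_hkmeans
#' @export
tidy.germ_hkmeans <- function(x, ...) x$clusters

#' @rdname hkmeans
#' @method glance germ_hkmeans
#' @export
glance.germ_hkmeans <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$clusters),
         tot_withinss = x$tot_withinss,
         hclust_withinss = x$hclust_withinss)
}

#' Rand index between two partitions
#'
#' The proportion of object pairs on whose co-membership two partitions
#' agree; 1 means identical partitions, and values near the expected
#' chance level indicate no recovered structure.
#'
#' @param a,b Two label vectors of equal length.
#' @return A number in \[0, 1\].
#' @examples
#' rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("Label vectors must have equal length.")
  n <- length(a)
  if (n < 2) abort("Need at least two objects.")
  tab <- table(a, b)
  s_ij <- sum(choose(tab, 2))
  s_i <- sum(choose(rowSums(tab), 2))
  s_j <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  (tot + 2 * s_ij - s_i - s_j) / tot
}
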