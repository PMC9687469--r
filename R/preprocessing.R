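#' Fit per-feature standardization parameters
#'
#' Computes per-column means and standard deviations on the training table
#' only, so that held-out data can be transformed with training statistics
#' (no leakage). The population convention (divide by N) is used, matching
#' the semantics of the usual machine-learning standard scaler; set
#' `population = FALSE` for the sample (N-1) convention.
#'
#' Constant columns are flagged and their sd is treated as 1 (with a
#' warning), so degenerate synthetic inputs pass through unchanged rather
#' than erroring.
#'
#' @param train a [labeled_table()] with at least 2 rows.
#' @param population logical; population (1/N) vs sample (1/(N-1)) variance.
#' @return An object of class `standardizer` with `means`, `sds` and a
#'   logical `constant` flag per feature.
#' @export
fit_standardizer <- function(train, population = TRUE) {
  x <- train$features
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a standardizer",
                         call. = FALSE)
  means <- colMeans(x)
  centered <- sweep(x, 2, means)
  denom <- if (population) nrow(x) else nrow(x) - 1L
  sds <- sqrt(colSums(centered^2) / denom)
  constant <- sds < 1e-12
  if (any(constant)) {
    warning(sprintf("%d constant feature(s) (%s): sd treated as 1",
                    sum(constant),
                    paste(colnames(x)[constant], collapse = ", ")),
            call. = FALSE)
    sds[constant] <- 1
  }
  structure(list(means = means, sds = sds, constant = constant,
                 population = population),
            class = "standardizer")
}

#' Apply fitted standardization to a table
#'
#' @param table a [labeled_table()] whose feature count matches the fit.
#' @param params a `standardizer` from [fit_standardizer()].
#' @return A [labeled_table()] with each column transformed as
#'   `(x - mean) / sd`; labels untouched.
#' @export
apply_standardizer <- function(table, params) {
  if (!inherits(params, "standardizer")) {
    stop("`params` must come from fit_standardizer()", call. = FALSE)
  }
  if (ncol(table$features) != length(params$means)) {
    stop(sprintf("dimension mismatch: table has %d features, standardizer was fitted on %d",
                 ncol(table$features), length(params$means)), call. = FALSE)
  }
  x <- sweep(sweep(table$features, 2, params$means), 2, params$sds, "/")
  labeled_table(x, table$labels)
}

#' Fit a principal component analysis on training data
#'
#' Eigendecomposition of the training covariance matrix; the top-`k`
#' eigenvectors become the loadings and the corresponding eigenvalues the
#' explained variances (sorted descending). For determinism across
#' eigensolvers, each loading column is sign-fixed so its
#' largest-magnitude entry is non-negative.
#'
#' @param train a [labeled_table()] (typically already standardized).
#' @param k number of components, `1 <= k <= min(n_samples - 1, n_features)`.
#' @return An object of class `pca_params` with orthonormal `loadings`
#'   (`n_features x k`), `explained_variance` (length `k`, non-increasing),
#'   the training column means `center`, and `k`.
#' @export
fit_pca <- function(train, k) {
  x <- train$features
  k <- check_count(k, "k")
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (k > kmax) {
    stop_param("k", sprintf("must be at most min(n_samples - 1, n_features) = %d",
                            kmax))
  }
  center <- colMeans(x)
  eig <- eigen(cov(x), symmetric = TRUE)
  load <- eig$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude entry of each column non-negative
  for (j in seq_len(k)) {
    piv <- which.max(abs(load[, j]))
    if (load[piv, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(k))
  structure(list(loadings = load,
                 explained_variance = pmax(eig$values[seq_len(k)], 0),
                 center = center, k = k),
            class = "pca_params")
}

#' Project a table onto fitted principal components
#'
#' Centers with the training means stored in `params` and multiplies by the
#' loadings; columns are named `PC1..PCk` and labels pass through.
#'
#' @param table a [labeled_table()] with the feature count PCA was fitted on.
#' @param params a `pca_params` from [fit_pca()].
#' @return A [labeled_table()] with `k` columns.
#' @export
project_pca <- function(table, params) {
  if (!inherits(params, "pca_params")) {
    stop("`params` must come from fit_pca()", call. = FALSE)
  }
  if (ncol(table$features) != nrow(params$loadings)) {
    stop(sprintf("dimension mismatch: table has %d features, PCA was fitted on %d",
                 ncol(table$features), nrow(params$loadings)), call. = FALSE)
  }
  scores <- sweep(table$features, 2, params$center) %*% params$loadings
  labeled_table(scores, table$labels)
}

#' Serialize fitted preprocessing parameters to JSON
#'
#' Stores means, sds, loadings (row-major), explained variances and `k` in a
#' single JSON document so that a preprocessing front-end can be reused
#' across runs.
#'
#' @param std a `standardizer`, or NULL.
#' @param pca a `pca_params`, or NULL.
#' @param path file to write; when NULL the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_preproc <- function(std = NULL, pca = NULL, path = NULL) {
  doc <- list()
  if (!is.null(std)) {
    doc$standardizer <- list(means = unname(std$means), sds = unname(std$sds),
                             constant = unname(std$constant),
                             population = std$population)
  }
  if (!is.null(pca)) {
    doc$pca <- list(
      loadings = unname(pca$loadings),  # row-major nested arrays
      explained_variance = unname(pca$explained_variance),
      center = unname(pca$center), k = pca$k,
      feature_names = rownames(pca$loadings)
    )
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_preproc
#' @export
read_preproc <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  out <- list(standardizer = NULL, pca = NULL)
  if (!is.null(doc$standardizer)) {
    s <- doc$standardizer
    out$standardizer <- structure(
      list(means = s$means, sds = s$sds, constant = s$constant,
           population = s$population),
      class = "standardizer")
  }
  if (!is.null(doc$pca)) {
    p <- doc$pca
    load <- matrix(p$loadings, nrow = length(p$center))
    rownames(load) <- p$feature_names
    colnames(load) <- paste0("PC", seq_len(p$k))
    out$pca <- structure(
      list(loadings = load, explained_variance = p$explained_variance,
           center = p$center, k = p$k),
      class = "pca_params")
  }
  out
}
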