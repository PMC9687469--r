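#' Hybrid model parameters
#'
#' Bundles the classical linear projection (a `2 x n` weight matrix mapping
#' `n` input features to the two encoding angles) with the circuit angles.
#' The total trainable parameter count is `2n + 3 * n_layers`
#' (`2n + 12` for the default circuit).
#'
#' @param weights numeric `2 x n` matrix.
#' @param thetas numeric vector of circuit angles (`3 * n_layers`).
#' @param config an [embedding_config()].
#' @return An object of class `hybrid_params`.
#' @export
hybrid_params <- function(weights, thetas, config = embedding_config()) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 2L || ncol(weights) < 1L) {
    stop("`weights` must be a 2 x n matrix with n >= 1", call. = FALSE)
  }
  structure(list(weights = weights,
                 thetas = quantum_params(thetas, config)),
            class = "hybrid_params")
}

#' @export
print.hybrid_params <- function(x, ...) {
  cat(sprintf("<hybrid_params> 2 x %d linear weights + %d circuit angles (%d total)\n",
              ncol(x$weights), length(x$thetas),
              2 * ncol(x$weights) + length(x$thetas)))
  invisible(x)
}

#' Linear projection of a feature vector to the encoding angles
#'
#' `(x1, x2) = W f`: plain matrix multiplication, no bias term (a bias would
#' change the published parameter count).
#'
#' @param features numeric vector of length `n`, or an `m x n` matrix.
#' @param weights numeric `2 x n` matrix (or a `hybrid_params`).
#' @return For a vector input, `c(x1, x2)`; for a matrix, an `m x 2` matrix.
#' @export
project_features <- function(features, weights) {
  if (inherits(weights, "hybrid_params")) weights <- weights$weights
  if (is.matrix(features)) {
    if (ncol(features) != ncol(weights)) {
      stop(sprintf("dimension mismatch: %d features vs 2 x %d weights",
                   ncol(features), ncol(weights)), call. = FALSE)
    }
    out <- features %*% t(weights)
    colnames(out) <- c("x1", "x2")
    return(out)
  }
  if (length(features) != ncol(weights)) {
    stop(sprintf("dimension mismatch: %d features vs 2 x %d weights",
                 length(features), ncol(weights)), call. = FALSE)
  }
  drop(weights %*% features)
}

#' Total trainable parameter count of the hybrid model
#'
#' `2 * n_features` linear weights plus `3 * n_layers` circuit angles:
#' `2n + 12` under the default configuration (72 for 30 features, 1036 for
#' 512, 28 for 8 principal components).
#'
#' @param n_features number of input features (after any PCA reduction).
#' @param config an [embedding_config()].
#' @return Integer parameter count.
#' @examples
#' param_count(30)  # 72
#' @export
param_count <- function(n_features, config = embedding_config()) {
  n_features <- check_count(n_features, "n_features")
  2L * n_features + n_quantum_params(config)
}

#' @rdname param_count
#' @export
linear_param_count <- function(n_features) {
  2L * check_count(n_features, "n_features")
}

#' Feature count of a flattened image
#'
#' Convenience for the parameter accounting of pixel-level inputs:
#' `height * width * channels` (a 224 x 224 RGB image flattens to 150528
#' features).
#'
#' @param height,width,channels image dimensions.
#' @return Integer feature count.
#' @export
n_flattened_features <- function(height, width, channels = 3L) {
  check_count(height, "height") * check_count(width, "width") *
    check_count(channels, "channels")
}

#' Randomly initialize hybrid model parameters
#'
#' The `"normal"` scheme (default) draws linear weights from `N(0, 0.1^2)`
#' and circuit angles uniformly on `[0, 2*pi)`; `"zero"` sets everything to
#' zero (useful for fixtures). Deterministic per seed; the caller's RNG
#' state is untouched.
#'
#' @param n_features number of input features.
#' @param seed integer seed.
#' @param scheme initialization scheme name.
#' @param config an [embedding_config()].
#' @return A [hybrid_params()].
#' @export
init_params <- function(n_features, seed, scheme = "normal",
                        config = embedding_config()) {
  n_features <- check_count(n_features, "n_features")
  schemes <- c("normal", "zero")
  if (!scheme %in% schemes) {
    stop(sprintf("unknown scheme '%s'; available schemes: %s", scheme,
                 paste(schemes, collapse = ", ")), call. = FALSE)
  }
  nq <- n_quantum_params(config)
  with_seed(seed, {
    if (scheme == "normal") {
      hybrid_params(matrix(rnorm(2 * n_features, sd = 0.1), 2, n_features),
                    runif(nq, 0, 2 * pi), config)
    } else {
      hybrid_params(matrix(0, 2, n_features), rep(0, nq), config)
    }
  })
}

#' Embed one sample end to end
#'
#' Composition of the linear projection and the quantum feature map:
#' `embed_pair(project_features(f, W), thetas)`.
#'
#' @param features numeric feature vector.
#' @param params a [hybrid_params()].
#' @param config an [embedding_config()].
#' @return The embedded [two_qubit_state()].
#' @export
embed_sample <- function(features, params, config = embedding_config()) {
  x <- project_features(features, params$weights)
  embed_pair(x[1], x[2], params$thetas, config)
}

#' Embed every sample of a labeled table
#'
#' @param table a [labeled_table()].
#' @param params a [hybrid_params()].
#' @param config an [embedding_config()].
#' @return A `4 x n_samples` complex amplitude matrix with the table's
#'   labels attached as attribute `"labels"`.
#' @export
embed_table <- function(table, params, config = embedding_config()) {
  x12 <- project_features(table$features, params$weights)
  states <- embed_batch(x12, params$thetas, config)
  attr(states, "labels") <- table$labels
  states
}

# flatten/unflatten for the optimizer: linear weights column-major, then
# circuit angles
flatten_params <- function(params) {
  c(as.vector(params$weights), params$thetas)
}
unflatten_params <- function(vec, n_features, config = embedding_config()) {
  nw <- 2L * n_features
  hybrid_params(matrix(vec[seq_len(nw)], 2, n_features),
                vec[-seq_len(nw)], config)
}

#' Serialize hybrid parameters to JSON
#'
#' Weights are stored row-major, circuit angles in consumption order, so a
#' checkpoint can be reloaded for an exact resume.
#'
#' @param params a [hybrid_params()].
#' @param path file to write; when NULL the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
params_to_json <- function(params, path = NULL) {
  doc <- list(weights = unname(params$weights), thetas = params$thetas)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  config <- embedding_config(n_layers = length(doc$thetas) / 3L)
  hybrid_params(doc$weights, doc$thetas, config)
}
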