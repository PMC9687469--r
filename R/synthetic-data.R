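#' Specification for a synthetic two-class feature table
#'
#' Describes a Gaussian two-class generative model with a shared low-rank
#' covariance component, used to emulate clinical-style tabular data (a few
#' hundred samples, ~30 correlated continuous features, partially
#' overlapping classes) as well as the overparameterized regime where the
#' feature count far exceeds the sample count.
#'
#' Class-conditional model: `x | class = mu_c + W z + e`, with `W` an
#' `n_features x cov_rank` matrix of `N(0, cov_sd^2)` entries drawn once per
#' seed (shared between classes, so PCA has a meaningful low-rank structure
#' to find), `z ~ N(0, I)`, `e ~ N(0, noise_sd^2 I)`, and class means
#' `mu_a, mu_b = +/- (separation/2) u` for a random unit direction `u`.
#'
#' @param n_per_class samples per class (default 285, giving 570 rows — the
#'   clinical dataset rounded to even per-class counts).
#' @param n_features number of feature columns (default 30).
#' @param separation Euclidean distance between the two class mean vectors,
#'   in standardized units (default 3: partially overlapping classes).
#' @param cov_rank rank of the shared covariance component, in
#'   `[1, n_features]` (default 5).
#' @param noise_sd isotropic noise standard deviation (default 1).
#' @param cov_sd scale of the low-rank component's entries (default 1; set
#'   to 0 for a noise-only configuration).
#' @param seed integer seed; identical spec and seed give bit-identical
#'   output.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_two_class_table()]
#' @export
synthetic_spec <- function(n_per_class = 285L, n_features = 30L,
                           separation = 3, cov_rank = 5L, noise_sd = 1,
                           cov_sd = 1, seed = 1L) {
  spec <- list(
    n_per_class = check_count(n_per_class, "n_per_class"),
    n_features = check_count(n_features, "n_features"),
    separation = check_scalar(separation, "separation", lower = 0),
    cov_rank = check_count(cov_rank, "cov_rank"),
    noise_sd = check_scalar(noise_sd, "noise_sd", lower = 0,
                            strict_lower = TRUE),
    cov_sd = check_scalar(cov_sd, "cov_sd", lower = 0),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (spec$cov_rank > spec$n_features) {
    stop_param("cov_rank", "must be at most n_features")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic two-class labeled table
#'
#' Draws `2 * n_per_class` samples from the Gaussian model described in
#' [synthetic_spec()]. Rows are ordered class `"a"` then class `"b"`;
#' feature columns are named `f1..fn`. Output is deterministic per
#' (spec, seed) and the caller's RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return A [labeled_table()] with labels `"a"` and `"b"`; the class means
#'   differ by a vector of Euclidean length `spec$separation`.
#' @examples
#' tab <- generate_two_class_table(synthetic_spec(n_per_class = 20,
#'                                                n_features = 5, seed = 7))
#' table(tab$labels)
#' @export
generate_two_class_table <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("`spec` must be created with synthetic_spec()", call. = FALSE)
  }
  n <- spec$n_features
  m <- spec$n_per_class
  with_seed(spec$seed, {
    u <- rnorm(n)
    u <- u / sqrt(sum(u^2))
    w <- matrix(rnorm(n * spec$cov_rank, sd = spec$cov_sd), n, spec$cov_rank)
    half <- (spec$separation / 2) * u
    draw <- function(mu, m) {
      z <- matrix(rnorm(m * spec$cov_rank), m, spec$cov_rank)
      e <- matrix(rnorm(m * n, sd = spec$noise_sd), m, n)
      sweep(z %*% t(w) + e, 2, mu, "+")
    }
    feats <- rbind(draw(half, m), draw(-half, m))
    colnames(feats) <- paste0("f", seq_len(n))
    labeled_table(feats, rep(c("a", "b"), each = m))
  })
}

#' Split a labeled table into train and test parts
#'
#' Deterministic (per seed) disjoint row partition whose union restores the
#' input. By default the split is stratified: each class contributes its own
#' rounded share of training rows, so per-class proportions are preserved
#' within one sample even for small tables. `stratified = FALSE` gives a
#' simple random split of the pooled rows.
#'
#' @param table a [labeled_table()].
#' @param train_fraction fraction of rows assigned to the training part,
#'   strictly between 0 and 1 (the clinical study's 3:2 split is 0.6).
#' @param seed integer seed for the permutation.
#' @param stratified split within each class (default) or over pooled rows.
#' @return List with elements `train` and `test`, both `labeled_table`s.
#' @examples
#' tab <- generate_two_class_table(synthetic_spec(n_per_class = 25,
#'                                                n_features = 4, seed = 1))
#' sp <- split_train_test(tab, 0.6, seed = 1)
#' n_samples(sp$train)
#' @export
split_train_test <- function(table, train_fraction, seed,
                             stratified = TRUE) {
  train_fraction <- check_scalar(train_fraction, "train_fraction",
                                 lower = 0, upper = 1, strict_lower = TRUE)
  if (train_fraction >= 1) stop_param("train_fraction", "must be < 1")
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(class_levels(table), function(lv) {
        rows <- which(table$labels == lv)
        if (length(rows) < 2L) {
          stop(sprintf("class '%s' has fewer than 2 samples; cannot stratify",
                       lv), call. = FALSE)
        }
        sample(rows, round(train_fraction * length(rows)))
      }), use.names = FALSE)
    } else {
      sample(n_samples(table), round(train_fraction * n_samples(table)))
    }
  })
  idx <- sort(idx)
  list(train = subset_table(table, idx),
       test = subset_table(table, setdiff(seq_len(n_samples(table)), idx)))
}
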