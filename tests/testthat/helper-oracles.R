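# Independent oracles used across the suite: dense tensor-product gate
# matrices, a brute-force circuit composition, and central finite
# differences for the gradient contract.

rx_mat2 <- function(p) {
  matrix(c(cos(p / 2), -1i * sin(p / 2), -1i * sin(p / 2), cos(p / 2)), 2, 2)
}
ry_mat2 <- function(p) {
  matrix(complex(real = c(cos(p / 2), sin(p / 2), -sin(p / 2), cos(p / 2))),
         2, 2)
}
zz_mat4 <- function(t) diag(exp(-1i * t / 2 * c(1, -1, -1, 1)))

# dense 4x4 unitary route (kronecker products applied to the raw vector)
oracle_rx_pair <- function(v, x1, x2) drop((rx_mat2(x1) %x% rx_mat2(x2)) %*% v)
oracle_ry_pair <- function(v, a, b) drop((ry_mat2(a) %x% ry_mat2(b)) %*% v)
oracle_zz <- function(v, t) drop(zz_mat4(t) %*% v)

oracle_embed <- function(x1, x2, th, layers = 4, final_encoding = TRUE) {
  v <- c(1 + 0i, 0, 0, 0)
  for (l in seq_len(layers)) {
    v <- oracle_rx_pair(v, x1, x2)
    v <- oracle_zz(v, th[3 * l - 2])
    v <- oracle_ry_pair(v, th[3 * l - 1], th[3 * l])
  }
  if (final_encoding) v <- oracle_rx_pair(v, x1, x2)
  v
}

random_state <- function() {
  v <- complex(real = rnorm(4), imaginary = rnorm(4))
  two_qubit_state(v / sqrt(sum(Mod(v)^2)))
}

random_state_matrix <- function(m) {
  v <- matrix(complex(real = rnorm(4 * m), imaginary = rnorm(4 * m)), 4, m)
  sweep(v, 2, sqrt(colSums(Mod(v)^2)), "/")
}

# central finite differences of the batch cost wrt the flattened parameters
fd_gradient <- function(params, fa, fb, config = embedding_config(),
                        h = 1e-6) {
  vec <- c(as.vector(params$weights), params$thetas)
  n <- ncol(params$weights)
  reparam <- function(v) {
    hybrid_params(matrix(v[seq_len(2 * n)], 2, n), v[-seq_len(2 * n)], config)
  }
  vapply(seq_along(vec), function(i) {
    vp <- vec; vp[i] <- vp[i] + h
    vm <- vec; vm[i] <- vm[i] - h
    (batch_cost(reparam(vp), fa, fb, config) -
       batch_cost(reparam(vm), fa, fb, config)) / (2 * h)
  }, numeric(1))
}

rel_err <- function(got, want) {
  sqrt(sum((got - want)^2)) / max(sqrt(sum(want^2)), 1e-12)
}

# small separable fixture for end-to-end runs
separable_table <- function(n_per_class = 15, n_features = 4, seed = 2) {
  generate_two_class_table(synthetic_spec(
    n_per_class = n_per_class, n_features = n_features, separation = 8,
    cov_rank = 2, noise_sd = 0.5, seed = seed))
}
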