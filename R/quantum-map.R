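#' Two-qubit statevector
#'
#' Amplitudes are stored in the order `|00>, |01>, |10>, |11>` with qubit 1
#' the left position. The constructor checks normalization to 1e-8; the gate
#' operations themselves preserve the norm to machine precision.
#'
#' @param amplitudes complex vector of length 4.
#' @return An object of class `two_qubit_state` (a named complex vector).
#' @export
two_qubit_state <- function(amplitudes) {
  amplitudes <- as.complex(amplitudes)
  if (length(amplitudes) != 4L) {
    stop("a two-qubit state has exactly 4 amplitudes", call. = FALSE)
  }
  nrm <- sum(Mod(amplitudes)^2)
  if (abs(nrm - 1) > 1e-8) {
    stop(sprintf("state is not normalized (|amplitudes|^2 sums to %.10f)", nrm),
         call. = FALSE)
  }
  structure(stats::setNames(amplitudes, c("00", "01", "10", "11")),
            class = "two_qubit_state")
}

#' @export
print.two_qubit_state <- function(x, ...) {
  cat("<two_qubit_state>\n")
  print(unclass(x))
  invisible(x)
}

# 2x2 rotation matrices; exp(-i phi/2 X) and exp(-i phi/2 Y)
rx_matrix <- function(phi) {
  c <- cos(phi / 2); s <- sin(phi / 2)
  matrix(c(complex(real = c), complex(imaginary = -s),
           complex(imaginary = -s), complex(real = c)), 2, 2)
}
ry_matrix <- function(phi) {
  c <- cos(phi / 2); s <- sin(phi / 2)
  matrix(complex(real = c(c, s, -s, c)), 2, 2)
}

# apply single-qubit gates g1 (x) g2 by reshaping the amplitude vector as a
# 2x2 matrix A[q1, q2]
apply_pair <- function(state, g1, g2) {
  a <- matrix(unclass(state), 2, 2, byrow = TRUE)
  out <- g1 %*% a %*% t(g2)
  two_qubit_state(as.vector(t(out)))
}

#' Circuit gate operations
#'
#' The three gate families of the embedding circuit, acting on a
#' [two_qubit_state()]: paired data-encoding rotations
#' `Rx(x1) (x) Rx(x2)`, the ZZ entangler `exp(-i theta/2 Z (x) Z)` (which
#' multiplies the even-parity amplitudes `|00>, |11>` by `exp(-i theta/2)`
#' and the odd-parity ones by `exp(+i theta/2)`), and paired trainable
#' rotations `Ry(theta_a) (x) Ry(theta_b)`. Angles are unrestricted
#' (periodic); all three preserve the norm.
#'
#' @param state a [two_qubit_state()].
#' @param x1,x2 encoding angles (radians) for qubits 1 and 2.
#' @return The transformed [two_qubit_state()].
#' @export
rx_pair <- function(state, x1, x2) {
  apply_pair(state, rx_matrix(x1), rx_matrix(x2))
}

#' @rdname rx_pair
#' @param theta entangler angle (radians).
#' @export
zz_coupling <- function(state, theta) {
  ph <- exp(complex(imaginary = -theta / 2))
  two_qubit_state(unclass(state) * c(ph, Conj(ph), Conj(ph), ph))
}

#' @rdname rx_pair
#' @param theta_a,theta_b rotation angles (radians) for qubits 1 and 2.
#' @export
ry_pair <- function(state, theta_a, theta_b) {
  apply_pair(state, ry_matrix(theta_a), ry_matrix(theta_b))
}

#' Embedding circuit configuration
#'
#' The default circuit repeats `n_layers = 4` ansatz blocks — data-encoding
#' Rx pair, ZZ entangler, Ry pair — consuming 3 trainable angles per block
#' (12 in total), and closes with one more data-encoding layer
#' (`final_encoding = TRUE`). Starting from `|00>` this is 13 gate layers,
#' i.e. a sequence of 14 states including the initial one.
#'
#' @param n_layers number of repeated ansatz blocks (default 4).
#' @param final_encoding apply a closing data re-encoding layer (default
#'   TRUE); FALSE gives the 12-transition variant.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(n_layers = 4L, final_encoding = TRUE) {
  n_layers <- check_count(n_layers, "n_layers")
  structure(list(n_layers = n_layers, params_per_layer = 3L,
                 final_encoding = isTRUE(final_encoding)),
            class = "embedding_config")
}

n_quantum_params <- function(config) config$n_layers * config$params_per_layer

#' Trainable circuit angles
#'
#' Validates a vector of circuit angles against a configuration: one angle
#' for each ZZ entangler and two for each Ry pair, consumed layer by layer
#' (so `3 * n_layers` in total; 12 for the default circuit).
#'
#' @param thetas numeric vector of angles (radians).
#' @param config an [embedding_config()].
#' @return The validated numeric vector.
#' @export
quantum_params <- function(thetas, config = embedding_config()) {
  thetas <- as.numeric(thetas)
  if (length(thetas) != n_quantum_params(config)) {
    stop(sprintf("expected %d quantum parameters (3 per layer), got %d",
                 n_quantum_params(config), length(thetas)), call. = FALSE)
  }
  thetas
}

#' Embed a pair of encoding angles into a two-qubit state
#'
#' Starting from `|00>`, applies `n_layers` repetitions of
#' `[Rx-pair(x1, x2); ZZ(theta); Ry-pair(theta, theta)]` followed (by
#' default) by one closing `Rx-pair(x1, x2)` re-encoding.
#'
#' @param x1,x2 encoding angles (radians), usually the output of the linear
#'   projection.
#' @param thetas circuit angles, length `3 * n_layers`.
#' @param config an [embedding_config()].
#' @return The embedded [two_qubit_state()].
#' @examples
#' embed_pair(0.3, -1.2, rep(0.1, 12))
#' @export
embed_pair <- function(x1, x2, thetas, config = embedding_config()) {
  thetas <- quantum_params(thetas, config)
  state <- two_qubit_state(c(1, 0, 0, 0))
  for (l in seq_len(config$n_layers)) {
    state <- rx_pair(state, x1, x2)
    state <- zz_coupling(state, thetas[3 * l - 2])
    state <- ry_pair(state, thetas[3 * l - 1], thetas[3 * l])
  }
  if (config$final_encoding) state <- rx_pair(state, x1, x2)
  state
}

#' Embed many (x1, x2) pairs at once
#'
#' Fast path over the compiled statevector simulator; identical to calling
#' [embed_pair()] row by row.
#'
#' @param x12 numeric matrix with two columns (x1, x2), one row per sample.
#' @param thetas circuit angles, length `3 * n_layers`.
#' @param config an [embedding_config()].
#' @return A `4 x nrow(x12)` complex matrix of state amplitudes.
#' @export
embed_batch <- function(x12, thetas, config = embedding_config()) {
  x12 <- as.matrix(x12)
  if (ncol(x12) != 2L) stop("`x12` must have two columns", call. = FALSE)
  thetas <- quantum_params(thetas, config)
  qml_embed_cpp(x12, thetas, config$n_layers, config$final_encoding)
}
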