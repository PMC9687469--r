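# Class-ensemble density matrices, the Hilbert-Schmidt distance and the
# training cost C = 1 - Dhs/2, plus the pairwise-overlap machinery shared by
# the trainer and the Gram-matrix exports.

# coerce a states argument (two_qubit_state, list of them, or 4 x M complex
# matrix) to a 4 x M matrix
as_state_matrix <- function(states) {
  if (inherits(states, "two_qubit_state")) {
    return(matrix(unclass(states), 4, 1))
  }
  if (is.list(states)) {
    return(vapply(states, function(s) as.complex(unclass(s)),
                  complex(4)))
  }
  if (is.matrix(states) && nrow(states) == 4L) return(states)
  stop("`states` must be two-qubit states or a 4 x M amplitude matrix",
       call. = FALSE)
}

#' Class ensemble of embedded states
#'
#' A non-empty collection of embedded two-qubit states sharing a class
#' label; the equal-weight average of their outer products is the class
#' density matrix.
#'
#' @param states a list of [two_qubit_state()]s or a `4 x M` complex
#'   amplitude matrix.
#' @param label class label attached to the ensemble.
#' @return An object of class `class_ensemble`.
#' @export
class_ensemble <- function(states, label = NA_character_) {
  states <- as_state_matrix(states)
  if (ncol(states) == 0L) stop("ensemble must be non-empty", call. = FALSE)
  nrms <- colSums(Mod(states)^2)
  if (any(abs(nrms - 1) > 1e-8)) {
    stop("all ensemble states must be normalized", call. = FALSE)
  }
  structure(list(states = states, label = label), class = "class_ensemble")
}

#' Density matrix of a class ensemble
#'
#' Equal-weight average of the outer products `|x><x|` over the ensemble:
#' a 4 x 4 Hermitian, positive semi-definite, trace-1 matrix.
#'
#' @param ensemble a [class_ensemble()], or anything [class_ensemble()]
#'   accepts as `states`.
#' @return A 4 x 4 complex matrix.
#' @export
density_matrix <- function(ensemble) {
  if (!inherits(ensemble, "class_ensemble")) {
    ensemble <- class_ensemble(ensemble)
  }
  s <- ensemble$states
  (s %*% Conj(t(s))) / ncol(s)
}

check_density <- function(m, arg) {
  if (!is.matrix(m) || any(dim(m) != 4L)) {
    stop(sprintf("`%s` must be a 4 x 4 matrix", arg), call. = FALSE)
  }
  if (max(Mod(m - Conj(t(m)))) > 1e-8) {
    stop(sprintf("`%s` is not Hermitian within tolerance", arg),
         call. = FALSE)
  }
  if (abs(Re(sum(diag(m))) - 1) > 1e-8) {
    stop(sprintf("`%s` does not have unit trace", arg), call. = FALSE)
  }
  invisible(m)
}

#' Hilbert-Schmidt distance between two density matrices
#'
#' `Dhs(rho, sigma) = tr[(rho - sigma)^2]`, in `[0, 2]` for density
#' matrices; 0 for identical ensembles and 2 for orthogonal pure states.
#'
#' @param rho,sigma 4 x 4 density matrices (Hermitian, trace 1).
#' @return Non-negative real distance.
#' @export
hs_distance <- function(rho, sigma) {
  check_density(rho, "rho")
  check_density(sigma, "sigma")
  d <- rho - sigma
  # tr(D^2) = sum |D_ij|^2 for Hermitian D
  sum(Mod(d)^2)
}

#' Hilbert-Schmidt training cost
#'
#' `C = 1 - Dhs(rho, sigma) / 2`, the quantity minimized during training;
#' range `[0, 1]`, with 0 for perfectly separated (orthogonal pure)
#' ensembles and 1 for identical ones.
#'
#' @inheritParams hs_distance
#' @return Cost in `[0, 1]`.
#' @export
hs_cost <- function(rho, sigma) {
  1 - 0.5 * hs_distance(rho, sigma)
}

#' Overlap (fidelity) between two embedded states
#'
#' `|<x|x'>|^2`, in `[0, 1]`; symmetric, and 1 for identical states up to
#' global phase.
#'
#' @param x,x_prime [two_qubit_state()]s (or length-4 complex vectors).
#' @return Real overlap in `[0, 1]`.
#' @export
state_overlap <- function(x, x_prime) {
  Mod(sum(Conj(as.complex(unclass(x))) * as.complex(unclass(x_prime))))^2
}

# all pairwise overlaps between the columns of two amplitude matrices
overlap_matrix <- function(sa, sb) {
  Mod(Conj(t(sa)) %*% sb)^2
}

#' Cost of two full class ensembles via the pairwise-overlap expansion
#'
#' Algebraically identical to [hs_cost()] of the two density matrices, but
#' computed from pairwise overlaps:
#' `Dhs = mean(aa') + mean(bb') - 2 mean(ab)` over all ordered pairs. This
#' is the form used in the training loop and for the reported full-split
#' training and test costs.
#'
#' @param states_a,states_b `4 x M` amplitude matrices (or ensembles) for
#'   the two classes.
#' @return Cost in `[0, 1]`.
#' @export
ensemble_cost <- function(states_a, states_b) {
  sa <- as_state_matrix(if (inherits(states_a, "class_ensemble"))
    states_a$states else states_a)
  sb <- as_state_matrix(if (inherits(states_b, "class_ensemble"))
    states_b$states else states_b)
  d <- mean(overlap_matrix(sa, sa)) + mean(overlap_matrix(sb, sb)) -
    2 * mean(overlap_matrix(sa, sb))
  1 - 0.5 * d
}
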