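#' Training configuration
#'
#' Defaults reproduce the published protocol: 1500 optimization steps with a
#' batch size of 10 and RMSProp with step size 0.01. The RMSProp decay (0.9)
#' and epsilon (1e-8) are the optimizer's standard values. `batch_mode`
#' `"per_class"` (default) draws `batch_size` samples from each class every
#' step, since the cost needs both ensembles; `"total"` draws `batch_size`
#' samples overall (redrawing if a class comes up empty).
#'
#' @param steps number of optimization steps (default 1500).
#' @param batch_size samples drawn per class (or in total) per step
#'   (default 10).
#' @param step_size RMSProp learning rate (default 0.01).
#' @param rms_decay squared-gradient averaging factor, in (0, 1)
#'   (default 0.9).
#' @param rms_epsilon denominator regularizer (default 1e-8).
#' @param seed integer seed controlling batch sampling.
#' @param batch_mode `"per_class"` or `"total"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(steps = 1500L, batch_size = 10L, step_size = 0.01,
                         rms_decay = 0.9, rms_epsilon = 1e-8, seed = 1L,
                         batch_mode = c("per_class", "total")) {
  structure(list(
    steps = check_count(steps, "steps", min = 0L),
    batch_size = check_count(batch_size, "batch_size"),
    step_size = check_scalar(step_size, "step_size", lower = 0,
                             strict_lower = TRUE),
    rms_decay = check_scalar(rms_decay, "rms_decay", lower = 0, upper = 1,
                             strict_lower = TRUE),
    rms_epsilon = check_scalar(rms_epsilon, "rms_epsilon", lower = 0,
                               strict_lower = TRUE),
    seed = check_count(seed, "seed", min = -.Machine$integer.max),
    batch_mode = match.arg(batch_mode)
  ), class = "train_config")
}

#' Batch cost and analytic gradient
#'
#' Cost `C = 1 - Dhs/2` of the two embedded feature batches, with its exact
#' gradient with respect to all `2n + 3*n_layers` parameters, computed by
#' forward-mode differentiation through the circuit (overlap form of the
#' Hilbert-Schmidt distance). The gradient matches central finite
#' differences of the cost.
#'
#' @param params a [hybrid_params()].
#' @param feats_a,feats_b numeric feature matrices (rows = samples) for the
#'   two classes; both non-empty.
#' @param config an [embedding_config()].
#' @return List with `cost`, `grad_weights` (2 x n), `grad_thetas`, and the
#'   flattened `gradient` (weights column-major, then angles) matching
#'   [flatten_params()][hybrid_params()] order.
#' @export
cost_gradient <- function(params, feats_a, feats_b,
                          config = embedding_config()) {
  feats_a <- as.matrix(feats_a)
  feats_b <- as.matrix(feats_b)
  if (nrow(feats_a) == 0L || nrow(feats_b) == 0L) {
    stop("both class batches must be non-empty", call. = FALSE)
  }
  out <- qml_cost_grad_cpp(feats_a, feats_b, params$weights, params$thetas,
                           config$n_layers, config$final_encoding, TRUE)
  out$gradient <- c(as.vector(out$grad_weights), out$grad_thetas)
  out
}

#' @rdname cost_gradient
#' @export
batch_cost <- function(params, feats_a, feats_b,
                       config = embedding_config()) {
  feats_a <- as.matrix(feats_a)
  feats_b <- as.matrix(feats_b)
  if (nrow(feats_a) == 0L || nrow(feats_b) == 0L) {
    stop("both class batches must be non-empty", call. = FALSE)
  }
  qml_cost_grad_cpp(feats_a, feats_b, params$weights, params$thetas,
                    config$n_layers, config$final_encoding, FALSE)$cost
}

#' One RMSProp update
#'
#' `avg <- decay * avg + (1 - decay) * g^2`;
#' `params <- params - step_size * g / sqrt(avg + epsilon)`.
#'
#' @param params numeric parameter vector.
#' @param grads gradient vector of the same length.
#' @param state optimizer state: list with `sq_grad_avg` (same length,
#'   non-negative) and `step_index`; NULL initializes a fresh state.
#' @param config a [train_config()].
#' @return List with updated `params` and `state`.
#' @export
rmsprop_step <- function(params, grads, state = NULL,
                         config = train_config()) {
  if (is.null(state)) {
    state <- list(sq_grad_avg = numeric(length(params)), step_index = 0L)
  }
  if (length(params) != length(grads) ||
      length(params) != length(state$sq_grad_avg)) {
    stop("params, grads and optimizer state must have equal lengths",
         call. = FALSE)
  }
  avg <- config$rms_decay * state$sq_grad_avg +
    (1 - config$rms_decay) * grads^2
  params <- params - config$step_size * grads / sqrt(avg + config$rms_epsilon)
  list(params = params,
       state = list(sq_grad_avg = avg,
                    step_index = state$step_index + 1L))
}

#' Train the hybrid embedding
#'
#' Minimizes the Hilbert-Schmidt cost over all `2n + 3*n_layers` parameters
#' with RMSProp. Each step draws a per-class mini-batch (with replacement
#' when a class is smaller than the batch size, so tiny fixtures train),
#' evaluates the batch cost and its analytic gradient, and updates. The
#' recorded trace holds the batch cost before each update plus the final
#' batch's cost after the last update (`steps + 1` values, all in `[0, 1]`).
#' Deterministic per `config$seed`.
#'
#' @param train_table a [labeled_table()] containing both classes.
#' @param init initial [hybrid_params()] (see [init_params()]).
#' @param config a [train_config()].
#' @param embedding an [embedding_config()].
#' @return List with `params` (trained [hybrid_params()]) and `trace`
#'   (list with `costs`).
#' @examples
#' tab <- generate_two_class_table(synthetic_spec(n_per_class = 15,
#'   n_features = 4, separation = 6, noise_sd = 0.5, cov_rank = 2, seed = 2))
#' fit <- train_embedding(tab, init_params(4, seed = 1),
#'                        train_config(steps = 50, seed = 3))
#' fit$trace$costs[c(1, 51)]
#' @export
train_embedding <- function(train_table, init, config = train_config(),
                            embedding = embedding_config()) {
  levels <- class_levels(train_table)
  if (length(levels) != 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  fa <- class_features(train_table, levels[2])  # class A = positive
  fb <- class_features(train_table, levels[1])
  if (ncol(fa) != ncol(init$weights)) {
    stop(sprintf("dimension mismatch: table has %d features, params expect %d",
                 ncol(fa), ncol(init$weights)), call. = FALSE)
  }
  n <- ncol(fa)
  vec <- flatten_params(init)
  state <- NULL
  costs <- numeric(config$steps + 1L)
  bs <- config$batch_size

  with_seed(config$seed, {
    last_a <- last_b <- NULL
    for (s in seq_len(config$steps)) {
      if (config$batch_mode == "per_class") {
        ia <- sample(nrow(fa), bs, replace = nrow(fa) < bs)
        ib <- sample(nrow(fb), bs, replace = nrow(fb) < bs)
      } else {
        repeat {
          m <- nrow(fa) + nrow(fb)
          ii <- sample(m, bs, replace = m < bs)
          ia <- ii[ii <= nrow(fa)]
          ib <- ii[ii > nrow(fa)] - nrow(fa)
          if (length(ia) > 0L && length(ib) > 0L) break
        }
      }
      last_a <- fa[ia, , drop = FALSE]
      last_b <- fb[ib, , drop = FALSE]
      params <- unflatten_params(vec, n, embedding)
      g <- cost_gradient(params, last_a, last_b, embedding)
      costs[s] <- g$cost
      upd <- rmsprop_step(vec, g$gradient, state, config)
      vec <- upd$params
      state <- upd$state
    }
    final <- unflatten_params(vec, n, embedding)
    costs[config$steps + 1L] <- if (config$steps > 0L) {
      batch_cost(final, last_a, last_b, embedding)
    } else {
      batch_cost(final, fa, fb, embedding)
    }
    list(params = final, trace = list(costs = costs))
  })
}
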