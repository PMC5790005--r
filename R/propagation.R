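## The mathematical core: a condition map becomes a parameterized
## signal-propagation model. Node states live in [-1, 1]; the fixed point of
## the damped synchronous update
##     x_j <- (1 - alpha) x_j + alpha * tanh(bias_j + sum_i W_ij x_i)
## (with perturbed nodes clamped at their input values throughout) is the
## model's response to a perturbation. Edge strengths are sign-constrained by
## the curated edge sign at all times, including mid-training.

new_propagation_model <- function(map, strengths, bias, alpha = 0.5,
                                  eps = 1e-6, max_iter = 200L,
                                  activation = "tanh") {
  stopifnot(inherits(map, "condition_map"))
  n <- length(map$nodes)
  e <- map$edges
  stopifnot(length(strengths) == nrow(e), length(bias) == n)
  if (activation != "tanh")
    ns_stop("unknown activation rule '%s' (available: tanh)", activation)
  m <- structure(list(condition = map$condition, nodes = map$nodes,
                      edges = e,
                      from_idx = match(e$source, map$nodes),
                      to_idx = match(e$target, map$nodes),
                      strengths = as.numeric(strengths),
                      bias = as.numeric(bias),
                      activation = activation, alpha = alpha, eps = eps,
                      max_iter = as.integer(max_iter),
                      map = map),
                 class = "propagation_model")
  check_sign_constraints(m)
  m
}

check_sign_constraints <- function(model) {
  bad <- model$edges$sign * model$strengths < 0
  if (any(bad))
    ns_stop("sign constraint violated on edge %s->%s",
            model$edges$source[bad][1L], model$edges$target[bad][1L])
  invisible(TRUE)
}

#' @export
print.propagation_model <- function(x, ...) {
  cat(sprintf("<propagation_model:%s> %d nodes, %d signed edges, activation=%s, alpha=%g, eps=%g\n",
              x$condition, length(x$nodes), nrow(x$edges), x$activation,
              x$alpha, x$eps))
  invisible(x)
}

model_weight_matrix <- function(model) {
  n <- length(model$nodes)
  W <- matrix(0, n, n)
  if (length(model$strengths))
    W[cbind(model$from_idx, model$to_idx)] <- model$strengths
  W
}

#' Build an untrained propagation model from a condition map
#'
#' Strengths are initialized small-random with the curated signs; biases
#' start at zero. Hyperparameter defaults: damping `alpha = 0.5`,
#' convergence tolerance `eps = 1e-6`, `max_iter = 200`, `init_scale = 0.1`,
#' tanh activation.
#'
#' @param map A `condition_map`.
#' @param hyperparams Optional list overriding `alpha`, `eps`, `max_iter`,
#'   `init_scale`, `activation`.
#' @param seed Integer seed for the random initialization.
#' @return A `propagation_model`.
#' @export
build_model <- function(map, hyperparams = list(), seed = 1L) {
  stopifnot(inherits(map, "condition_map"))
  if (length(map$nodes) == 0L) ns_stop("cannot build a model on an empty map")
  defaults <- list(alpha = 0.5, eps = 1e-6, max_iter = 200L, init_scale = 0.1,
                   activation = "tanh")
  bad <- setdiff(names(hyperparams), names(defaults))
  if (length(bad)) ns_stop("unknown hyperparameter(s): %s",
                           paste(bad, collapse = ", "))
  hp <- utils::modifyList(defaults, hyperparams)
  ne <- nrow(map$edges)
  strengths <- with_seed(seed,
    map$edges$sign * stats::runif(ne, 0, hp$init_scale))
  new_propagation_model(map, strengths, rep(0, length(map$nodes)),
                        alpha = hp$alpha, eps = hp$eps,
                        max_iter = hp$max_iter, activation = hp$activation)
}

# Batched fixed-point propagation. `signatures` is a list of named numeric
# clamp vectors (possibly empty). Returns states matrix (nodes x runs),
# per-run converged flags and the iteration count.
propagate_batch <- function(model, signatures) {
  n <- length(model$nodes)
  m <- length(signatures)
  X <- matrix(0, n, m, dimnames = list(model$nodes, NULL))
  Mask <- matrix(FALSE, n, m)
  for (j in seq_len(m)) {
    sig <- signatures[[j]]
    if (length(sig) == 0L) next
    idx <- match(names(sig), model$nodes)
    if (anyNA(idx))
      ns_stop("input signature names unknown protein(s): %s",
              paste(names(sig)[is.na(idx)], collapse = ", "))
    if (any(abs(sig) > 1)) ns_stop("input signature values must lie in [-1, 1]")
    Mask[idx, j] <- TRUE
    X[idx, j] <- sig
  }
  if (m == 0L)
    return(list(states = X, converged = logical(0), iterations = 0L))
  tW <- t(model_weight_matrix(model))
  b <- model$bias
  alpha <- model$alpha
  any_clamp <- any(Mask)
  iters <- 0L
  Xp <- X
  for (it in seq_len(model$max_iter)) {
    Xn <- (1 - alpha) * X + alpha * tanh(tW %*% X + b)
    if (any_clamp) Xn[Mask] <- X[Mask]
    dm <- max(abs(Xn - X))
    Xp <- X
    X <- Xn
    iters <- it
    if (dm < model$eps) break
  }
  last_delta <- apply(abs(X - Xp), 2L, max)
  list(states = clip1(X), converged = last_delta < model$eps,
       iterations = iters)
}

#' Propagate a perturbation to its fixed point
#'
#' Nodes named in `input_signature` are clamped at their input values for
#' the whole iteration; all other nodes start at 0 and follow the damped
#' tanh update until the largest per-node change falls below the model's
#' `eps` or the iteration cap is hit (in which case `converged` is FALSE and
#' the final iterate is returned).
#'
#' @param model A `propagation_model`.
#' @param input_signature Named numeric vector of clamp values in [-1, 1];
#'   may be empty. Unknown protein names are an error.
#' @return A `state_vector`: `state` (named, in [-1, 1]), `converged`,
#'   `iterations`.
#' @export
propagate <- function(model, input_signature = numeric(0)) {
  stopifnot(inherits(model, "propagation_model"))
  res <- propagate_batch(model, list(input_signature))
  structure(list(state = setNames(res$states[, 1L], model$nodes),
                 converged = res$converged[1L],
                 iterations = res$iterations),
            class = "state_vector")
}

#' @export
print.state_vector <- function(x, ...) {
  cat(sprintf("<state_vector> %d nodes, converged=%s after %d iteration(s)\n",
              length(x$state), x$converged, x$iterations))
  invisible(x)
}

# Residuals of a model against a restriction table, from one batched
# propagation of all row inputs.
restriction_residuals <- function(model, rt) {
  states <- propagate_batch(model, lapply(rt$rows, `[[`, "input"))$states
  lapply(seq_along(rt$rows), function(r) {
    row <- rt$rows[[r]]
    idx <- match(names(row$output), model$nodes)
    if (anyNA(idx))
      ns_stop("restriction row '%s' names protein(s) outside the map: %s",
              row$row_id, paste(names(row$output)[is.na(idx)], collapse = ", "))
    states[idx, r] - row$output
  })
}

#' Evaluate restriction satisfaction of a model
#'
#' A row is satisfied when every required output state matches the
#' propagated state within the row's tolerance.
#'
#' @param model A `propagation_model`.
#' @param rt A [restriction_table].
#' @return List with `satisfaction` (fraction in [0, 1]), logical
#'   `per_row` vector, per-row `objective` mean squared residual.
#' @export
evaluate_restrictions <- function(model, rt) {
  stopifnot(inherits(rt, "restriction_table"))
  if (length(rt$rows) == 0L) ns_stop("restriction table is empty")
  res <- restriction_residuals(model, rt)
  tol <- vapply(rt$rows, `[[`, 1, "tolerance")
  per_row <- mapply(function(r, t) all(abs(r) <= t), res, tol)
  mse <- vapply(res, function(r) mean(r^2), 1)
  list(satisfaction = mean(per_row),
       per_row = setNames(per_row, vapply(rt$rows, `[[`, "", "row_id")),
       objective = mean(mse), row_mse = mse)
}

#' Train a propagation model against a restriction table
#'
#' Seeded simulated annealing over edge strengths and node biases with
#' geometric cooling. Proposals perturb a random subset of parameters and
#' are projected back onto the sign constraints (an activating edge's
#' strength is never negative, an inhibiting edge's never positive). The
#' objective is the mean squared residual between propagated read-out states
#' and the required outputs; the returned model is the best iterate by
#' (satisfaction, then objective), so training never degrades the initial
#' model's satisfaction.
#'
#' @param model An initial `propagation_model` (see [build_model]).
#' @param rt A [restriction_table]; every restriction protein must be in the
#'   model's map.
#' @param optimizer_params Optional list overriding `n_steps` (default
#'   2000), `t0`, `t_end`, `proposal_sd`, `frac` (fraction of parameters
#'   perturbed per step), `strength_max`, `bias_max`.
#' @param seed Integer seed for the annealing run.
#' @return List with `model` (trained) and `report` (a `fit_report`:
#'   satisfaction, per-row residual flags, objective trajectory, seed).
#' @export
train <- function(model, rt, optimizer_params = list(), seed = 1L) {
  stopifnot(inherits(model, "propagation_model"),
            inherits(rt, "restriction_table"))
  if (length(rt$rows) == 0L) ns_stop("restriction table is empty")
  defaults <- list(n_steps = 3000L, n_polish = 1500L, t0 = 0.02, t_end = 1e-4,
                   proposal_sd = 0.12, frac = 0.15, strength_max = 1.5,
                   bias_max = 1, search_eps = 1e-4, lambda = 0.01)
  bad <- setdiff(names(optimizer_params), names(defaults))
  if (length(bad)) ns_stop("unknown optimizer parameter(s): %s",
                           paste(bad, collapse = ", "))
  op <- utils::modifyList(defaults, optimizer_params)
  ne <- length(model$strengths)
  n <- length(model$nodes)
  npar <- ne + n
  sgn <- model$edges$sign

  project <- function(par) {
    s <- par[seq_len(ne)]
    if (ne) {
      s <- ifelse(sgn > 0, pmin(pmax(s, 0), op$strength_max),
                  pmax(pmin(s, 0), -op$strength_max))
    }
    b <- pmin(op$bias_max, pmax(-op$bias_max, par[ne + seq_len(n)]))
    c(s, b)
  }
  set_par <- function(par) {
    model$strengths <- par[seq_len(ne)]
    model$bias <- par[ne + seq_len(n)]
    model
  }
  # annealing evaluations run at a coarser fixed-point tolerance; the final
  # report re-evaluates the best iterate at the model's own eps. A ridge
  # penalty keeps parameters the restrictions do not constrain near zero
  # (parsimony: unsupported interactions carry no signal).
  score <- function(par) {
    m <- set_par(par)
    m$eps <- max(m$eps, op$search_eps)
    ev <- evaluate_restrictions(m, rt)
    list(obj = ev$objective + op$lambda * mean(par^2), sat = ev$satisfaction)
  }

  par <- project(c(model$strengths, model$bias))
  cur <- score(par)
  init_sat <- cur$sat
  init_obj <- cur$obj
  best_par <- par; best <- cur
  n_keep <- max(1L, op$n_steps %/% 100L)
  traj <- numeric(0)
  cool <- if (op$n_steps > 1) (op$t_end / op$t0)^(1 / (op$n_steps - 1)) else 1
  with_seed(seed, {
    temp <- op$t0
    for (step in seq_len(op$n_steps)) {
      k <- max(1L, round(op$frac * npar))
      idx <- sample.int(npar, k)
      cand <- par
      cand[idx] <- cand[idx] + stats::rnorm(k, 0, op$proposal_sd)
      cand <- project(cand)
      sc <- score(cand)
      if (sc$obj <= cur$obj ||
          stats::runif(1) < exp((cur$obj - sc$obj) / temp)) {
        par <- cand; cur <- sc
      }
      if (cur$sat > best$sat ||
          (cur$sat == best$sat && cur$obj < best$obj)) {
        best_par <- par; best <- cur
      }
      if (step %% n_keep == 0L) traj <- c(traj, best$obj)
      temp <- temp * cool
    }
    # greedy polish from the best annealing iterate: small proposals,
    # improvements only
    par <- best_par; cur <- best
    for (step in seq_len(op$n_polish)) {
      k <- max(1L, round(0.05 * npar))
      idx <- sample.int(npar, k)
      cand <- par
      cand[idx] <- cand[idx] + stats::rnorm(k, 0, op$proposal_sd / 3)
      cand <- project(cand)
      sc_ <- score(cand)
      if (sc_$obj <= cur$obj) { par <- cand; cur <- sc_ }
      if (cur$sat > best$sat ||
          (cur$sat == best$sat && cur$obj < best$obj)) {
        best_par <- par; best <- cur
      }
    }
  })
  trained <- set_par(best_par)
  check_sign_constraints(trained)
  ev <- evaluate_restrictions(trained, rt)
  report <- structure(list(satisfaction = ev$satisfaction,
                           satisfaction_initial = init_sat,
                           per_row = ev$per_row,
                           row_mse = ev$row_mse,
                           objective = ev$objective,
                           objective_initial = init_obj,
                           objective_trajectory = traj,
                           n_steps = op$n_steps,
                           seed = as.integer(seed)),
                      class = "fit_report")
  list(model = trained, report = report)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> satisfaction %.3f (initial %.3f), objective %.4g (initial %.4g), %d annealing steps, seed %d\n",
              x$satisfaction, x$satisfaction_initial, x$objective,
              x$objective_initial, x$n_steps, x$seed))
  invisible(x)
}

#' k-fold cross-validation of restriction satisfaction
#'
#' Rows are split into k folds keyed on sorted row ids (so permuting the
#' table's row order does not change the fold assignment); for each fold a
#' fresh model from `model_builder` is trained on the remaining rows and
#' satisfaction is evaluated on the held-out rows.
#'
#' @param model_builder Zero-argument function returning a fresh untrained
#'   `propagation_model`.
#' @param rt A [restriction_table] with at least `k_folds` rows.
#' @param k_folds Number of folds (>= 2).
#' @param seed Integer seed (drives the fold shuffle and each fold's
#'   training run).
#' @param optimizer_params Passed to [train].
#' @return List with `mean` held-out satisfaction and `per_fold` values.
#' @export
cross_validate <- function(model_builder, rt, k_folds, seed = 1L,
                           optimizer_params = list()) {
  stopifnot(is.function(model_builder), inherits(rt, "restriction_table"))
  nr <- length(rt$rows)
  if (k_folds < 2L) ns_stop("k_folds must be >= 2")
  if (nr < k_folds) ns_stop("fewer restriction rows (%d) than folds (%d)",
                            nr, k_folds)
  ids <- sort(vapply(rt$rows, `[[`, "", "row_id"))
  fold_of <- with_seed(derive_seed(seed, "cv_folds"),
                       setNames(sample(rep(seq_len(k_folds),
                                           length.out = nr)), ids))
  per_fold <- vapply(seq_len(k_folds), function(f) {
    held <- names(fold_of)[fold_of == f]
    train_rows <- Filter(function(r) !(r$row_id %in% held), rt$rows)
    test_rows <- Filter(function(r) r$row_id %in% held, rt$rows)
    fit <- train(model_builder(), restriction_table(train_rows),
                 optimizer_params = optimizer_params,
                 seed = derive_seed(seed, paste0("cv_fold_", f)))
    evaluate_restrictions(fit$model, restriction_table(test_rows))$satisfaction
  }, 1)
  list(mean = mean(per_fold), per_fold = per_fold)
}
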