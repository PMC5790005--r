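# Shared fixtures: tiny hand-built networks, a model constructor with fixed
# parameters, and an independent fixed-point oracle for acyclic maps.

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# chain A -> B -> C -> D, all activating, weight 1
chain_interactome <- function() {
  interactome(data.frame(source = c("A", "B", "C"),
                         target = c("B", "C", "D"),
                         sign = 1, weight = 1))
}

all_true_flags <- c(safe_profile = TRUE, no_pain_liability = TRUE,
                    no_known_regen_effect = TRUE, crosses_bbb = TRUE)

# a propagation model over an explicit edge list with fixed strengths/biases
make_model <- function(edges, strengths, bias = NULL, nodes = NULL, ...) {
  net <- interactome(edges, nodes = nodes)
  ss <- seed_set("fixture", data.frame(protein = net$nodes, motive = "M1",
                                       expected_state = 1))
  map <- expand_map(net, ss, policy = list(method = "k_hop", k = 0,
                                           keep_largest_component = FALSE))
  model <- build_model(map, hyperparams = list(...), seed = 1)
  model$strengths <- unname(strengths[paste(model$edges$source,
                                            model$edges$target)])
  stopifnot(!anyNA(model$strengths))
  if (is.null(bias)) bias <- setNames(rep(0, length(model$nodes)), model$nodes)
  model$bias <- unname(bias[model$nodes])
  model
}

# seeded random DAG model: edges only from lower to higher node index
random_dag_model <- function(n, seed, p = 0.4) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) pairs <- cbind(1L, 2L)
  sign <- sample(c(-1, 1), nrow(pairs), replace = TRUE)
  edges <- data.frame(source = nodes[pairs[, 1L]], target = nodes[pairs[, 2L]],
                      sign = sign, weight = runif(nrow(pairs), 0.2, 1))
  strengths <- setNames(sign * runif(nrow(pairs), 0, 1.2),
                        paste(edges$source, edges$target))
  bias <- setNames(rnorm(n, 0, 0.3), nodes)
  make_model(edges, strengths, bias, nodes = nodes, eps = 1e-12, max_iter = 500)
}

# Independent oracle: evaluate an acyclic model's fixed point in dependency
# order (never touches the package's iterative propagation loop).
topo_oracle <- function(model, clamp = numeric(0)) {
  nodes <- model$nodes
  parents <- split(seq_len(nrow(model$edges)), model$edges$target)
  state <- setNames(rep(NA_real_, length(nodes)), nodes)
  state[names(clamp)] <- clamp
  repeat {
    todo <- names(state)[is.na(state)]
    if (length(todo) == 0L) break
    progressed <- FALSE
    for (nd in todo) {
      pe <- parents[[nd]]
      srcs <- model$edges$source[pe]
      if (all(!is.na(state[srcs]))) {
        inp <- model$bias[match(nd, nodes)] +
          sum(model$strengths[pe] * state[srcs])
        state[nd] <- tanh(inp)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("oracle: graph is not acyclic")
  }
  state
}

# small scenario for fast end-to-end tests
fast_scenario <- function(seed = 1L, ...) {
  scenario(seed = seed, n_nodes = 80L, mean_degree = 5, n_restrictions = 25L,
           n_drugs = 12L, ...)
}

fast_optimizer <- list(n_steps = 600L, n_polish = 300L)
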