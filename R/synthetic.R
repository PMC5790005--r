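## Synthetic study generator. Every generator is a pure, seeded function of
## a scenario: a sparse signed interactome with two planted hub regulators
## converging on a read-out effector set (the known synergistic mechanism),
## motive-grouped seed sets for a degeneration and a protection condition,
## a hidden ground-truth propagation model, a restriction table sampled from
## that model's fixed points, and a drug library with planted null,
## single-active, synergistic-pair and decoy drugs.

#' Define a synthetic scenario
#'
#' Holds every knob of the synthetic study in one validated object. The
#' defaults are the package's reference desk-scale conditions: a 150-node
#' interactome with mean degree 5 and 25% inhibitory edges, two conditions
#' with 2 motives x 2 seeds and 40% seed overlap, 6 read-out proteins
#' driven by two convergent hub regulators, 40 noiseless restrictions at
#' tolerance 0.5, and a 50-drug library containing one planted synergistic
#' pair, one decoy pair that is ineligible on exactly one flag, two
#' single-active drugs and null drugs targeting low-influence nodes.
#'
#' @param seed Integer master seed; every generator derives its own stream
#'   from it.
#' @param n_nodes,mean_degree,inhibitory_fraction Interactome size, target
#'   undirected mean degree (2E/V) and fraction of inhibitory edges.
#' @param n_motives,seeds_per_motive Seed-set layout per condition.
#' @param seed_overlap Fraction of seed proteins shared between conditions.
#' @param disagreement_prob Probability that a shared seed's expected states
#'   disagree between the two conditions.
#' @param n_readout,n_pain Sizes of the protective read-out and adverse
#'   (pain) signature node sets.
#' @param branch_weight Interactome weight of the planted hub-to-read-out
#'   edges; ~0.6 makes each hub alone drive the read-outs weakly
#'   (tanh(0.6) ~ 0.54) and the pair strongly (tanh(1.2) ~ 0.83).
#' @param n_restrictions,restriction_noise,restriction_tolerance Truth-table
#'   size, row sign-flip noise rate in [0, 1), and per-row tolerance.
#' @param n_drugs,targets_per_drug Library size and the (min, max) targets
#'   of null drugs.
#' @param n_planted_pairs Number of planted synergistic pairs (0 or 1).
#' @param n_single_actives Number of planted single-active drugs.
#' @param planted_margin Minimum simulated synergy (percentage points) the
#'   planted pair must show over its singles at generation time.
#' @param planted_single_max Maximum single-agent efficacy either planted
#'   pair member may show alone ("moves the read-out weakly"); embeddings
#'   whose background paths saturate the read-outs are rejected and
#'   regenerated.
#' @return A validated `scenario` object.
#' @export
scenario <- function(seed = 1L, n_nodes = 150L, mean_degree = 5,
                     inhibitory_fraction = 0.25, n_motives = 2L,
                     seeds_per_motive = 2L, seed_overlap = 0.4,
                     disagreement_prob = 0.5, n_readout = 6L, n_pain = 4L,
                     branch_weight = 0.6, n_restrictions = 40L,
                     restriction_noise = 0, restriction_tolerance = 0.5,
                     n_drugs = 50L, targets_per_drug = c(1L, 3L),
                     n_planted_pairs = 1L, n_single_actives = 2L,
                     planted_margin = 18, planted_single_max = 62) {
  sc <- list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
             mean_degree = mean_degree,
             inhibitory_fraction = inhibitory_fraction,
             n_motives = as.integer(n_motives),
             seeds_per_motive = as.integer(seeds_per_motive),
             seed_overlap = seed_overlap,
             disagreement_prob = disagreement_prob,
             n_readout = as.integer(n_readout), n_pain = as.integer(n_pain),
             branch_weight = branch_weight,
             n_restrictions = as.integer(n_restrictions),
             restriction_noise = restriction_noise,
             restriction_tolerance = restriction_tolerance,
             n_drugs = as.integer(n_drugs),
             targets_per_drug = as.integer(targets_per_drug),
             n_planted_pairs = as.integer(n_planted_pairs),
             n_single_actives = as.integer(n_single_actives),
             planted_margin = planted_margin,
             planted_single_max = planted_single_max)
  if (sc$n_nodes < 10L) ns_stop("scenario: n_nodes must be >= 10")
  if (sc$mean_degree >= sc$n_nodes)
    ns_stop("scenario: infeasible degree request (mean degree >= n_nodes)")
  if (sc$seed_overlap < 0 || sc$seed_overlap > 1)
    ns_stop("scenario: seed_overlap must lie in [0, 1]")
  if (sc$restriction_noise < 0 || sc$restriction_noise >= 1)
    ns_stop("scenario: restriction_noise must lie in [0, 1)")
  if (sc$inhibitory_fraction < 0 || sc$inhibitory_fraction > 1)
    ns_stop("scenario: inhibitory_fraction must lie in [0, 1]")
  if (!sc$n_planted_pairs %in% c(0L, 1L))
    ns_stop("scenario: n_planted_pairs must be 0 or 1 at desk scale")
  if (length(sc$targets_per_drug) != 2L ||
      sc$targets_per_drug[1] > sc$targets_per_drug[2] ||
      sc$targets_per_drug[1] < 1L)
    ns_stop("scenario: targets_per_drug must be a feasible (min, max) range")
  if (sc$n_restrictions < 1L) ns_stop("scenario: n_restrictions must be >= 1")
  structure(sc, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> seed %d: %d nodes (deg %.1f, %.0f%% inhibitory), %dx%d seeds/condition (overlap %.0f%%), %d restrictions (noise %.0f%%), %d drugs\n",
              x$seed, x$n_nodes, x$mean_degree, 100 * x$inhibitory_fraction,
              x$n_motives, x$seeds_per_motive, 100 * x$seed_overlap,
              x$n_restrictions, 100 * x$restriction_noise, x$n_drugs))
  invisible(x)
}

#' Generate a sparse signed interactome with a planted synergy motif
#'
#' A directed configuration-style random graph with heavy-tailed out-degree
#' (hubs plus leaves). Source nodes are drawn proportionally to a Pareto-like
#' fitness; the two highest-fitness nodes become the planted hub regulators
#' and both receive activating edges (weight `branch_weight`) onto a common
#' read-out node set, embedding a convergence motif whose joint activation
#' is superadditive under a saturating propagation rule. The undirected mean
#' degree is matched exactly by construction; weakly connected components
#' beyond the giant one are bridged so the largest component covers the
#' graph. Fully deterministic under the scenario seed.
#'
#' @param sc A [scenario].
#' @return An [interactome] with a `planted` attribute listing the branch
#'   hubs and read-out nodes (NULL when the graph is too small to plant).
#' @export
generate_interactome <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  n <- sc$n_nodes
  m_total <- round(n * sc$mean_degree / 2)
  nodes <- sprintf("P%03d", seq_len(n))
  with_seed(derive_seed(sc$seed, "interactome"), {
    fitness <- stats::runif(n)^(-0.45)
    hub_order <- order(fitness, decreasing = TRUE)
    r_eff <- max(0L, min(sc$n_readout, floor(m_total / 3), n - 4L))
    planted <- NULL
    planted_edges <- NULL
    if (r_eff >= 2L && sc$n_planted_pairs >= 1L) {
      # mid-fitness regulators: connected enough to sit in the expanded map,
      # without the giant organic neighbourhood of the top hubs that would
      # confound the planted convergence motif
      pos <- min(n - 1L, max(1L, ceiling(0.3 * n)))
      u <- nodes[hub_order[pos]]
      v <- nodes[hub_order[pos + 1L]]
      readout <- sample(setdiff(nodes, c(u, v)), r_eff)
      planted <- list(branch = c(u, v), readout = sort(readout))
      planted_edges <- data.frame(source = rep(c(u, v), each = r_eff),
                                  target = rep(readout, 2L),
                                  sign = 1, weight = sc$branch_weight,
                                  stringsAsFactors = FALSE)
    }
    used <- if (is.null(planted_edges)) character(0) else
      c(paste(planted_edges$source, planted_edges$target, sep = "\r"),
        paste(planted_edges$target, planted_edges$source, sep = "\r"))
    m_rand <- m_total - if (is.null(planted_edges)) 0L else nrow(planted_edges)
    if (m_rand < 0L) ns_stop("generate_interactome: degree request too small")
    src <- character(0); dst <- character(0)
    guard <- 0L
    while (length(src) < m_rand) {
      need <- m_rand - length(src)
      cand_s <- nodes[sample.int(n, 3L * need + 10L, replace = TRUE,
                                 prob = fitness)]
      cand_t <- nodes[sample.int(n, 3L * need + 10L, replace = TRUE)]
      ok <- cand_s != cand_t
      cand_s <- cand_s[ok]; cand_t <- cand_t[ok]
      key <- paste(cand_s, cand_t, sep = "\r")
      rkey <- paste(cand_t, cand_s, sep = "\r")
      keep <- !(key %in% used) & !(rkey %in% used) & !duplicated(key) &
        !(key %in% rkey[duplicated(rkey) | seq_along(rkey) < match(rkey, key, nomatch = 0)])
      # simpler in-batch reciprocal screen: drop any pair whose reverse
      # appears earlier in the batch
      seen <- character(0)
      for (i in which(keep)) {
        if (key[i] %in% seen || rkey[i] %in% seen) keep[i] <- FALSE
        else seen <- c(seen, key[i])
      }
      add <- utils::head(which(keep), need)
      src <- c(src, cand_s[add]); dst <- c(dst, cand_t[add])
      used <- c(used, paste(cand_s[add], cand_t[add], sep = "\r"),
                paste(cand_t[add], cand_s[add], sep = "\r"))
      guard <- guard + 1L
      if (guard > 200L)
        ns_stop("generate_interactome: could not place %d edges", m_rand)
    }
    rand_edges <- data.frame(source = src, target = dst, sign = 1,
                             weight = stats::runif(m_rand, 0.3, 1),
                             stringsAsFactors = FALSE)
    n_inh <- min(m_rand, round(sc$inhibitory_fraction * m_total))
    if (n_inh > 0L)
      rand_edges$sign[sample.int(m_rand, n_inh)] <- -1
    edges <- rbind(planted_edges, rand_edges)
    net <- interactome(edges, nodes = nodes)
    comp <- igraph::components(as_igraph(net), mode = "weak")
    if (comp$no > 1L) {
      giant_id <- which.max(comp$csize)
      giant <- names(comp$membership)[comp$membership == giant_id]
      extra <- do.call(rbind, lapply(which(seq_len(comp$no) != giant_id),
        function(ci) {
          member <- names(comp$membership)[comp$membership == ci][1L]
          data.frame(source = sample(giant, 1L), target = member, sign = 1,
                     weight = 0.5, stringsAsFactors = FALSE)
        }))
      net <- interactome(rbind(net$edges, extra), nodes = nodes)
    }
    attr(net, "planted") <- planted
    net
  })
}

sample_weighted <- function(x, size, prob) {
  if (size > length(x)) ns_stop("cannot sample %d from %d items", size, length(x))
  x[sample.int(length(x), size, prob = prob)]
}

#' Generate motive-grouped seed sets for the two conditions
#'
#' Seeds are drawn degree-weighted (curated seed lists are enriched for
#' well-connected signalling proteins); when the interactome carries a
#' planted motif its two hub regulators are always part of the degeneration
#' seed list, so the degeneration map contains the planted circuit. The two
#' conditions share `seed_overlap` of their proteins, and shared proteins
#' receive disagreeing expected states with probability `disagreement_prob`.
#'
#' @param net An [interactome] (optionally with a `planted` attribute).
#' @param sc A [scenario].
#' @return List with elements `degeneration` and `protection`
#'   ([seed_set] objects).
#' @export
generate_condition_seeds <- function(net, sc) {
  stopifnot(inherits(net, "interactome"), inherits(sc, "scenario"))
  n_seed <- sc$n_motives * sc$seeds_per_motive
  shared_n <- round(sc$seed_overlap * n_seed)
  if (2L * n_seed - shared_n > length(net$nodes))
    ns_stop("generate_condition_seeds: %d distinct seed proteins requested but only %d nodes",
            2L * n_seed - shared_n, length(net$nodes))
  deg <- table(factor(c(net$edges$source, net$edges$target),
                      levels = net$nodes))
  prob <- as.numeric(deg) + 1
  planted <- attr(net, "planted")
  forced <- if (is.null(planted)) character(0) else planted$branch
  with_seed(derive_seed(sc$seed, "seeds"), {
    if (length(forced) > n_seed) forced <- forced[seq_len(n_seed)]
    pool <- setdiff(net$nodes, forced)
    extra <- sample_weighted(pool, n_seed - length(forced),
                             prob[match(pool, net$nodes)])
    deg_prot <- c(forced, extra)
    shared <- if (shared_n > 0) sample(deg_prot, shared_n) else character(0)
    pool2 <- setdiff(net$nodes, deg_prot)
    pro_prot <- c(shared,
                  sample_weighted(pool2, n_seed - shared_n,
                                  prob[match(pool2, net$nodes)]))
    deg_state <- setNames(sample(c(-1, 1), n_seed, replace = TRUE), deg_prot)
    pro_state <- setNames(sample(c(-1, 1), n_seed, replace = TRUE), pro_prot)
    flip <- stats::runif(length(shared)) < sc$disagreement_prob
    pro_state[shared] <- ifelse(flip, -deg_state[shared], deg_state[shared])
    motive_of <- function(prefix)
      paste0(prefix, rep(seq_len(sc$n_motives), each = sc$seeds_per_motive))
    list(degeneration = seed_set("degeneration",
           data.frame(protein = deg_prot, motive = motive_of("deg_M"),
                      expected_state = unname(deg_state),
                      stringsAsFactors = FALSE)),
         protection = seed_set("protection",
           data.frame(protein = pro_prot, motive = motive_of("pro_M"),
                      expected_state = unname(pro_state),
                      stringsAsFactors = FALSE)))
  })
}

# Search for two hub regulators with common activating out-neighbours, used
# when an interactome carries no planted motif annotation.
select_readout_circuit <- function(net, max_hubs = 10L) {
  if (!nrow(net$edges)) return(NULL)
  pos <- net$edges[net$edges$sign > 0, , drop = FALSE]
  outdeg <- sort(table(pos$source), decreasing = TRUE)
  hubs <- names(utils::head(outdeg, max_hubs))
  best <- NULL
  for (i in seq_along(hubs)) for (j in seq_along(hubs)) {
    if (j <= i) next
    common <- intersect(pos$target[pos$source == hubs[i]],
                        pos$target[pos$source == hubs[j]])
    common <- setdiff(common, c(hubs[i], hubs[j]))
    if (length(common) >= 2L && (is.null(best) || length(common) > length(best$readout)))
      best <- list(branch = c(hubs[i], hubs[j]), readout = sort(common))
  }
  best
}

#' Generate the hidden ground-truth propagation model
#'
#' Edge strengths are drawn as sign x weight x Uniform(0.8, 1.2) (curated
#' signs respected), biases as small Gaussians. The model records the
#' read-out node set and branch regulators of the planted motif (or finds a
#' convergent hub pair by search when the interactome has no planted
#' annotation); restrictions and drug labels are derived from it.
#'
#' @param net A non-empty [interactome].
#' @param sc A [scenario].
#' @param map Optional `condition_map`: when given, the hidden model is
#'   parameterized on the map's induced subgraph — the same universe a
#'   trained condition model lives in — so its restriction fixed points are
#'   representable by training.
#' @return A `propagation_model` with a `gt` element holding `branch` and
#'   `readout` node sets.
#' @export
generate_ground_truth_model <- function(net, sc, map = NULL) {
  stopifnot(inherits(net, "interactome"), inherits(sc, "scenario"))
  if (length(net$nodes) == 0L)
    ns_stop("generate_ground_truth_model: empty interactome")
  if (is.null(map))
    map <- condition_map_from_parts("ground_truth", net$nodes, net$edges)
  with_seed(derive_seed(sc$seed, "ground_truth"), {
    strengths <- map$edges$sign * map$edges$weight *
      stats::runif(nrow(map$edges), 0.8, 1.2)
    bias <- pmin(0.2, pmax(-0.2, stats::rnorm(length(map$nodes), 0, 0.05)))
    model <- new_propagation_model(map, strengths, bias)
    circuit <- attr(net, "planted")
    if (is.null(circuit)) circuit <- select_readout_circuit(net)
    if (!is.null(circuit) &&
        !all(c(circuit$branch, circuit$readout) %in% map$nodes))
      ns_stop("read-out circuit falls outside the model map")
    model$gt <- circuit
    model
  })
}

#' Total absolute downstream influence of nodes
#'
#' Influence of node i is the summed absolute fixed-point state over all
#' nodes when i is clamped at +1 — the "total absolute downstream
#' reachability weight" used to define low-influence targets for null drugs.
#'
#' @param model A `propagation_model`.
#' @param nodes Nodes to evaluate (default: all map nodes).
#' @return Named numeric influence vector.
#' @export
node_influence <- function(model, nodes = model$nodes) {
  stopifnot(all(nodes %in% model$nodes))
  st <- propagate_batch(model, lapply(nodes, function(nd) setNames(1, nd)))
  setNames(colSums(abs(st$states)) - 1, nodes)
}

#' Generate protective and adverse phenotype signatures
#'
#' The protection signature desires full activation (+1) of the ground-truth
#' read-out nodes. The pain signature desires activation of map nodes that
#' the planted pair leaves essentially untouched (smallest absolute response
#' to the joint branch perturbation), so adverse liability is a property a
#' candidate can avoid.
#'
#' @param gt_model Ground-truth model from [generate_ground_truth_model].
#' @param map The degeneration `condition_map`.
#' @param sc A [scenario].
#' @return List with `protection` and `pain` [phenotype_signature]s.
#' @export
generate_phenotype_signatures <- function(gt_model, map, sc) {
  circuit <- gt_model$gt
  if (is.null(circuit)) ns_stop("ground-truth model has no read-out circuit")
  missing <- setdiff(c(circuit$branch, circuit$readout), map$nodes)
  if (length(missing))
    ns_stop("planted circuit node(s) outside the degeneration map: %s",
            paste(missing, collapse = ", "))
  pair_state <- propagate(gt_model,
                          setNames(c(1, 1), circuit$branch))$state
  cand <- setdiff(map$nodes, c(circuit$branch, circuit$readout))
  if (length(cand) < sc$n_pain)
    ns_stop("not enough map nodes to build a pain signature")
  quiet <- cand[order(abs(pair_state[cand]), cand)]
  pain_nodes <- with_seed(derive_seed(sc$seed, "pain"),
                          sample(utils::head(quiet, max(sc$n_pain * 3L,
                                                        sc$n_pain)),
                                 sc$n_pain))
  list(protection = phenotype_signature("protection", circuit$readout, 1, 1),
       pain = phenotype_signature("pain", sort(pain_nodes), 1, 1))
}

#' Sample a restriction table from the ground-truth model
#'
#' The first rows perturb each branch regulator alone and the pair jointly
#' (mirroring single-drug indication knowledge feeding a truth table); the
#' remaining rows clamp 2-3 random non-read-out nodes at +/-1, sampled
#' proportionally to their ground-truth influence so most rows carry
#' decisive read-out responses. Required outputs are the ground-truth
#' fixed-point states of the read-out set. With noise, each row is
#' sign-flipped (all output values negated) with probability
#' `restriction_noise`; flipped rows are recorded in the `noisy_rows`
#' attribute (for benchmarking only).
#'
#' @param gt_model Ground-truth model carrying the read-out circuit.
#' @param sc A [scenario].
#' @param map Optional `condition_map`; restriction input nodes are then
#'   drawn from the map so every restriction protein is trainable.
#' @param observe Optional extra nodes whose fixed-point states are reported
#'   in every row's required output (e.g. the adverse-signature proteins:
#'   the proteomic contrasts behind a truth table profile every marker, not
#'   only the efficacy read-outs).
#' @return A [restriction_table] with `clean_rows` / `noisy_rows` attributes.
#' @export
generate_restrictions <- function(gt_model, sc, map = NULL, observe = NULL) {
  stopifnot(inherits(gt_model, "propagation_model"), inherits(sc, "scenario"))
  circuit <- gt_model$gt
  if (is.null(circuit) || length(circuit$readout) == 0L)
    ns_stop("generate_restrictions: read-out set is empty")
  readout <- unique(c(circuit$readout, observe))
  if (!all(readout %in% gt_model$nodes))
    ns_stop("generate_restrictions: observed node(s) outside the model map")
  pool_nodes <- if (is.null(map)) gt_model$nodes else map$nodes
  pool <- setdiff(pool_nodes, readout)
  infl <- node_influence(gt_model, pool)
  nr <- sc$n_restrictions
  with_seed(derive_seed(sc$seed, "restrictions"), {
    br <- circuit$branch
    # designed rows mirror single-drug indication knowledge: each branch
    # regulator alone (both directions) and the joint perturbations
    fixed <- list(setNames(1, br[1L]), setNames(1, br[2L]),
                  setNames(c(1, 1), br),
                  setNames(-1, br[1L]), setNames(-1, br[2L]),
                  setNames(c(-1, -1), br))
    inputs <- fixed[seq_len(min(length(fixed), nr))]
    while (length(inputs) < nr) {
      k <- sample(2:3, 1L)
      # half the rows target influential nodes (decisive read-out responses),
      # half are uniform so the table also pins down which perturbations do
      # nothing — both carry signal for training
      nodes <- if (stats::runif(1) < 0.5)
        sample_weighted(pool, k, infl + 1e-6)
      else sample(pool, k)
      inputs[[length(inputs) + 1L]] <-
        setNames(sample(c(-1, 1), k, replace = TRUE), sort(nodes))
    }
    states <- propagate_batch(gt_model, inputs)$states
    ro_idx <- match(readout, gt_model$nodes)
    flip <- stats::runif(nr) < sc$restriction_noise
    rows <- lapply(seq_len(nr), function(r) {
      out <- setNames(states[ro_idx, r], readout)
      if (flip[r]) out <- -out
      list(row_id = sprintf("r%03d", r), input = inputs[[r]],
           output = clip1(out), tolerance = sc$restriction_tolerance)
    })
    rt <- restriction_table(rows)
    attr(rt, "clean_rows") <- sprintf("r%03d", which(!flip))
    attr(rt, "noisy_rows") <- sprintf("r%03d", which(flip))
    rt
  })
}

#' Shuffle restriction outputs across rows (negative control)
#'
#' Keeps every input signature but permutes the required outputs (and their
#' tolerances) among rows, destroying the input-output association while
#' preserving both marginals. Used as a label-shuffled chance control for
#' training benchmarks.
#'
#' @param rt A [restriction_table].
#' @param seed Integer seed for the permutation.
#' @return A [restriction_table].
#' @export
shuffle_restrictions <- function(rt, seed = 1L) {
  stopifnot(inherits(rt, "restriction_table"))
  n <- length(rt$rows)
  perm <- with_seed(seed, sample.int(n))
  rows <- lapply(seq_len(n), function(i) {
    r <- rt$rows[[i]]
    r$output <- rt$rows[[perm[i]]]$output
    r$tolerance <- rt$rows[[perm[i]]]$tolerance
    r
  })
  restriction_table(rows)
}

#' Generate a drug library with planted ground truth
#'
#' Drug roles: the planted pair's members each agonize one branch regulator
#' of the read-out circuit (each alone moves the read-outs weakly, jointly
#' strongly — verified here by direct simulation on the ground-truth model
#' with margin `planted_margin`); a decoy pair clamps complementary halves
#' of the read-out set directly but its second member fails exactly one
#' eligibility flag; single actives clamp a fixed small read-out subset;
#' null drugs hit 1-3 nodes from the bottom influence quartile. Eligibility
#' flags are TRUE for all planted candidates and TRUE with probability 0.9
#' per flag for nulls.
#'
#' @param net The [interactome].
#' @param gt_model Ground-truth model carrying the read-out circuit.
#' @param sc A [scenario].
#' @param map Optional `condition_map` restricting null-drug target choice
#'   to trainable (map) nodes.
#' @return List with `library` (named list of [drug_signature]s) and
#'   `labels` (ground-truth roles).
#' @export
generate_drug_library <- function(net, gt_model, sc, map = NULL) {
  stopifnot(inherits(net, "interactome"),
            inherits(gt_model, "propagation_model"), inherits(sc, "scenario"))
  circuit <- gt_model$gt
  if (is.null(circuit) || length(circuit$readout) < 4L)
    ns_stop(paste("generate_drug_library: cannot find complementary upstream",
                  "branches with >= 4 common read-out targets; increase",
                  "n_readout or graph density"))
  readout <- circuit$readout
  br <- circuit$branch
  prot_sig <- phenotype_signature("protection", readout, 1, 1)
  st <- propagate_batch(gt_model, list(setNames(1, br[1L]),
                                       setNames(1, br[2L]),
                                       setNames(c(1, 1), br)))$states
  eff <- score_states(st, prot_sig)
  syn <- synergy_score(eff[3L], eff[1L], eff[2L])
  if (syn < sc$planted_margin || min(eff[1:2]) < 5 ||
      max(eff[1:2]) > sc$planted_single_max)
    ns_stop(paste0("generate_drug_library: planted pair failed verification ",
                   sprintf("(singles %.1f / %.1f, pair %.1f, synergy %.1f < margin %.1f)",
                           eff[1L], eff[2L], eff[3L], syn, sc$planted_margin)))
  n_special <- 2L * sc$n_planted_pairs + 2L + sc$n_single_actives
  if (sc$n_drugs < n_special + 1L)
    ns_stop("generate_drug_library: n_drugs too small for the planted roles")
  ids <- sprintf("D%03d", seq_len(sc$n_drugs))
  all_true <- setNames(rep(TRUE, 4L),
                       c("safe_profile", "no_pain_liability",
                         "no_known_regen_effect", "crosses_bbb"))
  tgt <- function(proteins, action = 1)
    data.frame(protein = proteins, action = action, stringsAsFactors = FALSE)
  lib <- list()
  i <- 0L
  planted_pair <- character(0)
  if (sc$n_planted_pairs == 1L) {
    planted_pair <- ids[1:2]
    lib[[ids[1L]]] <- drug_signature(ids[1L], tgt(br[1L]), all_true)
    lib[[ids[2L]]] <- drug_signature(ids[2L], tgt(br[2L]), all_true)
    i <- 2L
  }
  half <- length(readout) %/% 2L
  decoy_pair <- ids[i + 1:2]
  decoy_flags <- all_true
  decoy_flags["safe_profile"] <- FALSE   # ineligible on exactly one flag
  lib[[decoy_pair[1L]]] <- drug_signature(decoy_pair[1L],
                                          tgt(readout[1:2]), all_true)
  lib[[decoy_pair[2L]]] <- drug_signature(decoy_pair[2L],
                                          tgt(readout[3:4]), decoy_flags)
  i <- i + 2L
  single_actives <- character(0)
  if (sc$n_single_actives > 0L) {
    single_actives <- ids[i + seq_len(sc$n_single_actives)]
    sa_targets <- readout[c(1L, 3L)]
    for (id in single_actives)
      lib[[id]] <- drug_signature(id, tgt(sa_targets), all_true)
    i <- i + sc$n_single_actives
  }
  null_ids <- ids[(i + 1L):sc$n_drugs]
  pool_nodes <- if (is.null(map)) gt_model$nodes else map$nodes
  pool <- setdiff(pool_nodes, c(readout, br))
  infl <- node_influence(gt_model, pool)
  low <- pool[infl <= stats::quantile(infl, 0.25)]
  if (length(low) < sc$targets_per_drug[2])
    low <- pool[order(infl)][seq_len(min(length(pool), 5L))]
  with_seed(derive_seed(sc$seed, "drug_library"), {
    for (id in null_ids) {
      k <- sample(seq(sc$targets_per_drug[1L], sc$targets_per_drug[2L]), 1L)
      k <- min(k, length(low))
      prot <- sample(low, k)
      flags <- setNames(stats::runif(4L) < 0.9, names(all_true))
      lib[[id]] <- drug_signature(id, tgt(sort(prot),
                                          sample(c(-1, 1), k, replace = TRUE)),
                                  flags)
    }
  })
  labels <- list(planted_pairs = if (length(planted_pair))
                   list(planted_pair) else list(),
                 single_actives = single_actives,
                 decoy_pair = decoy_pair,
                 null_drugs = null_ids,
                 branch = br, readout = readout,
                 moa_nodes = readout,
                 planted_synergy_pts = unname(syn),
                 planted_single_efficacy = unname(eff[1:2]),
                 planted_pair_efficacy = unname(eff[3L]))
  list(library = lib[ids], labels = labels)
}

#' Generate a complete synthetic study
#'
#' Orchestrates the generators in dependency order: interactome, seed sets,
#' degeneration/protection maps (default k = 1 expansion), ground-truth
#' model, phenotype signatures, restriction table and drug library. If
#' planted-pair verification fails (rare), regeneration is retried with a
#' sub-seed up to `max_attempts` times before a hard error. Optionally
#' writes all external tables plus a `ground_truth.yaml` label file.
#'
#' @param sc A [scenario].
#' @param outdir Optional output directory (created if missing).
#' @param max_attempts Bounded retries with derived sub-seeds.
#' @return List with all generated objects and the labels.
#' @export
generate_scenario_data <- function(sc, outdir = NULL, max_attempts = 8L) {
  stopifnot(inherits(sc, "scenario"))
  last_err <- NULL
  for (attempt in seq_len(max_attempts)) {
    sc_try <- sc
    if (attempt > 1L)
      sc_try$seed <- derive_seed(sc$seed, paste0("retry", attempt))
    res <- tryCatch({
      net <- generate_interactome(sc_try)
      seeds <- generate_condition_seeds(net, sc_try)
      map_deg <- expand_map(net, seeds$degeneration)
      map_pro <- expand_map(net, seeds$protection)
      gt <- generate_ground_truth_model(net, sc_try, map = map_deg)
      sigs <- generate_phenotype_signatures(gt, map_deg, sc_try)
      rt <- generate_restrictions(gt, sc_try, map = map_deg,
                                  observe = names(sigs$pain$desired))
      dl <- generate_drug_library(net, gt, sc_try, map = map_deg)
      labels <- c(dl$labels,
                  list(pain_nodes = names(sigs$pain$desired),
                       clean_rows = attr(rt, "clean_rows"),
                       noisy_rows = attr(rt, "noisy_rows"),
                       scenario_seed = sc_try$seed, attempt = attempt))
      list(scenario = sc_try, interactome = net, seed_sets = seeds,
           map_degeneration = map_deg, map_protection = map_pro,
           ground_truth_model = gt, signatures = sigs, restrictions = rt,
           library = dl$library, labels = labels)
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      if (!is.null(outdir)) write_scenario_data(res, outdir)
      return(res)
    }
    last_err <- res
    ns_log("scenario generation attempt %d failed (%s); retrying",
           attempt, conditionMessage(res))
  }
  ns_stop("scenario generation failed after %d attempts: %s", max_attempts,
          conditionMessage(last_err))
}

write_scenario_data <- function(data, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_interactome(data$interactome, file.path(outdir, "interactome.tsv"))
  write_seed_sets(data$seed_sets, file.path(outdir, "seeds.tsv"))
  write_restrictions(data$restrictions, file.path(outdir, "restrictions.tsv"))
  write_drug_library(data$library, file.path(outdir, "drug_targets.tsv"),
                     file.path(outdir, "drug_metadata.tsv"))
  write_signatures(data$signatures, file.path(outdir, "signatures.tsv"))
  yaml::write_yaml(data$labels, file.path(outdir, "ground_truth.yaml"))
  invisible(outdir)
}
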