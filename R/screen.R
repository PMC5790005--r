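## Pairwise in-silico drug screen: clamp each drug's targets on the trained
## degeneration model, propagate to the fixed point, score the state against
## the protective and adverse phenotype signatures, compute highest-single-
## agent synergy, and apply the two-tier thresholds plus the four curated
## eligibility requirements.

#' Construct a phenotype signature
#'
#' A weighted set of read-out proteins with desired states, used to score a
#' propagated state for efficacy (protection signature) or adverse liability
#' (pain signature).
#'
#' @param label Signature label, e.g. "protection" or "pain".
#' @param proteins Character vector of read-out proteins.
#' @param desired Desired states in [-1, 1], nonzero.
#' @param weight Non-negative per-protein weights (sum must be positive).
#' @return A `phenotype_signature`.
#' @export
phenotype_signature <- function(label, proteins, desired, weight = 1) {
  stopifnot(is.character(label), length(label) == 1L)
  proteins <- as.character(proteins)
  desired <- rep_len(as.numeric(desired), length(proteins))
  weight <- rep_len(as.numeric(weight), length(proteins))
  if (length(proteins) == 0L) ns_stop("signature '%s' is empty", label)
  if (anyDuplicated(proteins)) ns_stop("signature '%s': duplicate protein", label)
  if (any(abs(desired) > 1) || any(desired == 0))
    ns_stop("signature '%s': desired states must be nonzero and in [-1, 1]", label)
  if (any(weight < 0) || sum(weight) <= 0)
    ns_stop("signature '%s': weights must be >= 0 with positive sum", label)
  o <- order(proteins)
  structure(list(label = label,
                 desired = setNames(desired[o], proteins[o]),
                 weight = setNames(weight[o], proteins[o])),
            class = "phenotype_signature")
}

#' Build the clamp signature of one or two drugs
#'
#' Each target is clamped at action sign times the dose magnitude; when two
#' drugs hit the same target the clamp value is the sum, clipped to [-1, 1].
#' Targets absent from the model's map are skipped and counted in the
#' `coverage` attribute (fraction of targets on the map); a drug set with
#' zero on-map targets yields an empty signature and a warning.
#'
#' @param drugs A `drug_signature` or list of one or two of them.
#' @param model A `propagation_model`.
#' @param dose Dose magnitude scalar (default 1).
#' @return Named numeric clamp vector with a `coverage` attribute.
#' @export
drug_input_signature <- function(drugs, model, dose = 1) {
  if (inherits(drugs, "drug_signature")) drugs <- list(drugs)
  stopifnot(length(drugs) %in% 1:2,
            all(vapply(drugs, inherits, TRUE, "drug_signature")))
  tg <- do.call(rbind, lapply(drugs, `[[`, "targets"))
  n_total <- nrow(tg)
  on_map <- tg$protein %in% model$nodes
  tg <- tg[on_map, , drop = FALSE]
  vals <- tapply(tg$action * dose, tg$protein, sum)
  sig <- clip1(setNames(as.numeric(vals), names(vals)))
  coverage <- if (n_total > 0) nrow(tg) / n_total else 1
  if (n_total > 0 && nrow(tg) == 0L)
    ns_warn("drug set {%s}: no target on the map (coverage 0)",
            paste(vapply(drugs, `[[`, "", "drug"), collapse = ", "))
  attr(sig, "coverage") <- coverage
  sig
}

score_states <- function(states, signature) {
  idx <- match(names(signature$desired), rownames(states))
  if (anyNA(idx))
    ns_stop("signature '%s' names protein(s) missing from the state: %s",
            signature$label,
            paste(names(signature$desired)[is.na(idx)], collapse = ", "))
  w <- signature$weight / sum(signature$weight)
  agree <- crossprod(states[idx, , drop = FALSE],
                     w * sign(signature$desired))[, 1L]
  100 * pmax(0, agree)
}

#' Efficacy of a propagated state against the protection signature
#'
#' 100 x max(0, weighted mean over signature proteins of
#' state x sign(desired)) — a weighted directional-agreement score on
#' [0, 100]. A state equal to a full-magnitude signature scores 100; an
#' all-zero state scores 0.
#'
#' @param state A `state_vector` or named numeric state.
#' @param signature A `phenotype_signature`.
#' @return Percentage in [0, 100].
#' @export
efficacy_score <- function(state, signature) {
  stopifnot(inherits(signature, "phenotype_signature"))
  if (inherits(state, "state_vector")) state <- state$state
  states <- matrix(state, ncol = 1, dimnames = list(names(state), NULL))
  unname(score_states(states, signature))
}

#' Adverse liability of a propagated state against the pain signature
#'
#' Identical contract to [efficacy_score], scored against the adverse
#' signature: 100 means the state matches the pain phenotype, 0 means no
#' (or opposite) alignment.
#'
#' @inheritParams efficacy_score
#' @return Percentage in [0, 100].
#' @export
adverse_score <- function(state, signature) efficacy_score(state, signature)

#' Highest-single-agent synergy
#'
#' Pair efficacy minus the better single-agent efficacy, in percentage
#' points; negative values are retained.
#'
#' @param pair_efficacy,efficacy_a,efficacy_b Percentages in [0, 100].
#' @return Synergy in percentage points.
#' @export
synergy_score <- function(pair_efficacy, efficacy_a, efficacy_b) {
  stopifnot(all(c(pair_efficacy, efficacy_a, efficacy_b) >= 0),
            all(c(pair_efficacy, efficacy_a, efficacy_b) <= 100))
  pair_efficacy - pmax(efficacy_a, efficacy_b)
}

#' Number of unordered drug pairs in a library of n drugs
#' @param n Library size.
#' @return n(n-1)/2.
#' @export
n_pair_count <- function(n) {
  stopifnot(n >= 0)
  n * (n - 1) / 2
}

#' Screen all single drugs and binary combinations
#'
#' Evaluates the n singles, then all n(n-1)/2 unordered pairs: each
#' combination's clamp signature is propagated to its fixed point and scored
#' for efficacy and adverse liability; synergy is pair efficacy minus the
#' better single. Deterministic given model and library; pairs are stored in
#' canonical (lexicographic) drug-id order.
#'
#' @param model A trained `propagation_model`.
#' @param library Named list of `drug_signature` objects (non-empty).
#' @param signatures List with elements `protection` and `pain`
#'   (`phenotype_signature` objects).
#' @param config Optional list: `dose` (default 1), `chunk` (propagation
#'   batch size, default 512), `verbose` (progress logging, default FALSE).
#' @return A `screen_result`: `singles` and `pairs` data.frames.
#' @export
screen_combinations <- function(model, library, signatures, config = list()) {
  stopifnot(inherits(model, "propagation_model"), length(library) > 0L,
            inherits(signatures$protection, "phenotype_signature"),
            inherits(signatures$pain, "phenotype_signature"))
  defaults <- list(dose = 1, chunk = 512L, verbose = FALSE)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) ns_stop("unknown screen config key(s): %s",
                           paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  ids <- vapply(library, `[[`, "", "drug")
  names(library) <- ids
  ord <- order(ids)
  library <- library[ord]
  ids <- ids[ord]
  n <- length(ids)

  sig_of <- lapply(library, function(d)
    suppressWarnings(drug_input_signature(d, model, dose = cfg$dose)))
  coverage <- vapply(sig_of, function(s) attr(s, "coverage"), 1)

  single_states <- propagate_batch(model, sig_of)$states
  eff_s <- score_states(single_states, signatures$protection)
  adv_s <- score_states(single_states, signatures$pain)
  singles <- data.frame(drug = ids, efficacy_pct = unname(eff_s),
                        adverse_pct = unname(adv_s),
                        coverage = unname(coverage),
                        stringsAsFactors = FALSE)
  if (cfg$verbose) ns_log("screened %d single drugs", n)

  if (n < 2L) {
    pairs <- data.frame(drug_a = character(0), drug_b = character(0),
                        efficacy_pct = numeric(0), adverse_pct = numeric(0),
                        synergy_pts = numeric(0), stringsAsFactors = FALSE)
  } else {
    cmb <- utils::combn(n, 2L)
    m <- ncol(cmb)
    eff_p <- adv_p <- numeric(m)
    for (start in seq(1L, m, by = cfg$chunk)) {
      idx <- start:min(m, start + cfg$chunk - 1L)
      sigs <- lapply(idx, function(j)
        suppressWarnings(drug_input_signature(
          list(library[[cmb[1L, j]]], library[[cmb[2L, j]]]),
          model, dose = cfg$dose)))
      st <- propagate_batch(model, sigs)$states
      eff_p[idx] <- score_states(st, signatures$protection)
      adv_p[idx] <- score_states(st, signatures$pain)
      if (cfg$verbose)
        ns_log("screened %d / %d pairs", min(m, start + cfg$chunk - 1L), m)
    }
    pairs <- data.frame(drug_a = ids[cmb[1L, ]], drug_b = ids[cmb[2L, ]],
                        efficacy_pct = eff_p, adverse_pct = adv_p,
                        synergy_pts = synergy_score(eff_p,
                                                    singles$efficacy_pct[cmb[1L, ]],
                                                    singles$efficacy_pct[cmb[2L, ]]),
                        stringsAsFactors = FALSE)
    swap <- pairs$drug_a > pairs$drug_b
    tmp <- pairs$drug_a[swap]
    pairs$drug_a[swap] <- pairs$drug_b[swap]
    pairs$drug_b[swap] <- tmp
    pairs <- pairs[order(pairs$drug_a, pairs$drug_b), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(singles = singles, pairs = pairs), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d singles, %d pairs; best pair efficacy %.1f%%, best synergy %.1f pts\n",
              nrow(x$singles), nrow(x$pairs),
              if (nrow(x$pairs)) max(x$pairs$efficacy_pct) else NA,
              if (nrow(x$pairs)) max(x$pairs$synergy_pts) else NA))
  invisible(x)
}

#' Default two-tier candidate thresholds
#'
#' Pass tier: efficacy >= 23 (inclusive), adverse <= 17 (inclusive),
#' synergy > 20 (strict). Top tier: efficacy > 75 and adverse < 2.5 (both
#' strict). Boundary semantics are overridable via the returned list.
#'
#' @return Nested list with `pass` and `top` threshold blocks.
#' @export
default_thresholds <- function() {
  list(pass = list(efficacy_min = 23, adverse_max = 17, synergy_min = 20),
       top = list(efficacy_min = 75, adverse_max = 2.5))
}

#' Deterministic ranking of combination scores
#'
#' Total order: efficacy descending, adverse ascending, synergy descending,
#' then canonical drug ids.
#'
#' @param scores data.frame of pair scores.
#' @return The same data.frame, sorted.
#' @export
rank_combinations <- function(scores) {
  if (!nrow(scores)) return(scores)
  o <- order(-scores$efficacy_pct, scores$adverse_pct, -scores$synergy_pts,
             scores$drug_a, scores$drug_b)
  out <- scores[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Eligibility metadata table of a drug library
#' @param library Named list of `drug_signature` objects.
#' @return data.frame with drug id and the four eligibility flags.
#' @export
library_metadata <- function(library) {
  out <- do.call(rbind, lapply(library, function(d)
    data.frame(drug = d$drug, t(as.data.frame(d$eligibility)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Filter and rank screened combinations
#'
#' Eligibility requires all four flags true for both drugs. The pass list
#' holds eligible pairs meeting the pass tier (efficacy >= 23, adverse <=
#' 17, synergy > 20 by default); the top list additionally requires the top
#' tier (efficacy > 75, adverse < 2.5). Both are sorted by the deterministic
#' ranking rule.
#'
#' @param scores A `screen_result` or its `pairs` data.frame.
#' @param library_metadata data.frame from [library_metadata] (or a library
#'   list, from which it is derived).
#' @param thresholds Threshold list as from [default_thresholds].
#' @return List with `passing`, `top` and fully `annotated` data.frames.
#' @export
filter_candidates <- function(scores, library_metadata,
                              thresholds = default_thresholds()) {
  if (inherits(scores, "screen_result")) scores <- scores$pairs
  if (is.list(library_metadata) && !is.data.frame(library_metadata))
    library_metadata <- library_metadata(library_metadata)
  flags <- c("safe_profile", "no_pain_liability", "no_known_regen_effect",
             "crosses_bbb")
  stopifnot(all(c("drug", flags) %in% names(library_metadata)))
  ok <- apply(library_metadata[flags], 1L, all)
  eligible_drug <- setNames(ok, library_metadata$drug)
  th <- thresholds
  scores$eligible <- as.logical(eligible_drug[scores$drug_a] &
                                eligible_drug[scores$drug_b])
  if (anyNA(scores$eligible))
    ns_stop("scored drug(s) missing from the metadata table")
  scores$pass_tier <- scores$eligible &
    scores$efficacy_pct >= th$pass$efficacy_min &
    scores$adverse_pct <= th$pass$adverse_max &
    scores$synergy_pts > th$pass$synergy_min
  scores$top_tier <- scores$pass_tier &
    scores$efficacy_pct > th$top$efficacy_min &
    scores$adverse_pct < th$top$adverse_max
  annotated <- rank_combinations(scores)
  list(passing = annotated[annotated$pass_tier, , drop = FALSE],
       top = annotated[annotated$top_tier, , drop = FALSE],
       annotated = annotated)
}

#' Extract mode-of-action nodes for a drug pair
#'
#' For every non-clamped map node the synergy contribution is the absolute
#' difference between the pair's propagated state and the single-drug state
#' of larger magnitude at that node (node-wise highest-single-agent
#' expectation). Nodes are ranked by contribution; ties break on node name,
#' and the result is invariant to drug order.
#'
#' @param model A trained `propagation_model`.
#' @param pair List of two `drug_signature` objects.
#' @param protection_signature Unused for the contribution itself but
#'   reported alongside (desired states of the read-outs), may be NULL.
#' @param top_k Number of nodes to return (>= 1).
#' @param dose Dose magnitude (default 1).
#' @return data.frame: node, contribution, state_pair, state_a, state_b,
#'   is_readout.
#' @export
extract_moa <- function(model, pair, protection_signature = NULL, top_k = 10L,
                        dose = 1) {
  stopifnot(inherits(model, "propagation_model"), length(pair) == 2L)
  if (top_k < 1L) ns_stop("top_k must be >= 1")
  pair <- pair[order(vapply(pair, `[[`, "", "drug"))]
  sig_a <- suppressWarnings(drug_input_signature(pair[[1L]], model, dose))
  sig_b <- suppressWarnings(drug_input_signature(pair[[2L]], model, dose))
  sig_ab <- suppressWarnings(drug_input_signature(pair, model, dose))
  st <- propagate_batch(model, list(sig_ab, sig_a, sig_b))$states
  clamped <- model$nodes %in% names(sig_ab)
  a <- st[, 2L]; b <- st[, 3L]
  ref <- ifelse(abs(a) > abs(b), a, ifelse(abs(b) > abs(a), b, pmax(a, b)))
  contribution <- abs(st[, 1L] - ref)
  out <- data.frame(node = model$nodes, contribution = contribution,
                    state_pair = st[, 1L], state_a = a, state_b = b,
                    is_readout = if (is.null(protection_signature)) FALSE
                    else model$nodes %in% names(protection_signature$desired),
                    stringsAsFactors = FALSE)
  out <- out[!clamped, , drop = FALSE]
  out <- out[order(-out$contribution, out$node), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
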