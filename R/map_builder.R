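## Condition-specific map construction: expand curated seed sets over the
## interactome into induced subnetworks and compute their summary statistics
## (node count, undirected links per node, seed/motive counts).

condition_map_from_parts <- function(condition, nodes, edges,
                                     seeds = character(0),
                                     missing_seeds = character(0),
                                     motives = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    stopifnot(all(edges$source %in% nodes), all(edges$target %in% nodes))
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(motives))
    motives <- data.frame(protein = character(0), motive = character(0),
                          stringsAsFactors = FALSE)
  structure(list(condition = condition, nodes = nodes, edges = edges,
                 seeds = sort(unique(seeds)),
                 missing_seeds = sort(unique(missing_seeds)),
                 motives = motives),
            class = "condition_map")
}

#' @export
print.condition_map <- function(x, ...) {
  st <- map_stats(x)
  cat(sprintf("<condition_map:%s> %d nodes, %d links (avg %.1f/node), %d seeds%s\n",
              x$condition, st$n_nodes, st$n_edges, st$avg_links, st$n_seeds,
              if (length(x$missing_seeds))
                sprintf(" (%d seeds absent from interactome)",
                        length(x$missing_seeds)) else ""))
  invisible(x)
}

as_igraph <- function(net, min_weight = 0) {
  ed <- net$edges
  if (min_weight > 0) ed <- ed[ed$weight >= min_weight, , drop = FALSE]
  igraph::graph_from_data_frame(ed[, c("source", "target"), drop = FALSE],
                                directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Expand a seed set into a condition-specific map
#'
#' Expansion policies: `"k_hop"` grows the union of k-step neighbourhoods
#' (both edge directions) around the seeds, optionally restricted to edges
#' with weight >= `min_weight`; `"sp_closure"` adds the nodes on shortest
#' paths between every seed pair. With `keep_largest_component = TRUE` the
#' result is trimmed to its largest weakly connected component, but seeds
#' are never dropped: seeds outside that component stay in the map, and
#' seeds absent from the interactome are reported in `missing_seeds` rather
#' than silently discarded. Map edges are always the full interactome edges
#' induced on the final node set.
#'
#' @param net An [interactome].
#' @param seeds A [seed_set].
#' @param policy List with elements `method` ("k_hop" or "sp_closure"),
#'   `k` (non-negative integer, k_hop only), `min_weight` (edge filter used
#'   during expansion only) and `keep_largest_component`.
#' @return A `condition_map`.
#' @export
expand_map <- function(net, seeds,
                       policy = list(method = "k_hop", k = 1, min_weight = 0,
                                     keep_largest_component = TRUE)) {
  stopifnot(inherits(net, "interactome"), inherits(seeds, "seed_set"))
  defaults <- list(method = "k_hop", k = 1, min_weight = 0,
                   keep_largest_component = TRUE)
  bad <- setdiff(names(policy), names(defaults))
  if (length(bad)) ns_stop("unknown expansion policy key(s): %s",
                           paste(bad, collapse = ", "))
  policy <- utils::modifyList(defaults, policy)
  seed_prot <- unique(seeds$entries$protein)
  present <- intersect(seed_prot, net$nodes)
  missing <- setdiff(seed_prot, net$nodes)
  if (length(missing))
    ns_log("expand_map(%s): %d seed(s) absent from interactome: %s",
           seeds$condition, length(missing), paste(missing, collapse = ", "))
  if (length(present) == 0L)
    ns_stop("expand_map(%s): no seed protein present in the interactome",
            seeds$condition)
  g <- as_igraph(net, policy$min_weight)
  if (policy$method == "k_hop") {
    k <- policy$k
    stopifnot(is.numeric(k), k >= 0)
    nb <- igraph::ego(g, order = k, nodes = present, mode = "all")
    keep <- unique(c(present, unlist(lapply(nb, names))))
  } else if (policy$method == "sp_closure") {
    keep <- present
    if (length(present) > 1L) {
      for (i in seq_along(present)[-length(present)]) {
        sp <- suppressWarnings(
          igraph::shortest_paths(g, from = present[i],
                                 to = present[(i + 1):length(present)],
                                 mode = "all"))
        keep <- unique(c(keep, unlist(lapply(sp$vpath, names))))
      }
    }
  } else ns_stop("unknown expansion method '%s'", policy$method)
  if (isTRUE(policy$keep_largest_component) && length(keep) > 1L) {
    sub <- igraph::induced_subgraph(as_igraph(net), keep)
    comp <- igraph::components(sub, mode = "weak")
    giant <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    keep <- unique(c(giant, present))
  }
  ed <- net$edges[net$edges$source %in% keep & net$edges$target %in% keep, ,
                  drop = FALSE]
  condition_map_from_parts(seeds$condition, keep, ed, seeds = present,
                           missing_seeds = missing,
                           motives = seeds$entries[
                             seeds$entries$protein %in% present,
                             c("protein", "motive"), drop = FALSE])
}

#' Summary statistics of a condition map
#'
#' "Links per node" counts the undirected collapse of the directed edge set
#' (a reciprocal pair counts once): average = 2 x links / nodes, defined as
#' 0 for an empty map.
#'
#' @param map A `condition_map`.
#' @return A `map_stats` list: `n_nodes`, `n_edges` (undirected links),
#'   `avg_links`, `n_seeds`, `n_motives`.
#' @export
map_stats <- function(map) {
  stopifnot(inherits(map, "condition_map"))
  n <- length(map$nodes)
  und <- if (nrow(map$edges))
    unique(paste(pmin(map$edges$source, map$edges$target),
                 pmax(map$edges$source, map$edges$target), sep = "\r"))
  else character(0)
  e <- length(und)
  structure(list(n_nodes = n, n_edges = e,
                 avg_links = if (n > 0) 2 * e / n else 0,
                 n_seeds = length(map$seeds),
                 n_motives = length(unique(map$motives$motive))),
            class = "map_stats")
}

#' @export
print.map_stats <- function(x, ...) {
  cat(sprintf("%d nodes, %d links, average links per node %.1f, %d seeds in %d motives\n",
              x$n_nodes, x$n_edges, x$avg_links, x$n_seeds, x$n_motives))
  invisible(x)
}

#' Node overlap between two condition maps
#' @param map_a,map_b `condition_map` objects.
#' @return Integer size of the node-set intersection (symmetric).
#' @export
map_overlap <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "condition_map"), inherits(map_b, "condition_map"))
  length(intersect(map_a$nodes, map_b$nodes))
}
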