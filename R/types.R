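## Domain containers: signed interactome, seed sets, drug signatures,
## restriction ("truth") tables. All constructors validate invariants and
## canonicalize order so that loading is row-order insensitive.

#' Construct a signed interactome
#'
#' A directed protein graph with edge signs (+1 activating, -1 inhibiting)
#' and confidence weights in (0, 1].
#'
#' @param edges data.frame with columns `source`, `target`, `sign`, `weight`.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the edge endpoints. Extra isolated nodes are allowed.
#' @param directed Logical, kept for provenance (always TRUE here).
#' @return An object of class `interactome`.
#' @export
interactome <- function(edges = data.frame(source = character(0),
                                           target = character(0),
                                           sign = numeric(0),
                                           weight = numeric(0)),
                        nodes = NULL, directed = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "target", "sign", "weight")
  if (!all(need %in% names(edges)))
    ns_stop("interactome edges need columns: %s", paste(need, collapse = ", "))
  edges <- edges[need]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.numeric(edges$sign)
  edges$weight <- as.numeric(edges$weight)
  if (nrow(edges)) {
    if (any(edges$source == edges$target))
      ns_stop("self-loop edge(s) not allowed: %s",
              paste(unique(edges$source[edges$source == edges$target]), collapse = ", "))
    if (!all(edges$sign %in% c(-1, 1)))
      ns_stop("edge signs must be +1 or -1")
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0) || any(edges$weight > 1))
      ns_stop("edge weights must lie in (0, 1]")
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key))
      ns_stop("duplicate edge(s) after merge: %s",
              paste(unique(key[duplicated(key)]), collapse = ", "))
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d nodes, %d directed signed edges (%d inhibitory)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Construct a condition seed set
#'
#' Curated seed proteins grouped into functional motives, each with an
#' expected activation state for the condition. A protein may belong to more
#' than one motive but at most once per motive.
#'
#' @param condition Condition label, e.g. "degeneration".
#' @param entries data.frame with columns `protein`, `motive`,
#'   `expected_state` (+1 or -1).
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(condition, entries) {
  stopifnot(is.character(condition), length(condition) == 1L, nzchar(condition))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("protein", "motive", "expected_state")
  if (!all(need %in% names(entries)))
    ns_stop("seed set entries need columns: %s", paste(need, collapse = ", "))
  entries <- entries[need]
  entries$protein <- as.character(entries$protein)
  entries$motive <- as.character(entries$motive)
  entries$expected_state <- as.numeric(entries$expected_state)
  if (nrow(entries)) {
    if (any(!nzchar(trimws(entries$motive))))
      ns_stop("seed set '%s': blank motive label", condition)
    if (!all(entries$expected_state %in% c(-1, 1)))
      ns_stop("seed set '%s': expected_state must be +1 or -1", condition)
    key <- paste(entries$protein, entries$motive, sep = "\r")
    if (anyDuplicated(key))
      ns_stop("seed set '%s': protein listed twice in the same motive: %s",
              condition, entries$protein[duplicated(key)][1L])
    entries <- entries[order(entries$motive, entries$protein), , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(list(condition = condition, entries = entries), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set:%s> %d entries, %d proteins, %d motives\n",
              x$condition, nrow(x$entries), length(unique(x$entries$protein)),
              length(unique(x$entries$motive))))
  invisible(x)
}

#' Construct a drug signature
#'
#' A drug's target set with action signs (+1 agonist, -1 antagonist) and the
#' four curated eligibility flags used by the candidate filter.
#'
#' @param drug Drug identifier.
#' @param targets data.frame with columns `protein`, `action`; may be empty
#'   (a null drug is legal).
#' @param eligibility Named logical vector with entries `safe_profile`,
#'   `no_pain_liability`, `no_known_regen_effect`, `crosses_bbb`.
#' @return An object of class `drug_signature`.
#' @export
drug_signature <- function(drug, targets = data.frame(protein = character(0),
                                                      action = numeric(0)),
                           eligibility) {
  stopifnot(is.character(drug), length(drug) == 1L, nzchar(drug))
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  if (!all(c("protein", "action") %in% names(targets)))
    ns_stop("drug '%s': targets need columns protein, action", drug)
  targets <- targets[c("protein", "action")]
  targets$protein <- as.character(targets$protein)
  targets$action <- as.numeric(targets$action)
  if (nrow(targets)) {
    if (!all(targets$action %in% c(-1, 1)))
      ns_stop("drug '%s': actions must be +1 or -1", drug)
    if (anyDuplicated(targets$protein))
      ns_stop("drug '%s': duplicate target %s", drug,
              targets$protein[duplicated(targets$protein)][1L])
    targets <- targets[order(targets$protein), , drop = FALSE]
    rownames(targets) <- NULL
  }
  flags <- c("safe_profile", "no_pain_liability", "no_known_regen_effect",
             "crosses_bbb")
  if (!is.logical(eligibility) || !all(flags %in% names(eligibility)) ||
      anyNA(eligibility[flags]))
    ns_stop("drug '%s': eligibility must name all four flags (no defaults assumed)",
            drug)
  structure(list(drug = drug, targets = targets,
                 eligibility = eligibility[flags]),
            class = "drug_signature")
}

#' Construct a restriction ("truth") table
#'
#' Each row pairs a sparse input perturbation signature with the output node
#' states the trained model must reproduce within a per-row tolerance.
#'
#' @param rows A list; each element is `list(row_id=, input=, output=,
#'   tolerance=)` where `input` and `output` are named numeric vectors with
#'   values in [-1, 1].
#' @return An object of class `restriction_table`.
#' @export
restriction_table <- function(rows) {
  stopifnot(is.list(rows))
  ids <- vapply(rows, function(r) as.character(r$row_id), character(1))
  if (anyDuplicated(ids)) ns_stop("duplicate restriction row_id: %s",
                                  ids[duplicated(ids)][1L])
  rows <- lapply(rows, function(r) {
    r$row_id <- as.character(r$row_id)
    r$input <- unlist(r$input)
    r$output <- unlist(r$output)
    if (is.null(r$tolerance)) r$tolerance <- 0.5
    r$tolerance <- as.numeric(r$tolerance)
    if (length(r$output) == 0L)
      ns_stop("restriction row '%s' has no output entries", r$row_id)
    vals <- c(r$input, r$output)
    if (any(!is.finite(vals)) || any(abs(vals) > 1))
      ns_stop("restriction row '%s': values must lie in [-1, 1]", r$row_id)
    if (!is.finite(r$tolerance) || r$tolerance < 0)
      ns_stop("restriction row '%s': tolerance must be >= 0", r$row_id)
    r$input <- r$input[order(names(r$input))]
    r$output <- r$output[order(names(r$output))]
    r
  })
  rows <- rows[order(ids)]
  structure(list(rows = rows), class = "restriction_table")
}

#' @export
print.restriction_table <- function(x, ...) {
  n_out <- vapply(x$rows, function(r) length(r$output), 1L)
  cat(sprintf("<restriction_table> %d rows, %s output node(s)/row\n",
              length(x$rows),
              if (length(n_out)) paste(range(n_out), collapse = "-") else "0"))
  invisible(x)
}

#' Number of restriction rows
#' @param x A `restriction_table`.
#' @return Integer row count.
#' @export
n_restrictions <- function(x) {
  stopifnot(inherits(x, "restriction_table"))
  length(x$rows)
}
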