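## Reading and writing the pipeline's external tables. All files are UTF-8,
## tab-separated, with a mandatory header; lines starting with '#' are
## comments. Loaders canonicalize order so permuting input rows yields an
## identical in-memory object, and every writer round-trips through its
## reader to the printed precision.

#' Read a signed interactome edge table
#'
#' Supported dialects: `"edge"` (`source<TAB>target<TAB>sign<TAB>weight`,
#' sign tokens `+`, `-`, `+1`, `-1`) and `"sif"`
#' (`source<TAB>relation<TAB>target`), where relations map to signs through
#' `sign_lexicon` and edges get weight 1.
#'
#' Self-loop rows are dropped (counted in the log). Duplicate (source,
#' target) rows with equal sign merge by maximum weight; with opposite signs
#' the loader fails loudly rather than choosing a sign silently.
#'
#' @param path Path to the edge table.
#' @param dialect `"edge"` or `"sif"`.
#' @param sign_lexicon Named numeric vector (relation -> +1/-1), required for
#'   the sif dialect.
#' @return An [interactome].
#' @export
read_interactome <- function(path, dialect = c("edge", "sif"),
                             sign_lexicon = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "edge") {
    tab <- read_strict_tsv(path, c("source", "target", "sign", "weight"))
    ln <- attr(tab, "lineno")
    if (nrow(tab) == 0L) return(interactome())
    sign <- parse_sign_token(tab$sign, path, ln)
    weight <- parse_num(tab$weight, "weight", path, ln)
    ed <- data.frame(source = tab$source, target = tab$target,
                     sign = sign, weight = weight, stringsAsFactors = FALSE)
  } else {
    tab <- read_strict_tsv(path, c("source", "relation", "target"))
    ln <- attr(tab, "lineno")
    if (nrow(tab) == 0L) return(interactome())
    if (is.null(sign_lexicon))
      ns_stop("sif dialect needs a relation->sign lexicon")
    sgn <- unname(sign_lexicon[tab$relation])
    if (anyNA(sgn)) {
      i <- which(is.na(sgn))[1L]
      ns_stop("%s: relation '%s' not in sign lexicon (line %d)", path,
              tab$relation[i], ln[i])
    }
    ed <- data.frame(source = tab$source, target = tab$target,
                     sign = as.numeric(sgn), weight = 1, stringsAsFactors = FALSE)
  }
  loops <- ed$source == ed$target
  if (any(loops)) {
    ns_log("read_interactome: dropped %d self-loop row(s)", sum(loops))
    ed <- ed[!loops, , drop = FALSE]
  }
  key <- paste(ed$source, ed$target, sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0L) {
    conf <- tapply(ed$sign, key, function(s) length(unique(s)) > 1L)
    if (any(conf))
      ns_stop("%s: duplicate edge with conflicting signs: %s", path,
              gsub("\r", " -> ", names(conf)[conf][1L]))
    agg <- do.call(rbind, lapply(split(ed, key), function(d)
      d[which.max(d$weight), , drop = FALSE]))
    ns_log("read_interactome: merged %d duplicate row(s) by max weight", n_dup)
    ed <- agg
  }
  interactome(ed)
}

#' Write an interactome edge table
#' @param net An [interactome].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interactome <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  ed <- net$edges
  rows <- if (nrow(ed)) sprintf("%s\t%s\t%s\t%s", ed$source, ed$target,
                                ifelse(ed$sign > 0, "+1", "-1"),
                                fmt_num(ed$weight)) else character(0)
  write_tsv_lines(c("source", "target", "sign", "weight"), rows, path)
}

#' Read condition seed sets
#'
#' Layout: `condition<TAB>protein<TAB>motive<TAB>expected_state`. Returns one
#' [seed_set] per condition label present. The same protein may appear under
#' several motives; a duplicate (condition, protein, motive) row is an error.
#'
#' @param path Path to the seed table.
#' @return Named list of [seed_set] objects, keyed by condition.
#' @export
read_seed_sets <- function(path) {
  tab <- read_strict_tsv(path, c("condition", "protein", "motive",
                                 "expected_state"))
  ln <- attr(tab, "lineno")
  if (nrow(tab) == 0L) return(list())
  blank <- !nzchar(tab$motive)
  if (any(blank))
    ns_stop("%s: blank motive label (line %d)", path, ln[blank][1L])
  state <- parse_sign_token(tab$expected_state, path, ln)
  out <- lapply(split(seq_len(nrow(tab)), tab$condition), function(idx)
    seed_set(tab$condition[idx[1L]],
             data.frame(protein = tab$protein[idx], motive = tab$motive[idx],
                        expected_state = state[idx], stringsAsFactors = FALSE)))
  out[sort(names(out))]
}

#' Write condition seed sets
#' @param seed_sets List of [seed_set] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_seed_sets <- function(seed_sets, path) {
  rows <- unlist(lapply(seed_sets, function(ss) {
    e <- ss$entries
    if (!nrow(e)) return(character(0))
    sprintf("%s\t%s\t%s\t%s", ss$condition, e$protein, e$motive,
            ifelse(e$expected_state > 0, "+1", "-1"))
  }), use.names = FALSE)
  write_tsv_lines(c("condition", "protein", "motive", "expected_state"),
                  rows, path)
}

#' Read a drug library (targets plus eligibility metadata)
#'
#' `targets_path` holds `drug<TAB>target<TAB>action`; `metadata_path` holds
#' `drug<TAB>safe_profile<TAB>no_pain_liability<TAB>no_known_regen_effect<TAB>crosses_bbb`.
#' Every drug must have a metadata row (no eligibility defaults are assumed);
#' a drug with metadata but no target rows yields an empty-target signature.
#'
#' @param targets_path Path to the target table.
#' @param metadata_path Path to the eligibility table.
#' @return Named list of [drug_signature] objects.
#' @export
read_drug_library <- function(targets_path, metadata_path) {
  tg <- read_strict_tsv(targets_path, c("drug", "target", "action"))
  ln_t <- attr(tg, "lineno")
  md <- read_strict_tsv(metadata_path,
                        c("drug", "safe_profile", "no_pain_liability",
                          "no_known_regen_effect", "crosses_bbb"))
  ln_m <- attr(md, "lineno")
  if (anyDuplicated(md$drug))
    ns_stop("%s: duplicate metadata row for drug %s", metadata_path,
            md$drug[duplicated(md$drug)][1L])
  action <- if (nrow(tg)) parse_sign_token(tg$action, targets_path, ln_t)
            else numeric(0)
  flags <- c("safe_profile", "no_pain_liability", "no_known_regen_effect",
             "crosses_bbb")
  fl <- lapply(flags, function(f) parse_flag(md[[f]], f, metadata_path, ln_m))
  names(fl) <- flags
  missing_md <- setdiff(unique(tg$drug), md$drug)
  if (length(missing_md))
    ns_stop("%s: no metadata row for drug %s (eligibility flags are mandatory)",
            metadata_path, missing_md[1L])
  lib <- lapply(seq_len(nrow(md)), function(i) {
    idx <- which(tg$drug == md$drug[i])
    drug_signature(md$drug[i],
                   data.frame(protein = tg$target[idx], action = action[idx],
                              stringsAsFactors = FALSE),
                   setNames(vapply(flags, function(f) fl[[f]][i], TRUE), flags))
  })
  names(lib) <- md$drug
  lib[sort(names(lib))]
}

#' Write a drug library
#' @param library Named list of [drug_signature] objects.
#' @param targets_path,metadata_path Output paths for the two tables.
#' @return Invisibly, `targets_path`.
#' @export
write_drug_library <- function(library, targets_path, metadata_path) {
  library <- library[order(vapply(library, `[[`, "", "drug"))]
  t_rows <- unlist(lapply(library, function(d) {
    if (!nrow(d$targets)) return(character(0))
    sprintf("%s\t%s\t%s", d$drug, d$targets$protein,
            ifelse(d$targets$action > 0, "+1", "-1"))
  }), use.names = FALSE)
  m_rows <- vapply(library, function(d)
    paste(c(d$drug, ifelse(d$eligibility, "TRUE", "FALSE")), collapse = "\t"),
    character(1))
  write_tsv_lines(c("drug", "target", "action"), t_rows, targets_path)
  write_tsv_lines(c("drug", "safe_profile", "no_pain_liability",
                    "no_known_regen_effect", "crosses_bbb"),
                  unname(m_rows), metadata_path)
}

#' Read a restriction table (long format)
#'
#' Layout: `row_id<TAB>side(in|out)<TAB>protein<TAB>value<TAB>tolerance`.
#' Tolerance must be identical across the lines of one row.
#'
#' @param path Path to the restriction table.
#' @return A [restriction_table].
#' @export
read_restrictions <- function(path) {
  tab <- read_strict_tsv(path, c("row_id", "side", "protein", "value",
                                 "tolerance"))
  ln <- attr(tab, "lineno")
  if (nrow(tab) == 0L) return(restriction_table(list()))
  bad <- !tab$side %in% c("in", "out")
  if (any(bad))
    ns_stop("%s: side must be 'in' or 'out' (line %d)", path, ln[bad][1L])
  val <- parse_num(tab$value, "value", path, ln)
  tol <- parse_num(tab$tolerance, "tolerance", path, ln)
  rows <- lapply(split(seq_len(nrow(tab)), tab$row_id), function(idx) {
    if (length(unique(tol[idx])) != 1L)
      ns_stop("%s: row '%s' has inconsistent tolerances", path,
              tab$row_id[idx[1L]])
    is_in <- tab$side[idx] == "in"
    list(row_id = tab$row_id[idx[1L]],
         input = setNames(val[idx][is_in], tab$protein[idx][is_in]),
         output = setNames(val[idx][!is_in], tab$protein[idx][!is_in]),
         tolerance = tol[idx][1L])
  })
  restriction_table(unname(rows))
}

#' Write a restriction table (long format)
#' @param rt A [restriction_table].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_restrictions <- function(rt, path) {
  stopifnot(inherits(rt, "restriction_table"))
  rows <- unlist(lapply(rt$rows, function(r) {
    c(if (length(r$input))
        sprintf("%s\tin\t%s\t%s\t%s", r$row_id, names(r$input),
                fmt_num(unname(r$input)), fmt_num(r$tolerance)),
      sprintf("%s\tout\t%s\t%s\t%s", r$row_id, names(r$output),
              fmt_num(unname(r$output)), fmt_num(r$tolerance)))
  }), use.names = FALSE)
  write_tsv_lines(c("row_id", "side", "protein", "value", "tolerance"),
                  rows, path)
}

#' Read phenotype signatures
#'
#' Layout: `label<TAB>protein<TAB>desired<TAB>weight`; returns one
#' [phenotype_signature] per label.
#'
#' @param path Path to the signature table.
#' @return Named list of [phenotype_signature] objects.
#' @export
read_signatures <- function(path) {
  tab <- read_strict_tsv(path, c("label", "protein", "desired", "weight"))
  ln <- attr(tab, "lineno")
  if (nrow(tab) == 0L) return(list())
  des <- parse_num(tab$desired, "desired", path, ln)
  w <- parse_num(tab$weight, "weight", path, ln)
  out <- lapply(split(seq_len(nrow(tab)), tab$label), function(idx)
    phenotype_signature(tab$label[idx[1L]], tab$protein[idx],
                        des[idx], w[idx]))
  out[sort(names(out))]
}

#' Write phenotype signatures
#' @param signatures List of [phenotype_signature] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signatures <- function(signatures, path) {
  rows <- unlist(lapply(signatures, function(s)
    sprintf("%s\t%s\t%s\t%s", s$label, names(s$desired),
            fmt_num(unname(s$desired)), fmt_num(unname(s$weight)))),
    use.names = FALSE)
  write_tsv_lines(c("label", "protein", "desired", "weight"), rows, path)
}

#' Write ranked combination scores
#'
#' Applies the screening module's deterministic ranking (efficacy
#' descending, adverse ascending, synergy descending, then canonical drug
#' ids) and writes the columns `drug_a, drug_b, efficacy_pct, adverse_pct,
#' synergy_pts, eligible, pass_tier, top_tier`. Percentages are printed at
#' fixed 6-decimal precision, and the written file re-reads to those values.
#'
#' @param scores data.frame of annotated pair scores (see
#'   [filter_candidates]); an empty data.frame writes a header-only file.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranked_combinations <- function(scores, path) {
  cols <- c("drug_a", "drug_b", "efficacy_pct", "adverse_pct", "synergy_pts",
            "eligible", "pass_tier", "top_tier")
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  for (cc in c("eligible", "pass_tier", "top_tier"))
    if (is.null(scores[[cc]])) scores[[cc]] <- logical(nrow(scores))
  if (!all(cols %in% names(scores)) && nrow(scores))
    ns_stop("scores must carry columns: %s", paste(cols, collapse = ", "))
  if (nrow(scores)) {
    scores <- rank_combinations(scores)
    rows <- sprintf("%s\t%s\t%.6f\t%.6f\t%.6f\t%s\t%s\t%s",
                    scores$drug_a, scores$drug_b, scores$efficacy_pct,
                    scores$adverse_pct, scores$synergy_pts,
                    scores$eligible, scores$pass_tier, scores$top_tier)
  } else rows <- character(0)
  dir <- dirname(path)
  if (!dir.exists(dir)) ns_stop("cannot write to %s: directory missing", path)
  write_tsv_lines(cols, rows, path)
}

#' Read ranked combination scores
#' @param path Path written by [write_ranked_combinations].
#' @return data.frame of pair scores.
#' @export
read_ranked_combinations <- function(path) {
  cols <- c("drug_a", "drug_b", "efficacy_pct", "adverse_pct", "synergy_pts",
            "eligible", "pass_tier", "top_tier")
  tab <- read_strict_tsv(path, cols)
  ln <- attr(tab, "lineno")
  for (cc in c("efficacy_pct", "adverse_pct", "synergy_pts"))
    tab[[cc]] <- parse_num(tab[[cc]], cc, path, ln)
  for (cc in c("eligible", "pass_tier", "top_tier"))
    tab[[cc]] <- parse_flag(tab[[cc]], cc, path, ln)
  attr(tab, "lineno") <- NULL
  tab
}

#' Save a propagation model checkpoint
#'
#' Flat parameter table (`kind<TAB>name<TAB>sign<TAB>weight<TAB>value`) with
#' hyperparameters in `#!`-prefixed header lines. Numbers are printed with 17
#' significant digits so the reload is bit-exact.
#'
#' @param model A [propagation_model].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "propagation_model"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#! condition\t%s", model$condition),
               sprintf("#! activation\t%s", model$activation),
               sprintf("#! alpha\t%s", fmt_num(model$alpha, 17)),
               sprintf("#! eps\t%s", fmt_num(model$eps, 17)),
               sprintf("#! max_iter\t%d", model$max_iter)), con)
  writeLines("kind\tname\tsign\tweight\tvalue", con)
  e <- model$edges
  if (nrow(e))
    writeLines(sprintf("edge\t%s->%s\t%s\t%s\t%s", e$source, e$target,
                       ifelse(e$sign > 0, "+1", "-1"), fmt_num(e$weight, 17),
                       fmt_num(model$strengths, 17)), con)
  writeLines(sprintf("node\t%s\tNA\tNA\t%s", model$nodes,
                     fmt_num(model$bias, 17)), con)
  invisible(path)
}

#' Load a propagation model checkpoint
#' @param path Path written by [write_model_checkpoint].
#' @return A [propagation_model].
#' @export
read_model_checkpoint <- function(path) {
  if (!file.exists(path)) ns_stop("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#!", lines)]
  kv <- do.call(rbind, strsplit(sub("^#!\\s*", "", hdr), "\t", fixed = TRUE))
  hy <- setNames(kv[, 2], kv[, 1])
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(lines[!grepl("^#", lines)], tmp)
  tab <- read_strict_tsv(tmp, c("kind", "name", "sign", "weight", "value"))
  en <- tab[tab$kind == "edge", , drop = FALSE]
  nd <- tab[tab$kind == "node", , drop = FALSE]
  parts <- strsplit(en$name, "->", fixed = TRUE)
  edges <- data.frame(source = vapply(parts, `[`, "", 1L),
                      target = vapply(parts, `[`, "", 2L),
                      sign = if (nrow(en)) parse_sign_token(en$sign, path)
                             else numeric(0),
                      weight = parse_num(en$weight, "weight", path),
                      stringsAsFactors = FALSE)
  cm <- condition_map_from_parts(condition = unname(hy[["condition"]]),
                                 nodes = nd$name, edges = edges)
  model <- new_propagation_model(cm,
                                 strengths = parse_num(en$value, "strength", path),
                                 bias = parse_num(nd$value, "bias", path),
                                 alpha = as.numeric(hy[["alpha"]]),
                                 eps = as.numeric(hy[["eps"]]),
                                 max_iter = as.integer(hy[["max_iter"]]),
                                 activation = unname(hy[["activation"]]))
  model
}
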