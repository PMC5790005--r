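## End-to-end orchestration: synth -> build-maps -> train -> screen ->
## filter -> moa, driven by one strict-schema config, with per-stage seeds
## derived from the global seed, a manifest recording hashes and seeds, and
## byte-deterministic outputs (fixed float formatting throughout).

default_run_config <- function() {
  list(run_dir = "netscreen_run",
       seed = 1L,
       force = FALSE,
       scenario = list(),
       expansion = list(method = "k_hop", k = 1, min_weight = 0,
                        keep_largest_component = TRUE),
       model = list(),
       optimizer = list(),
       thresholds = default_thresholds(),
       screen = list(dose = 1),
       moa = list(top_k = 10L))
}

merge_strict <- function(defaults, override, where = "config") {
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    ns_stop("unknown %s key(s): %s", where, paste(bad, collapse = ", "))
  for (k in names(override)) {
    if (is.list(defaults[[k]]) && is.list(override[[k]]) &&
        !is.null(names(defaults[[k]])) && k != "scenario")
      defaults[[k]] <- merge_strict(defaults[[k]], override[[k]],
                                    paste0(where, "$", k))
    else defaults[[k]] <- override[[k]]
  }
  defaults
}

stage_files <- list(
  synth = c("interactome.tsv", "seeds.tsv", "restrictions.tsv",
            "drug_targets.tsv", "drug_metadata.tsv", "signatures.tsv",
            "ground_truth.yaml"),
  maps = c("map_degeneration_nodes.tsv", "map_protection_nodes.tsv",
           "map_stats.tsv"),
  train = c("model_checkpoint.tsv", "fit_report.json"),
  screen = c("ranked.tsv", "singles.tsv"),
  filter = c("passing.tsv", "top.tsv"),
  moa = c("moa.tsv"))

#' Run the full in-silico screening pipeline
#'
#' Executes synth, build-maps, train, screen, filter and moa in order inside
#' `config$run_dir`. Stages whose outputs already exist are skipped unless
#' `config$force` is TRUE; a `manifest.json` records the effective config,
#' per-stage derived seeds, input md5 hashes and output files. Identical
#' config and seed produce byte-identical outputs.
#'
#' @param config A named list (strict schema: unknown keys are an error) or
#'   the path to a YAML file holding one. Keys: `run_dir`, `seed`, `force`,
#'   `scenario`, `expansion`, `model`, `optimizer`, `thresholds`, `screen`,
#'   `moa`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_strict(default_run_config(), config)
  run_dir <- cfg$run_dir
  if (!dir.exists(run_dir)) dir.create(run_dir, recursive = TRUE)
  p <- function(f) file.path(run_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("netscreen")),
                   seed = cfg$seed, config = cfg, stages = list())
  stage_done <- function(stage)
    all(file.exists(vapply(stage_files[[stage]], p, "")))
  run_stage <- function(stage, fun) {
    if (!cfg$force && stage_done(stage)) {
      ns_log("stage %s: outputs exist, skipped (use force to rerun)", stage)
      manifest$stages[[stage]] <<- list(status = "reused",
                                        files = stage_files[[stage]])
      return(invisible(NULL))
    }
    seed <- derive_seed(cfg$seed, stage)
    ok <- tryCatch({ fun(seed); TRUE },
                   error = function(e) {
                     ns_stop("pipeline stage '%s' failed: %s", stage,
                             conditionMessage(e))
                   })
    manifest$stages[[stage]] <<- list(status = "run", seed = seed,
                                      files = stage_files[[stage]])
    invisible(NULL)
  }

  run_stage("synth", function(seed) {
    sc <- do.call(scenario, c(list(seed = seed), cfg$scenario))
    generate_scenario_data(sc, outdir = run_dir)
  })

  run_stage("maps", function(seed) {
    net <- read_interactome(p("interactome.tsv"))
    seeds <- read_seed_sets(p("seeds.tsv"))
    maps <- lapply(seeds, function(ss) expand_map(net, ss, cfg$expansion))
    for (cond in names(maps))
      write_tsv_lines(c("protein", "is_seed"),
                      sprintf("%s\t%s", maps[[cond]]$nodes,
                              maps[[cond]]$nodes %in% maps[[cond]]$seeds),
                      p(sprintf("map_%s_nodes.tsv", cond)))
    st <- lapply(maps, map_stats)
    write_tsv_lines(c("condition", "n_nodes", "n_edges", "avg_links",
                      "n_seeds", "n_motives", "overlap"),
                    vapply(names(st), function(cond)
                      sprintf("%s\t%d\t%d\t%.6f\t%d\t%d\t%d", cond,
                              st[[cond]]$n_nodes, st[[cond]]$n_edges,
                              st[[cond]]$avg_links, st[[cond]]$n_seeds,
                              st[[cond]]$n_motives,
                              map_overlap(maps[[1L]], maps[[2L]])),
                      character(1)),
                    p("map_stats.tsv"))
  })

  run_stage("train", function(seed) {
    net <- read_interactome(p("interactome.tsv"))
    seeds <- read_seed_sets(p("seeds.tsv"))
    map_deg <- expand_map(net, seeds$degeneration, cfg$expansion)
    rt <- read_restrictions(p("restrictions.tsv"))
    model <- build_model(map_deg, cfg$model, seed = seed)
    fit <- train(model, rt, optimizer_params = cfg$optimizer, seed = seed)
    write_model_checkpoint(fit$model, p("model_checkpoint.tsv"))
    rep <- fit$report
    jsonlite::write_json(list(satisfaction = rep$satisfaction,
                              satisfaction_initial = rep$satisfaction_initial,
                              objective = rep$objective,
                              objective_initial = rep$objective_initial,
                              n_steps = rep$n_steps, seed = rep$seed),
                         p("fit_report.json"), auto_unbox = TRUE, digits = NA)
  })

  run_stage("screen", function(seed) {
    model <- read_model_checkpoint(p("model_checkpoint.tsv"))
    lib <- read_drug_library(p("drug_targets.tsv"), p("drug_metadata.tsv"))
    sigs <- read_signatures(p("signatures.tsv"))
    res <- screen_combinations(model, lib, sigs, cfg$screen)
    flt <- filter_candidates(res, library_metadata(lib), cfg$thresholds)
    write_ranked_combinations(flt$annotated, p("ranked.tsv"))
    write_tsv_lines(c("drug", "efficacy_pct", "adverse_pct", "coverage"),
                    sprintf("%s\t%.6f\t%.6f\t%.6f", res$singles$drug,
                            res$singles$efficacy_pct, res$singles$adverse_pct,
                            res$singles$coverage),
                    p("singles.tsv"))
  })

  run_stage("filter", function(seed) {
    ranked <- read_ranked_combinations(p("ranked.tsv"))
    write_ranked_combinations(ranked[ranked$pass_tier, , drop = FALSE],
                              p("passing.tsv"))
    write_ranked_combinations(ranked[ranked$top_tier, , drop = FALSE],
                              p("top.tsv"))
  })

  run_stage("moa", function(seed) {
    ranked <- read_ranked_combinations(p("passing.tsv"))
    if (nrow(ranked) == 0L) {
      write_tsv_lines(c("node", "contribution", "state_pair", "state_a",
                        "state_b", "is_readout"), character(0), p("moa.tsv"))
      return(invisible(NULL))
    }
    model <- read_model_checkpoint(p("model_checkpoint.tsv"))
    lib <- read_drug_library(p("drug_targets.tsv"), p("drug_metadata.tsv"))
    sigs <- read_signatures(p("signatures.tsv"))
    top_pair <- list(lib[[ranked$drug_a[1L]]], lib[[ranked$drug_b[1L]]])
    moa <- extract_moa(model, top_pair, sigs$protection,
                       top_k = cfg$moa$top_k, dose = cfg$screen$dose)
    write_tsv_lines(c("node", "contribution", "state_pair", "state_a",
                      "state_b", "is_readout"),
                    sprintf("%s\t%.6f\t%.6f\t%.6f\t%.6f\t%s", moa$node,
                            moa$contribution, moa$state_pair, moa$state_a,
                            moa$state_b, moa$is_readout),
                    p("moa.tsv"))
  })

  all_files <- unlist(stage_files, use.names = FALSE)
  present <- all_files[file.exists(vapply(all_files, p, ""))]
  manifest$hashes <- as.list(tools::md5sum(vapply(present, p, "")))
  names(manifest$hashes) <- present
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Prints map statistics (node counts, average links per node, overlap),
#' the fit report, screen counts (drugs, pairs = n(n-1)/2) and pass/top
#' counts. Identical across re-invocations on the same run directory.
#'
#' @param run_dir Directory written by [run_pipeline].
#' @return Invisibly, the summary as a character vector.
#' @export
report_summary <- function(run_dir) {
  mp <- file.path(run_dir, "manifest.json")
  if (!file.exists(mp)) ns_stop("missing manifest: %s (incomplete run?)", mp)
  manifest <- jsonlite::read_json(mp)
  p <- function(f) file.path(run_dir, f)
  stats <- read_strict_tsv(p("map_stats.tsv"),
                           c("condition", "n_nodes", "n_edges", "avg_links",
                             "n_seeds", "n_motives", "overlap"))
  fit <- jsonlite::read_json(p("fit_report.json"))
  singles <- read_strict_tsv(p("singles.tsv"),
                             c("drug", "efficacy_pct", "adverse_pct",
                               "coverage"))
  ranked <- read_ranked_combinations(p("ranked.tsv"))
  n_drugs <- nrow(singles)
  lines <- c(
    sprintf("netscreen run %s (seed %s)", run_dir, manifest$seed),
    vapply(seq_len(nrow(stats)), function(i)
      sprintf("  map %-12s %s nodes, avg links/node %.1f (%s seeds)",
              stats$condition[i], stats$n_nodes[i],
              as.numeric(stats$avg_links[i]), stats$n_seeds[i]), ""),
    sprintf("  map overlap    %s proteins", stats$overlap[1L]),
    sprintf("  truth-table fit: satisfaction %.3f (initial %.3f), objective %.4g",
            fit$satisfaction, fit$satisfaction_initial, fit$objective),
    sprintf("  screen: %d drugs -> %d binary combinations", n_drugs,
            as.integer(n_pair_count(n_drugs))),
    sprintf("  candidates: %d pass tier, %d top tier", sum(ranked$pass_tier),
            sum(ranked$top_tier)))
  if (sum(ranked$pass_tier) > 0) {
    best <- ranked[ranked$pass_tier, ][1L, ]
    lines <- c(lines,
               sprintf("  best candidate: %s + %s (efficacy %.1f%%, adverse %.1f%%, synergy %.1f pts)",
                       best$drug_a, best$drug_b, best$efficacy_pct,
                       best$adverse_pct, best$synergy_pts))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
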