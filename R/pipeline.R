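#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Accepts a
#' YAML file path or a nested list with blocks:
#'
#' * `generator` — fields for [generator_config()] (the synthetic study
#'   conditions);
#' * `aop` — `alpha`, `mode`;
#' * `threshold` — `rule` (`max_f1` or `precision_floor`), optional
#'   `precision_floor`;
#' * top level — `seed`, `specialty`, `labels` (`auto_review` or
#'   `ground_truth`), `suppress` (small-cell masking toggle), `test_year`,
#'   `out_dir`.
#'
#' The seed is propagated to every stochastic stage: the training corpus
#' uses `seed`, the test corpus `seed + 1`.
#'
#' @param config YAML path or list; omitted fields take defaults.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 20170101L,
    specialty = "20",
    labels = "auto_review",
    suppress = TRUE,
    test_year = 2020L,
    out_dir = "lateraleye-results",
    generator = list(),
    aop = list(alpha = 1, mode = "confidence"),
    threshold = list(rule = "max_f1", precision_floor = NULL)
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$labels %in% c("auto_review", "ground_truth")) {
    abort("labels must be 'auto_review' or 'ground_truth'", class = "lateraleye_config_error")
  }
  if (!cfg$threshold$rule %in% c("max_f1", "precision_floor")) {
    abort("threshold rule must be 'max_f1' or 'precision_floor'",
      class = "lateraleye_config_error"
    )
  }
  gen_args <- cfg$generator
  gen_args$seed <- gen_args$seed %||% cfg$seed
  cfg$generator <- do.call(generator_config, gen_args)
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulate (train + test corpora over one shared code
#' universe) -> study-population filter -> association training ->
#' precision-recall threshold selection on the discordant subgroups ->
#' scoring -> method comparison, writing all artifacts and a reproducibility
#' manifest to `out_dir`:
#'
#' `train_claims.csv`, `test_claims.csv`, `code_map.csv`,
#' `code_relations.csv`, `model.json`, `threshold.json`, `scores.csv`,
#' `subgroups.csv`, `selection_flow.json`, `comparison_report.csv`,
#' `summary.txt`, `pr_points.csv`, `manifest.json`.
#'
#' Outputs are deterministic given the config (the manifest records input
#' digests so any run can be reproduced byte-for-byte). On failure a
#' `FAILED` marker naming the stage is left in `out_dir` and the error is
#' re-raised.
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @return Invisibly, a list with the output paths, the selected threshold,
#'   and the comparison report.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  stage <- "setup"
  result <- tryCatch(
    {
      stage <- "simulate"
      universe <- build_code_universe(cfg$generator)
      train <- simulate_claims(cfg$generator,
        map = universe,
        seed = cfg$seed, id_prefix = "TR"
      )
      test <- simulate_claims(cfg$generator,
        map = universe,
        seed = cfg$seed + 1L, years = cfg$test_year, id_prefix = "TE"
      )
      write_claims(train, file.path(out, "train_claims.csv"))
      write_claims(test, file.path(out, "test_claims.csv"))
      readr::write_csv(universe$entries, file.path(out, "code_map.csv"), progress = FALSE)
      readr::write_csv(universe$relations, file.path(out, "code_relations.csv"),
        progress = FALSE
      )
      inform(sprintf(
        "simulate: %d training claims, %d test claims", nrow(train), nrow(test)
      ))

      stage <- "filter"
      population <- filter_study_population(test, universe, specialty = cfg$specialty)
      flow <- attr(population, "selection_flow")
      jsonlite::write_json(flow, file.path(out, "selection_flow.json"),
        auto_unbox = TRUE, digits = NA
      )
      subgroup <- assign_subgroup(population, universe)
      readr::write_csv(
        tibble(claim_id = population$claim_id, subgroup = as.character(subgroup)),
        file.path(out, "subgroups.csv"),
        progress = FALSE
      )
      inform(sprintf(
        "filter: %d of %d test claims retained (%d LR, %d RL)",
        nrow(population), nrow(test), sum(subgroup == "LR"), sum(subgroup == "RL")
      ))

      stage <- "train"
      model <- train_associations(train, universe,
        alpha = cfg$aop$alpha, mode = cfg$aop$mode
      )
      write_association_table(model, file.path(out, "model.json"))

      stage <- "threshold"
      discordant <- population[subgroup %in% c("LR", "RL"), , drop = FALSE]
      labels <- if (cfg$labels == "auto_review") {
        auto_review(discordant, universe)$is_error
      } else {
        claim_truth_field(discordant, "is_error", NA)
      }
      scored <- score_claims(discordant, model)
      pr <- precision_recall_points(scored$claim_score, labels)
      threshold <- select_threshold(
        pr,
        rule = cfg$threshold$rule,
        precision_floor = cfg$threshold$precision_floor
      )
      jsonlite::write_json(
        unclass(threshold), file.path(out, "threshold.json"),
        auto_unbox = TRUE, digits = NA
      )
      inform(sprintf(
        "threshold: %.4g (%s; precision %.3f, recall %.3f)",
        threshold$value, threshold$selection_rule, threshold$precision, threshold$recall
      ))

      stage <- "score"
      scored$flagged <- scored$claim_score < threshold$value
      readr::write_csv(
        scored[, c("claim_id", "claim_score", "flagged")],
        file.path(out, "scores.csv"),
        progress = FALSE
      )

      stage <- "evaluate"
      report <- compare_methods(population, universe, model, threshold,
        labels = cfg$labels
      )
      report$pr_points <- pr
      if (isTRUE(cfg$suppress)) report <- suppress_small_cells(report)
      render_report(report, out)

      stage <- "manifest"
      files <- sort(setdiff(list.files(out), c("manifest.json", "FAILED")))
      manifest <- list(
        package_version = as.character(utils::packageVersion("lateraleye")),
        seed = cfg$seed,
        specialty = cfg$specialty,
        labels = cfg$labels,
        threshold = unclass(threshold),
        generator = unclass(cfg$generator),
        digests = as.list(setNames(
          unname(tools::md5sum(file.path(out, files))), files
        ))
      )
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
        auto_unbox = TRUE, digits = NA, null = "null"
      )
      list(
        out_dir = out, threshold = threshold, report = report,
        selection_flow = flow, manifest = manifest
      )
    },
    error = function(e) {
      writeLines(
        sprintf("stage: %s\n%s", stage, conditionMessage(e)),
        file.path(out, "FAILED")
      )
      abort(
        sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
        class = "lateraleye_pipeline_error", parent = e
      )
    }
  )
  invisible(result)
}
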