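#' Default pipeline configuration
#'
#' Settings that emulate the source cohort end to end: simulate at the
#' calibrated defaults, screen all baseline covariates at 0.05, backward
#' Wald elimination forcing age and surgical status, logit-scale optimal 1:1
#' matching, and delta-method mediation adjusted for the propensity score.
#'
#' @param n simulated cohort size.
#' @param seed master seed.
#' @param output_dir artifact directory.
#' @return a nested config list; serialize with [yaml::write_yaml()].
#' @export
default_config <- function(n = 734, seed = 1L, output_dir = "rilmed-out") {
  list(
    input = list(simulate = list(n = n)),
    screening = list(candidates = default_candidates(), alpha = 0.05),
    propensity = list(forced = c("age", "surgery"), criterion = "wald",
                      distance_scale = "logit"),
    mediation = list(interaction = FALSE, ci_method = "delta", boot_reps = 500),
    subgroup = list(strata = "surgery", min_events = 10),
    output_dir = output_dir,
    seed = as.integer(seed)
  )
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_config(), config)
  if (!is.null(config$input)) cfg$input <- config$input
  has_csv <- !is.null(cfg$input$csv)
  has_sim <- !is.null(cfg$input$simulate)
  if (has_csv == has_sim) abort("config must name exactly one input source (csv or simulate)")
  cfg
}

write_tsv_out <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

mediation_as_list <- function(res) {
  list(effects = res$effects, pm = res$pm, pm_valid = res$pm_valid,
       pm_reason = res$pm_reason, median_diff = res$median_diff,
       reference_hazard = res$reference_hazard,
       reference_median = res$reference_median,
       mediator_model = tidy(res$mediator_fit),
       outcome_model = tidy(res$outcome_fit),
       n = res$n, n_events = res$n_events,
       config = res$config[c("a", "astar", "interaction", "ci_method", "seed")])
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> summarise -> screen -> propensity model -> optimal
#' match -> balance -> group comparisons (odds-ratio table, hazard-ratio
#' table, Kaplan-Meier step functions, log-rank tests) -> mediation ->
#' surgical-subgroup mediation, writing every artifact plus a deterministic
#' manifest (seed, config hash, per-file checksums) under `output_dir`.
#' Identical config + seed reproduce byte-identical artifacts.
#'
#' @param config a config list or path to a YAML config (see
#'   [default_config()]).
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) a list with the cohort, matched cohort, `ps_model`,
#'   pairs, mediation result, subgroup table, and the manifest.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  cfg <- read_config(config)
  seed <- cfg$seed
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  files <- character(0)
  say <- function(stage, fmt, ...) {
    if (!quiet) inform(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- "input"
  res <- tryCatch({
    cohort <- if (!is.null(cfg$input$csv)) {
      read_cohort(cfg$input$csv, quiet = quiet)
    } else {
      sim <- cfg$input$simulate
      params <- if (!is.null(sim$params)) params_from_yaml(sim$params)
                else default_paper_params(n = sim$n %||% 734)
      simulate_cohort(params, seed = seed)
    }
    say(stage, "cohort of %d patients, %d events", nrow(cohort), sum(cohort$event))
    files <- c(files, write_tsv_out(cohort, out("cohort.tsv")))

    stage <- "summary"
    files <- c(files, write_tsv_out(summarize_cohort(cohort), out("cohort_summary.tsv")))

    stage <- "screening"
    screen <- univariate_screen(cohort, cfg$screening$candidates,
                                alpha = cfg$screening$alpha)
    say(stage, "%d/%d covariates flagged", sum(screen$flagged), nrow(screen))
    files <- c(files, write_tsv_out(screen, out("screen.tsv")))

    stage <- "propensity"
    ps <- fit_ps_model(cohort, cfg$screening$candidates,
                       forced = cfg$propensity$forced,
                       criterion = cfg$propensity$criterion)
    pairs <- optimal_match(ps, cohort, distance_scale = cfg$propensity$distance_scale,
                           caliper = cfg$propensity$caliper)
    matched <- matched_cohort(cohort, pairs)
    say(stage, "retained %s; %d matched pairs, total distance %.4f",
        paste(ps$selected, collapse = "+"), nrow(pairs),
        attr(pairs, "total_distance"))
    files <- c(files, write_tsv_out(pairs, out("matched_pairs.tsv")))
    files <- c(files, write_tsv_out(match_diagnostics(cohort, pairs), out("balance.tsv")))
    files <- c(files, write_tsv_out(summarize_cohort(matched), out("matched_summary.tsv")))

    stage <- "comparison"
    ps_m <- ps$scores[match(matched$id, cohort$id)]
    matched$ps <- ps_m
    or_tab <- dplyr::bind_rows(
      dplyr::mutate(fit_table(fit_logistic(matched, g4ril ~ modality)),
                    model = "univariable"),
      dplyr::mutate(fit_table(fit_logistic(matched, g4ril ~ modality + ps)),
                    model = "ps-adjusted"))
    hr_tab <- dplyr::bind_rows(
      dplyr::mutate(fit_table(fit_cox(matched, survival::Surv(os_months, event) ~ modality)),
                    model = "univariable"),
      dplyr::mutate(fit_table(fit_cox(matched, survival::Surv(os_months, event) ~ modality + ps)),
                    model = "ps-adjusted"))
    files <- c(files, write_tsv_out(or_tab, out("g4ril_or_table.tsv")))
    files <- c(files, write_tsv_out(hr_tab, out("os_hr_table.tsv")))
    km1 <- km_estimate(matched, group = "modality")
    matched$arm_mediator <- paste0("mod", matched$modality, "_g4ril", matched$g4ril)
    km2 <- km_estimate(matched, group = "arm_mediator")
    files <- c(files, write_tsv_out(tidy(km1), out("km_by_modality.tsv")))
    files <- c(files, write_tsv_out(tidy(km2), out("km_by_modality_g4ril.tsv")))
    lr <- dplyr::bind_rows(
      dplyr::mutate(logrank_test(matched, group = "modality"), comparison = "modality"),
      dplyr::mutate(logrank_test(matched, group = "g4ril"), comparison = "g4ril"))
    files <- c(files, write_tsv_out(lr, out("logrank.tsv")))

    stage <- "mediation"
    med <- mediate(matched, ps = ps_m,
                   interaction = isTRUE(cfg$mediation$interaction),
                   ci_method = cfg$mediation$ci_method,
                   boot_reps = cfg$mediation$boot_reps %||% 500,
                   seed = seed)
    say(stage, "NIE HR %.3f, NDE HR %.3f, PM %.3f",
        med$effects$hr[med$effects$effect == "nie"],
        med$effects$hr[med$effects$effect == "nde"], med$pm)
    files <- c(files, write_json_out(mediation_as_list(med), out("mediation.json")))

    stage <- "subgroup"
    sub <- subgroup_mediation(matched, strata = cfg$subgroup$strata, ps = ps_m,
                              min_events = cfg$subgroup$min_events %||% 10,
                              interaction = isTRUE(cfg$mediation$interaction),
                              ci_method = cfg$mediation$ci_method,
                              boot_reps = cfg$mediation$boot_reps %||% 500,
                              seed = seed)
    files <- c(files, write_json_out(
      lapply(seq_len(nrow(sub)), function(i) {
        c(list(stratum = sub$stratum[i], underpowered = sub$underpowered[i]),
          mediation_as_list(sub$result[[i]]))
      }), out("subgroup.json")))

    stage <- "manifest"
    cfg_hashable <- cfg
    cfg_hashable$output_dir <- NULL    # hash the analysis settings, not the destination
    manifest <- list(
      seed = seed,
      config_hash = unname(tools::md5sum(
        {tf <- out(".config.yaml"); writeLines(yaml::as.yaml(cfg_hashable), tf); tf})),
      stages = c("input", "summary", "screening", "propensity", "comparison",
                 "mediation", "subgroup"),
      files = as.list(setNames(unname(tools::md5sum(sort(files))),
                               basename(sort(files))))
    )
    unlink(out(".config.yaml"))
    write_json_out(manifest, out("manifest.json"))

    list(cohort = cohort, matched = matched, ps_model = ps, pairs = pairs,
         screen = screen, mediation = med, subgroup = sub, manifest = manifest,
         output_dir = cfg$output_dir)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ", conditionMessage(e)),
          parent = e)
  })
  invisible(res)
}

cli_usage <- function() {
  paste(
    "usage: rilmed <subcommand> [options]",
    "  simulate --seed <int> --out <csv> [--n <int>] [--params <yaml>]",
    "  run      --config <yaml> [--seed <int>] [--out <dir>]",
    "  match    --in <csv> --out <dir>",
    "  mediate  --in <csv> --out <json> [--seed <int>]",
    "  report   --in <dir>",
    sep = "\n")
}

cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (i + 1 > length(args)) stop("missing value for ", a, call. = FALSE)
    out[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' In-process implementation of the shell interface (a thin wrapper script
#' lives at `system.file("cli", "rilmed.R", package = "rilmed")`). Returns an
#' exit code: 0 on success, 2 on usage errors, 1 on runtime failure, with a
#' one-line diagnostic on stderr.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code.
#' @export
rilmed_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { message(cli_usage()); return(2L) }
  sub_cmd <- args[1]
  known <- c("simulate", "run", "match", "mediate", "report")
  opts <- tryCatch(cli_args(args[-1]), error = function(e) e)
  if (!sub_cmd %in% known || inherits(opts, "error") ||
      !all(names(opts) %in% c("seed", "out", "n", "params", "config", "in"))) {
    message(cli_usage())
    return(2L)
  }
  run <- function() {
    switch(sub_cmd,
      simulate = {
        if (is.null(opts$out)) stop("simulate needs --out", call. = FALSE)
        params <- if (!is.null(opts$params)) params_from_yaml(opts$params)
                  else default_paper_params(n = as.integer(opts$n %||% 734))
        cohort <- simulate_cohort(params, seed = as.integer(opts$seed %||% params$seed))
        write_cohort(cohort, opts$out)
        message("wrote ", nrow(cohort), " patients to ", opts$out)
      },
      run = {
        if (is.null(opts$config)) stop("run needs --config", call. = FALSE)
        cfg <- read_config(opts$config)
        if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
        if (!is.null(opts$out)) cfg$output_dir <- opts$out
        run_pipeline(cfg, quiet = TRUE)
        message("artifacts in ", cfg$output_dir)
      },
      match = {
        if (is.null(opts[["in"]]) || is.null(opts$out)) {
          stop("match needs --in and --out", call. = FALSE)
        }
        cohort <- read_cohort(opts[["in"]], quiet = TRUE)
        ps <- fit_ps_model(cohort)
        pairs <- optimal_match(ps, cohort)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        write_tsv_out(pairs, file.path(opts$out, "matched_pairs.tsv"))
        write_tsv_out(match_diagnostics(cohort, pairs),
                      file.path(opts$out, "balance.tsv"))
        message(nrow(pairs), " pairs, total distance ",
                format(attr(pairs, "total_distance")))
      },
      mediate = {
        if (is.null(opts[["in"]]) || is.null(opts$out)) {
          stop("mediate needs --in and --out", call. = FALSE)
        }
        cohort <- read_cohort(opts[["in"]], quiet = TRUE)
        ps <- fit_ps_model(cohort)
        pairs <- optimal_match(ps, cohort)
        matched <- matched_cohort(cohort, pairs)
        med <- mediate(matched, ps = ps$scores[match(matched$id, cohort$id)],
                       seed = as.integer(opts$seed %||% 1))
        write_json_out(mediation_as_list(med), opts$out)
        message("mediation result in ", opts$out)
      },
      report = {
        if (is.null(opts[["in"]])) stop("report needs --in", call. = FALSE)
        p <- file.path(opts[["in"]], "mediation.json")
        if (!file.exists(p)) stop("no mediation.json under ", opts[["in"]], call. = FALSE)
        x <- jsonlite::read_json(p, simplifyVector = TRUE)
        e <- x$effects
        for (i in seq_len(nrow(e))) {
          message(sprintf("%-3s HR %.3f (95%% CI %.3f-%.3f)", toupper(e$effect[i]),
                          e$hr[i], e$conf.low[i], e$conf.high[i]))
        }
        message(sprintf("PM %.3f; mediated median gain %.2f months", x$pm,
                        x$median_diff$estimate))
      })
    0L
  }
  tryCatch(run(), error = function(e) { message("rilmed: ", conditionMessage(e)); 1L })
}
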