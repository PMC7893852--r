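#' Config-driven end-to-end pipeline
#'
#' Runs simulate -> link -> cohort -> classify (EMR + admin) ->
#' comorbidity -> summarize against one output directory, writing every
#' stage's table as CSV plus a JSON manifest with the seed, a config hash
#' and per-stage row counts. Outputs are byte-identical across runs with
#' the same configuration (no timestamps are written), supporting the
#' distributed-analysis pattern where several sites agree on one
#' configuration and run it locally.
#'
#' @name cli_pipeline
NULL

PIPELINE_STAGES <- c("simulate", "link", "cohort", "classify", "comorbidity",
                     "summarize")

#' @param out_dir Output directory for all artifacts.
#' @param n_persons Simulated EMR cohort size (default 5000).
#' @param index_year Index calendar year (default 2014).
#' @param seed Integer seed used for every stochastic stage.
#' @param salt Salt for identifier scrambling.
#' @param stages Subset of
#'   `c("simulate","link","cohort","classify","comorbidity","summarize")`,
#'   in pipeline order; later stages reload earlier outputs from
#'   `out_dir` when the earlier stage is not being run.
#' @param emr_rules Optional path to an EMR rule JSON (default: shipped).
#' @param admin_rules Optional path to an admin rule YAML (default: shipped).
#' @param condition_rules Optional path to a condition YAML (default: shipped).
#' @param sim Optional list of extra [sim_config()] arguments.
#' @rdname cli_pipeline
#' @export
pipeline_config <- function(out_dir, n_persons = 5000, index_year = 2014,
                            seed = 1, salt = "frailscan",
                            stages = PIPELINE_STAGES, emr_rules = NULL,
                            admin_rules = NULL, condition_rules = NULL,
                            sim = list()) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (index_year < 1900) abort("index_year must be >= 1900")
  structure(list(out_dir = out_dir, n_persons = as.integer(n_persons),
                 index_year = as.integer(index_year), seed = as.integer(seed),
                 salt = salt, stages = stages, emr_rules = emr_rules,
                 admin_rules = admin_rules, condition_rules = condition_rules,
                 sim = sim), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @rdname cli_pipeline
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

flatten_calls <- function(calls) {
  out <- calls
  if ("evidence" %in% names(out)) {
    out$evidence <- vapply(out$evidence, function(e) {
      if (nrow(e) == 0) "" else
        paste(sprintf("%s@%s:%s", e$atom, format(e$date), e$snippet),
              collapse = "|")
    }, character(1))
  }
  out
}

write_stage_csv <- function(x, dir, name) {
  for (col in names(x)) {
    if (inherits(x[[col]], "Date")) x[[col]] <- format(x[[col]], "%Y-%m-%d")
    if (is.factor(x[[col]])) x[[col]] <- as.character(x[[col]])
  }
  readr::write_csv(x, file.path(dir, name), na = "", eol = "\n",
                   progress = FALSE)
  nrow(x)
}

need_stage_input <- function(state, key, stage, loader) {
  if (!is.null(state[[key]])) return(state[[key]])
  out <- tryCatch(loader(), error = function(e) NULL)
  if (is.null(out)) {
    abort(sprintf("stage '%s': missing upstream output '%s' (run the earlier stages or point out_dir at their artifacts)",
                  stage, key))
  }
  out
}

#' Run the pipeline
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json` in `out_dir`).
#' @rdname cli_pipeline
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$out_dir
  iy <- config$index_year
  state <- list()
  counts <- list()
  log <- function(...) message(sprintf(...))

  if ("simulate" %in% config$stages) {
    log("stage simulate: n=%d seed=%d", config$n_persons, config$seed)
    sc <- do.call(sim_config, c(list(n_persons = config$n_persons,
                                     index_year = iy, seed = config$seed),
                                config$sim))
    gen <- generate_cohort(sc)
    write_bundle(gen$emr, file.path(out, "emr"))
    write_bundle(gen$admin, file.path(out, "admin"))
    counts$truth <- write_stage_csv(gen$truth, out, "truth.csv")
    state$emr <- gen$emr; state$admin <- gen$admin
  }

  load_bundles <- function(stage) {
    state$emr <<- need_stage_input(state, "emr", stage, function()
      read_bundle(file.path(out, "emr"), "emr"))
    state$admin <<- need_stage_input(state, "admin", stage, function()
      read_bundle(file.path(out, "admin"), "admin"))
  }

  if ("link" %in% config$stages) {
    load_bundles("link")
    log("stage link")
    state$crosswalk <- link_deterministic(state$emr, state$admin,
                                          salt = config$salt)
    counts$crosswalk <- write_stage_csv(state$crosswalk$links, out,
                                        "crosswalk.csv")
  }

  load_crosswalk <- function(stage) {
    state$crosswalk <<- need_stage_input(state, "crosswalk", stage, function() {
      links <- readr::read_csv(file.path(out, "crosswalk.csv"),
                               col_types = "cccc", progress = FALSE)
      list(links = links)
    })
  }

  if ("cohort" %in% config$stages) {
    load_bundles("cohort"); load_crosswalk("cohort")
    log("stage cohort: index year %d", iy)
    state$cohort <- build_cohort(state$emr, state$admin, state$crosswalk, iy)
    counts$cohort <- write_stage_csv(state$cohort, out, "cohort.csv")
  }

  load_cohort <- function(stage) {
    state$cohort <<- need_stage_input(state, "cohort", stage, function() {
      x <- readr::read_csv(file.path(out, "cohort.csv"), col_types = "cccidlc",
                           progress = FALSE)
      x$exclusion_reason <- factor(x$exclusion_reason, levels = EXCLUSION_LEVELS)
      x
    })
  }

  if ("classify" %in% config$stages) {
    load_bundles("classify"); load_cohort("classify")
    log("stage classify")
    emr_def <- if (is.null(config$emr_rules)) default_emr_definition() else
      read_case_definition(config$emr_rules)
    admin_cfg <- admin_rule_config(config$admin_rules)
    state$emr_calls <- apply_emr_definition(emr_def, state$emr, state$cohort, iy)
    state$admin_calls <- apply_admin_definition(state$admin, state$cohort, iy,
                                                admin_cfg)
    counts$emr_calls <- write_stage_csv(flatten_calls(state$emr_calls), out,
                                        "emr_calls.csv")
    counts$admin_calls <- write_stage_csv(state$admin_calls, out,
                                          "admin_calls.csv")
    state$groups <- assign_groups(state$emr_calls, state$admin_calls)
    counts$groups <- write_stage_csv(state$groups, out, "groups.csv")
  }

  if ("comorbidity" %in% config$stages) {
    load_bundles("comorbidity"); load_cohort("comorbidity")
    log("stage comorbidity")
    defs <- condition_defs(config$condition_rules)
    state$comorbid_emr <- classify_conditions(state$emr, state$cohort, iy, defs)
    state$comorbid_admin <- classify_conditions(state$admin, state$cohort, iy,
                                                defs)
    counts$comorbidity_emr <- write_stage_csv(state$comorbid_emr, out,
                                              "comorbidity_emr.csv")
    counts$comorbidity_admin <- write_stage_csv(state$comorbid_admin, out,
                                                "comorbidity_admin.csv")
  }

  if ("summarize" %in% config$stages) {
    load_bundles("summarize"); load_cohort("summarize")
    for (key in c("groups", "comorbid_emr", "comorbid_admin")) {
      fname <- c(groups = "groups.csv", comorbid_emr = "comorbidity_emr.csv",
                 comorbid_admin = "comorbidity_admin.csv")[[key]]
      state[[key]] <- need_stage_input(state, key, "summarize", function() {
        x <- readr::read_csv(file.path(out, fname), col_types = readr::cols(),
                             progress = FALSE)
        if ("group" %in% names(x)) x$group <- factor(x$group, GROUP_LEVELS)
        if ("band" %in% names(x)) x$band <- factor(x$band, c("0-1", "2", "3+"))
        x
      })
    }
    log("stage summarize")
    state$summary <- summarize_cohort(state$groups, state$cohort, state$emr,
                                      state$admin, state$comorbid_emr,
                                      state$comorbid_admin, iy)
    counts$summary_characteristics <- write_stage_csv(
      state$summary$characteristics, out, "summary_characteristics.csv")
    counts$summary_utilization <- write_stage_csv(
      state$summary$utilization, out, "summary_utilization.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("frailscan")),
    seed = config$seed, index_year = iy, stages = config$stages,
    config_hash = fnv_hash(paste(deparse(config[setdiff(names(config), "out_dir")]),
                                 collapse = "")),
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
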