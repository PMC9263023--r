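#' Read a controller/patient configuration document
#'
#' A single YAML document with optional `controller`, `patient` and
#' `schedule` namespaces whose keys mirror [ctrl_config()],
#' [patient_params()] and [build_schedule()] arguments.  `weight_kg` may be
#' given once at the top level and is shared by all namespaces.
#'
#' @param path YAML file path.
#' @return list with elements `config` (a `ctrl_config`), `params` (a
#'   `patient_params`) and `schedule` (an `experiment_schedule`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (!is.list(doc)) stop("malformed config: top level must be a mapping")
  w <- doc$weight_kg
  ctrl_args <- if (is.list(doc$controller)) doc$controller else list()
  pat_args <- if (is.list(doc$patient)) doc$patient else list()
  if (!is.null(w)) {
    ctrl_args$weight_kg <- ctrl_args$weight_kg %||% w
    pat_args$weight_kg <- pat_args$weight_kg %||% w
  }
  if (is.null(ctrl_args$weight_kg))
    stop("config must provide weight_kg (top level or under controller:)")
  if (!is.null(ctrl_args$branch_scale_factors))
    ctrl_args$branch_scale_factors <- unlist(ctrl_args$branch_scale_factors)
  config <- do.call(ctrl_config, ctrl_args)
  pat_args$weight_kg <- pat_args$weight_kg %||% config$weight_kg
  params <- do.call(patient_params, pat_args)
  schedule <- build_schedule(params$weight_kg, params$ebv_ml_per_kg)
  list(config = config, params = params, schedule = schedule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the default configuration document
#'
#' @param path output YAML path.
#' @param weight_kg subject weight in kg.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path, weight_kg = 70) {
  cfg <- ctrl_config(weight_kg = weight_kg)
  par <- patient_params(weight_kg = weight_kg)
  doc <- list(
    weight_kg = weight_kg,
    controller = cfg[setdiff(names(cfg), "weight_kg")],
    patient = par[setdiff(names(par), c("weight_kg", "ebv_ml", "svr_baseline"))]
  )
  doc$controller$branch_scale_factors <- as.list(cfg$branch_scale_factors)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write / read a decision event log (JSON lines)
#'
#' One JSON record per decision tick: time, the 1-min MAP and CVP averages,
#' zone, the interventions emitted (kind, magnitude, branch), the
#' norepinephrine rate after the tick and the responsiveness status.
#'
#' @param ticks list of per-tick records (as in an `hc_run`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(ticks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tk in ticks) {
    rec <- tk
    rec$interventions <- lapply(tk$interventions, function(iv)
      iv[c("kind", "magnitude", "branch", "time_s")])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
}

#' Read / write a vitals CSV
#'
#' Live-mode schema: header `time_s,pap_mmHg,cvp_mmHg` with an optional
#' `dap_mmHg` column, any sample rate of at least 1 Hz, times
#' non-decreasing.
#'
#' @param path CSV path.
#' @return data.frame with the schema above.
#' @export
read_vitals_csv <- function(path) {
  if (!file.exists(path)) stop("vitals file not found: ", path)
  v <- utils::read.csv(path)
  need <- c("time_s", "pap_mmHg", "cvp_mmHg")
  if (!all(need %in% names(v)))
    stop("vitals CSV must have columns: ", paste(need, collapse = ", "))
  if (is.unsorted(v$time_s)) stop("vitals time_s must be non-decreasing")
  v
}

#' @rdname read_vitals_csv
#' @param vitals data.frame to write.
#' @export
write_vitals_csv <- function(vitals, path) {
  utils::write.csv(vitals, path, row.names = FALSE)
  invisible(path)
}

#' Replay the controller over a recorded vitals stream
#'
#' Controller-only mode: runs the decision engine over an externally
#' recorded (or exported) vitals stream with no simulator in the loop.
#' Trailing 1-min averages are evaluated at the decision cadence; the first
#' 60 s are warm-up and produce no decisions; ticks containing non-finite
#' pressures are flagged and skipped; boluses impose the usual
#' infusion-plus-assessment lockout.  Norepinephrine rates are tracked in
#' the controller state but (by construction) do not feed back into the
#' recorded pressures.
#'
#' @param vitals data.frame as from [read_vitals_csv()].
#' @param config a [ctrl_config()].
#' @param state optional starting [ctrl_state()].
#' @return list with `ticks` (decision records, flagged ticks carry
#'   `invalid = TRUE`), `interventions` (flat data.frame) and the final
#'   `state`.
#' @export
replay_controller <- function(vitals, config, state = ctrl_state()) {
  stopifnot(inherits(config, "ctrl_config"))
  t_start <- vitals$time_s[1]
  t_end <- vitals$time_s[nrow(vitals)]
  period <- config$decision_period_s
  ticks <- list()
  lockout_until <- -Inf
  t <- t_start + 60           # warm-up: first full 1-min window
  while (t <= t_end) {
    if (t >= lockout_until) {
      in_win <- vitals$time_s > t - 60 & vitals$time_s <= t
      map_avg <- mean(vitals$pap_mmHg[in_win])
      cvp_avg <- mean(vitals$cvp_mmHg[in_win])
      if (!is.finite(map_avg) || map_avg < 0 || !is.finite(cvp_avg)) {
        ticks[[length(ticks) + 1L]] <- list(time_s = t, map_avg = map_avg,
                                            cvp_avg = cvp_avg, invalid = TRUE,
                                            interventions = list())
      } else {
        d <- decide(vitals_window(t, map_avg, cvp_avg), state, config)
        state <- d$state
        kinds <- vapply(d$interventions, function(x) x$kind, "")
        if (any(kinds %in% c("fluid_bolus", "test_bolus")))
          lockout_until <- t + config$bolus_duration_s + 60
        ticks[[length(ticks) + 1L]] <- list(
          time_s = t, map_avg = map_avg, cvp_avg = cvp_avg, zone = d$zone,
          interventions = d$interventions, ne_rate_after = state$ne_rate,
          responsiveness = state$responsiveness)
      }
    }
    t <- t + period
  }
  list(ticks = ticks, interventions = flatten_interventions(ticks),
       state = state)
}

#' Save run artifacts to a directory
#'
#' Writes the vitals CSV, the JSON-lines event log, the time-in-range
#' report and a manifest (seed, weight, schedule summary, artifact paths,
#' config hash, package version) sufficient to identify and replay the run.
#'
#' @param run an `hc_run` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
save_run <- function(run, dir) {
  stopifnot(inherits(run, "hc_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vit_path <- file.path(dir, "vitals.csv")
  write_vitals_csv(run$vitals, vit_path)
  ev_path <- file.path(dir, "events.jsonl")
  write_event_log(run$ticks, ev_path)
  rep_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(run$report), rep_path, auto_unbox = TRUE,
                       digits = NA)
  cfg_json <- jsonlite::toJSON(unclass(run$config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    seed = run$seed,
    weight_kg = run$config$weight_kg,
    controller_enabled = run$controller_enabled,
    schedule = run$schedule[, c("action", "start_s", "end_s")],
    config_md5 = unname(tools::md5sum(tmp)),
    config = jsonlite::fromJSON(cfg_json),
    artifacts = list(vitals = "vitals.csv", events = "events.jsonl",
                     report = "report.json"),
    package_version = as.character(utils::packageVersion("hemocontrol")))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Load a per-run report from a run directory
#'
#' @param dir run directory written by [save_run()].
#' @return the report as a list.
#' @export
load_report <- function(dir) {
  p <- file.path(dir, "report.json")
  if (!file.exists(p)) stop("missing report.json in ", dir)
  jsonlite::fromJSON(p)
}
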