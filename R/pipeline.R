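# Pipeline orchestration: ingest -> QC -> load estimation -> cumulative
# metrics -> reliability -> correlation reporting, either in memory
# (process_cohort) or staged on disk with CSV/JSON interchange
# (run_pipeline / run_stage). All randomness lives in the synthetic
# generator; the analysis stages are deterministic, so rerunning a pipeline
# on identical inputs reproduces every numeric output.

#' Pipeline configuration
#'
#' @param output_dir Directory for all stage outputs (created if needed).
#' @param input_dir Optional directory of existing recordings in the
#'   package dialect (`recordings/*.csv` + sidecars, `profiles.csv`,
#'   optionally `measures.csv`). When `NULL` the `simulate` stage generates
#'   the cohort from `scenario`.
#' @param scenario A [scenario_config()] (used by the simulate stage).
#' @param geometry A [sensor_geometry()].
#' @param qc A [qc_rules()].
#' @param thresholds Named numeric `c(overall =, high =)` in xBW; must be
#'   positive with `overall < high`.
#' @param seed Optional integer; overrides `scenario$seed`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, input_dir = NULL,
                            scenario = scenario_config(),
                            geometry = sensor_geometry(),
                            qc = qc_rules(),
                            thresholds = default_thresholds(),
                            seed = NULL) {
  if (thresholds[["overall"]] <= 0 ||
      thresholds[["overall"]] >= thresholds[["high"]]) {
    stop_tendonload(
      "thresholds must be positive with overall < high", "config")
  }
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  structure(
    list(output_dir = output_dir, input_dir = input_dir,
         scenario = scenario, geometry = geometry, qc = qc,
         thresholds = thresholds),
    class = "pipeline_config")
}

#' Run QC, estimation and summarisation on an in-memory cohort
#'
#' The in-memory core of the pipeline: for every session, applies
#' [qc_session()]; excluded sessions go to the exclusion log and are not
#' estimated, all others are converted to tendon load traces and reduced to
#' per-day metrics. Participants left with no valid recording are excluded
#' with a logged reason.
#'
#' @param recordings List of [insole_recording()] objects (any mix of
#'   participants).
#' @param profiles Tibble of [participant_profile()] rows covering every
#'   participant present.
#' @param geometry A [sensor_geometry()].
#' @param rules A [qc_rules()].
#' @param thresholds Named numeric `c(overall =, high =)` in xBW.
#' @return A list: `qc_reports` (one row per session), `daily_metrics`,
#'   `summaries` (one row per retained participant), `exclusions` (tibble
#'   of excluded sessions and participants with reasons).
#' @export
process_cohort <- function(recordings, profiles,
                           geometry = sensor_geometry(),
                           rules = qc_rules(),
                           thresholds = default_thresholds()) {
  qc_reports <- list()
  daily_rows <- list()
  for (rec in recordings) {
    pid <- attr(rec, "participant_id")
    profile <- profiles[profiles$participant_id == pid, ]
    if (nrow(profile) == 0L) {
      stop_tendonload(paste0("no profile for participant ", pid),
                      "integrity")
    }
    res <- qc_session(rec, profile, rules)
    qc_reports[[length(qc_reports) + 1L]] <- res$report
    if (res$report$status != "excluded") {
      tr <- estimate_trace(res$recording, geometry, profile,
                           qc = res$report)
      daily_rows[[length(daily_rows) + 1L]] <-
        daily_load_metrics(list(tr), thresholds)
    }
  }
  qc_reports <- dplyr::bind_rows(qc_reports)
  daily <- dplyr::bind_rows(daily_rows)
  if (nrow(daily) > 0L) {
    daily <- daily |>
      dplyr::group_by(.data$participant_id, .data$day_index) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                       .groups = "drop") |>
      dplyr::arrange(.data$participant_id, .data$day_index)
  }
  session_excl <- dplyr::filter(qc_reports, .data$status == "excluded") |>
    dplyr::select("participant_id", "session_id", "exclusion_reason")
  retained <- unique(daily$participant_id)
  lost <- setdiff(profiles$participant_id, retained)
  participant_excl <- tibble::tibble(
    participant_id = lost, session_id = NA_character_,
    exclusion_reason = rep("no valid recordings", length(lost)))
  summaries <- purrr::map(retained, function(pid) {
    summarize_load(daily[daily$participant_id == pid, ],
                   thresholds = thresholds)
  }) |> dplyr::bind_rows()
  list(qc_reports = qc_reports,
       daily_metrics = daily,
       summaries = summaries,
       exclusions = dplyr::bind_rows(session_excl, participant_excl))
}

pipeline_stages <- c("simulate", "qc", "estimate", "summarize",
                     "reliability", "correlate")

stage_outputs <- function(out_dir) {
  list(
    simulate = file.path(out_dir, c("recordings", "profiles.csv")),
    qc = file.path(out_dir, c("qc/qc_reports.csv", "qc/recordings")),
    estimate = file.path(out_dir, "traces"),
    summarize = file.path(out_dir, c("metrics/daily_metrics.csv",
                                     "metrics/summaries.csv")),
    reliability = file.path(out_dir, "reliability/reliability.csv"),
    correlate = file.path(out_dir, "correlations/correlations.csv")
  )
}

require_stage <- function(config, stage) {
  paths <- stage_outputs(config$output_dir)[[stage]]
  if (!all(file.exists(paths))) {
    stop_tendonload(
      paste0("missing output of stage '", stage,
             "'; run that stage first"),
      "dependency")
  }
}

read_profiles <- function(out_dir) {
  readr::read_csv(file.path(out_dir, "profiles.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

list_recordings <- function(dir) {
  sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
}

write_trace <- function(tr, path) {
  readr::write_csv(tibble::tibble(time_s = fmt_double(tr$t),
                                  load_bw = fmt_double(tr$load)),
                   path, progress = FALSE)
  meta <- recording_meta(tr)
  jsonlite::write_json(
    list(participant_id = meta$participant_id,
         session_id = meta$session_id,
         start_time = format(meta$start_time, "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC"),
         sample_rate = meta$sample_rate, day_index = meta$day_index),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  new_tendon_load_trace(df$time_s, df$load_bw, list(
    participant_id = meta$participant_id, session_id = meta$session_id,
    start_time = as.POSIXct(meta$start_time, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%S"),
    sample_rate = meta$sample_rate,
    day_index = meta$day_index %||% NA_integer_))
}

#' Run one pipeline stage against the staged on-disk outputs
#'
#' Each stage reads the previous stage's serialized outputs from
#' `config$output_dir` and writes its own; running a stage before its
#' dependency raises a dependency error naming the missing stage.
#' Stages: `simulate` (or ingest of `input_dir`), `qc`, `estimate`,
#' `summarize`, `reliability`, `correlate`.
#'
#' @param config A [pipeline_config()].
#' @param stage One of `r paste(pipeline_stages, collapse = ", ")`.
#' @return The stage's primary output, invisibly.
#' @export
run_stage <- function(config, stage = pipeline_stages) {
  stage <- match.arg(stage)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = stage_simulate(config),
    qc = stage_qc(config),
    estimate = stage_estimate(config),
    summarize = stage_summarize(config),
    reliability = stage_reliability(config),
    correlate = stage_correlate(config))
}

stage_simulate <- function(config) {
  out_dir <- config$output_dir
  rec_dir <- file.path(out_dir, "recordings")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$input_dir)) {
    # ingest an existing dataset in the package dialect
    src_rec <- file.path(config$input_dir, "recordings")
    if (!dir.exists(src_rec) ||
        !file.exists(file.path(config$input_dir, "profiles.csv"))) {
      stop_tendonload(
        "input_dir must contain recordings/ and profiles.csv", "format")
    }
    for (f in list.files(src_rec, full.names = TRUE)) {
      file.copy(f, rec_dir, overwrite = TRUE)
    }
    file.copy(file.path(config$input_dir, "profiles.csv"), out_dir,
              overwrite = TRUE)
    msr <- file.path(config$input_dir, "measures.csv")
    if (file.exists(msr)) file.copy(msr, out_dir, overwrite = TRUE)
    return(invisible(NULL))
  }
  cohort <- generate_cohort(config$scenario)
  for (rec in cohort$recordings) {
    write_recording(rec, file.path(rec_dir,
                                   paste0(attr(rec, "session_id"), ".csv")))
  }
  readr::write_csv(cohort$profiles, file.path(out_dir, "profiles.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$measures, file.path(out_dir, "measures.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(participants = cohort$ground_truth$participants,
         days = cohort$ground_truth$days),
    file.path(out_dir, "ground_truth.json"),
    dataframe = "columns", digits = NA)
  invisible(cohort)
}

stage_qc <- function(config) {
  require_stage(config, "simulate")
  out_dir <- config$output_dir
  profiles <- read_profiles(out_dir)
  qc_rec_dir <- file.path(out_dir, "qc", "recordings")
  dir.create(qc_rec_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  for (f in list_recordings(file.path(out_dir, "recordings"))) {
    rec <- read_recording(f)
    pid <- attr(rec, "participant_id")
    profile <- profiles[profiles$participant_id == pid, ]
    res <- qc_session(rec, profile, config$qc)
    reports[[length(reports) + 1L]] <- res$report
    if (res$report$status != "excluded") {
      write_recording(res$recording, file.path(qc_rec_dir, basename(f)))
    }
  }
  reports <- dplyr::bind_rows(reports)
  readr::write_csv(reports, file.path(out_dir, "qc", "qc_reports.csv"),
                   progress = FALSE)
  invisible(reports)
}

stage_estimate <- function(config) {
  require_stage(config, "qc")
  out_dir <- config$output_dir
  profiles <- read_profiles(out_dir)
  trace_dir <- file.path(out_dir, "traces")
  dir.create(trace_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list_recordings(file.path(out_dir, "qc", "recordings"))) {
    rec <- read_recording(f)
    pid <- attr(rec, "participant_id")
    profile <- profiles[profiles$participant_id == pid, ]
    tr <- estimate_trace(rec, config$geometry, profile)
    write_trace(tr, file.path(trace_dir, basename(f)))
  }
  invisible(trace_dir)
}

stage_summarize <- function(config) {
  require_stage(config, "estimate")
  out_dir <- config$output_dir
  metrics_dir <- file.path(out_dir, "metrics")
  dir.create(metrics_dir, recursive = TRUE, showWarnings = FALSE)
  daily_rows <- list()
  for (f in list_recordings(file.path(out_dir, "traces"))) {
    tr <- read_trace(f)
    daily_rows[[length(daily_rows) + 1L]] <-
      daily_load_metrics(list(tr), config$thresholds)
  }
  daily <- dplyr::bind_rows(daily_rows) |>
    dplyr::group_by(.data$participant_id, .data$day_index) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                     .groups = "drop") |>
    dplyr::arrange(.data$participant_id, .data$day_index)
  summaries <- purrr::map(unique(daily$participant_id), function(pid) {
    summarize_load(daily[daily$participant_id == pid, ],
                   thresholds = config$thresholds)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select(-"days_included")
  readr::write_csv(daily, file.path(metrics_dir, "daily_metrics.csv"),
                   progress = FALSE)
  readr::write_csv(summaries, file.path(metrics_dir, "summaries.csv"),
                   progress = FALSE)
  qc <- readr::read_csv(file.path(out_dir, "qc", "qc_reports.csv"),
                        show_col_types = FALSE, progress = FALSE)
  profiles <- read_profiles(out_dir)
  excl <- dplyr::filter(qc, .data$status == "excluded") |>
    dplyr::select("participant_id", "session_id", "exclusion_reason")
  lost <- setdiff(profiles$participant_id, unique(daily$participant_id))
  if (length(lost) > 0L) {
    excl <- dplyr::bind_rows(excl, tibble::tibble(
      participant_id = lost, session_id = NA_character_,
      exclusion_reason = "no valid recordings"))
  }
  readr::write_csv(excl, file.path(metrics_dir, "exclusions.csv"),
                   progress = FALSE)
  invisible(summaries)
}

stage_reliability <- function(config) {
  require_stage(config, "summarize")
  out_dir <- config$output_dir
  daily <- readr::read_csv(
    file.path(out_dir, "metrics", "daily_metrics.csv"),
    show_col_types = FALSE, progress = FALSE)
  rel <- tryCatch(
    suppressWarnings(reliability_analysis(daily)),
    tendonload_domain_error = function(e) {
      warn(paste0("reliability analysis skipped: ", conditionMessage(e)))
      tibble::tibble(metric = character(), k = integer(),
                     mape_mean = double(), mape_sd = double(),
                     pearson_r = double(), icc = double(),
                     n_subsets = integer(), n_participants = integer())
    })
  dir.create(file.path(out_dir, "reliability"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(rel, file.path(out_dir, "reliability",
                                  "reliability.csv"), progress = FALSE)
  invisible(rel)
}

stage_correlate <- function(config) {
  require_stage(config, "summarize")
  out_dir <- config$output_dir
  summaries <- readr::read_csv(
    file.path(out_dir, "metrics", "summaries.csv"),
    show_col_types = FALSE, progress = FALSE)
  profiles <- read_profiles(out_dir)
  outcomes <- profiles[, intersect(c("participant_id", "age", "visa_a",
                                     "pas"), names(profiles))]
  msr_path <- file.path(out_dir, "measures.csv")
  if (file.exists(msr_path)) {
    measures <- readr::read_csv(msr_path, show_col_types = FALSE,
                                progress = FALSE)
    outcomes <- dplyr::left_join(
      measures, outcomes,
      by = c("participant_id",
             intersect(c("age", "visa_a", "pas"), names(measures))))
  }
  tab <- correlation_table(summaries, outcomes)
  dir.create(file.path(out_dir, "correlations"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(tab, file.path(out_dir, "correlations",
                                  "correlations.csv"), progress = FALSE)
  invisible(tab)
}

#' Run the full pipeline
#'
#' Executes every stage in order against `config$output_dir` and writes a
#' run manifest (`manifest.json`: configuration hash, package version,
#' seed, timestamp). Rerunning with an identical config reproduces every
#' numeric output exactly (the manifest timestamp is the only thing that
#' changes).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summaries`, `reliability`,
#'   `correlations`, `qc_reports`, `exclusions` read back from disk.
#' @export
run_pipeline <- function(config) {
  for (stage in pipeline_stages) run_stage(config, stage)
  out_dir <- config$output_dir
  manifest <- list(
    package = "tendonload",
    version = as.character(packageVersion("tendonload")),
    config_hash = rlang::hash(config[c("scenario", "geometry", "qc",
                                       "thresholds")]),
    seed = config$scenario$seed,
    stages = pipeline_stages,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  read_out <- function(...) {
    readr::read_csv(file.path(out_dir, ...), show_col_types = FALSE,
                    progress = FALSE)
  }
  invisible(list(
    summaries = read_out("metrics", "summaries.csv"),
    reliability = read_out("reliability", "reliability.csv"),
    correlations = read_out("correlations", "correlations.csv"),
    qc_reports = read_out("qc", "qc_reports.csv"),
    exclusions = read_out("metrics", "exclusions.csv")))
}

#' Reanalyze an existing dataset directory
#'
#' Runs the full pipeline (QC through correlations) on a directory holding
#' recordings in the package dialect -- `recordings/*.csv` with JSON
#' sidecars, `profiles.csv`, optionally `measures.csv` -- rather than a
#' simulated cohort. This is the harness for recomputing descriptive and
#' subsampling results from a deposited dataset once it has been converted
#' to the dialect.
#'
#' @param input_dir Dataset directory as above.
#' @param output_dir Where to write the pipeline outputs.
#' @param ... Passed to [pipeline_config()] (geometry, qc, thresholds).
#' @return See [run_pipeline()].
#' @export
reanalyze_dataset <- function(input_dir, output_dir, ...) {
  config <- pipeline_config(output_dir = output_dir, input_dir = input_dir,
                            ...)
  run_pipeline(config)
}
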