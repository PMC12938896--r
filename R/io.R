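# Readers/writers for course and report formats, run configuration, and the
# command-line entry point.
#
# JSON is the canonical course format (one object per course, field names as
# in the domain types). The CSV alternative is a directory of three files -
# measurements.csv, treatments.csv, clinical.csv - joined on patient_id /
# lesion_id / assessment_index; measurements.csv additionally carries
# assessment_day so the scan grid round-trips.

#' Write a patient course
#'
#' @param course a `patient_course`
#' @param path JSON file path, or an existing directory for `format="csv"`
#' @param format `"json"` (canonical) or `"csv"` (three-file projection)
#' @return `path`, invisibly
#' @export
write_course <- function(course, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      patient_id = course$patient_id,
      assessment_days = course$assessment_days,
      lesions = course$lesions,
      treatments = course$treatments,
      measurements = course$measurements,
      clinical = course$clinical)
    jsonlite::write_json(obj, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    m <- course$measurements
    m <- cbind(patient_id = course$patient_id,
               m[, 1:2, drop = FALSE],
               assessment_day = course$assessment_days[m$assessment_index + 1L],
               m[, -(1:2), drop = FALSE])
    utils::write.csv(m, file.path(path, "measurements.csv"), row.names = FALSE)
    tr <- course$treatments
    tr_flat <- data.frame(
      patient_id = rep(course$patient_id, nrow(tr)),
      treatment_id = tr$treatment_id, modality = tr$modality,
      start_day = tr$start_day,
      targeted_lesion_ids = vapply(tr$targeted_lesion_ids, paste,
                                   character(1), collapse = ";"),
      stringsAsFactors = FALSE)
    utils::write.csv(tr_flat, file.path(path, "treatments.csv"),
                     row.names = FALSE)
    cl <- cbind(patient_id = rep(course$patient_id, nrow(course$clinical)),
                course$clinical)
    utils::write.csv(cl, file.path(path, "clinical.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read and validate a patient course
#'
#' Parses the canonical JSON document or the three-file CSV directory,
#' reconstructs the course, and validates it; all invariant violations are
#' raised together. Round-trips with [write_course()].
#'
#' @param path JSON file or CSV directory
#' @param format `"json"` or `"csv"`
#' @return a validated `patient_course`
#' @export
read_course <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  course <- if (format == "json") .read_course_json(path) else .read_course_csv(path)
  assert_valid_course(course)
  course
}

.read_course_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("patient_id", "assessment_days", "measurements")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("course JSON missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  les <- obj$lesions
  if (!is.null(les) && NROW(les) == 0L) les <- NULL
  tr <- obj$treatments
  if (!is.null(tr) && NROW(tr)) {
    tl <- tr$targeted_lesion_ids
    if (is.null(tl)) tl <- rep(list(character()), nrow(tr))
    tr$targeted_lesion_ids <- I(lapply(tl, function(x)
      if (is.null(x) || all(is.na(x))) character() else as.character(x)))
  } else tr <- NULL
  cl <- obj$clinical
  if (!is.null(cl) && NROW(cl) == 0L) cl <- NULL
  patient_course(obj$patient_id, obj$assessment_days, obj$measurements,
                 lesions = les, treatments = tr, clinical = cl)
}

.read_course_csv <- function(path) {
  fp <- function(f) file.path(path, f)
  for (f in c("measurements.csv", "treatments.csv", "clinical.csv"))
    if (!file.exists(fp(f))) stop("missing ", f, " under ", path, call. = FALSE)
  m <- utils::read.csv(fp("measurements.csv"), stringsAsFactors = FALSE)
  need <- c("patient_id", "lesion_id", "assessment_index", "assessment_day",
            "longest_diameter_mm")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("measurements.csv missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  days <- unique(m[order(m$assessment_index), c("assessment_index", "assessment_day")])
  grid <- rep(NA_integer_, max(days$assessment_index) + 1L)
  grid[days$assessment_index + 1L] <- days$assessment_day
  if (any(is.na(grid)))
    stop("measurements.csv does not cover every assessment index", call. = FALSE)
  tr <- utils::read.csv(fp("treatments.csv"), stringsAsFactors = FALSE)
  if (nrow(tr)) {
    tr$targeted_lesion_ids <- I(lapply(strsplit(
      ifelse(is.na(tr$targeted_lesion_ids), "", tr$targeted_lesion_ids), ";"),
      function(x) x[nzchar(x)]))
    tr$patient_id <- NULL
  } else tr <- NULL
  cl <- utils::read.csv(fp("clinical.csv"), stringsAsFactors = FALSE)
  if (nrow(cl)) cl$patient_id <- NULL else cl <- NULL
  patient_course(m$patient_id[1L], grid,
                 m[, setdiff(names(m), c("patient_id", "assessment_day"))],
                 treatments = tr, clinical = cl)
}

# round every numeric in a nested structure to 6 significant digits
.round6 <- function(x) {
  if (is.double(x)) signif(x, 6)
  else if (is.list(x)) lapply(x, .round6)
  else if (is.data.frame(x)) { x[] <- lapply(x, .round6); x }
  else x
}

#' Write an assessment report
#'
#' Writes `report.json` (full nested structure, sorted keys, floats at six
#' significant digits for byte-stable diffs), `timepoints.csv` (flat
#' per-timepoint table), and `audit.log` (one fired rule per line) into a
#' directory.
#'
#' @param report an `assessment_report` from [assess_course()]
#' @param dir output directory (created if needed)
#' @param formats subset of `c("json", "csv")`
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir, formats = c("json", "csv")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if ("json" %in% formats) {
    obj <- list(
      patient_id = report$patient_id,
      policy = report$policy,
      best_overall = report$best_overall,
      time_to_progression_days = report$time_to_progression_days,
      discrepancy_flag = report$discrepancy_flag,
      n_baseline_lesions = report$n_baseline_lesions,
      mixed_response_fractions = report$mixed_response_fractions,
      timepoints = report$timepoints,
      lesion_final_categories = as.list(report$lesions$final),
      dbf = list(
        reference_day = report$dbf$reference_day,
        total_new_lesions = report$dbf$total_new_lesions,
        total_volume_mm3 = report$dbf$total_volume_mm3,
        latency_days = report$dbf$latency_days,
        bmv_per_year = report$dbf$bmv_per_year,
        vbmv_mm3_per_year = report$dbf$vbmv_mm3_per_year,
        events = report$dbf$events[, c("event_day", "count", "volume_mm3",
                                       "confirmed")]))
    obj <- .round6(obj)
    obj <- obj[order(names(obj))]
    jsonlite::write_json(obj, file.path(dir, "report.json"),
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if ("csv" %in% formats)
    utils::write.csv(report$timepoints, file.path(dir, "timepoints.csv"),
                     row.names = FALSE)
  writeLines(report$audit_log, file.path(dir, "audit.log"))
  invisible(dir)
}

#' Run configuration
#'
#' Bundles input, output, and classification settings for [run_assess()].
#' Unknown configuration keys are rejected.
#'
#' @param course_path path to a course (JSON file or CSV directory)
#' @param out_dir output directory for the report
#' @param format course input format
#' @param report_formats subset of `c("json","csv")`
#' @param config an [assessment_config()] or a plain list of its fields
#' @return a `run_config` list
#' @export
run_config <- function(course_path, out_dir, format = c("json", "csv"),
                       report_formats = c("json", "csv"),
                       config = assessment_config()) {
  structure(list(course_path = course_path, out_dir = out_dir,
                 format = match.arg(format),
                 report_formats = report_formats,
                 config = as_assessment_config(config)),
            class = "run_config")
}

#' Assess a course from disk and write the report
#'
#' Deterministic end-to-end run: read + validate the course, assess it under
#' the configured policy, and write the report. Identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param rc a [run_config()]
#' @return the `assessment_report`, invisibly
#' @export
run_assess <- function(rc) {
  course <- read_course(rc$course_path, rc$format)
  report <- assess_course(course, rc$config)
  write_report(report, rc$out_dir, rc$report_formats)
  invisible(report)
}

#' Compare designation policies on one course
#'
#' Runs the assessment under A1, A2, and A-Rx and tabulates the
#' per-assessment overall categories and target counts, flagging
#' disagreements.
#'
#' @param course a valid `patient_course`
#' @param cfg an [assessment_config()] (its `policy` field is ignored)
#' @return data.frame with one row per assessment: day, per-policy overall
#'   category and target count, and `disagree`
#' @export
compare_policies <- function(course, cfg = assessment_config()) {
  reports <- lapply(POLICIES, function(p) {
    cfg$policy <- p
    assess_course(course, cfg)
  })
  names(reports) <- POLICIES
  out <- data.frame(
    assessment_index = reports$A1$timepoints$assessment_index,
    day = reports$A1$timepoints$day)
  for (p in POLICIES) {
    out[[paste0("overall_", tolower(p))]] <- reports[[p]]$timepoints$overall
    out[[paste0("n_targets_", tolower(p))]] <- lengths(reports[[p]]$timeline$targets)
  }
  out$disagree <- !(out$overall_a1 == out$overall_a2 &
                      out$overall_a2 == out$overall_arx)
  out
}

#' Command-line entry point
#'
#' Implements the `bmrs` command (see `inst/cli/bmrs`):
#' \preformatted{
#' bmrs assess --course FILE [--policy a1|a2|arx] [--format json|csv]
#'             [--config cfg.json] [--out DIR]
#' bmrs scenario NAME [--out FILE]
#' bmrs simulate --seed N [--params params.json] [--out FILE]
#' bmrs compare-policies --course FILE [--format json|csv]
#' }
#' Configuration files are JSON objects with [assessment_config()] field
#' names; command-line flags override them.
#'
#' @param args character vector of command-line arguments
#' @return integer exit status (0 iff the requested output was written)
#' @export
bmrs_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: bmrs <assess|scenario|simulate|compare-policies> [options]"
  if (length(args) == 0L) { message(usage); return(1L) }
  cmd <- args[1L]
  rest <- args[-1L]
  res <- tryCatch(switch(
    cmd,
    assess = .cli_assess(rest),
    scenario = .cli_scenario(rest),
    simulate = .cli_simulate(rest),
    `compare-policies` = .cli_compare(rest),
    { message(usage); 1L }
  ), error = function(e) { message("bmrs: ", conditionMessage(e)); 1L })
  invisible(res)
}

.cli_config <- function(opt) {
  cfg <- if (!is.null(opt$config)) {
    as_assessment_config(jsonlite::fromJSON(opt$config, simplifyVector = TRUE))
  } else assessment_config()
  if (!is.null(opt$policy))
    cfg$policy <- c(a1 = "A1", a2 = "A2", arx = "ARx")[[tolower(opt$policy)]]
  cfg
}

.cli_assess <- function(args) {
  spec <- list(
    optparse::make_option("--course", type = "character"),
    optparse::make_option("--format", type = "character", default = "json"),
    optparse::make_option("--policy", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "."))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args)
  if (is.null(opt$course)) stop("--course is required")
  run_assess(run_config(opt$course, opt$out, format = opt$format,
                        config = .cli_config(opt)))
  0L
}

.cli_scenario <- function(args) {
  name <- args[!startsWith(args, "--")][1L]
  spec <- list(optparse::make_option("--out", type = "character",
                                     default = "course.json"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = setdiff(args, name))
  if (is.na(name)) stop("scenario name required; one of ",
                        paste(scenario_names(), collapse = ", "))
  write_course(build_scenario(name), opt$out)
  0L
}

.cli_simulate <- function(args) {
  spec <- list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--params", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "course.json"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args)
  pl <- if (!is.null(opt$params))
    jsonlite::fromJSON(opt$params, simplifyVector = TRUE) else list()
  pl$seed <- opt$seed
  write_course(simulate_course(do.call(simulation_params, pl)), opt$out)
  0L
}

.cli_compare <- function(args) {
  spec <- list(
    optparse::make_option("--course", type = "character"),
    optparse::make_option("--format", type = "character", default = "json"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args)
  if (is.null(opt$course)) stop("--course is required")
  course <- read_course(opt$course, opt$format)
  tab <- compare_policies(course)
  utils::write.csv(tab, stdout(), row.names = FALSE)
  0L
}
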