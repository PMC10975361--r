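# End-to-end pipeline: EDA -> detrending escalation -> LOOCV per method ->
# metrics -> comparison, with all artifacts written to an output directory.
# The configuration is a flat key = value text file; command-line flags (see
# inst/cli/stinterp.R) override file values.

run_config_defaults <- function() {
  list(
    data = "", stations = "", out_dir = "stinterp-out",
    methods = "idw,bss,stk",
    idw_beta = "auto", idw_betas = "1,2,3,4,5,6,7,8,9,10",
    k_nearest = "3", offset = "auto",
    families = "exponential,spherical,gaussian,matern",
    k_t = "5", trend = "tensor_spline", trend_refit = "fixed_sp",
    seed = "1", n_perm = "999",
    distance = "great_circle_km", verbose = "1"
  )
}

#' Read or write a flat key = value run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Config file path.
#' @return `read_run_config()`: a named list of configuration strings.
#' @export
read_run_config <- function(path) {
  defaults <- run_config_defaults()
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort(sprintf("Malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    if (!key %in% names(defaults)) abort(sprintf("Unknown config key: '%s'", key))
    out[[key]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' @rdname read_run_config
#' @param config Named list of configuration values.
#' @return `write_run_config()`: `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  merged <- modifyList(defaults, config)
  writeLines(sprintf("%s = %s", names(merged), unlist(merged)), path)
  invisible(path)
}

#' Run the full interpolation workflow from a configuration
#'
#' Reads the series, performs EDA, walks the detrending escalation (recording
#' every branch), runs LOOCV for the configured methods, writes predictions
#' and metric CSVs, a JSON report (including the method comparison and
#' autocorrelation tests), and a plain-text log of every decision taken.
#'
#' @param config Named list from [read_run_config()] (or a path to a config
#'   file).
#' @return Invisibly, a list with the [benchmark_methods()] result, the
#'   escalation record, and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_run_config(config)
  config <- modifyList(run_config_defaults(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    st_log(line, verbose = config$verbose != "0")
  }
  stations <- read_stations(config$stations)
  data <- read_series(config$data)
  note("Loaded %d stations, %d months.", nrow(stations),
       dplyr::n_distinct(data$time_index))

  esc <- detrend_escalate(data, stations)
  for (ln in esc$log) note("escalation: %s", ln)
  note("Detrending level selected: %s", esc$level)

  methods <- strsplit(config$methods, ",")[[1]]
  families <- strsplit(config$families, ",")[[1]]
  offset <- if (config$offset == "auto") NULL else as.numeric(config$offset)
  idw_beta <- if (config$idw_beta == "auto") "auto" else as.numeric(config$idw_beta)
  bench <- benchmark_methods(
    data, stations,
    methods = methods, seed = as.integer(config$seed),
    idw_beta = idw_beta,
    idw_betas = as.numeric(strsplit(config$idw_betas, ",")[[1]]),
    k_nearest = as.integer(config$k_nearest), offset = offset,
    stk_options = list(
      spatial_families = families, temporal_families = families,
      trend_kind = config$trend, trend_refit = config$trend_refit,
      k_t = as.integer(config$k_t)
    ),
    n_perm = as.integer(config$n_perm),
    convention = config$distance
  )
  paths <- character()
  for (nm in names(bench$folds)) {
    p1 <- file.path(config$out_dir, paste0("predictions_", nm, ".csv"))
    readr::write_csv(bench$folds[[nm]], p1)
    p2 <- file.path(config$out_dir, paste0("metrics_", nm, ".csv"))
    write_metrics(bench$metrics[[nm]], p2)
    paths <- c(paths, p1, p2)
    note("Wrote %s and %s.", p1, p2)
  }
  report <- list(
    methods = names(bench$folds),
    escalation_level = esc$level,
    idw_beta = bench$idw_beta,
    aggregates = lapply(bench$aggregates, as.data.frame),
    autocorr = as.data.frame(bench$autocorr)
  )
  if (!is.null(bench$comparisons)) {
    report$friedman <- lapply(bench$comparisons, function(cc) as.data.frame(cc$friedman))
    report$nemenyi_p <- lapply(bench$comparisons, function(cc) cc$nemenyi_p)
    report$reduction_pct <- lapply(bench$comparisons, function(cc) cc$reduction_pct)
  }
  if (!is.null(bench$stk)) {
    report$stk_families <- list(spatial = bench$stk$spatial_family,
                                temporal = bench$stk$temporal_family)
    report$stk_family_table <- as.data.frame(bench$stk$family_table)
  }
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("Wrote %s.", report_path)
  writeLines(log_lines, log_path)
  invisible(list(benchmark = bench, escalation = esc,
                 paths = c(paths, report_path, log_path)))
}
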