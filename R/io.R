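#' Read a long-format panel CSV
#'
#' Expected schema: header row; columns `subject_id`, `time` (decimal years),
#' `state_code` (one of `"0"` or the configured state labels), then one
#' column per covariate. Validates codes (error naming the offending row),
#' within-subject time ordering (error), and drops subjects with fewer than
#' two visits with a warning.
#'
#' @param path CSV file path.
#' @param space A [state_space()] object used to validate codes.
#' @return Panel tibble, sorted by subject and time.
#' @export
read_panel_csv <- function(path, space) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "time", "state_code")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("Panel CSV must have columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data$state_code <- as.character(data$state_code)
  bad <- !(data$state_code %in% c("0", space$states))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("Unknown state code \"", data$state_code[i], "\" at data row ", i,
         " (subject ", data$subject_id[i], ").", call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$subject_id, .data$time)
  byid <- split(data$time, data$subject_id)
  nonmono <- vapply(byid, function(tt) any(diff(tt) <= 0), logical(1))
  if (any(nonmono)) {
    stop("Non-increasing visit times within subject ",
         names(byid)[nonmono][1L], ".", call. = FALSE)
  }
  nvis <- vapply(byid, length, integer(1))
  if (any(nvis < 2L)) {
    warning(sum(nvis < 2L), " subject(s) with a single visit dropped.",
            call. = FALSE)
    keep <- data$subject_id %in% names(byid)[nvis >= 2L]
    data <- data[keep, , drop = FALSE]
  }
  data
}

#' Write a panel tibble to CSV
#'
#' Comma-separated, UTF-8, `.` decimal point; the exact inverse of
#' [read_panel_csv()] on valid data.
#'
#' @param data Panel tibble.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_panel_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Read a model configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON. Schema:
#' \preformatted{
#' n_severity: 2          # disability states D1..Dm
#' resolution: true       # include the D0 -> R transition
#' lambda:                # initial baseline intensities (per year)
#'   "D0->R": 0.4
#'   "D0->D1": 0.4
#'   ...
#' covariates:            # optional: per-transition covariate start values
#'   "D0->D1": {z: 1.0}
#' }
#' An example ships in `inst/extdata/scenario1-config.yml`.
#'
#' @param path Configuration file path.
#' @return List with `space` ([state_space()]) and `params` ([msm_params()]).
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$n_severity) || is.null(cfg$lambda)) {
    stop("Model config needs at least `n_severity` and `lambda`.",
         call. = FALSE)
  }
  space <- state_space(cfg$n_severity,
                       resolution = isTRUE(cfg$resolution %||% TRUE))
  lam <- unlist(cfg$lambda)
  beta <- lapply(cfg$covariates %||% list(), function(b) unlist(b))
  list(space = space, params = msm_params(lam, beta, space))
}

#' Write a run manifest
#'
#' Records, alongside every output, what produced it: package version, the
#' invoked command/parameters, the master seed, a timestamp and per-stage
#' record counts — enough to re-run bit-identically.
#'
#' @param dir Output directory (created if needed).
#' @param command Character description of the invocation.
#' @param seed Master seed.
#' @param counts Named list of record counts.
#' @param extra Named list of further fields.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_run_manifest <- function(dir, command, seed = NULL, counts = list(),
                               extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(
    list(
      tool = "resolvemsm",
      version = as.character(utils::packageVersion("resolvemsm")),
      command = command,
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      counts = counts
    ),
    extra
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
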