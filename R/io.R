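#' Trial-log CSV schema
#'
#' The ordered column set used to serialize trial logs, with semantic types.
#' The schema is versioned so external files can be checked and adapted.
#'
#' @return Named character vector: column name -> type
#'   (`integer`/`character`/`numeric`/`logical`).
#' @export
trial_csv_schema <- function() {
  c(participant_id = "integer", study = "integer", list_id = "integer",
    list_type = "character", presentation_index = "integer",
    step_index = "integer", augend = "integer", addend1 = "integer",
    addend2 = "integer", chosen_plan = "character",
    step_type = "character", dual_type = "character",
    latency_ms = "numeric", entry_ms = "numeric",
    list_correct = "logical", late_entry = "logical")
}

#' Write a trial log to CSV
#'
#' The file starts with a `#`-prefixed provenance line recording the schema
#' version, the study and the RNG seed, followed by a standard CSV body.
#'
#' @param log A `trial_log`.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header (defaults to the
#'   log's `seed` attribute).
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(log, path, seed = attr(log, "seed")) {
  cols <- names(trial_csv_schema())
  stopifnot(all(cols %in% names(log)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# decadd trial log | schema=1 | study=%s | seed=%s",
    paste(unique(log$study), collapse = "/"),
    if (is.null(seed)) "NA" else as.character(seed)
  ), con)
  utils::write.csv(as.data.frame(log)[, cols], con, row.names = FALSE)
  invisible(path)
}

#' Validate a trial log row by row
#'
#' Checks the domain rules a schema-valid log must satisfy: addends are
#' digits 1-9, latencies positive, presentation indices at least 1, augends
#' non-negative.
#'
#' @param log A data frame in trial-log shape.
#' @return A data frame of violations (`row`, `column`, `problem`);
#'   zero rows when the log is valid.
#' @export
validate_trial_log <- function(log) {
  problems <- list()
  note <- function(rows, column, problem) {
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<- data.frame(
        row = rows, column = column, problem = problem,
        stringsAsFactors = FALSE
      )
    }
  }
  missing_cols <- setdiff(names(trial_csv_schema()), names(log))
  if (length(missing_cols)) {
    stop("missing mapped columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  note(which(!(log$addend1 %in% 1:9)), "addend1",
       "addends must be digits 1..9")
  a2_bad <- which(!is.na(log$addend2) & !(log$addend2 %in% 1:9))
  note(a2_bad, "addend2", "addends must be digits 1..9")
  note(which(!is.finite(log$latency_ms) | log$latency_ms <= 0),
       "latency_ms", "latencies must be positive")
  note(which(is.na(log$presentation_index) | log$presentation_index < 1),
       "presentation_index", "presentation index starts at 1")
  note(which(is.na(log$augend) | log$augend < 0), "augend",
       "augends are non-negative")
  if (length(problems) == 0) {
    return(data.frame(row = integer(0), column = character(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, problems)
}

#' Read a trial log from CSV
#'
#' Reads a serialized log, optionally adapting an external column schema via
#' a mapping, and validates the domain rules. `#`-prefixed provenance lines
#' are ignored.
#'
#' @param path CSV path.
#' @param schema_map Optional named character vector mapping internal column
#'   names to the file's column names (e.g.
#'   `c(latency_ms = "RT", participant_id = "subj")`), or the path of a JSON
#'   file holding such a mapping.
#' @param validate Stop on row-level violations (default). With
#'   `validate = FALSE` the violation report is attached as attribute
#'   `problems` instead.
#' @return A `trial_log` data frame.
#' @export
read_trial_csv <- function(path, schema_map = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.character(schema_map) && length(schema_map) == 1 &&
      file.exists(schema_map)) {
    schema_map <- unlist(jsonlite::read_json(schema_map))
  }
  if (!is.null(schema_map)) {
    for (internal in names(schema_map)) {
      external <- schema_map[[internal]]
      if (!external %in% names(df)) {
        stop("schema map expects column '", external,
             "' (for '", internal, "') which is absent from ", path,
             call. = FALSE)
      }
      names(df)[names(df) == external] <- internal
    }
  }
  schema <- trial_csv_schema()
  for (col in setdiff(names(schema), names(df))) {
    df[[col]] <- switch(schema[[col]],
                        integer = NA_integer_, numeric = NA_real_,
                        logical = NA, character = NA_character_)
  }
  df <- df[, names(schema)]
  for (col in names(schema)) {
    df[[col]] <- switch(
      schema[[col]],
      integer = as.integer(df[[col]]),
      numeric = as.numeric(df[[col]]),
      logical = if (is.logical(df[[col]])) df[[col]] else
        as.logical(as.integer(df[[col]]) != 0L),
      character = as.character(df[[col]])
    )
  }
  problems <- validate_trial_log(df)
  if (nrow(problems) > 0) {
    if (validate) {
      stop("trial log fails validation (", nrow(problems), " problems), e.g. ",
           problems$problem[1], " at row ", problems$row[1],
           call. = FALSE)
    }
    attr(df, "problems") <- problems
  }
  class(df) <- c("trial_log", "data.frame")
  df
}

#' Round-trip simulation parameters through JSON
#'
#' @param params A [sim_params()].
#' @param path JSON path.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a [sim_params()].
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  payload <- unclass(params)
  # per-type vectors become JSON objects so the type names survive
  payload$base_latency <- as.list(payload$base_latency)
  payload$error_hazard <- as.list(payload$error_hazard)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$base_latency <- unlist(raw$base_latency)
  raw$error_hazard <- unlist(raw$error_hazard)
  do.call(sim_params, raw)
}

#' Replicate the analysis from deposited raw data
#'
#' Runs the full study analysis on externally deposited trial data (e.g. the
#' study's public repository, downloaded by the user), adapting its column
#' schema via a mapping config. Because it is not stated whether the
#' published list latencies include the result-entry interval, the analysis
#' is run under both conventions and both reports are returned.
#'
#' @param osf_dir Directory holding the downloaded raw-data CSV(s).
#' @param study 1 or 2; used to locate a file whose name contains
#'   `study<study>` (if several CSVs are present).
#' @param schema_map Column mapping as in [read_trial_csv()].
#' @param config Base [measurement_config()].
#' @return A list of class `decadd_replication` with elements
#'   `entry_excluded` and `entry_included` (two `decadd_report`s) and
#'   `source` (the file used).
#' @export
decadd_replicate <- function(osf_dir, study, schema_map = NULL,
                             config = measurement_config()) {
  if (!dir.exists(osf_dir)) {
    stop("raw-data directory not found: ", osf_dir,
         "; download the deposited data first", call. = FALSE)
  }
  files <- list.files(osf_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no CSV files in ", osf_dir, call. = FALSE)
  hit <- grep(paste0("study", study), basename(files), ignore.case = TRUE)
  file <- if (length(hit)) files[hit[1]] else files[1]
  log <- read_trial_csv(file, schema_map = schema_map)
  cfg_in <- config
  cfg_in$include_entry <- TRUE
  cfg_ex <- config
  cfg_ex$include_entry <- FALSE
  structure(
    list(entry_excluded = run_study_analysis(log, study, cfg_ex),
         entry_included = run_study_analysis(log, study, cfg_in),
         source = file),
    class = "decadd_replication"
  )
}

#' @method print decadd_replication
#' @export
print.decadd_replication <- function(x, ...) {
  cat("Replication from:", x$source, "\n")
  cat("-- convention: list latency excludes the entry interval --\n")
  print(x$entry_excluded)
  cat("\n-- convention: list latency includes the entry interval --\n")
  print(x$entry_included$list_table, digits = 4)
  invisible(x)
}
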