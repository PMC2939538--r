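#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file and resolves it against the
#' default parameter set: omitted keys keep their defaults, unknown keys
#' are an error naming the offending key. Lookup tables are given as
#' two-column lists/arrays of (x, y) knots. Besides model parameters the
#' file may carry the run settings `days`, `seed` and `protocol` (one of
#' `"control"`, `"saline"`, `"furosemide"`, `"forced-drink"`,
#' `"no-icf-exchange"`).
#'
#' @param path path to the configuration file.
#' @return A list of class `hh_config`: `params` ([hh_params()]),
#'   `protocol` name, `days`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  run <- list(days = raw$days %||% 20L,
              seed = raw$seed %||% 1L,
              protocol = raw$protocol %||% "control")
  raw$days <- raw$seed <- raw$protocol <- NULL
  known <- names(formals(hh_params))
  known <- setdiff(known, "...")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (nm in grep("_table$", names(raw), value = TRUE))
    raw[[nm]] <- as_knot_matrix(raw[[nm]], nm)
  for (nm in c("circadian_avp", "drinking", "gut")) {
    if (!is.null(raw[[nm]])) {
      defaults <- eval(formals(hh_params)[[nm]])
      bad <- setdiff(names(raw[[nm]]), names(defaults))
      if (length(bad))
        stop("unknown key(s) in '", nm, "': ", paste(bad, collapse = ", "))
      defaults[names(raw[[nm]])] <- raw[[nm]]
      raw[[nm]] <- defaults
    }
  }
  params <- do.call(hh_params, raw)
  out <- c(list(params = params), run)
  class(out) <- "hh_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_knot_matrix <- function(x, name) {
  m <- if (is.matrix(x)) x
  else if (is.data.frame(x)) as.matrix(x)
  else if (is.list(x) && length(x) == 2L && !is.null(x$x))
    # YAML 1.1 reads a bare `y:` key as TRUE, so take "the element that is
    # not x" as the ordinates
    cbind(x = unlist(x$x),
          y = unlist(x[[setdiff(seq_along(x), which(names(x) == "x"))]]))
  else if (is.list(x)) do.call(rbind, lapply(x, unlist))
  else stop("cannot interpret table '", name, "'")
  if (ncol(m) != 2L) stop("table '", name, "' must have two columns")
  colnames(m) <- c("x", "y")
  storage.mode(m) <- "double"
  check_knot_table(m, name)
}

#' Build the protocol named in a configuration
#'
#' @param config an [load_config()] result (or a protocol name string).
#' @param days run length, days.
#' @return An [hh_protocol()].
#' @export
config_protocol <- function(config, days = NULL) {
  name <- if (is.character(config)) config else config$protocol
  if (is.null(days))
    days <- if (is.character(config)) 1L else config$days
  switch(name,
         control = hh_protocol(days),
         saline = saline_challenge(days = max(2, days)),
         furosemide = furosemide_challenge(days = max(2, days)),
         `forced-drink` = forced_drink_protocol(days),
         `no-icf-exchange` = icf_block_protocol(days),
         stop("unknown protocol preset: ", name))
}

#' Write simulation outputs
#'
#' The per-minute series goes to a CSV file (RFC-4180-style, with a
#' leading `#` comment line giving the units and the clock time written
#' both as minute index and HH:MM); the summary goes to JSON.
#'
#' @param series an `hh_series`.
#' @param summary an `hh_summary` (or `NULL` to skip).
#' @param csv_path,json_path output paths (`NULL` skips either file).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(series, summary = NULL, csv_path = NULL,
                          json_path = NULL) {
  written <- character(0)
  if (!is.null(csv_path)) {
    df <- as.data.frame(series)
    df$clock <- sprintf("%02d:%02d", df$tod %/% 60, df$tod %% 60)
    df <- df[, c("t_min", "clock", setdiff(names(df), c("t_min", "clock")))]
    con <- file(csv_path, "w")
    writeLines(paste("# units: volumes ml, concentrations mmol/L, AVP",
                     "pg/ml, flows ml/min, sodium mmol; minute 0 = 08:00"),
               con)
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       qmethod = "double")
    close(con)
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    if (is.null(summary)) stop("a summary is required for JSON output")
    payload <- list(
      days = summary$days,
      mean = as.list(summary$mean),
      sd = as.list(summary$sd),
      maintenance_avp = if (!is.null(summary$maintenance_avp))
        as.list(summary$maintenance_avp),
      phases = if (!is.null(summary$phases)) list(
        restoration_onset = summary$phases$restoration_onset,
        maintenance_onset = summary$phases$maintenance_onset,
        maintenance_threshold = summary$phases$maintenance_threshold),
      seed = attr(series, "seed")
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, json_path)
  }
  invisible(written)
}

#' Read back a series CSV
#'
#' Inverse of the CSV branch of [write_outputs()].
#'
#' @param path CSV path.
#' @return A data frame with the numeric series columns.
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
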