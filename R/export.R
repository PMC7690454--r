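#' Write a timecourse to tidy CSV and/or JSON
#'
#' Works for both [estimate_probabilities()] results (columns `time`,
#' `node`, `probability`) and [run_population()] results (columns
#' `window_time`, `quantity`, `value`).
#'
#' @param x A `bp_timecourse` or `bp_pop_timecourse`.
#' @param csv,json Optional file paths; each format is written when its
#'   path is given.
#' @return The tidy data frame, invisibly.
#' @export
write_timecourse <- function(x, csv = NULL, json = NULL) {
  df <- as.data.frame(x)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, dataframe = "columns", digits = NA)
  invisible(df)
}

#' Write a scenario to a JSON overlay file
#' @param scenario A [bp_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(list(name = scenario$name, edits = scenario$edits),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a scenario from a JSON overlay file
#' @param path Path to a file written by [write_scenario()].
#' @return A [bp_scenario()].
#' @export
read_scenario <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  bp_scenario(doc$name, doc$edits)
}

#' Write the shipped model definition files
#'
#' Serializes a model bundle to `<stem>.bnd`, `<stem>.cfg` and (when the
#' model has population features) `<stem>.upp` using the canonical writer.
#'
#' @param model A [bp_model()].
#' @param stem Path stem (without extension).
#' @return Character vector of the files written, invisibly.
#' @export
write_model_files <- function(model, stem) {
  txt <- write_model(model$network, model$initial, model$settings)
  files <- character(0)
  for (ext in names(txt)) {
    f <- paste0(stem, ".", ext)
    writeLines(txt[[ext]], f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Locate a shipped model definition file
#' @param name Model name (`"phenomenological"` or `"extended"`).
#' @return Named character vector of file paths (`bnd`, `cfg`, `upp`).
#' @export
icd_model_files <- function(name = c("phenomenological", "extended")) {
  name <- match.arg(name)
  dir <- system.file("extdata", "models", package = "boolpop")
  out <- c(bnd = file.path(dir, paste0(name, ".bnd")),
           cfg = file.path(dir, paste0(name, ".cfg")),
           upp = file.path(dir, paste0(name, ".upp")))
  if (!all(file.exists(out))) stop("shipped model files not found", call. = FALSE)
  out
}
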