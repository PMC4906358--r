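# Delimited-text and JSON serialization of the package's tables and
# parameter objects. All files are plain text with a versioned schema tag.

.SCHEMA_VERSION <- "predinf-1"

#' Write / read task and behaviour tables as CSV
#'
#' Plain CSV with a `# schema:` comment line. Task tables carry
#' `block, trial, helicopter, bag, noise_sd, is_changepoint, is_catch,
#' is_gold`; behaviour tables `block, trial, bucket, ...`.
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @return `read_table_csv` returns the data.frame; writers return `path`
#'   invisibly.
#' @export
write_table_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", .SCHEMA_VERSION), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Serialize flexible-model parameters to JSON
#'
#' Parameter vectors are written with explicit names and an encoding note
#' (uncertainty underestimation is stored in log units).
#'
#' @param params A [flexible_params()] object.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "flexible_params"))
  x <- unclass(params)
  x$encoding <- list(log_uu = "log", schema = .SCHEMA_VERSION)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  flexible_params(
    hazard = x$hazard, surprise_sens = x$surprise_sens, log_uu = x$log_uu,
    heli_cue_sd = x$heli_cue_sd, noise_scale = x$noise_scale,
    noise_offset = x$noise_offset,
    noise_shape = if (is.null(x$noise_shape)) NA_real_ else x$noise_shape,
    update_variability = x$update_variability,
    lr_variability = x$lr_variability)
}

#' Write a fit result to JSON
#'
#' @param fit A `fit_result` from [fit_subject()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
fit_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  x <- unclass(fit)
  x$params <- if (is.null(fit$params)) NULL else unclass(fit$params)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null", pretty = TRUE),
             path)
  invisible(path)
}

# deterministic polynomial content hash (mod 2^31 - 1) of a character
# vector; used for manifest fingerprints without binary serialization
.content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
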