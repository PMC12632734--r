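#' Write a session bundle to disk
#'
#' A session bundle is a directory of three columnar files — `spikes`,
#' `trials`, `units` (CSV by default, Parquet when the arrow package is
#' available) — plus `session.json` holding the epoch specification, any
#' generator ground truth, and provenance.
#'
#' @param ds A [spike_dataset()].
#' @param path Bundle directory (created if needed).
#' @param format `"csv"` or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(ds, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "spike_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  writer <- switch(format,
    csv = function(df, f) utils::write.csv(df, paste0(f, ".csv"),
                                           row.names = FALSE),
    parquet = function(df, f) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("parquet output requires the arrow package")
      }
      arrow::write_parquet(df, paste0(f, ".parquet"))
    })
  writer(ds$spikes, file.path(path, "spikes"))
  writer(ds$trials, file.path(path, "trials"))
  writer(ds$units, file.path(path, "units"))
  meta <- list(epochs = ds$epochs,
               areas = as.list(table(ds$units$area)),
               generator = paste0("wmstates ", as.character(utils::packageVersion("wmstates"))))
  truth <- attr(ds, "truth")
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a session bundle
#'
#' Loads `spikes`, `trials` and `units` (CSV or Parquet, auto-detected by
#' extension) plus `session.json` from a bundle directory and returns a
#' validated [spike_dataset()]; cue locations from a many-location task
#' variant are grouped to the 8 canonical angles.
#'
#' @param path Bundle directory written by [write_session()].
#' @return A [spike_dataset()] (with attribute `truth` when the bundle
#'   records generator ground truth).
#' @export
read_session <- function(path) {
  read_one <- function(stem) {
    csv <- file.path(path, paste0(stem, ".csv"))
    pq <- file.path(path, paste0(stem, ".parquet"))
    if (file.exists(csv)) {
      as_tibble(utils::read.csv(csv))
    } else if (file.exists(pq)) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("parquet bundle requires the arrow package")
      }
      as_tibble(arrow::read_parquet(pq))
    } else {
      abort(paste0("bundle file missing: ", stem, ".(csv|parquet) in ", path))
    }
  }
  spikes <- read_one("spikes")
  trials <- read_one("trials")
  units <- read_one("units")
  meta_file <- file.path(path, "session.json")
  epochs <- odr_epochs()
  truth <- NULL
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    if (!is.null(meta$epochs)) epochs <- as_tibble(meta$epochs)
    if (!is.null(meta$truth)) truth <- as_tibble(meta$truth)
  }
  ds <- spike_dataset(spikes, trials, units, epochs = epochs)
  if (!is.null(truth)) attr(ds, "truth") <- truth
  ds
}
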