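CONTAINER_SCHEMA <- "peristalmap/1"

#' Save or load the single-file analysis container
#'
#' `save_container()` writes any collection of pipeline products (a `dpmap`,
#' state maps, masks, event tables, metadata) losslessly to one file;
#' `load_container()` restores them. The file carries a schema-version tag so
#' stale files fail cleanly rather than half-loading. Event and bolus tables
#' can additionally be exported as CSV with [export_events_csv()].
#'
#' @param object Any R object or named list of pipeline products.
#' @param path File path to write to / read from.
#' @return `load_container()` returns the stored object; `save_container()`
#'   returns `path` invisibly.
#' @export
save_container <- function(object, path) {
  saveRDS(list(schema = CONTAINER_SCHEMA, payload = object), path)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read container '", path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$schema, CONTAINER_SCHEMA))
    stop("container schema mismatch: expected '", CONTAINER_SCHEMA, "'")
  obj$payload
}

#' Export an event or bolus table to CSV
#'
#' @param table A data frame (as returned by [summarize_events()]'s `table`
#'   field or [bolus_table()]).
#' @param path Output CSV path.
#' @export
export_events_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
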