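# Plain-text I/O for every table the pipeline consumes or emits. All tables
# are CSV with documented headers; metadata travels as JSON sidecars.

#' Write / read a tracked-cell table
#'
#' Columns: `strain`, `chamber`, `cell`, `founder`, `birth` (h), `rate` (1/h),
#' `depart` (h; empty when the cell never leaves).
#'
#' @param tracks a track table (see [filter_tracks()]).
#' @param path CSV path.
#' @return `write_tracks_csv` returns `path` invisibly; `read_tracks_csv`
#'   returns the validated data frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  check_track_table(tracks)
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) stop("read_tracks_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("read_tracks_csv: empty table in ", path)
  check_track_table(df)
  if (!("depart" %in% names(df))) df$depart <- NA_real_
  df
}

#' Write field snapshots as CSV matrices with a JSON sidecar
#'
#' One CSV per field (plain matrix, no headers) plus `<prefix>_meta.json`
#' recording the lattice spec, the snapshot time, and any extra parameters.
#'
#' @param fields a `field_set`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param time snapshot time stamp (h).
#' @param params optional named list stored in the sidecar.
#' @return Invisible character vector of the files written.
#' @export
write_fields_csv <- function(fields, dir, prefix = "fields", time = NA_real_,
                             params = list()) {
  stopifnot(inherits(fields, "field_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (f in c("P", "E", "O")) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, f))
    utils::write.table(fields[[f]], p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, p)
  }
  meta <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(
    list(spec = unclass(fields$spec), time = time, params = params),
    meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, meta))
}

#' Write a sweep result as tidy CSV plus JSON metadata
#'
#' @param sweep a `sweep_result`.
#' @param path CSV path; the metadata sidecar replaces the extension by
#'   `.json`.
#' @return Invisible character vector of the files written.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.csv(sweep$results, path, row.names = FALSE, quote = FALSE)
  meta <- sub("\\.csv$", ".json", path)
  grids <- sweep[intersect(names(sweep), c("rho_grid", "kenz_grid", "drel_grid"))]
  jsonlite::write_json(c(list(kind = sweep$kind), grids,
                         list(base_seed = sweep$base$seed)),
                       meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(path, meta))
}

#' Write / read long-format OD curves
#'
#' Columns: `strain`, `replicate`, `condition`, `time` (h), `od`.
#' @param curves data frame as produced by [gen_od_curves()].
#' @param path CSV path.
#' @export
write_od_csv <- function(curves, path) {
  need <- c("strain", "replicate", "condition", "time", "od")
  miss <- setdiff(need, names(curves))
  if (length(miss)) stop("write_od_csv: missing columns: ",
                         paste(miss, collapse = ", "))
  utils::write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_od_csv
#' @export
read_od_csv <- function(path) {
  if (!file.exists(path)) stop("read_od_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "replicate", "condition", "time", "od")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_od_csv: missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("read_od_csv: empty table in ", path)
  df
}

# Build a sim_config from a (possibly partial) nested list, rejecting unknown
# keys with a field-level message.
sim_config_from_list <- function(conf) {
  known_top <- c("lattice", "transport", "depoly", "kinetics", "rho",
                 "duration", "dt", "seed", "snapshot_times")
  unknown <- setdiff(names(conf), known_top)
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  take <- function(block, builder, fields) {
    args <- conf[[block]]
    if (is.null(args)) return(builder())
    bad <- setdiff(names(args), fields)
    if (length(bad))
      stop(sprintf("config: unknown key(s) in '%s': %s", block,
                   paste(bad, collapse = ", ")))
    if (!is.null(args$boundary)) args$boundary <- unlist(args$boundary)
    do.call(builder, args)
  }
  spec <- take("lattice", lattice_spec,
               c("n_rows", "n_cols", "spacing", "boundary", "closed"))
  transport <- take("transport", transport_params,
                    c("D_P", "D_E", "D_O", "D_rel"))
  depoly <- take("depoly", depoly_params, c("k_cat", "K_P", "conv"))
  kinetics <- take("kinetics", kinetic_params,
                   c("K_enz", "mu_max", "K_m", "Y", "b_conv"))
  args <- list(spec = spec, transport = transport, depoly = depoly,
               kinetics = kinetics)
  for (k in c("rho", "duration", "dt", "seed", "snapshot_times"))
    if (!is.null(conf[[k]])) args[[k]] <- conf[[k]]
  do.call(sim_config, args)
}

#' Read a simulation configuration from JSON
#'
#' Nested JSON with optional blocks `lattice`, `transport`, `depoly`,
#' `kinetics` and top-level `rho`, `duration`, `dt`, `seed`,
#' `snapshot_times`; omitted entries take package defaults, unknown keys are
#' rejected with a field-level message.
#'
#' @param path JSON file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("read_sim_config: no such file: ", path)
  conf <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config_from_list(conf)
}
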