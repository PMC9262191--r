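# Analysis project container: per-cell feature time series, single features,
# synchronization states and metadata, with lossless persistence, project
# fusion and spreadsheet export.

.PROJECT_SCHEMA <- "mitotraj-project"
.PROJECT_VERSION <- 1L

#' Create an analysis project
#'
#' A project holds one entry per extracted cell (trajectory): metadata keys,
#' per-frame centroids, the feature time-series matrix, single features and
#' the synchronization states, plus a global feature-name registry and a
#' configuration snapshot. After trajectory extraction every cell has the
#' identical window length, and every time series that length.
#'
#' @param cells list of cell entries (see [run_pipeline()]); each needs at
#'   least `id`, `metadata`, `ts` (frames x features matrix), `single`
#'   (named numeric), `sync`.
#' @param config named list snapshotting the parameters used.
#' @return object of class `cell_project`.
#' @export
cell_project <- function(cells = list(), config = list()) {
  ts_features <- if (length(cells)) colnames(cells[[1]]$ts) else character()
  single_features <- if (length(cells)) names(cells[[1]]$single) else character()
  nf <- if (length(cells)) nrow(cells[[1]]$ts) else 0L
  for (cell in cells) {
    if (!identical(colnames(cell$ts), ts_features))
      stop_mitotraj("cell '", cell$id, "' has a different feature registry")
    if (nrow(cell$ts) != nf)
      stop_mitotraj("cell '", cell$id, "' has window length ", nrow(cell$ts),
                    ", expected ", nf)
    if (!identical(names(cell$single), single_features))
      stop_mitotraj("cell '", cell$id, "' has different single features")
  }
  names(cells) <- vapply(cells, `[[`, "", "id")
  structure(list(version = .PROJECT_VERSION,
                 ts_features = ts_features,
                 single_features = single_features,
                 window_length = nf,
                 config = config,
                 cells = cells),
            class = "cell_project")
}

#' @export
print.cell_project <- function(x, ...) {
  cat("cell_project: ", length(x$cells), " cell(s), window ",
      x$window_length, " frames, ", length(x$ts_features),
      " time-series features, ", length(x$single_features),
      " single features\n", sep = "")
  nsync <- sum(vapply(x$cells, function(cell) isTRUE(cell$sync$valid), TRUE))
  cat("  synchronized: ", nsync, "/", length(x$cells), "\n", sep = "")
  invisible(x)
}

#' Save / load a project
#'
#' Lossless round trip of all arrays, strings and configuration via native
#' serialization, with an embedded schema tag and version so that truncated
#' or foreign files are rejected with a clear error.
#'
#' @param project a [cell_project()].
#' @param path file path.
#' @return `load_project` returns the project; `save_project` its path,
#'   invisibly.
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "cell_project"))
  saveRDS(list(schema = .PROJECT_SCHEMA, version = .PROJECT_VERSION,
               project = project), path)
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  if (!file.exists(path)) stop_mitotraj("project file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_mitotraj("corrupt or unreadable project file '", path, "': ",
                  conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$schema, .PROJECT_SCHEMA))
    stop_mitotraj("'", path, "' is not a mitotraj project file")
  if (!identical(obj$version, .PROJECT_VERSION))
    stop_mitotraj("project schema version ", obj$version,
                  " does not match this package (", .PROJECT_VERSION, ")")
  obj$project
}

#' Fuse several projects into one
#'
#' Projects obtained for different positions can be fused into a single
#' project for joint selection and statistics. Feature registries and window
#' lengths must match exactly; per-cell metadata is preserved verbatim and
#' the fused cell count is the sum of the inputs. Clashing cell ids are
#' disambiguated with a position prefix. Fusion is associative up to cell
#' ordering.
#'
#' @param projects list of [cell_project()] objects (a single project is
#'   returned unchanged).
#' @return the fused project.
#' @export
fuse_projects <- function(projects) {
  if (inherits(projects, "cell_project")) return(projects)
  stopifnot(is.list(projects), length(projects) >= 1L)
  if (length(projects) == 1L) return(projects[[1]])
  ref <- projects[[1]]
  for (i in seq_along(projects)[-1]) {
    p <- projects[[i]]
    if (!identical(p$ts_features, ref$ts_features) ||
        !identical(p$single_features, ref$single_features)) {
      diffs <- c(setdiff(p$ts_features, ref$ts_features),
                 setdiff(ref$ts_features, p$ts_features),
                 setdiff(p$single_features, ref$single_features),
                 setdiff(ref$single_features, p$single_features))
      stop_mitotraj("feature registries differ between projects: ",
                    paste(unique(diffs), collapse = ", "))
    }
    if (!identical(p$window_length, ref$window_length))
      stop_mitotraj("window lengths differ: ", p$window_length, " vs ",
                    ref$window_length)
  }
  all_cells <- list()
  for (i in seq_along(projects)) {
    for (cell in projects[[i]]$cells) {
      if (cell$id %in% names(all_cells)) {
        base <- paste0("p", i, "_", cell$id)
        id <- base
        k <- 1L
        while (id %in% names(all_cells)) {
          k <- k + 1L
          id <- paste0(base, "_", k)
        }
        cell$id <- id
      }
      all_cells[[cell$id]] <- cell
    }
  }
  out <- cell_project(unname(all_cells), config = ref$config)
  out
}

#' Export selected cells' features as spreadsheet files
#'
#' Writes a long-format time-series table (`cell`, `frame`, `feature`,
#' `value` plus the metadata columns) and a single-feature table (`cell`,
#' `feature`, `value` plus metadata) as CSV.
#'
#' @param project a [cell_project()].
#' @param selection character vector of cell ids (see [select_cells()]);
#'   must be non-empty.
#' @param path_prefix output prefix; writes `<prefix>_timeseries.csv` and
#'   `<prefix>_single.csv`.
#' @return named character vector of the written paths, invisibly.
#' @export
export_features <- function(project, selection, path_prefix) {
  stopifnot(inherits(project, "cell_project"))
  if (length(selection) == 0L)
    stop_mitotraj("empty selection: nothing to export")
  missing_ids <- setdiff(selection, names(project$cells))
  if (length(missing_ids))
    stop_mitotraj("unknown cell id(s): ", paste(missing_ids, collapse = ", "))
  meta_keys <- unique(unlist(lapply(project$cells[selection],
                                    function(cell) names(cell$metadata))))
  long <- do.call(rbind, lapply(selection, function(id) {
    cell <- project$cells[[id]]
    nf <- nrow(cell$ts)
    nfeat <- ncol(cell$ts)
    d <- data.frame(cell = id,
                    frame = rep(seq_len(nf), nfeat),
                    feature = rep(colnames(cell$ts), each = nf),
                    value = sprintf("%.17g", as.numeric(cell$ts)))
    for (k in meta_keys) d[[k]] <- unname(cell$metadata[k])
    d
  }))
  single <- do.call(rbind, lapply(selection, function(id) {
    cell <- project$cells[[id]]
    d <- data.frame(cell = id, feature = names(cell$single),
                    value = sprintf("%.17g", as.numeric(cell$single)))
    for (k in meta_keys) d[[k]] <- unname(cell$metadata[k])
    d
  }))
  paths <- c(timeseries = paste0(path_prefix, "_timeseries.csv"),
             single = paste0(path_prefix, "_single.csv"))
  write.csv(long, paths["timeseries"], row.names = FALSE)
  write.csv(single, paths["single"], row.names = FALSE)
  invisible(paths)
}
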