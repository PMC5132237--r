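#' Construct a single-cell life history
#'
#' A `cell_life_history` holds one mother cell's per-replicative-age series:
#' cross-sectional area just before each budding event, the elapsed time of
#' that measurement relative to the first observed G1, and optionally the
#' background-corrected average fluorescence intensity of a reporter.
#' Replicative age runs 1..K; the size of the cell at death is not part of
#' the series, so K equals the number of completed divisions (the
#' replicative lifespan when death was observed).
#'
#' @param cell_id unique identifier of the cell within its dataset.
#' @param sizes numeric vector of cross-sectional areas (um^2), one per
#'   recorded replicative age; all positive.
#' @param times numeric vector of elapsed hours since the first observed G1,
#'   same length as `sizes`, strictly increasing with `times[1] == 0`.
#' @param avg_fluor optional numeric vector of average fluorescence
#'   intensities (AU), same length as `sizes`, all non-negative.
#' @param death_observed logical; `FALSE` marks a censored cell (washed out
#'   before death). Curated datasets contain only death-observed cells.
#' @param experiment_id optional provenance label.
#'
#' @return an object of class `cell_life_history`.
#' @seealso [compute_rls()], [life_history_dataset()]
#' @export
cell_life_history <- function(cell_id, sizes, times, avg_fluor = NULL,
                              death_observed = TRUE, experiment_id = NA_character_) {
  cell <- structure(
    list(cell_id = as.character(cell_id),
         experiment_id = as.character(experiment_id),
         sizes = as.numeric(sizes),
         times = as.numeric(times),
         avg_fluor = if (!is.null(avg_fluor)) as.numeric(avg_fluor),
         death_observed = isTRUE(death_observed)),
    class = "cell_life_history")
  validate_cell(cell)
  cell
}

#' Validate a cell life history
#'
#' Enforces the series invariants: equal lengths, strictly increasing times
#' starting at 0, positive sizes, non-negative fluorescence. Errors name the
#' offending `cell_id`.
#'
#' @param cell a [cell_life_history()].
#' @return the cell, invisibly, if valid.
#' @export
validate_cell <- function(cell) {
  id <- cell$cell_id
  k <- length(cell$sizes)
  if (k < 1L)
    stop("cell '", id, "': empty series", call. = FALSE)
  if (length(cell$times) != k)
    stop("cell '", id, "': sizes and times differ in length (",
         k, " vs ", length(cell$times), ")", call. = FALSE)
  if (anyNA(cell$sizes) || anyNA(cell$times))
    stop("cell '", id, "': interior missing values are not allowed", call. = FALSE)
  if (!all(is.finite(cell$sizes)) || !all(is.finite(cell$times)))
    stop("cell '", id, "': non-finite values", call. = FALSE)
  if (any(cell$sizes <= 0))
    stop("cell '", id, "': non-positive size entries", call. = FALSE)
  if (k > 1 && any(diff(cell$times) <= 0))
    stop("cell '", id, "': times are not strictly increasing", call. = FALSE)
  if (!is.null(cell$avg_fluor)) {
    if (length(cell$avg_fluor) != k)
      stop("cell '", id, "': fluorescence series length mismatch", call. = FALSE)
    if (anyNA(cell$avg_fluor) || any(cell$avg_fluor < 0))
      stop("cell '", id, "': invalid fluorescence values", call. = FALSE)
  }
  invisible(cell)
}

#' Assemble a cohort of cell life histories
#'
#' @param cells list of [cell_life_history()] objects with unique ids.
#' @param name short dataset label.
#' @param source provenance string (file path or `"synthetic"`).
#' @return an object of class `life_history_dataset`.
#' @export
life_history_dataset <- function(cells, name = "dataset", source = "memory") {
  if (length(cells) < 1L) stop("a dataset needs at least one cell", call. = FALSE)
  lapply(cells, validate_cell)
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate cell_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  structure(list(cells = cells, name = name, source = source),
            class = "life_history_dataset")
}

#' Replicative lifespan of a cell
#'
#' The replicative lifespan (RLS) is the number of divisions a mother cell
#' completes. Each recorded G1 entry immediately precedes one budding event
#' and the death frame is excluded from the series, so the RLS equals the
#' series length K.
#'
#' @param cell a [cell_life_history()].
#' @return integer count of divisions.
#' @export
compute_rls <- function(cell) {
  length(cell$sizes)
}

#' Vector of lifespans over a dataset
#' @param dataset a [life_history_dataset()].
#' @return named integer vector, one RLS per cell, in dataset order.
#' @export
dataset_rls <- function(dataset) {
  rls <- vapply(dataset$cells, function(c) length(c$sizes), integer(1))
  setNames(rls, vapply(dataset$cells, function(c) c$cell_id, character(1)))
}

#' Summarise a life-history dataset
#'
#' @param dataset a [life_history_dataset()].
#' @return a list of class `cellspan_summary` with `n_cells`, `n_entries`
#'   (total non-missing size measurements), `rls_median`, `rls_min`,
#'   `rls_max`, `start_size_median` (median of the first-G1 sizes, um^2) and
#'   `has_fluorescence`.
#' @export
dataset_summary <- function(dataset) {
  rls <- dataset_rls(dataset)
  starts <- vapply(dataset$cells, function(c) c$sizes[1], numeric(1))
  fl <- vapply(dataset$cells, function(c) !is.null(c$avg_fluor), logical(1))
  structure(list(
    name = dataset$name,
    n_cells = length(dataset$cells),
    n_entries = sum(rls),
    rls_median = median(rls),
    rls_min = min(rls),
    rls_max = max(rls),
    start_size_median = median(starts),
    has_fluorescence = all(fl)
  ), class = "cellspan_summary")
}

#' @export
print.cellspan_summary <- function(x, ...) {
  cat("Life-history dataset '", x$name, "'\n", sep = "")
  cat("  cells:          ", x$n_cells, "\n")
  cat("  data entries:   ", x$n_entries, "\n")
  cat(sprintf("  RLS median:      %g  (range %d-%d)\n",
              x$rls_median, x$rls_min, x$rls_max))
  cat(sprintf("  start size med.: %.2f um^2\n", x$start_size_median))
  cat("  fluorescence:   ", if (x$has_fluorescence) "yes" else "no", "\n")
  invisible(x)
}

#' @export
print.life_history_dataset <- function(x, ...) {
  print(dataset_summary(x))
  invisible(x)
}

#' @export
print.cell_life_history <- function(x, ...) {
  cat("cell '", x$cell_id, "': ", length(x$sizes), " divisions over ",
      sprintf("%.1f", max(x$times)), " h",
      if (!is.null(x$avg_fluor)) ", with fluorescence" else "",
      if (!x$death_observed) " (censored)" else "", "\n", sep = "")
  invisible(x)
}
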