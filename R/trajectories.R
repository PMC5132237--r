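#' Division durations of a cell
#'
#' First differences of the per-age time stamps: `durations[a]` is the
#' length, in hours, of the division taking the cell from replicative age
#' `a` to `a + 1`. The durations telescope back to the total observed time.
#'
#' @param cell a [cell_life_history()] with at least 2 recorded ages.
#' @return object of class `division_profile`: list with `ages` (1..K-1)
#'   and `durations` (hours).
#' @export
division_durations <- function(cell) {
  k <- length(cell$times)
  if (k < 2L)
    stop("cell '", cell$cell_id, "': need at least two ages for durations",
         call. = FALSE)
  structure(list(ages = seq_len(k - 1L), durations = diff(cell$times)),
            class = "division_profile")
}

#' Time needed to reach a replicative age
#'
#' @param cell a [cell_life_history()].
#' @param n target replicative age, `n <= K`.
#' @return hours elapsed from the first observed G1 to the n-th recorded G1
#'   (0 for `n = 1`).
#' @export
time_to_age <- function(cell, n) {
  if (n < 1L || n > length(cell$times))
    stop("cell '", cell$cell_id, "': age ", n, " outside recorded range",
         call. = FALSE)
  cell$times[n]
}

#' Detect the Senescence Entry Point from a division-duration profile
#'
#' Late in life the division durations of a yeast mother cell lengthen
#' abruptly; the onset is the Senescence Entry Point (SEP). The detector
#' formalises the visual "elbow" call: both axes are rescaled to the unit
#' square (hours and divisions are incommensurable), a chord is drawn from
#' the first to the last point of the profile, and the SEP is the interior
#' point with the largest perpendicular distance to the chord on the
#' slowdown side — the side the profile sags towards when durations stay
#' flat before a late rise. Ties break to the earliest age. If no interior
#' point clears the chord by more than `epsilon` (profiles that are linear,
#' or bend the other way), no SEP is called.
#'
#' @param profile a [division_durations()] result (raw durations; spline-
#'   smoothed profiles may be supplied instead if desired).
#' @param epsilon minimum chord distance, in rescaled units, for a call.
#' @return object of class `sep_result`: list with `sep_age` (profile age
#'   of the elbow, `NA` when none) and `chord_distance`.
#' @export
detect_sep <- function(profile, epsilon = 0.02) {
  a <- profile$ages
  d <- profile$durations
  m <- length(d)
  if (m < 3L)
    stop("need at least 3 profile points to detect an elbow", call. = FALSE)
  if (any(d <= 0)) stop("durations must be positive", call. = FALSE)
  xr <- range(a); yr <- range(d)
  if (diff(yr) == 0)  # perfectly flat: chord coincides with the data
    return(structure(list(sep_age = NA_integer_, chord_distance = 0),
                     class = "sep_result"))
  x <- (a - xr[1]) / diff(xr)
  y <- (d - yr[1]) / diff(yr)
  # signed offset from the chord through (x1,y1)-(xm,ym); negative = below
  dx <- x[m] - x[1]; dy <- y[m] - y[1]
  len <- sqrt(dx^2 + dy^2)
  off <- ((x - x[1]) * dy - (y - y[1]) * dx) / len   # >0 below chord here
  interior <- 2:(m - 1L)
  below <- off[interior]
  best <- which(below > epsilon)
  if (!length(best))
    return(structure(list(sep_age = NA_integer_, chord_distance = 0),
                     class = "sep_result"))
  imax <- best[which.max(below[best])]   # which.max takes the earliest tie
  structure(list(sep_age = a[interior[imax]],
                 chord_distance = below[imax]),
            class = "sep_result")
}

#' @export
print.sep_result <- function(x, ...) {
  if (is.na(x$sep_age)) cat("no SEP detected\n")
  else cat(sprintf("SEP at age %d (chord distance %.3f)\n",
                   x$sep_age, x$chord_distance))
  invisible(x)
}

#' Pre/post-SEP masks over replicative ages
#'
#' @param cell a [cell_life_history()].
#' @param sep a [detect_sep()] result for that cell.
#' @return list of two logical vectors over ages 1..K: `pre` (ages strictly
#'   before the SEP; all ages when no SEP was called) and `post` (ages at or
#'   after the SEP). The two masks partition 1..K.
#' @export
split_pre_post_sep <- function(cell, sep) {
  k <- length(cell$sizes)
  ages <- seq_len(k)
  if (is.na(sep$sep_age)) {
    pre <- rep(TRUE, k)
  } else {
    pre <- ages < sep$sep_age
  }
  list(pre = pre, post = !pre)
}

#' Fit a whole cohort: trajectories, folds, durations and SEP calls
#'
#' Runs the per-cell pipeline over a dataset: spline-smooths the size
#' series (and the fluorescence series when present), derives fold-increase
#' values from the fitted sizes, computes division durations, and calls the
#' SEP on each cell's raw duration profile. Cells with fewer than 4
#' recorded ages cannot support an elbow call and are marked `too_short`;
#' they are excluded from SEP-conditional analyses downstream.
#'
#' @param dataset a [life_history_dataset()].
#' @param spar smoothing parameter passed to [fit_smoothing_spline()].
#' @param sep_epsilon chord-distance tolerance for [detect_sep()].
#' @param sep_on_fitted logical; call the SEP on spline-smoothed durations
#'   instead of raw ones (default `FALSE`).
#' @return an object of class `cellspan_cohort`: list with
#'   \describe{
#'     \item{points}{long data frame, one row per (cell, age): `cell_id`,
#'       `age`, `time`, `size_raw`, `size_fit`, `fold`, `fluor_raw`,
#'       `fluor_fit`, `pre_sep`.}
#'     \item{cells}{per-cell data frame: `cell_id`, `rls`, `death_observed`,
#'       `start_size`, `end_size`, `sep_age`, `sep_status`,
#'       `sep_chord_distance`, `sep_size` (fitted size at the SEP age).}
#'     \item{spar, name}{fit provenance.}
#'   }
#' @export
fit_cohort <- function(dataset, spar = 0.5, sep_epsilon = 0.02,
                       sep_on_fitted = FALSE) {
  has_fluor <- all(vapply(dataset$cells, function(c) !is.null(c$avg_fluor),
                          logical(1)))
  pts <- vector("list", length(dataset$cells))
  per <- vector("list", length(dataset$cells))
  for (i in seq_along(dataset$cells)) {
    cell <- dataset$cells[[i]]
    k <- length(cell$sizes)
    ages <- seq_len(k)
    sfit <- fit_smoothing_spline(ages, cell$sizes, spar)
    fold <- normalize_to_start(sfit)$values
    ffit <- rep(NA_real_, k)
    if (has_fluor)
      ffit <- fit_smoothing_spline(ages, cell$avg_fluor, spar)$values

    sep_age <- NA_integer_; sep_dist <- NA_real_
    if (k < 4L) {
      sep_status <- "too_short"
    } else {
      prof <- division_durations(cell)
      if (sep_on_fitted && k >= 5L)
        prof$durations <- fit_smoothing_spline(prof$ages, prof$durations,
                                               spar)$values
      sep <- detect_sep(prof, epsilon = sep_epsilon)
      sep_age <- sep$sep_age
      sep_dist <- sep$chord_distance
      sep_status <- if (is.na(sep_age)) "none" else "detected"
    }
    pre <- if (is.na(sep_age)) rep(TRUE, k) else ages < sep_age

    pts[[i]] <- data.frame(
      cell_id = cell$cell_id, age = ages, time = cell$times,
      size_raw = cell$sizes, size_fit = sfit$values, fold = fold,
      fluor_raw = if (has_fluor) cell$avg_fluor else NA_real_,
      fluor_fit = ffit, pre_sep = pre,
      stringsAsFactors = FALSE)
    per[[i]] <- data.frame(
      cell_id = cell$cell_id, rls = k, death_observed = cell$death_observed,
      start_size = cell$sizes[1], end_size = cell$sizes[k],
      sep_age = sep_age, sep_status = sep_status,
      sep_chord_distance = sep_dist,
      sep_size = if (!is.na(sep_age)) sfit$values[sep_age] else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(points = do.call(rbind, pts), cells = do.call(rbind, per),
                 spar = spar, name = dataset$name,
                 has_fluorescence = has_fluor),
            class = "cellspan_cohort")
}

#' @export
print.cellspan_cohort <- function(x, ...) {
  cat("fitted cohort '", x$name, "': ", nrow(x$cells), " cells, ",
      nrow(x$points), " points (spar ", x$spar, ")\n", sep = "")
  cat("  SEP calls: ", sum(x$cells$sep_status == "detected"), " detected, ",
      sum(x$cells$sep_status == "none"), " none, ",
      sum(x$cells$sep_status == "too_short"), " too short\n", sep = "")
  invisible(x)
}
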