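#' Pearson product-moment correlation
#'
#' Thin, validating wrapper used by every correlation screen in the
#' package: errors on length mismatch, short series and constant input
#' rather than returning `NA`.
#'
#' @param x,y numeric vectors of equal length, at least 3, neither constant.
#' @return the sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  cor(x, y)
}

# Resolve a feature specification to a column of cohort$points.
feature_column <- function(cohort, feature) {
  if (is.function(feature)) return(feature(cohort$points))
  col <- switch(feature,
                fold_increase = "fold",
                raw_size = "size_raw",
                fitted_size = "size_fit",
                concentration = "fluor_fit",
                raw_concentration = "fluor_raw",
                time = "time",
                stop("unknown feature '", feature, "'", call. = FALSE))
  if (col %in% c("fluor_fit", "fluor_raw") && !cohort$has_fluorescence)
    stop("cohort has no fluorescence channel", call. = FALSE)
  cohort$points[[col]]
}

#' Per-age correlation of a life-history feature with lifespan
#'
#' At each replicative age `a`, the chosen per-cell feature of the cells
#' still alive (and measured) at `a` is correlated with their eventual
#' replicative lifespans. Because late-life values are dominated by the
#' post-SEP burst of enlargement, the screen can optionally drop, at each
#' age, the cells already past their SEP (`exclude_post_sep`); cells whose
#' profiles were too short for an SEP call are then excluded altogether,
#' while cells with no detectable elbow contribute at every age. Ages with
#' fewer than `min_n` contributing cells are omitted. No multiple-testing
#' adjustment is applied across ages; the series is a descriptive screen.
#'
#' @param cohort a [fit_cohort()] result.
#' @param feature `"fold_increase"` (default), `"raw_size"`,
#'   `"fitted_size"`, `"concentration"`, `"time"`, or a function of the
#'   points table returning one value per row.
#' @param min_n minimum number of cells for an age to be reported.
#' @param exclude_post_sep logical, see above.
#' @return data frame of class `age_correlation_series` with columns `age`,
#'   `n`, `r`.
#' @export
per_age_lifespan_correlation <- function(cohort, feature = "fold_increase",
                                         min_n = 10, exclude_post_sep = FALSE) {
  pts <- cohort$points
  val <- feature_column(cohort, feature)
  rls <- setNames(cohort$cells$rls, cohort$cells$cell_id)
  keep <- rep(TRUE, nrow(pts))
  if (exclude_post_sep) {
    ok_cells <- cohort$cells$cell_id[cohort$cells$sep_status != "too_short"]
    keep <- pts$pre_sep & pts$cell_id %in% ok_cells
  }
  out <- list()
  for (a in sort(unique(pts$age))) {
    sel <- pts$age == a & keep & !is.na(val)
    if (sum(sel) < max(min_n, 3L)) next
    y <- rls[pts$cell_id[sel]]
    x <- val[sel]
    if (sd(x) == 0 || sd(y) == 0) next
    out[[length(out) + 1L]] <- data.frame(age = a, n = sum(sel), r = cor(x, y))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(age = integer(), n = integer(), r = numeric())
  class(res) <- c("age_correlation_series", "data.frame")
  res
}

#' Per-age correlation restricted to long-lived cells
#'
#' The unconditional screen mixes cells that die young with long-lived
#' survivors; restricting to cells that reached at least `min_rls`
#' divisions shows how a feature relates to lifespan among the longer-lived
#' part of the population.
#'
#' @inheritParams per_age_lifespan_correlation
#' @param min_rls keep only cells with RLS at or above this age;
#'   `min_rls = 0` reproduces the unconditional series.
#' @return data frame as in [per_age_lifespan_correlation()].
#' @export
conditional_age_correlation <- function(cohort, feature = "concentration",
                                        min_rls = 0, min_n = 10,
                                        exclude_post_sep = FALSE) {
  keep_ids <- cohort$cells$cell_id[cohort$cells$rls >= min_rls]
  if (length(keep_ids) < 3L)
    stop("fewer than 3 cells reach RLS ", min_rls, call. = FALSE)
  sub <- cohort
  sub$cells <- cohort$cells[cohort$cells$cell_id %in% keep_ids, , drop = FALSE]
  sub$points <- cohort$points[cohort$points$cell_id %in% keep_ids, , drop = FALSE]
  per_age_lifespan_correlation(sub, feature, min_n = min_n,
                               exclude_post_sep = exclude_post_sep)
}

#' Median split of the population at a given age
#'
#' Cells alive at `age` are split at the population median of the chosen
#' feature at that age. The tie rule is strict: cells strictly below the
#' threshold form the `less` group, cells at or above it the `more` group.
#'
#' @inheritParams per_age_lifespan_correlation
#' @param age replicative age of the split.
#' @return object of class `group_split`: list with `age`, `feature`,
#'   `threshold`, `less_ids`, `more_ids`, `n_less`, `n_more`, `degenerate`
#'   (TRUE when every value equals the threshold).
#' @export
median_split_at_age <- function(cohort, age = 5, feature = "fold_increase") {
  pts <- cohort$points
  if (age > max(pts$age))
    stop("no cell reaches age ", age, call. = FALSE)
  val <- feature_column(cohort, feature)
  sel <- pts$age == age & !is.na(val)
  ids <- pts$cell_id[sel]
  v <- val[sel]
  thr <- median(v)
  less <- ids[v < thr]
  more <- ids[v >= thr]
  structure(list(age = age, feature = if (is.function(feature)) "custom" else feature,
                 threshold = thr, less_ids = less, more_ids = more,
                 n_less = length(less), n_more = length(more),
                 degenerate = sd(v) == 0),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("median split at age %d on %s: threshold %.4g, %d below / %d at-or-above%s\n",
              x$age, x$feature, x$threshold, x$n_less, x$n_more,
              if (x$degenerate) " (degenerate: all values tied)" else ""))
  invisible(x)
}

#' Kaplan-Meier survival over replicative age
#'
#' Product-limit estimate of the probability of surviving past each
#' replicative age, with right-censoring support (a censored cell was
#' washed out before death). Without censoring the curve equals the
#' empirical survival function and the median equals the sample median.
#'
#' @param lifespans integer divisions at death or censoring.
#' @param death_observed logical vector (`FALSE` = censored); recycled.
#' @return object of class `survival_curve`: data frame `curve` with `age`,
#'   `n_risk`, `n_event`, `surv`, plus `median_rls` (smallest age at which
#'   survival drops to 0.5 or below) and `n`.
#' @export
km_estimate <- function(lifespans, death_observed = TRUE) {
  if (!length(lifespans)) stop("no observations", call. = FALSE)
  death_observed <- rep_len(as.logical(death_observed), length(lifespans))
  fit <- survival::survfit(
    survival::Surv(lifespans, death_observed) ~ 1, conf.type = "none")
  curve <- data.frame(age = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  med <- curve$age[curve$surv <= 0.5]
  structure(list(curve = curve,
                 median_rls = if (length(med)) min(med) else NA_real_,
                 n = length(lifespans)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve, n = %d, median RLS %g\n", x$n, x$median_rls))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank comparison of lifespan distributions
#' (1-df chi-square, two-sided, no continuity correction).
#'
#' @param lifespans_a,lifespans_b divisions at death/censoring per group.
#' @param events_a,events_b logical death indicators, recycled.
#' @return list of class `cellspan_test`: `method`, `statistic`, `p_value`.
#' @export
logrank_test <- function(lifespans_a, lifespans_b,
                         events_a = TRUE, events_b = TRUE) {
  if (!length(lifespans_a) || !length(lifespans_b))
    stop("both groups must be non-empty", call. = FALSE)
  events_a <- rep_len(as.logical(events_a), length(lifespans_a))
  events_b <- rep_len(as.logical(events_b), length(lifespans_b))
  if (!any(events_a) && !any(events_b))
    stop("no events in either group", call. = FALSE)
  time <- c(lifespans_a, lifespans_b)
  ev <- c(events_a, events_b)
  grp <- rep(c("a", "b"), c(length(lifespans_a), length(lifespans_b)))
  sd_ <- survival::survdiff(survival::Surv(time, ev) ~ grp)
  structure(list(method = "log-rank", statistic = unname(sd_$chisq),
                 p_value = pchisq(unname(sd_$chisq), df = 1, lower.tail = FALSE)),
            class = "cellspan_test")
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided comparison of two samples' distributions. For small inputs
#' (`n + m <= 10`) the exact permutation distribution of the U statistic is
#' enumerated (ties handled by mid-rank scoring of the permuted
#' assignments); larger samples use the normal approximation with tie
#' correction and continuity correction via [stats::wilcox.test()].
#'
#' @param x,y numeric samples, each non-empty.
#' @return list of class `cellspan_test`: `method`, `statistic` (U for the
#'   first sample), `p_value`.
#' @export
ranksum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  n <- length(x); m <- length(y)
  u <- u_statistic(x, y)
  if (n + m <= 10L) {
    pooled <- c(x, y)
    idx <- combn(n + m, n)
    centre <- n * m / 2
    dev <- abs(u - centre)
    us <- apply(idx, 2, function(ii) u_statistic(pooled[ii], pooled[-ii]))
    p <- mean(abs(us - centre) >= dev - 1e-9)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  structure(list(method = method, statistic = u, p_value = p),
            class = "cellspan_test")
}

# U statistic of x against y with 1/2 credit for ties.
u_statistic <- function(x, y) {
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
}

#' @export
print.cellspan_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.3g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Percent difference between two group medians
#'
#' @param median_a,median_b group medians; `median_b` is the reference and
#'   must be positive.
#' @return integer percent, `round(100 * (median_a - median_b) / median_b)`.
#' @export
percent_median_difference <- function(median_a, median_b) {
  if (median_b <= 0) stop("reference median must be positive", call. = FALSE)
  round(100 * (median_a - median_b) / median_b)
}

#' Total reporter fluorescence
#'
#' The average intensity of a fluorescent reporter approximates its
#' concentration; multiplying by the cross-sectional area gives a proxy for
#' the total amount in the cell.
#'
#' @param avg_intensity average fluorescence intensity (AU).
#' @param area cross-sectional area (um^2). Both non-negative; vectorised.
#' @return total fluorescence (AU um^2).
#' @export
total_fluorescence <- function(avg_intensity, area) {
  if (any(avg_intensity < 0, na.rm = TRUE) || any(area < 0, na.rm = TRUE))
    stop("fluorescence and area must be non-negative", call. = FALSE)
  avg_intensity * area
}

#' Concentration-size relation at one age
#'
#' Cross-sectional regression of fitted reporter concentration on fitted
#' cell size over the cells alive at a given age: rapidly enlarging cells
#' dilute their cytosol, so the relation is typically negative at mid ages.
#'
#' @param cohort a [fit_cohort()] result with a fluorescence channel.
#' @param age replicative age at which to compare cells.
#' @param min_n minimum number of cells required.
#' @return list with `age`, `n`, `r` (Pearson) and `slope` (OLS slope of
#'   concentration on size, AU per um^2).
#' @export
concentration_size_relation <- function(cohort, age, min_n = 10) {
  if (!cohort$has_fluorescence)
    stop("cohort has no fluorescence channel", call. = FALSE)
  pts <- cohort$points
  sel <- pts$age == age & !is.na(pts$fluor_fit)
  if (sum(sel) < min_n)
    stop("only ", sum(sel), " cells alive at age ", age, call. = FALSE)
  x <- pts$size_fit[sel]
  y <- pts$fluor_fit[sel]
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input at age ", age, call. = FALSE)
  list(age = age, n = sum(sel), r = cor(x, y),
       slope = unname(coef(lm(y ~ x))[2]))
}

#' Population fold summaries of total and average fluorescence by age
#'
#' For each cell, total fluorescence (intensity x area) and average
#' intensity are expressed as fold change relative to the cell's first G1;
#' the population median of each fold is reported per age. A rising total
#' with a flat-or-falling average is the signature of reporter amounts
#' growing with age while the concentration dilutes.
#'
#' @inheritParams concentration_size_relation
#' @param min_n minimum cells per reported age.
#' @return data frame with `age`, `n`, `total_fold_median`,
#'   `avg_fold_median`.
#' @export
fluorescence_fold_summary <- function(cohort, min_n = 10) {
  if (!cohort$has_fluorescence)
    stop("cohort has no fluorescence channel", call. = FALSE)
  pts <- cohort$points
  tot <- total_fluorescence(pts$fluor_fit, pts$size_fit)
  first <- !duplicated(pts$cell_id)
  tot1 <- setNames(tot[first], pts$cell_id[first])
  avg1 <- setNames(pts$fluor_fit[first], pts$cell_id[first])
  tot_fold <- tot / tot1[pts$cell_id]
  avg_fold <- pts$fluor_fit / avg1[pts$cell_id]
  out <- list()
  for (a in sort(unique(pts$age))) {
    sel <- pts$age == a & is.finite(tot_fold)
    if (sum(sel) < min_n) next
    out[[length(out) + 1L]] <- data.frame(
      age = a, n = sum(sel),
      total_fold_median = median(tot_fold[sel]),
      avg_fold_median = median(avg_fold[sel]))
  }
  do.call(rbind, out)
}
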