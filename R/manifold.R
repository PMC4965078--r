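#' Constant-burst-size manifolds in CV²-versus-mean space
#'
#' A manifold is the hyperbola traced by a promoter whose burst size is
#' fixed while its burst frequency varies: in mRNA (FISH) units
#' `cv2(mean) = B / mean`; in calibrated fluorescence (MESF) units
#' `cv2(mean) = 5000 (B + 1) / mean` (the inverse of the MESF burst-size
#' formula). Curves are strictly decreasing in the mean and ordered by `B`.
#'
#' @param burst_levels numeric burst sizes, one per curve (e.g. `0:12`).
#' @param units `"fish"` or `"mesf"`.
#' @param mesf_per_burst calibration constant for MESF units.
#' @return An object of class `manifold_set`.
#' @export
manifold_set <- function(burst_levels, units = c("fish", "mesf"),
                         mesf_per_burst = 5000) {
  units <- match.arg(units)
  if (any(burst_levels < 0))
    stop("burst levels must be >= 0", call. = FALSE)
  structure(list(burst_levels = sort(unique(burst_levels)), units = units,
                 mesf_per_burst = mesf_per_burst),
            class = "manifold_set")
}

#' @export
print.manifold_set <- function(x, ...) {
  cat(sprintf("manifold set (%s units): burst sizes %s\n", x$units,
              paste(signif(x$burst_levels, 4), collapse = ", ")))
  invisible(x)
}

#' Evaluate manifold curves on a grid of means
#'
#' @param mset a [manifold_set()].
#' @param mean_grid positive means at which to evaluate each curve.
#' @return A long data.frame with columns `B`, `mean_grid`, `cv2`, ready for
#'   plotting or CSV export.
#' @export
manifold_curves <- function(mset, mean_grid) {
  stopifnot(inherits(mset, "manifold_set"))
  if (any(mean_grid <= 0)) stop("mean_grid must be positive", call. = FALSE)
  out <- expand.grid(mean_grid = mean_grid, B = mset$burst_levels,
                     KEEP.OUT.ATTRS = FALSE)
  out$cv2 <- .manifold_cv2(out$B, out$mean_grid, mset)
  out[, c("B", "mean_grid", "cv2")]
}

.manifold_cv2 <- function(B, mean, mset) {
  if (mset$units == "fish") B / mean
  else mset$mesf_per_burst * (B + 1) / mean
}

# burst-size coordinate of a (mean, cv2) point in the set's unit system
.point_burst <- function(mean, cv2, mset) {
  if (mset$units == "fish") cv2 * mean
  else pmax(cv2 * mean / mset$mesf_per_burst - 1, 0)
}

#' Fit the extreme (min/max) burst-size manifolds of a clone panel
#'
#' Returns the pair of hyperbolae bounding a panel in CV²-versus-mean
#' space. Each extreme manifold passes exactly through one clone's
#' (mean, CV²) point, i.e. its level is that clone's burst-size estimate.
#' With `method = "range"` (default) the bounding clones are those with the
#' smallest and largest burst-size estimate, which guarantees every fitted
#' point lies between the two curves. `method = "brightness"` instead takes
#' the dimmest (smallest-mean) and brightest clones; the two choices
#' coincide whenever brightness ranks with burst size, as in the measured
#' clone panels this analysis emulates, but only `"range"` is a bound by
#' construction.
#'
#' @param estimates a `burst_estimates` data.frame (>= 2 clones).
#' @param units unit system of the returned [manifold_set()].
#' @param method `"range"` or `"brightness"` (see Details).
#' @param mesf_per_burst calibration constant for MESF units.
#' @return A list with `B_min`, `B_max`, and `manifolds` (a two-curve
#'   [manifold_set()]).
#' @export
fit_extreme_manifolds <- function(estimates, units = c("fish", "mesf"),
                                  method = c("range", "brightness"),
                                  mesf_per_burst = 5000) {
  units <- match.arg(units)
  method <- match.arg(method)
  if (!is.data.frame(estimates) ||
      !all(c("mean", "burst_size") %in% names(estimates)))
    stop("estimates must contain mean and burst_size columns", call. = FALSE)
  if (nrow(estimates) < 2)
    stop("need at least 2 clones to fit extreme manifolds", call. = FALSE)
  if (method == "range") {
    B_min <- min(estimates$burst_size)
    B_max <- max(estimates$burst_size)
  } else {
    B_min <- estimates$burst_size[which.min(estimates$mean)]
    B_max <- estimates$burst_size[which.max(estimates$mean)]
  }
  list(B_min = B_min, B_max = B_max,
       manifolds = manifold_set(c(B_min, B_max), units = units,
                                mesf_per_burst = mesf_per_burst))
}

#' Log-log regression of CV² on the mean
#'
#' Least-squares fit of `log(cv2) ~ log(mean)` across populations. Points
#' lying on a single constant-burst-size manifold give slope exactly -1
#' and intercept `log(B)`: the inverse noise-mean scaling.
#'
#' @param summaries data.frame with positive `mean` and `cv2` columns
#'   (>= 3 rows).
#' @return List with `slope`, `intercept`, `r` (Pearson correlation of the
#'   log-log points).
#' @export
loglog_slope <- function(summaries) {
  if (!is.data.frame(summaries) ||
      !all(c("mean", "cv2") %in% names(summaries)))
    stop("summaries must contain mean and cv2 columns", call. = FALSE)
  if (nrow(summaries) < 3)
    stop("need at least 3 populations for a log-log fit", call. = FALSE)
  if (any(summaries$mean <= 0) || any(summaries$cv2 <= 0))
    stop("means and cv2 must be positive for a log-log fit", call. = FALSE)
  x <- log(summaries$mean)
  y <- log(summaries$cv2)
  if (max(x) - min(x) < .Machine$double.eps^0.5)
    stop("degenerate mean range: all populations share one mean",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r = stats::cor(x, y))
}

#' Paired before/after perturbation analysis of a clone panel
#'
#' Quantifies how an activating perturbation (e.g. TNF-like stimulation
#' that raises burst frequency) moves a clone panel in CV²-versus-mean
#' space:
#' * `contraction_fraction` — proportion of clones whose mean increased
#'   while CV² decreased (the noise contraction the inverse noise-mean
#'   correlation predicts);
#' * `containment_fraction` — proportion of all points (both conditions)
#'   lying between the extreme manifolds;
#' * an exclusion-region report — points above the `B_max` curve scaled by
#'   `margin` or below the `B_min` curve scaled by `1/margin`, i.e. in the
#'   regions of noise-mean space the bursting model leaves devoid of data;
#' * a per-clone `modulation` call: `"frequency"` when the burst-size
#'   estimate changes by at most `class_threshold` (relative), `"size"`
#'   when it changes more with an increased mean, else `"mixed"`.
#'
#' @param before,after `burst_estimates` data.frames with matching
#'   `clone_id` sets (one condition each).
#' @param manifolds optional result of [fit_extreme_manifolds()]; fitted to
#'   `before` when NULL.
#' @param class_threshold relative burst-size change separating frequency-
#'   from size-modulation (default 0.25).
#' @param margin exclusion-region scale factor beyond the extreme
#'   manifolds (default 1.5).
#' @param units unit system for manifold containment.
#' @return An object of class `perturbation_result`: list with `clones`
#'   (per-clone paired table), `contraction_fraction`,
#'   `containment_fraction`, `exclusion` (counts outside the margin band),
#'   `B_min`, `B_max`.
#' @export
perturbation_analysis <- function(before, after, manifolds = NULL,
                                  class_threshold = 0.25, margin = 1.5,
                                  units = c("fish", "mesf")) {
  units <- match.arg(units)
  for (tbl in list(before, after))
    if (!is.data.frame(tbl) ||
        !all(c("clone_id", "mean", "cv2", "burst_size") %in% names(tbl)))
      stop("before/after must be burst_estimates tables", call. = FALSE)
  missing_after <- setdiff(before$clone_id, after$clone_id)
  missing_before <- setdiff(after$clone_id, before$clone_id)
  if (length(missing_after) || length(missing_before))
    stop("unmatched clones across conditions: ",
         paste(unique(c(missing_after, missing_before)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(before$clone_id) || anyDuplicated(after$clone_id))
    stop("duplicate clone_id within a condition", call. = FALSE)
  after <- after[match(before$clone_id, after$clone_id), , drop = FALSE]

  if (is.null(manifolds))
    manifolds <- fit_extreme_manifolds(before, units = units)
  mset <- manifolds$manifolds
  B_min <- manifolds$B_min
  B_max <- manifolds$B_max

  dB_rel <- (after$burst_size - before$burst_size) / before$burst_size
  mean_up <- after$mean > before$mean
  cv2_down <- after$cv2 < before$cv2
  modulation <- ifelse(abs(dB_rel) <= class_threshold, "frequency",
                       ifelse(mean_up, "size", "mixed"))
  clones <- data.frame(clone_id = before$clone_id,
                       mean_before = before$mean, mean_after = after$mean,
                       cv2_before = before$cv2, cv2_after = after$cv2,
                       B_before = before$burst_size,
                       B_after = after$burst_size,
                       delta_B_rel = dB_rel,
                       mean_up = mean_up, cv2_down = cv2_down,
                       modulation = modulation,
                       stringsAsFactors = FALSE)

  pts_B <- c(.point_burst(before$mean, before$cv2, mset),
             .point_burst(after$mean, after$cv2, mset))
  contained <- pts_B >= B_min & pts_B <= B_max
  above_excl <- pts_B > B_max * margin
  below_excl <- pts_B < B_min / margin

  structure(list(clones = clones,
                 contraction_fraction = mean(mean_up & cv2_down),
                 containment_fraction = mean(contained),
                 exclusion = list(margin = margin,
                                  n_above = sum(above_excl),
                                  n_below = sum(below_excl),
                                  n_points = length(pts_B)),
                 B_min = B_min, B_max = B_max, units = units,
                 class_threshold = class_threshold),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("Perturbation analysis of", nrow(x$clones), "paired clones\n")
  cat(sprintf("  contraction fraction (mean up & CV2 down): %.3f\n",
              x$contraction_fraction))
  cat(sprintf("  containment within [B_min = %.3g, B_max = %.3g]: %.3f\n",
              x$B_min, x$B_max, x$containment_fraction))
  cat(sprintf("  exclusion band (x%.2g): %d above, %d below of %d points\n",
              x$exclusion$margin, x$exclusion$n_above, x$exclusion$n_below,
              x$exclusion$n_points))
  cat("  modulation calls:",
      paste(sprintf("%s=%d", names(table(x$clones$modulation)),
                    as.integer(table(x$clones$modulation))), collapse = ", "),
      "\n")
  invisible(x)
}
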