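#' Linear distance-trend regression
#'
#' Ordinary least-squares regression of a per-synapse statistic against
#' distance, with the two-sided t-test on the slope (the test of the
#' population-average trend) and Pearson's r. This is the statistic used for
#' all distance-trend panels: Pr vs distance, PPR vs distance, spine density
#' vs distance, burst peak-slope vs distance.
#'
#' @param x Distances (micrometres) or any predictor.
#' @param y Response values.
#' @return A list of class `trend_regression`: `slope, intercept, pearson_r,
#'   p_value, slope_se, conf_low, conf_high, n`.
#' @examples
#' r <- regress_trend(1:10, 2 * (1:10) + 1)
#' r$slope  # 2
#' @export
regress_trend <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite points")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit, "x", level = 0.95)
  structure(list(slope = unname(s["x", "Estimate"]),
                 intercept = unname(s["(Intercept)", "Estimate"]),
                 pearson_r = unname(stats::cor(x, y)),
                 p_value = unname(s["x", "Pr(>|t|)"]),
                 slope_se = unname(s["x", "Std. Error"]),
                 conf_low = unname(ci[1]), conf_high = unname(ci[2]),
                 n = n),
            class = "trend_regression")
}

#' @export
print.trend_regression <- function(x, ...) {
  cat(sprintf(
    "trend_regression: slope = %.3g (95%% CI %.3g..%.3g), r = %.3f, p = %.3g, n = %d\n",
    x$slope, x$conf_low, x$conf_high, x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' Pool values into distance bins and re-regress on bin means
#'
#' Averages `y` (and `x`) within fixed-width distance bins and recomputes the
#' trend regression on the bin means. Pooling over groups of synapses cancels
#' the large synapse-to-synapse variability around the trend, raising
#' Pearson's r while representing the same dataset; the slope and its
#' significance test the same population trend.
#'
#' @inheritParams regress_trend
#' @param bin_width Bin width in micrometres (default 25).
#' @return List with `bins` (data frame: `bin_mid, x_mean, y_mean, n`) and
#'   `regression` (a `trend_regression` on the bin means).
#' @export
bin_and_pool <- function(x, y, bin_width = 25) {
  if (bin_width <= 0) stop("bin_width must be positive")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  edges <- seq(floor(min(x) / bin_width) * bin_width,
               ceiling(max(x) / bin_width) * bin_width, by = bin_width)
  idx <- cut(x, breaks = edges, include.lowest = TRUE)
  xb <- tapply(x, idx, mean); yb <- tapply(y, idx, mean)
  nb <- tapply(x, idx, length)
  keep_b <- !is.na(xb)
  bins <- data.frame(bin_mid = edges[-length(edges)][keep_b] + bin_width / 2,
                     x_mean = as.numeric(xb[keep_b]),
                     y_mean = as.numeric(yb[keep_b]),
                     n = as.integer(nb[keep_b]))
  if (nrow(bins) < 2) stop("need at least 2 non-empty bins")
  list(bins = bins, regression = regress_trend(bins$x_mean, bins$y_mean))
}

#' Percentage Pr difference between same-branch synapse pairs
#'
#' For pairs of synapses recorded on one dendritic branch, computes the
#' percentage difference in release probability,
#' `100 * |P1_a - P1_b| / mean(P1_a, P1_b)` (pair-mean denominator, so the
#' measure is symmetric in the two synapses), and regresses it against the
#' separation along the branch.
#'
#' @param pairs Data frame with columns `P1_a, P1_b, separation_um`
#'   (separations > 0).
#' @return List with `pct_diff` (per-pair values) and `regression`
#'   (`trend_regression` of %dPr vs separation).
#' @export
pairwise_branch_difference <- function(pairs) {
  stopifnot(all(c("P1_a", "P1_b", "separation_um") %in% names(pairs)))
  if (any(pairs$separation_um <= 0)) stop("separations must be positive")
  m <- (pairs$P1_a + pairs$P1_b) / 2
  if (any(m == 0)) stop("a pair with both P1 = 0 has no defined %difference")
  pct <- 100 * abs(pairs$P1_a - pairs$P1_b) / m
  list(pct_diff = pct,
       regression = regress_trend(pairs$separation_um, pct))
}

#' Relative position of a synapse along its branch
#'
#' Scales the synapse coordinate to the 0--1 range between the branch origin
#' (0) and its end (1).
#'
#' @param distance_branch_origin Distance from the branch origin, micrometres.
#' @param branch_length Branch length, micrometres (> 0).
#' @return Fraction in [0, 1]; vectorised.
#' @export
relative_branch_position <- function(distance_branch_origin, branch_length) {
  if (any(branch_length <= 0)) stop("branch_length must be positive")
  if (any(distance_branch_origin < 0 | distance_branch_origin > branch_length))
    stop("distance must lie within [0, branch_length]")
  distance_branch_origin / branch_length
}

#' Local spine density around a position
#'
#' Counts protrusion positions within a window (default 10 micrometres)
#' centred on the synapse; both window edges are inclusive.
#'
#' @param positions Protrusion positions along the dendrite, micrometres.
#' @param centre Window centre, micrometres.
#' @param window Window length, micrometres (default 10).
#' @return Integer count (per `window` micrometres).
#' @export
spine_density <- function(positions, centre, window = 10) {
  if (window <= 0) stop("window must be positive")
  sum(positions >= centre - window / 2 & positions <= centre + window / 2)
}

#' Paired two-sample comparison
#'
#' Two-sided paired-sample t-test or Wilcoxon signed-rank test; the choice is
#' a user flag (normality screening is left to the analyst).
#'
#' @param a,b Equal-length numeric vectors of paired observations (n >= 5).
#' @param test `"t"` or `"wilcoxon"`.
#' @return The two-sided p-value. Identical samples give p = 1 (the t-test's
#'   degenerate zero-variance case is handled explicitly).
#' @export
compare_paired <- function(a, b, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- a - b
  if (all(d == 0)) {
    if (test == "wilcoxon") stop("all differences are zero: signed-rank test undefined")
    return(1)
  }
  if (test == "t") {
    if (stats::sd(d) == 0) return(0)   # constant non-zero shift
    stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }
}

#' Analytic spillover neighbourhood size
#'
#' Number of neighbouring synapses within a detection radius of a point,
#' given a volumetric synapse density: `floor(density * (4/3) * pi * r^3)`.
#' At the CA1 density of 2.0 synapses per cubic micrometre and the ~2
#' micrometre glutamate travel radius this exceeds 60 neighbours within the
#' ~33 cubic-micrometre sphere, which is why multi-synapse spillover dominates
#' extracellular glutamate-sensor signals.
#'
#' @param synapse_density Synapses per cubic micrometre.
#' @param detection_radius Radius, micrometres.
#' @param activated_fraction Fraction of local axons recruited by the
#'   stimulus, in (0, 1].
#' @return A list of class `spillover_config`: inputs plus `sphere_volume_um3`
#'   and `n_neighbours`.
#' @export
spillover_config <- function(synapse_density = 2.0, detection_radius = 2.0,
                             activated_fraction = 1.0) {
  if (synapse_density < 0 || detection_radius < 0)
    stop("density and radius must be non-negative")
  if (activated_fraction <= 0 || activated_fraction > 1)
    stop("activated_fraction must be in (0, 1]")
  vol <- 4 / 3 * pi * detection_radius^3
  structure(list(synapse_density = synapse_density,
                 detection_radius = detection_radius,
                 activated_fraction = activated_fraction,
                 sphere_volume_um3 = vol,
                 n_neighbours = floor(synapse_density * vol)),
            class = "spillover_config")
}

#' @export
print.spillover_config <- function(x, ...) {
  cat(sprintf(
    "spillover_config: %.1f syn/um^3 within %.1f um -> %.1f um^3, %d neighbours (%.0f%% activated)\n",
    x$synapse_density, x$detection_radius, x$sphere_volume_um3,
    x$n_neighbours, 100 * x$activated_fraction))
  invisible(x)
}
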