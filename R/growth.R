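# Growth-ratio analysis: per-spheroid growth ratios, subpopulation
# classification against control-derived cutoffs, correlations and k-means
# clustering of per-spheroid feature tables.

#' Growth ratio of a spheroid
#'
#' `GR = area_after / area_before` — the change in a spheroid's sectional
#' area over a treatment interval. The percent change is `100 * (GR - 1)`.
#'
#' @param area_before,area_after sectional areas, um^2 (> 0; vectorized).
#' @return data.frame with `gr` and `percent_change`.
#' @examples
#' growth_ratio(100, 123.7) # GR 1.237, +23.7%
#' @export
growth_ratio <- function(area_before, area_after) {
  if (any(area_before <= 0) || any(area_after <= 0))
    stop("areas must be > 0")
  gr <- area_after / area_before
  data.frame(gr = gr, percent_change = 100 * (gr - 1))
}

#' Classify spheroids into HP / mid / LP growth subpopulations
#'
#' High-proliferating (HP) spheroids have `GR` strictly above the upper
#' cutoff of a control-derived [make_cutoff()] rule; low-proliferating (LP)
#' spheroids fall strictly below the lower cutoff; the rest are `mid`.
#' Boundary values are `mid` (strict inequalities on both sides).
#'
#' @param gr numeric vector of growth ratios.
#' @param rule [make_cutoff()] rule built from a control population's GRs.
#' @return list with `class` (factor HP/mid/LP per spheroid), `fractions`
#'   (named proportions summing to 1) and `stats` (per-class n, GR mean, SD).
#' @export
classify_growth <- function(gr, rule) {
  stopifnot(inherits(rule, "cutoff_rule"))
  if (!length(gr)) stop("empty growth-ratio vector")
  cls <- factor(ifelse(gr > rule$upper, "HP",
                       ifelse(gr < rule$lower, "LP", "mid")),
                levels = c("HP", "mid", "LP"))
  stats <- do.call(rbind, lapply(levels(cls), function(l) {
    v <- gr[cls == l]
    data.frame(class = l, n = length(v),
               gr_mean = if (length(v)) mean(v) else NA_real_,
               gr_sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  list(class = cls,
       fractions = prop.table(table(cls)),
       stats = stats)
}

#' Relative change between two values
#'
#' `100 * (before - after) / before`: positive for a decrease, negative for
#' an increase (sign-preserving).
#'
#' @param before,after values in the same units; `before != 0`.
#' @return percent change (decrease positive).
#' @examples
#' relative_change(55.8, 28.3) # 49.3% decrease
#' @export
relative_change <- function(before, after) {
  if (any(before == 0)) stop("'before' must be nonzero")
  100 * (before - after) / before
}

#' Fold change between two values
#'
#' `after / before`; e.g. mean HP cell counts of 116 -> 232 give a twofold
#' increase.
#'
#' @param before,after positive values in the same units.
#' @return fold change.
#' @export
fold_change <- function(before, after) {
  if (any(before <= 0)) stop("'before' must be > 0")
  after / before
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, each with
#'   nonzero variance.
#' @return correlation coefficient r.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in 'x' or 'y'")
  stats::cor(x, y)
}

#' K-means clustering of per-spheroid features
#'
#' Clusters spheroids on a feature matrix (e.g. growth ratio vs receptor
#' mean FI). Features are z-scored before clustering because the raw scales
#' differ by an order of magnitude; clustering runs `stats::kmeans` with
#' `nstart` random starts under a fixed seed, and cluster labels are made
#' deterministic by renumbering clusters in increasing order of their center
#' on the first feature.
#'
#' @param features numeric matrix or data.frame, one row per spheroid.
#' @param k number of clusters (default 3: the high-, mid- and
#'   low-proliferating subgroups).
#' @param seed RNG seed for initialization.
#' @param nstart number of random starts.
#' @return list with `labels` (1..k), `centers` (original feature scale),
#'   `centers_z` (z-scored scale), `withinss_total`.
#' @export
kmeans_cluster <- function(features, k = 3, seed = 1, nstart = 10) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("'features' must be numeric")
  if (k < 1) stop("'k' must be >= 1")
  if (nrow(x) < k) stop("need at least k rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  km <- if (k == nrow(z)) {
    # one point per cluster: the partition is forced
    list(cluster = seq_len(k), centers = z, tot.withinss = 0)
  } else with_sim_seed(seed,
    stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100))
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  centers_z <- km$centers[ord, , drop = FALSE]
  rownames(centers_z) <- NULL
  centers <- sweep(sweep(centers_z, 2, sdv, "*"), 2, mu, "+")
  list(labels = labels, centers = centers, centers_z = centers_z,
       withinss_total = km$tot.withinss)
}
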