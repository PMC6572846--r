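#' Per-SNP-column clock rate
#'
#' SNP-only alignments compress a large surveyed region into its variable
#' columns.  A per-site mutation rate `mu` (substitutions per site per
#' year) over `reliable_sites` surveyed base pairs therefore corresponds to
#' a per-SNP-column rate of `mu * reliable_sites / n_snps` substitutions
#' per column per year, which is the clock used to convert tree heights in
#' p-distance units into years.
#'
#' @param mu mutation rate, substitutions per site per year.
#' @param reliable_sites number of surveyed base pairs.
#' @param n_snps number of SNP columns retained in the alignment.
#' @return the per-column rate (substitutions per SNP column per year).
#' @examples
#' clock_rate(0.74e-9, 14494268, 7834)   # ~1.37e-6 per column per year
#' @export
clock_rate <- function(mu, reliable_sites, n_snps) {
  if (n_snps <= 0) stop("n_snps must be positive")
  stopifnot(mu > 0, reliable_sites > 0)
  mu * reliable_sites / n_snps
}

#' Clock model for calibrating SNP-column trees
#'
#' Either pass `mu`, `reliable_sites` and `n_snps` (the per-column rate is
#' derived as in [clock_rate()]) or pass `per_column_rate` directly.
#'
#' @inheritParams clock_rate
#' @param per_column_rate substitutions per SNP column per year.
#' @return an object of class `clock_model`.
#' @export
clock_model <- function(mu = NULL, reliable_sites = NULL, n_snps = NULL,
                        per_column_rate = NULL) {
  if (is.null(per_column_rate)) {
    per_column_rate <- clock_rate(mu, reliable_sites, n_snps)
  } else {
    stopifnot(per_column_rate > 0)
  }
  structure(list(mu = mu, reliable_sites = reliable_sites, n_snps = n_snps,
                 per_column_rate = per_column_rate),
            class = "clock_model")
}

#' Calibrate an ultrametric tree to years
#'
#' Converts node heights in p-distance units (expected substitutions per
#' SNP column) into years by dividing by the clock's per-column rate;
#' equivalently, all branch lengths are scaled by `1 / per_column_rate`.
#'
#' @param tree a rooted ultrametric `phylo` with heights in p-distance
#'   units (e.g. from [upgma()] on a [p_distance()] matrix).
#' @param clock a [clock_model()].
#' @param tol relative tolerance for the ultrametricity check.
#' @return a `phylo` with branch lengths in years.
#' @export
calibrate_tree <- function(tree, clock, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), inherits(clock, "clock_model"))
  if (!ape::is.ultrametric(tree, option = 2, tol = tol))
    stop("tree must be ultrametric for clock calibration")
  if (max(node_times(tree)) <= 0)
    stop("tree has zero height; nothing to calibrate")
  tree$edge.length <- tree$edge.length / clock$per_column_rate
  tree
}

new_skyline <- function(df, estimator, ...) {
  structure(df, class = c("skyline_estimate", "data.frame"),
            estimator = estimator, ...)
}

#' Classical skyline estimate of effective population size
#'
#' Per-interval method-of-moments estimator: during an interval with `k`
#' lineages and length `w`, `E[w] = 2N / (k(k-1))`, so
#' `N_hat = k (k-1) w / 2`.  The estimate is a step function over the
#' coalescent intervals, in the same time unit as the genealogy (for trees
#' calibrated in years the estimate is effective size times generation
#' time).  Zero-length intervals yield `N_hat = 0` and are flagged
#' `degenerate`; [detect_change()] excludes them from window means.
#'
#' @param intervals a `coal_intervals` object ([coalescent_intervals()]),
#'   or a genealogy (`phylo`) from which intervals are taken.
#' @return a `skyline_estimate`: data frame with `t_start`, `t_end`, `N`,
#'   `degenerate`.
#' @export
classical_skyline <- function(intervals) {
  ci <- as_intervals(intervals)
  if (nrow(ci) < 1L) stop("need at least one coalescent interval")
  n_hat <- ci$k * (ci$k - 1) * ci$w / 2
  new_skyline(data.frame(t_start = ci$t_start, t_end = ci$t_end,
                         N = n_hat, degenerate = ci$w <= 0),
              estimator = "classical")
}

as_intervals <- function(x) {
  if (inherits(x, "phylo")) coalescent_intervals(x)
  else if (inherits(x, "coal_intervals")) x
  else stop("expected a genealogy or coalescent intervals")
}

# Collapse (near-)zero-length intervals into the following interval.
# Trees built from discrete SNP counts can carry tied node heights
# (effective multifurcations); treating each tie as its own interval lets
# likelihood-based estimators chase infinite-density spikes (N_hat -> 0 on
# a width-zero interval).  Composites pool each run of ties with the next
# positive-width interval, so every composite has >= 1 coalescence, a
# positive width, and an event count `events`; `cstat` accumulates
# k (k - 1) w / 2 over the pooled raw intervals.
collapse_intervals <- function(ci, rel_tol = 1e-9) {
  tol <- rel_tol * max(ci$t_end)
  out <- data.frame(k = integer(0), w = numeric(0), t_start = numeric(0),
                    t_end = numeric(0), events = integer(0),
                    cstat = numeric(0))
  pend_events <- 0L
  pend_c <- 0
  pend_k <- NA_integer_
  pend_t0 <- NA_real_
  for (j in seq_len(nrow(ci))) {
    pend_events <- pend_events + 1L
    pend_c <- pend_c + ci$k[j] * (ci$k[j] - 1) * ci$w[j] / 2
    if (is.na(pend_k)) {
      pend_k <- ci$k[j]
      pend_t0 <- ci$t_start[j]
    }
    if (ci$t_end[j] - pend_t0 > tol) {
      out <- rbind(out, data.frame(k = pend_k, w = ci$t_end[j] - pend_t0,
                                   t_start = pend_t0, t_end = ci$t_end[j],
                                   events = pend_events, cstat = pend_c))
      pend_events <- 0L; pend_c <- 0; pend_k <- NA_integer_
    }
  }
  if (pend_events > 0L) {  # trailing ties: fold into the last composite
    if (nrow(out) == 0L) stop("all coalescent intervals have zero length")
    last <- nrow(out)
    out$events[last] <- out$events[last] + pend_events
    out$cstat[last] <- out$cstat[last] + pend_c
    out$t_end[last] <- max(out$t_end[last], ci$t_end[nrow(ci)])
    out$w[last] <- out$t_end[last] - out$t_start[last]
  }
  out
}

#' Generalized (grouped) skyline estimate with AICc model selection
#'
#' Pools adjacent coalescent intervals into contiguous composite groups and
#' estimates one size per group: for a group pooling intervals `j` with `m`
#' pooled coalescences, `N_hat = sum_j k_j (k_j - 1) w_j / (2 m)` (the
#' constant-size maximum-likelihood estimate restricted to the group).
#' Candidate groupings come from a pooling-threshold family: for a
#' threshold `eps`, adjacent intervals are accumulated until each
#' composite spans at least `eps` time units (a trailing short composite is
#' merged backward).  The threshold — hence the group count — is chosen to
#' minimize small-sample-corrected AIC of the piecewise-constant coalescent
#' likelihood, with one parameter per group.  Restricting candidates to
#' this family (rather than freely optimized change points) keeps the
#' selection honest: a free per-interval size is always favored by the
#' unpenalized likelihood because single short intervals act as
#' infinite-density spikes.
#'
#' @inheritParams classical_skyline
#' @param n_eps number of candidate thresholds (log-spaced between the
#'   shortest and the total interval span), in addition to `eps = 0`.  A
#'   coarse grid is deliberate: every candidate is one more comparison the
#'   AICc minimum runs over, so a denser grid buys little resolution at the
#'   price of overfitting on size-homogeneous data.
#' @param eps optional fixed pooling threshold in time units; when given,
#'   model selection is skipped and that threshold is used directly
#'   (`eps = Inf` pools everything into the single-group constant-size
#'   MLE).
#' @return a `skyline_estimate` with one row per group and attributes
#'   `n_groups`, `eps` (chosen threshold), `logLik` and `aicc` (the AICc
#'   path over candidate thresholds).
#' @export
generalized_skyline <- function(intervals, n_eps = 15L, eps = NULL) {
  raw <- as_intervals(intervals)
  if (nrow(raw) < 2L) stop("need at least two coalescent intervals")
  ci <- collapse_intervals(raw)
  J <- nrow(ci)
  n_events <- sum(ci$events)
  span <- max(ci$t_end)
  w_min <- min(ci$w[ci$w > 0])
  eps_grid <- if (is.null(eps)) {
    c(0, exp(seq(log(w_min), log(span), length.out = n_eps)))
  } else {
    eps
  }

  pool_by_eps <- function(eps) {
    starts <- integer(0)
    acc <- 0
    for (j in seq_len(J)) {
      if (acc <= 0) starts <- c(starts, j)
      acc <- acc + ci$w[j]
      if (acc >= eps) acc <- 0
    }
    # trailing composite shorter than eps: merge into the previous group
    if (length(starts) > 1L) {
      last <- starts[length(starts)]
      if (sum(ci$w[last:J]) < eps) starts <- starts[-length(starts)]
    }
    starts
  }

  eval_grouping <- function(starts) {
    ends <- c(starts[-1L] - 1L, J)
    m <- vapply(seq_along(starts), function(i)
      sum(ci$events[starts[i]:ends[i]]), numeric(1))
    C <- vapply(seq_along(starts), function(i)
      sum(ci$cstat[starts[i]:ends[i]]), numeric(1))
    ll <- sum(-m * log(C / m) - m)
    p <- length(starts)
    aicc <- -2 * ll + 2 * p +
      if (n_events - p - 1 > 0) 2 * p * (p + 1) / (n_events - p - 1) else Inf
    list(starts = starts, ends = ends, m = m, C = C, ll = ll, aicc = aicc)
  }

  fits <- lapply(eps_grid, function(e) eval_grouping(pool_by_eps(e)))
  aicc_path <- vapply(fits, `[[`, numeric(1), "aicc")
  best <- fits[[which.min(aicc_path)]]
  n_hat <- best$C / best$m
  new_skyline(data.frame(t_start = ci$t_start[best$starts],
                         t_end = ci$t_end[best$ends],
                         N = n_hat, degenerate = n_hat <= 0),
              estimator = "generalized",
              n_groups = length(best$starts),
              eps = eps_grid[which.min(aicc_path)],
              logLik = best$ll, aicc = aicc_path)
}

#' Detection rule for a bottleneck-and-recovery size pattern
#'
#' Defines three disjoint time windows (years before present) and a fold
#' threshold `c`.  A skyline "detects" the pattern when its mean size in
#' the bottleneck window is less than `1/c` of its mean in the older
#' pre-bottleneck window AND its mean in the recent post-recovery window
#' exceeds `c` times the bottleneck mean.  The defaults bracket a crash at
#' 3,000 YBP and a recovery at 2,000 YBP with guard gaps.
#'
#' @param post,bottleneck,pre numeric length-2 windows `c(from, to)` in
#'   years before present, ordered `post < bottleneck < pre`.
#' @param fold fold-change threshold `c`, > 1.
#' @return an object of class `detection_rule`.
#' @export
detection_rule <- function(post = c(0, 1800), bottleneck = c(2100, 2900),
                           pre = c(3500, 10000), fold = 2) {
  chk <- function(w) stopifnot(length(w) == 2L, w[1] >= 0, w[2] > w[1])
  chk(post); chk(bottleneck); chk(pre)
  if (!(post[2] <= bottleneck[1] && bottleneck[2] <= pre[1]))
    stop("windows must be disjoint and ordered post < bottleneck < pre")
  if (fold <= 1) stop("fold threshold must exceed 1")
  structure(list(post = post, bottleneck = bottleneck, pre = pre,
                 fold = fold), class = "detection_rule")
}

# time-weighted mean of a skyline step function over [from, to],
# excluding degenerate (zero-length) intervals
window_mean <- function(est, window) {
  lo <- pmax(est$t_start, window[1])
  hi <- pmin(est$t_end, window[2])
  keep <- hi > lo & !est$degenerate
  if (!any(keep)) return(NA_real_)
  sum((hi - lo)[keep] * est$N[keep]) / sum((hi - lo)[keep])
}

#' Decide whether a skyline shows the bottleneck-and-recovery pattern
#'
#' @param est a `skyline_estimate` whose span covers all three windows of
#'   the rule.
#' @param rule a [detection_rule()].
#' @return `TRUE` if the pattern is detected, else `FALSE`.
#' @export
detect_change <- function(est, rule = detection_rule()) {
  stopifnot(inherits(est, "skyline_estimate"),
            inherits(rule, "detection_rule"))
  span <- c(min(est$t_start), max(est$t_end))
  for (w in list(rule$post, rule$bottleneck, rule$pre))
    if (w[1] < span[1] || w[2] > span[2])
      stop(sprintf("window [%g, %g] outside skyline span [%g, %g]",
                   w[1], w[2], span[1], span[2]))
  m_post <- window_mean(est, rule$post)
  m_bot <- window_mean(est, rule$bottleneck)
  m_pre <- window_mean(est, rule$pre)
  if (anyNA(c(m_post, m_bot, m_pre))) return(FALSE)
  (m_bot < m_pre / rule$fold) && (m_post > m_bot * rule$fold)
}

#' Write a skyline estimate as TSV
#'
#' @param est a `skyline_estimate`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_skyline <- function(est, path) {
  write.table(as.data.frame(est), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
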