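#' Effective sample size of an MCMC trace
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated
#' by the standard initial-positive-sequence rule: lags are accumulated in
#' pairs `(rho_{2t-1} + rho_{2t})` and accumulation stops at the first
#' non-positive pair.
#'
#' @param x numeric trace with at least 10 samples.
#' @return the effective sample size; a constant trace gives 0 with a
#'   warning.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples to estimate ESS")
  if (stats::var(x) == 0) {
    warning("constant trace; ESS is 0")
    return(0)
  }
  lag_max <- min(n - 1L, 2000L)
  rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  s <- 0
  t <- 1L
  while (t <= length(rho)) {
    pair <- rho[t] + if (t + 1L <= length(rho)) rho[t + 1L] else 0
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  tau <- 1 + 2 * s
  if (tau <= 0) return(n)
  n / tau
}

#' Bayesian skyline estimation on a fixed genealogy
#'
#' Piecewise-constant coalescent model: the `n - 1` coalescent intervals
#' are partitioned into `n_groups` contiguous groups, each with its own
#' size `N_g`.  The likelihood is
#' `prod_events 1/N_g(event) * exp(-sum_j k_j (k_j - 1) w_j / (2 N_g(j)))`,
#' the prior is uniform on `log N_g` (over a very wide window centred on
#' the constant-size MLE) and uniform over contiguous boundary
#' configurations.  Sampling is collapsed Metropolis-within-Gibbs: the
#' sizes integrate out analytically under the log-uniform prior
#' (`Gamma(m_g) C_g^{-m_g}` per group), the boundary chain runs on that
#' marginal with Metropolis steps mixing local shifts and uniform
#' repositions, and the sizes are drawn exactly from their conditional
#' (`1/N_g ~ Gamma(m_g, rate = C_g)`) for each recorded sample.  The
#' chain is
#' extended (doubled) until every `log N_g` trace reaches an effective
#' sample size of at least `target_ess`; if the budget `max_doublings` is
#' exhausted first, the returned `status` is `"not_converged"` and a
#' warning is raised — never a silent pass.
#'
#' @param gen a timed genealogy (`phylo`), e.g. calibrated in years.
#' @param n_groups number of size groups, `<= n - 1`.
#' @param chain_length sweeps in the initial chain.
#' @param burn_in fraction of each chain discarded as burn-in.
#' @param thin keep one sample every `thin` sweeps.
#' @param seed RNG seed (the run is deterministic given the seed).
#' @param target_ess required minimum ESS across group-size traces.
#' @param max_doublings how many times the chain may be doubled.
#' @return list with `skyline` (a `skyline_estimate` with posterior median
#'   `N` and 95% highest-posterior-density bands per coalescent interval),
#'   `trace` (matrix of sampled `log N_g`), `boundaries` (matrix of group
#'   start indices), `ess` (per-group ESS), `acceptance`, and `status`
#'   (`"converged"` or `"not_converged"`).
#' @export
bayesian_skyline <- function(gen, n_groups = 10L, chain_length = 20000L,
                             burn_in = 0.1, thin = 10L, seed = 1L,
                             target_ess = 200, max_doublings = 3L) {
  ci <- collapse_intervals(as_intervals(gen))
  J <- nrow(ci)
  n_groups <- as.integer(n_groups)
  if (n_groups < 1L || n_groups > J)
    stop("n_groups must be between 1 and the number of ",
         "(positive-length) coalescent intervals")
  if (!is.null(seed)) set.seed(seed)
  cum_c <- c(0, cumsum(ci$cstat))
  cum_e <- c(0, cumsum(ci$events))

  # state: group start indices (starts[1] == 1) and log sizes
  starts <- as.integer(round(seq(1, J + 1, length.out = n_groups + 1)))[
    seq_len(n_groups)]
  starts[1L] <- 1L
  n_mle <- cum_c[J + 1L] / cum_e[J + 1L]
  l_lo <- log(n_mle) - 20
  l_hi <- log(n_mle) + 20

  group_stats <- function(starts) {
    ends <- c(starts[-1L] - 1L, J)
    m <- cum_e[ends + 1L] - cum_e[starts]
    C <- cum_c[ends + 1L] - cum_c[starts]
    list(m = m, C = C)
  }
  gs <- group_stats(starts)
  # collapsed (sizes integrated out) log marginal of one group under the
  # log-uniform size prior: log Gamma(m) - m log C
  coll <- function(m, C) lgamma(m) - m * log(C)

  acc <- att <- 0
  samples_ln <- list()
  samples_st <- list()

  draw_sizes <- function() {
    # conditional given (m events, coalescent pressure C):
    # 1/N ~ Gamma(shape = m, rate = C); redraw until inside the prior
    # window (truncation is astronomically unlikely to bite)
    prop <- -log(rgamma(n_groups, shape = gs$m, rate = gs$C))
    bad <- which(prop < l_lo | prop > l_hi)
    while (length(bad)) {
      prop[bad] <- -log(rgamma(length(bad), shape = gs$m[bad],
                               rate = gs$C[bad]))
      bad <- bad[prop[bad] < l_lo | prop[bad] > l_hi]
    }
    prop
  }

  run_sweeps <- function(n_sweeps, record) {
    kept_ln <- if (record) matrix(0, nrow = ceiling(n_sweeps / thin),
                                  ncol = n_groups) else NULL
    kept_st <- if (record) matrix(0L, nrow = ceiling(n_sweeps / thin),
                                  ncol = n_groups) else NULL
    ki <- 0L
    for (sw in seq_len(n_sweeps)) {
      # Metropolis moves on the boundaries, sizes marginalized out
      if (n_groups > 1L) {
        for (rep in seq_len(n_groups)) {
          b <- if (n_groups == 2L) 2L else sample(2:n_groups, 1L)
          lo <- starts[b - 1L] + 1L
          hi <- if (b < n_groups) starts[b + 1L] - 1L else J
          cand <- if (runif(1L) < 0.5) {      # local shift
            starts[b] + (if (runif(1L) < 0.5) -1L else 1L)
          } else {                            # uniform reposition
            lo + sample.int(hi - lo + 1L, 1L) - 1L
          }
          att <<- att + 1
          if (cand < lo || cand > hi || cand == starts[b]) next
          new_starts <- starts
          new_starts[b] <- cand
          ngs <- group_stats(new_starts)
          idx <- c(b - 1L, b)
          d_ll <- sum(coll(ngs$m[idx], ngs$C[idx])) -
                  sum(coll(gs$m[idx], gs$C[idx]))
          if (log(runif(1L)) < d_ll) {
            starts <<- new_starts
            gs <<- ngs
            acc <<- acc + 1
          }
        }
      }
      if (record && sw %% thin == 0L) {
        ki <- ki + 1L
        kept_ln[ki, ] <- draw_sizes()
        kept_st[ki, ] <- starts
      }
    }
    if (record) list(ln = kept_ln[seq_len(ki), , drop = FALSE],
                     st = kept_st[seq_len(ki), , drop = FALSE])
  }

  n_burn <- ceiling(chain_length * burn_in)
  run_sweeps(n_burn, record = FALSE)
  out <- run_sweeps(chain_length - n_burn, record = TRUE)
  samples_ln <- out$ln
  samples_st <- out$st
  ess_v <- apply(samples_ln, 2L, function(v)
    if (stats::var(v) == 0) 0 else ess(v))
  doublings <- 0L
  while (min(ess_v) < target_ess && doublings < max_doublings) {
    out <- run_sweeps(chain_length, record = TRUE)
    samples_ln <- rbind(samples_ln, out$ln)
    samples_st <- rbind(samples_st, out$st)
    ess_v <- apply(samples_ln, 2L, function(v)
      if (stats::var(v) == 0) 0 else ess(v))
    doublings <- doublings + 1L
  }
  status <- if (min(ess_v) >= target_ess) "converged" else "not_converged"
  if (status == "not_converged")
    warning(sprintf("MCMC not converged: min ESS %.0f < %g after %d extensions",
                    min(ess_v), target_ess, doublings))

  # per-interval posterior: N at interval j is N_{group(j)}
  S <- nrow(samples_ln)
  traj <- matrix(0, nrow = S, ncol = J)
  for (s in seq_len(S)) {
    ends <- c(samples_st[s, -1L] - 1L, J)
    g_of_j <- rep(seq_len(n_groups), times = ends - samples_st[s, ] + 1L)
    traj[s, ] <- exp(samples_ln[s, g_of_j])
  }
  med <- apply(traj, 2L, median)
  hpd <- apply(traj, 2L, hpd_interval)
  sky <- new_skyline(data.frame(t_start = ci$t_start, t_end = ci$t_end,
                                N = med, lower = hpd[1L, ],
                                upper = hpd[2L, ],
                                degenerate = ci$w <= 0),
                     estimator = "bayesian", n_groups = n_groups)
  list(skyline = sky, trace = samples_ln, boundaries = samples_st,
       ess = ess_v,
       acceptance = if (sum(att) > 0) sum(acc) / sum(att) else NA_real_,
       status = status)
}

# smallest interval containing `prob` of the sample (empirical HPD)
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  width <- x[(m + 1L):n] - x[seq_len(n - m)]
  i <- which.min(width)
  c(x[i], x[i + m])
}
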