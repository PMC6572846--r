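# shared fixtures and small oracles used across test files

ea_tab <- east_asian_freqs()
mj <- ea_tab[, "Mainland Japanese"]
kr <- ea_tab[, "Korean"]

# similarity index recomputed term by term, independent of the package
si_by_hand <- function(w, y) {
  s <- 0
  for (i in seq_along(w)) {
    if (w[i] + y[i] > 0) s <- s + abs(w[i] - y[i]) / (w[i] + y[i])
  }
  unname(s)
}

# sum over clades of the unconstrained per-clade SI minimum (each term
# minimized over x_i in [0, 1] on its own, ignoring the simplex constraint):
# a certified lower bound on the constrained optimum
per_term_si_bound <- function(y, z, alpha) {
  total <- 0
  for (i in seq_along(y)) {
    term <- function(x) {
      w <- alpha * x + (1 - alpha) * z[i]
      if (w + y[i] == 0) 0 else abs(w - y[i]) / (w + y[i])
    }
    o <- stats::optimize(term, c(0, 1))
    total <- total + min(o$objective, term(0), term(1))
  }
  total
}

# least-squares branch fit of a fixed 4-taxon unrooted topology to a
# distance matrix; topologies indexed by the taxon paired with taxon 1
ls_fit_quartet <- function(d, mate) {
  taxa <- rownames(d)
  others <- setdiff(seq_len(4L), c(1L, mate))
  # unrooted quartet (1, mate | others): 5 branches
  # path design matrix rows: pairs in fixed order
  pairs <- t(combn(4L, 2L))
  X <- matrix(0, nrow = 6L, ncol = 5L)  # e1..e4 pendant, e5 internal
  for (r in seq_len(6L)) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    X[r, a] <- 1; X[r, b] <- 1
    same_side <- (a %in% c(1L, mate)) == (b %in% c(1L, mate))
    if (!same_side) X[r, 5L] <- 1
  }
  yv <- d[pairs]
  fit <- qr.solve(X, yv)
  resid <- sum((X %*% fit - yv)^2)
  list(branches = fit, rss = resid)
}

# brute-force quartet oracle: enumerate the 3 unrooted topologies, pick the
# least-squares best; returns the taxon index paired with taxon 1
best_quartet_topology <- function(d) {
  rss <- vapply(2:4, function(mate) ls_fit_quartet(d, mate)$rss, numeric(1))
  (2:4)[which.min(rss)]
}

# pair-counting agreement between two labelings (1 = identical partitions)
partition_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  pairs <- t(combn(length(a), 2L))
  same_a <- a[pairs[, 1L]] == a[pairs[, 2L]]
  same_b <- b[pairs[, 1L]] == b[pairs[, 2L]]
  mean(same_a == same_b)
}

make_skyline <- function(t_start, t_end, N) {
  structure(data.frame(t_start = t_start, t_end = t_end, N = N,
                       degenerate = FALSE),
            class = c("skyline_estimate", "data.frame"),
            estimator = "manual")
}
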