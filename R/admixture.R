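#' Draw candidate source-population clade frequencies
#'
#' Draws frequency vectors for a hypothetical source population by giving
#' each of the seven clades an independent Uniform(0,1) random number
#' `r_i` and normalizing: `x_i = r_i / sum(r)`.  This normalized-uniform
#' scheme is deliberately NOT a flat Dirichlet: the marginals differ from
#' Beta(1, 6), concentrating somewhat more mass near 1/7.
#'
#' Draws are consumed in iteration-major order (the seven numbers of draw 1,
#' then the seven of draw 2, ...), so results for a fixed seed do not depend
#' on how callers chunk their requests.
#'
#' @param n number of vectors to draw.
#' @param n_clades clades per vector.
#' @return an `n x n_clades` matrix; each row sums to 1.
#' @export
draw_source_freqs <- function(n = 1L, n_clades = 7L) {
  stopifnot(n >= 1, n_clades >= 1)
  r <- matrix(runif(n_clades * n), nrow = n_clades)  # column = one draw
  s <- colSums(r)
  while (any(s == 0)) {            # probability zero; redraw defensively
    bad <- which(s == 0)
    r[, bad] <- runif(n_clades * length(bad))
    s[bad] <- colSums(r[, bad, drop = FALSE])
  }
  t(sweep(r, 2L, s, "/"))
}

#' Two-way admixture of clade-frequency vectors
#'
#' Clade frequencies in an admixed population receiving a fraction `alpha`
#' of its ancestry from source `x` and `1 - alpha` from source `z`:
#' `w_i = alpha * x_i + (1 - alpha) * z_i`.
#'
#' @param x,z clade-frequency vectors of equal length.
#' @param alpha admixture proportion contributed by `x`, in \[0, 1\].
#' @return the admixed frequency vector.
#' @export
admix <- function(x, z, alpha) {
  if (length(x) != length(z))
    stop("x and z must have the same number of clades")
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * x + (1 - alpha) * z
}

#' Similarity index between two clade-frequency vectors
#'
#' `SI = sum_i |w_i - y_i| / (w_i + y_i)`, summed over clades.  Smaller
#' values mean a closer match; with 7 clades the index lies in \[0, 7\].
#' A term with `w_i = y_i = 0` is defined as 0 (both populations lack the
#' clade, so they agree there).
#'
#' @param w,y non-negative frequency vectors of equal length.
#' @return the similarity index (a single number).
#' @export
similarity_index <- function(w, y) {
  if (length(w) != length(y)) stop("w and y must have the same length")
  if (any(w < 0) || any(y < 0)) stop("frequencies must be non-negative")
  denom <- w + y
  term <- ifelse(denom == 0, 0, abs(w - y) / denom)
  sum(term)
}

#' Monte Carlo estimation of source-population clade frequencies
#'
#' Repeatedly draws candidate clade-frequency vectors `x` for the unobserved
#' source population ([draw_source_freqs()]), forms the admixed vector
#' `w = alpha * x + (1 - alpha) * z`, scores it against the observed
#' admixed-population vector `y` with the similarity index, and retains the
#' `top_k` draws with the smallest SI.  The retained vectors' mean is the
#' point estimate of the source population's clade frequencies.
#'
#' The loop is chunked and vectorized, with memory bounded by the chunk
#' size; the running top-`top_k` set is maintained across chunks, so
#' `n_iter = 1e8` completes in minutes.  For a fixed seed the result is
#' independent of `chunk_size` because uniform draws are consumed in
#' iteration order.  Ties in SI are broken by earlier iteration index.
#'
#' @param y observed clade frequencies in the admixed population.
#' @param z observed clade frequencies in the other (non-focal) source.
#' @param alpha admixture proportion contributed by the unobserved source
#'   (default 0.12).
#' @param n_iter number of Monte Carlo draws.
#' @param top_k number of smallest-SI draws to retain (default 20).
#' @param seed RNG seed; if `NULL` the current RNG state is used.
#' @param chunk_size draws generated per vectorized block.
#' @return an object of class `mc_result`: a list with `top_x` (a
#'   `top_k x n_clades` matrix, rows in ascending SI order), `top_si`,
#'   `top_iter` (iteration indices), `mean_freqs`, `si_threshold` (the
#'   largest retained SI), and the call parameters.
#' @examples
#' tab <- east_asian_freqs()
#' res <- run_mc(tab[, "Mainland Japanese"], tab[, "Korean"],
#'               n_iter = 1e4, seed = 1)
#' res$mean_freqs
#' @export
run_mc <- function(y, z, alpha = 0.12, n_iter = 1e8, top_k = 20L,
                   seed = NULL, chunk_size = 1e6L) {
  if (length(y) != length(z)) stop("y and z must have the same length")
  nc <- length(y)
  if (top_k > n_iter) stop("top_k cannot exceed n_iter")
  stopifnot(top_k >= 1, chunk_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- unname(y)
  z <- unname(z)

  best_si <- numeric(0)
  best_x <- matrix(numeric(0), nrow = nc)
  best_iter <- numeric(0)
  done <- 0
  while (done < n_iter) {
    m <- as.integer(min(chunk_size, n_iter - done))
    r <- matrix(runif(nc * m), nrow = nc)  # column-major: iteration order
    s <- .colSums(r, nc, m)
    si <- numeric(m)
    for (i in seq_len(nc)) {
      xi <- r[i, ] / s
      wi <- alpha * xi + (1 - alpha) * z[i]
      si <- si + abs(wi - y[i]) / (wi + y[i])
    }
    # merge this chunk's best into the running set
    keep <- order(si)[seq_len(min(top_k, m))]
    cand_si <- c(best_si, si[keep])
    cand_iter <- c(best_iter, done + keep)
    cand_x <- cbind(best_x, sweep(r[, keep, drop = FALSE], 2L,
                                  s[keep], "/"))
    ord <- order(cand_si, cand_iter)[seq_len(min(top_k, length(cand_si)))]
    best_si <- cand_si[ord]
    best_iter <- cand_iter[ord]
    best_x <- cand_x[, ord, drop = FALSE]
    done <- done + m
  }

  structure(list(
    top_x = t(best_x),
    top_si = best_si,
    top_iter = best_iter,
    mean_freqs = rowMeans(best_x),
    si_threshold = best_si[length(best_si)],
    alpha = alpha, n_iter = n_iter, top_k = top_k, seed = seed
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Admixture Monte Carlo: %g draws, top %d by similarity index\n",
              x$n_iter, x$top_k))
  cat(sprintf("SI threshold (largest retained): %.4f\n", x$si_threshold))
  cat("Mean source-population clade frequencies:\n")
  print(round(x$mean_freqs, 4))
  invisible(x)
}

#' Numerical lower bound on the attainable similarity index
#'
#' Minimizes `SI(admix(x, z, alpha), y)` over the frequency simplex by
#' multi-start local optimization (Nelder-Mead on a softmax
#' reparametrization) followed by coordinate-wise refinement with a
#' shrinking step.  Serves as an independent check on the Monte Carlo: no
#' sampled SI can fall below this optimum, and the selection threshold of a
#' large run must sit above it.
#'
#' @inheritParams run_mc
#' @param n_starts number of random restarts.
#' @param seed RNG seed for the restarts.
#' @return list with `minimum` (the optimal SI) and `argmin` (the
#'   frequency vector attaining it).
#' @export
min_si_search <- function(y, z, alpha = 0.12, n_starts = 40L, seed = 1L) {
  nc <- length(y)
  obj_x <- function(x) similarity_index(admix(x, z, alpha), y)
  obj_v <- function(v) {
    e <- exp(v - max(v))
    obj_x(e / sum(e))
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- c(list(rep(0, nc), log(pmax(y, 1e-4)), log(pmax(z, 1e-4))),
              lapply(seq_len(n_starts), function(i) rnorm(nc, 0, 2)))
  best <- NULL
  for (v0 in starts) {
    fit <- optim(v0, obj_v, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  e <- exp(best$par - max(best$par))
  x <- e / sum(e)
  # coordinate-wise refinement on the simplex with a shrinking step
  step <- 0.05
  f <- obj_x(x)
  while (step > 1e-7) {
    improved <- FALSE
    for (i in seq_len(nc)) {
      for (d in c(step, -step)) {
        xi <- x[i] + d
        if (xi < 0 || xi > 1) next
        cand <- x
        cand[i] <- xi
        cand <- cand / sum(cand)
        fc <- obj_x(cand)
        if (fc < f - 1e-14) {
          x <- cand; f <- fc; improved <- TRUE
        }
      }
    }
    if (!improved) step <- step / 2
  }
  list(minimum = f, argmin = x)
}
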