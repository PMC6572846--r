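#' Demographic models with piecewise-constant size
#'
#' A demographic model holds the present-day effective size `n0` (in gene
#' copies — haploid Y chromosomes here, so the coalescence rate for `k`
#' lineages is `k(k-1)/(2N)` per generation with no ploidy factor) and an
#' ordered set of historical events.  Each event, at a time in generations
#' before present, multiplies the current (backward-in-time) size by
#' `size_factor`, following the relative-size convention of standard
#' coalescent simulators.
#'
#' @param n0 present effective size in gene copies.
#' @param events `data.frame` with columns `time` (generations before
#'   present, strictly increasing, > 0) and `size_factor` (> 0); may have
#'   zero rows for a constant-size model.
#' @param growth_rate exponential growth rate; only 0 is supported (the
#'   models treated here are piecewise constant).
#' @return an object of class `demographic_model`.
#' @seealso [jomon_model()] for the packaged three-event history;
#'   [epoch_sizes()] for the implied backward epoch sizes.
#' @export
demographic_model <- function(n0, events = data.frame(time = numeric(0),
                                                      size_factor = numeric(0)),
                              growth_rate = 0) {
  stopifnot(n0 > 0)
  if (growth_rate != 0) stop("only growth_rate = 0 is supported")
  events <- as.data.frame(events)
  stopifnot(all(c("time", "size_factor") %in% names(events)))
  if (nrow(events)) {
    if (any(events$time <= 0)) stop("event times must be positive")
    if (is.unsorted(events$time, strictly = TRUE))
      stop("event times must be strictly increasing")
    if (any(events$size_factor <= 0)) stop("size factors must be positive")
  }
  structure(list(n0 = n0, events = events, growth_rate = growth_rate),
            class = "demographic_model")
}

#' Three-event male demographic history of the Jomon-period model
#'
#' The packaged model: present size 10,000 gene copies and, backward in
#' time, size multipliers 0.112 at 80 generations, 3.58 at 120 generations
#' and 0.172 at 580 generations.  Read forward in time (at 25 years per
#' generation) this is a population that grew around 14,500 years before
#' present, crashed around 3,000 YBP and recovered around 2,000 YBP.
#'
#' @return a [demographic_model()].
#' @export
jomon_model <- function() {
  demographic_model(
    n0 = 10000,
    events = data.frame(time = c(80, 120, 580),
                        size_factor = c(0.112, 3.58, 0.172)))
}

#' Backward epoch sizes implied by a demographic model
#'
#' @param model a [demographic_model()].
#' @return `data.frame` with `start`, `end` (generations before present;
#'   last `end` is `Inf`) and `N` (gene copies during the epoch).
#' @export
epoch_sizes <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  tms <- model$events$time
  n <- model$n0 * cumprod(c(1, model$events$size_factor))
  data.frame(start = c(0, tms), end = c(tms, Inf), N = n)
}

#' Simulate a coalescent genealogy under piecewise-constant demography
#'
#' Standard Kingman coalescent backward in time: with `k` extant lineages
#' and current size `N(t)` gene copies the next coalescence is exponential
#' with rate `k(k-1)/(2 N(t))` per generation; when a waiting time would
#' cross an epoch boundary the clock is restarted at the boundary with the
#' new size (valid by memorylessness).  Event times change only the rate,
#' never the lineage count.
#'
#' @param model a [demographic_model()].
#' @param n sample size (tips), >= 2.
#' @param seed optional RNG seed; if `NULL` the current RNG state is used.
#' @return a rooted, ultrametric `phylo` object with branch lengths in
#'   generations; tips are `t1` .. `tn` at time 0.
#' @export
simulate_genealogy <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  ep <- epoch_sizes(model)
  n <- as.integer(n)
  n_nodes <- 2L * n - 1L
  node_time <- numeric(n_nodes)
  edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
  edge_len <- numeric(2L * n - 2L)
  active <- seq_len(n)
  next_node <- n + 1L
  e_row <- 1L
  t <- 0
  epi <- 1L
  k <- n
  while (k > 1L) {
    rate <- k * (k - 1L) / (2 * ep$N[epi])
    wait <- rexp(1L, rate)
    if (t + wait > ep$end[epi]) {
      t <- ep$end[epi]
      epi <- epi + 1L
      next
    }
    t <- t + wait
    pair <- sample.int(k, 2L)
    a <- active[pair[1L]]
    b <- active[pair[2L]]
    node_time[next_node] <- t
    edge[e_row, ] <- c(next_node, a)
    edge_len[e_row] <- t - node_time[a]
    edge[e_row + 1L, ] <- c(next_node, b)
    edge_len[e_row + 1L] <- t - node_time[b]
    e_row <- e_row + 2L
    active <- c(active[-pair], next_node)
    next_node <- next_node + 1L
    k <- k - 1L
  }
  # renumber internals so the root (created last) is node n + 1
  remap <- seq_len(n_nodes)
  remap[(n + 1L):n_nodes] <- (2L * n - 1L):(n + 1L)
  edge[] <- remap[edge]
  phy <- structure(list(edge = edge,
                        edge.length = edge_len,
                        tip.label = paste0("t", seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Node times of an ultrametric genealogy
#'
#' Time before present of every node (tips first, then internals), taking
#' the deepest tip as time 0.
#'
#' @param gen a rooted `phylo` with branch lengths.
#' @return numeric vector of length `n + Nnode`.
#' @export
node_times <- function(gen) {
  depth <- ape::node.depth.edgelength(gen)
  max(depth[seq_len(ape::Ntip(gen))]) - depth
}

#' Coalescent intervals of a timed genealogy
#'
#' Decomposes an ultrametric genealogy into the intervals between
#' successive coalescences, from `n` lineages down to 2.
#'
#' @param gen a rooted ultrametric `phylo`; branch lengths in any time unit.
#' @return `data.frame` of class `coal_intervals` with columns `k` (lineage
#'   count during the interval), `w` (interval length), `t_start`, `t_end`
#'   (interval bounds, time before present).  `sum(w)` equals the TMRCA.
#' @export
coalescent_intervals <- function(gen) {
  stopifnot(inherits(gen, "phylo"))
  n <- ape::Ntip(gen)
  bt <- sort(unname(ape::branching.times(gen)))
  if (length(bt) != n - 1L)
    stop("genealogy must be binary with n - 1 coalescences")
  t0 <- c(0, bt[-length(bt)])
  structure(data.frame(k = n:2, w = bt - t0, t_start = t0, t_end = bt),
            class = c("coal_intervals", "data.frame"))
}

#' Drop a fixed budget of infinite-sites mutations on a genealogy
#'
#' Places exactly `n_snps` mutations on the genealogy, each on a branch
#' chosen with probability proportional to branch length (multinomial over
#' branches).  Under the infinite-sites model every mutation creates a new
#' biallelic column: tips below the mutated branch carry the derived allele
#' (1), all others the ancestral allele (0).
#'
#' @param gen a rooted `phylo` with positive total branch length.
#' @param n_snps number of mutations (= SNP columns), >= 1.
#' @param seed optional RNG seed.
#' @return haplotype matrix (samples x sites, integer 0/1) with tip labels
#'   as row names and `snp1` .. as column names.  Every column is
#'   segregating by construction.
#' @export
drop_mutations <- function(gen, n_snps, seed = NULL) {
  stopifnot(inherits(gen, "phylo"))
  if (n_snps < 1) stop("n_snps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  len <- gen$edge.length
  tot <- sum(len)
  if (!isTRUE(tot > 0)) stop("genealogy has zero total branch length")
  D <- edge_tip_indicator(gen)
  hit <- sample.int(nrow(gen$edge), size = n_snps, replace = TRUE,
                    prob = len)
  mat <- t(D[hit, , drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- gen$tip.label
  colnames(mat) <- paste0("snp", seq_len(n_snps))
  mat
}

# 0/1 indicator matrix: rows = edges, columns = tips; 1 if the tip descends
# from the edge's child node.
edge_tip_indicator <- function(gen) {
  n <- ape::Ntip(gen)
  po <- ape::reorder.phylo(gen, "postorder")
  n_nodes <- n + gen$Nnode
  below <- matrix(FALSE, nrow = n_nodes, ncol = n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]
    chd <- po$edge[i, 2L]
    below[par, ] <- below[par, ] | below[chd, ]
  }
  D <- below[gen$edge[, 2L], , drop = FALSE]
  colnames(D) <- gen$tip.label
  D * 1L
}

#' Partition a rooted genealogy at its root
#'
#' Splits the tips into the two subtrees of the root.  The side containing
#' more than half of the tips is the "major clade"; when the two sides are
#' equal there is no major clade.
#'
#' @param gen a rooted binary `phylo`.
#' @return list with tip-label vectors `A` and `B` (A listed first as
#'   encountered in the edge table), sizes `n_A`, `n_B`, and `major`: `"A"`,
#'   `"B"` or `NA` for a tie.
#' @export
root_partition <- function(gen) {
  stopifnot(inherits(gen, "phylo"))
  n <- ape::Ntip(gen)
  root <- n + 1L
  kids <- gen$edge[gen$edge[, 1L] == root, 2L]
  if (length(kids) != 2L) stop("genealogy root must be binary")
  D <- edge_tip_indicator(gen)
  rows <- match(kids, gen$edge[, 2L])
  A <- gen$tip.label[D[rows[1L], ] == 1L]
  B <- gen$tip.label[D[rows[2L], ] == 1L]
  major <- if (length(A) == length(B)) NA_character_
           else if (length(A) > length(B)) "A" else "B"
  list(A = A, B = B, n_A = length(A), n_B = length(B), major = major)
}

#' Extract the major root clade as a subtree
#'
#' @param gen a rooted binary `phylo`.
#' @return the induced subtree (`phylo`) of the root child containing more
#'   than half of the tips, with branch lengths preserved, or `NULL` when
#'   the root splits the tips evenly.
#' @export
major_clade <- function(gen) {
  part <- root_partition(gen)
  if (is.na(part$major)) return(NULL)
  ape::keep.tip(gen, if (part$major == "A") part$A else part$B)
}

#' Read / write genealogies in newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()]; branch
#' lengths round-trip at full precision (the writer keeps enough digits that
#' coalescent intervals agree to better than 1e-9 relative error).
#'
#' @param gen a `phylo`.
#' @param path file path.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
write_newick <- function(gen, path) {
  stopifnot(inherits(gen, "phylo"))
  ape::write.tree(gen, file = path, digits = 15)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  gen <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("malformed newick in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(gen)) stop("malformed newick in '", path, "'")
  gen
}
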