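#' Pairwise p-distance matrix from a haplotype matrix
#'
#' `d(a, b)` = fraction of SNP columns at which samples `a` and `b` differ.
#' Computed via a cross-product so that hundreds of samples by tens of
#' thousands of sites take well under a second.
#'
#' @param mat haplotype matrix, samples x sites, 0/1, no missing values.
#' @return symmetric numeric matrix with zero diagonal, entries in \[0, 1\],
#'   sample names as dimnames.
#' @export
p_distance <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) == 0L || ncol(mat) == 0L)
    stop("haplotype matrix must have at least one sample and one site")
  if (anyNA(mat)) stop("missing genotypes are not supported")
  m <- mat * 1.0
  shared11 <- tcrossprod(m)
  ones <- rowSums(m)
  diff <- outer(ones, ones, "+") - 2 * shared11
  d <- diff / ncol(mat)
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]).  Finite SNP sets
#' can yield slightly non-additive distances and hence negative estimated
#' branch lengths; following common practice these are clamped to zero with
#' the deficit transferred to the sibling branch at the same node, so path
#' lengths through the node are preserved where possible.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 samples.
#' @return an unrooted `phylo`.
#' @export
neighbor_joining <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3L) stop("neighbor joining requires at least 3 samples")
  phy <- ape::nj(as.dist(dm))
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    deficit <- phy$edge.length[e]
    sib <- which(phy$edge[, 1L] == phy$edge[e, 1L])
    sib <- setdiff(sib, e)
    phy$edge.length[e] <- 0
    if (length(sib)) {
      s <- sib[1L]
      phy$edge.length[s] <- phy$edge.length[s] + deficit
    }
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering; the resulting tree is rooted
#' and ultrametric, with each node's height equal to half the merge
#' distance (so tip-to-tip path lengths reproduce cluster-average
#' distances).
#'
#' @param d symmetric distance matrix (or `dist`) over >= 2 samples.
#' @return a rooted ultrametric `phylo` with heights in the input distance
#'   unit.
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 2L) stop("UPGMA requires at least 2 samples")
  hc <- stats::hclust(as.dist(dm), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples SNP columns with replacement `n_reps` times, rebuilds the NJ
#' tree from each pseudo-replicate, and records for every internal edge of
#' the full-data tree the percentage of replicates containing the same tip
#' bipartition.  Supports are stored as node labels.
#'
#' @param mat haplotype matrix, samples x sites.
#' @param n_reps number of bootstrap replicates, >= 1.
#' @param seed RNG seed for the resampling.
#' @return the full-data NJ `phylo` with `node.label` holding percent
#'   supports (`NA` for the unlabelled root position).
#' @export
bootstrap_support <- function(mat, n_reps, seed = 1L) {
  stopifnot(n_reps >= 1)
  full <- neighbor_joining(p_distance(mat))
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    boots[[b]] <- neighbor_joining(p_distance(mat[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  full$node.label <- round(100 * counts / n_reps)
  full
}

#' Cut a tree into clades by removing its longest edges
#'
#' Greedily removes, in decreasing length order (ties broken by edge
#' index), edges whose removal separates the tips of a current group into
#' two non-empty groups, stopping when `k` tip groups exist.  On data with
#' long inter-clade stems this recovers the stems as the cut edges.  The
#' delineation rule is this package's own operational choice for turning a
#' tree into discrete clades; it is validated on synthetic data where the
#' truth is known.
#'
#' @param tree a `phylo` (rooted or unrooted).
#' @param k number of clades, `1 <= k <=` number of tips.
#' @return named character vector: clade label (`clade1` .. `cladek`) per
#'   tip, labels ordered by each clade's smallest tip index.
#' @export
cut_clades <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop("cannot cut more clades than tips")
  n_nodes <- n + tree$Nnode
  removed <- rep(FALSE, nrow(tree$edge))
  ord <- order(-tree$edge.length, seq_along(tree$edge.length))
  groups <- 1L
  adj_tips <- function() {
    # connected components over non-removed edges; returns tip membership
    parent <- seq_len(n_nodes)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (e in which(!removed)) {
      a <- find(tree$edge[e, 1L]); b <- find(tree$edge[e, 2L])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n), find, integer(1))
  }
  for (e in ord) {
    if (groups >= k) break
    removed[e] <- TRUE
    comp <- adj_tips()
    g <- length(unique(comp))
    if (g > groups) groups <- g else removed[e] <- FALSE
  }
  comp <- adj_tips()
  first_tip <- vapply(split(seq_len(n), comp), min, integer(1))
  lab_order <- rank(first_tip)
  labels <- paste0("clade", lab_order[as.character(comp)])
  names(labels) <- tree$tip.label
  labels
}

#' Clade frequencies from label assignments
#'
#' @param labels character vector of clade labels (one per sample).
#' @param levels optional label ordering; defaults to sorted unique labels.
#' @return named numeric vector of per-clade frequencies (counts / n).
#' @export
clade_frequencies <- function(labels, levels = NULL) {
  if (length(labels) < 1L) stop("need at least one sample")
  if (is.null(levels)) levels <- sort(unique(labels))
  tab <- table(factor(labels, levels = levels))
  as.numeric(tab) / length(labels) -> f
  stats::setNames(f, levels)
}
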