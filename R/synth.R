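#' Configuration for the clade-structured synthetic SNP generator
#'
#' @param n_samples number of haploid samples, >= 2.
#' @param n_snps number of segregating SNP columns to generate, >= 1.
#' @param clade_freqs clade-frequency vector used to draw clade membership
#'   (sums to 1 within `tol`); defaults to the packaged mainland Japanese
#'   seven-clade vector.
#' @param stem_scale length of the stem separating each clade from the
#'   common root, as a multiple of the mean within-clade coalescent depth.
#'   Large values (the default 20) force clades to be deeply divergent and
#'   monophyletic in reconstructed trees, mimicking the distinct clades seen
#'   in real Y-chromosome trees.
#' @param seed RNG seed.
#' @param tol tolerance for `sum(clade_freqs) - 1` (printed tables carry
#'   rounding error).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_samples, n_snps,
                         clade_freqs = east_asian_freqs()[, "Mainland Japanese"],
                         stem_scale = 20, seed = 1L, tol = 0.01) {
  stopifnot(n_samples >= 2, stem_scale > 0)
  if (n_snps < 1) stop("n_snps must be at least 1")
  validate_freqs(clade_freqs, n_clades = length(clade_freqs), tol = tol)
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 clade_freqs = clade_freqs / sum(clade_freqs),
                 stem_scale = stem_scale, seed = seed),
            class = "synth_config")
}

#' Generate clade-structured haploid SNP data
#'
#' Emulates a sample of haploid chromosomes partitioned into deeply
#' divergent clades.  Clade sizes are a multinomial draw from
#' `clade_freqs`; each clade with two or more members gets an independent
#' constant-size Kingman coalescent genealogy (in coalescent time units),
#' and clade subtrees hang from a common root by stems of length
#' `stem_scale` times the mean within-clade depth, making every clade
#' monophyletic by construction.  Exactly `n_snps` mutations are then
#' dropped branch-proportionally under the infinite-sites model
#' ([drop_mutations()]).  Clades drawn with zero members are simply absent.
#'
#' @param config a [synth_config()].
#' @return list with `matrix` (haplotypes, samples x sites, 0/1),
#'   `labels` (true clade label per sample, aligned with row names),
#'   `genealogy` (the generating `phylo`), and `clade_sizes`.
#'   Deterministic given `config$seed`.
#' @export
generate_clade_haplotypes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nc <- length(config$clade_freqs)
  sizes <- as.integer(rmultinom(1L, config$n_samples, config$clade_freqs))
  present <- which(sizes > 0L)
  kingman <- demographic_model(n0 = 1)  # constant size, coalescent units
  subtrees <- vector("list", length(present))
  depths <- numeric(length(present))
  for (j in seq_along(present)) {
    if (sizes[present[j]] >= 2L) {
      tr <- simulate_genealogy(kingman, sizes[present[j]])
      subtrees[[j]] <- tr
      depths[j] <- max(node_times(tr))
    } else {
      subtrees[[j]] <- NA  # singleton clade: bare tip
      depths[j] <- NA_real_
    }
  }
  mean_depth <- if (all(is.na(depths))) 1 else mean(depths, na.rm = TRUE)
  stem <- config$stem_scale * mean_depth

  labels <- rep(paste0("clade", present), sizes[present])
  ids <- sprintf("s%03d", seq_len(config$n_samples))
  gen <- join_clades(subtrees, stem)
  gen$tip.label <- ids  # tips are laid out clade by clade, in `present` order
  mat <- drop_mutations(gen, config$n_snps)
  names(labels) <- rownames(mat)
  list(matrix = mat, labels = labels, genealogy = gen,
       clade_sizes = stats::setNames(sizes, paste0("clade", seq_len(nc))))
}

# Join clade subtrees (phylo objects, or NA for singleton tips) under a
# common root with a stem of the given length above each clade root/tip.
# With a single clade the subtree itself is returned (no stem).
join_clades <- function(subtrees, stem) {
  k <- length(subtrees)
  if (k == 1L) {
    if (identical(subtrees[[1L]], NA))
      stop("cannot build a genealogy from a single lone sample")
    return(subtrees[[1L]])
  }
  tip_counts <- vapply(subtrees, function(s)
    if (identical(s, NA)) 1L else ape::Ntip(s), integer(1))
  int_counts <- vapply(subtrees, function(s)
    if (identical(s, NA)) 0L else s$Nnode, integer(1))
  n <- sum(tip_counts)
  n_int <- 1L + sum(int_counts)  # new root + subtree internals
  edge <- matrix(0L, nrow = 0L, ncol = 2L)
  edge_len <- numeric(0)
  root <- n + 1L
  tip_off <- 0L
  int_off <- n + 1L  # internal ids handed out after the root
  for (j in seq_len(k)) {
    s <- subtrees[[j]]
    if (identical(s, NA)) {
      edge <- rbind(edge, c(root, tip_off + 1L))
      edge_len <- c(edge_len, stem)
      tip_off <- tip_off + 1L
    } else {
      nt <- ape::Ntip(s)
      remap <- c(tip_off + seq_len(nt), int_off + seq_len(s$Nnode))
      sub_edge <- matrix(remap[s$edge], ncol = 2L)
      sub_root <- int_off + 1L  # subtree root is its node nt + 1
      edge <- rbind(edge, c(root, sub_root), sub_edge)
      edge_len <- c(edge_len, stem, s$edge.length)
      tip_off <- tip_off + nt
      int_off <- int_off + s$Nnode
    }
  }
  storage.mode(edge) <- "integer"
  phy <- structure(list(edge = edge, edge.length = edge_len,
                        tip.label = paste0("t", seq_len(n)),
                        Nnode = n_int),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}
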