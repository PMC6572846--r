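test_that("p-distance counts mismatching columns", {
  m <- rbind(a = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
             b = c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
             c = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
             d = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  d <- p_distance(m)
  expect_equal(d["a", "d"], 0)
  expect_equal(d["a", "b"], 0.2)
  expect_equal(d["a", "c"], 1.0)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_error(p_distance(m[0, , drop = FALSE]), "at least one")
})

test_that("neighbor joining recovers additive quartets exactly", {
  # distances implied by the tree ((A:2,B:3):1,(C:4,D:5))
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- 5; dm["A", "C"] <- 7; dm["A", "D"] <- 8
  dm["B", "C"] <- 8; dm["B", "D"] <- 9; dm["C", "D"] <- 9
  dm <- dm + t(dm)
  tree <- neighbor_joining(dm)
  # brute-force oracle: least squares over all three quartet topologies
  expect_equal(best_quartet_topology(dm), 2L)  # A pairs with B
  expect_equal(ls_fit_quartet(dm, 2L)$rss, 0, tolerance = 1e-12)
  # path lengths reproduce the input exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(dm),
                                                      colnames(dm)],
               dm, tolerance = 1e-9)
  expect_error(neighbor_joining(dm[1:2, 1:2]), "at least 3")
})

test_that("three taxa resolve with the closed-form star lengths", {
  dm <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(dm)
  v <- stats::setNames(tree$edge.length[match(1:3, tree$edge[, 2L])],
                       tree$tip.label)
  expect_equal(v[["A"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(v[["B"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(v[["C"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(41)
  for (i in 1:5) {
    true <- ape::rtree(8)
    dm <- as.matrix(ape::cophenetic.phylo(true))
    est <- neighbor_joining(dm)
    expect_equal(as.matrix(ape::cophenetic.phylo(est))[rownames(dm),
                                                       colnames(dm)],
                 dm, tolerance = 1e-9)
  }
})

test_that("UPGMA is ultrametric with half-merge-distance heights", {
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(max(node_times(t2)), 0.1)
  # exact recovery of an ultrametric input
  g <- simulate_genealogy(demographic_model(100), 10, seed = 42)
  dm <- as.matrix(ape::cophenetic.phylo(g))
  rec <- upgma(dm)
  expect_true(ape::is.ultrametric(rec))
  expect_equal(as.matrix(ape::cophenetic.phylo(rec))[rownames(dm),
                                                     colnames(dm)],
               dm, tolerance = 1e-9)
  # ultrametricity holds on noisy (non-ultrametric) input too
  set.seed(43)
  noisy <- dm + matrix(runif(100, 0, 0.05), 10)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0
  tt <- upgma(noisy)
  depths <- ape::node.depth.edgelength(tt)[seq_len(10)]
  expect_lt(diff(range(depths)), 1e-9)
})

test_that("UPGMA height tracks the true TMRCA on clock-like SNP data", {
  set.seed(44)
  reps <- 60
  ratio <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- simulate_genealogy(demographic_model(200), 50)
    mat <- drop_mutations(g, 5000)
    est <- upgma(p_distance(mat))
    # p-distance heights scale as (time / total length); undo that scale
    ratio[i] <- max(node_times(est)) * sum(g$edge.length) /
      max(node_times(g))
  }
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("bootstrap supports are percentages and strong for deep clades", {
  cfg <- synth_config(30, 800, stem_scale = 20, seed = 45)
  sim <- generate_clade_haplotypes(cfg)
  tree <- bootstrap_support(sim$matrix, n_reps = 100, seed = 46)
  sup <- as.numeric(tree$node.label)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # determinism for a fixed seed
  tree2 <- bootstrap_support(sim$matrix, n_reps = 100, seed = 46)
  expect_identical(tree$node.label, tree2$node.label)
  # clade-defining edges: support of each true clade's bipartition
  labs <- sim$labels[tree$tip.label]
  present <- unique(labs)
  big <- names(which(table(labs) >= 2))
  for (cl in big) {
    node <- ape::getMRCA(tree, names(labs)[labs == cl])
    sup_cl <- as.numeric(tree$node.label[node - ape::Ntip(tree)])
    if (!is.na(sup_cl)) expect_gte(sup_cl, 95)
  }
})

test_that("clade cutting spans the trivial and synthetic cases", {
  g <- simulate_genealogy(demographic_model(50), 8, seed = 47)
  expect_equal(unname(unique(cut_clades(g, 1))), "clade1")
  singles <- cut_clades(g, 8)
  expect_equal(length(unique(singles)), 8L)
  expect_error(cut_clades(g, 0), "at least 1")
  expect_error(cut_clades(g, 9), "more clades than tips")
  cfg <- synth_config(60, 1500, stem_scale = 20, seed = 48)
  sim <- generate_clade_haplotypes(cfg)
  tree <- neighbor_joining(p_distance(sim$matrix))
  labels <- cut_clades(tree, length(unique(sim$labels)))
  expect_equal(partition_agreement(labels[rownames(sim$matrix)],
                                   sim$labels), 1)
})

test_that("clade frequencies reproduce published counts-to-frequency rounding", {
  labels <- rep(c("clade1", "clade2", "clade3", "other"),
                c(122, 100, 68, 55))
  f <- clade_frequencies(labels)
  expect_equal(round(f[["clade1"]], 3), 0.354)
  expect_equal(round(f[["clade3"]], 3), 0.197)
  expect_equal(sum(f), 1)
  expect_equal(unname(clade_frequencies("clade5")), 1)
})
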