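test_that("detection study is deterministic and records per-run artifacts", {
  out_dir <- withr::local_tempdir()
  a <- run_detection_study(n_runs = 2, sample_size = 60, n_snps = 2000,
                           seed = 71, output_dir = out_dir)
  b <- run_detection_study(n_runs = 2, sample_size = 60, n_snps = 2000,
                           seed = 71)
  expect_identical(a$runs$detected, b$runs$detected)
  expect_identical(a$runs$n_major, b$runs$n_major)
  expect_lte(a$detection_count, a$n_effective)
  expect_true(file.exists(file.path(out_dir, "study_report.json")))
  expect_true(file.exists(file.path(out_dir, "run001_tree.nwk")))
  expect_true(file.exists(file.path(out_dir, "run001_skyline.tsv")))
  rep_json <- jsonlite::read_json(file.path(out_dir, "study_report.json"))
  expect_equal(rep_json$config$seed, 71)
  expect_equal(rep_json$config$sample_size, 60)
})

test_that("major-clade sizes always exceed half the sample", {
  rep <- run_detection_study(n_runs = 5, sample_size = 50, n_snps = 1000,
                             seed = 72)
  done <- !is.na(rep$runs$n_major)
  expect_true(all(rep$runs$n_major[done] > 25))
})

test_that("admixture wrapper writes JSON and a top-k TSV", {
  json <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  run_admixture(mj, kr, n_iter = 2000, top_k = 20, seed = 73,
                out_json = json, out_tsv = tsv)
  top <- read.delim(tsv)
  expect_equal(nrow(top), 20L)
  expect_equal(ncol(top), 9L)  # rank, si, 7 clades
  expect_false(is.unsorted(top$si))
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$si_threshold, max(top$si), tolerance = 1e-12)
  expect_length(parsed$mean_freqs, 7L)
})

test_that("identical sources under full replacement give similarity zero", {
  res <- run_mc(mj, mj, alpha = 1, n_iter = 500, top_k = 5, seed = 74)
  # w = x never matches y exactly, but alpha = 0 collapses w onto y = z
  res0 <- run_mc(mj, mj, alpha = 0, n_iter = 500, top_k = 5, seed = 74)
  expect_equal(res0$top_si, rep(0, 5))
  expect_true(all(res$top_si >= 0))
})

test_that("frequency TSV reader validates its columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("clade\tfrequency\nclade1\t0.6\nclade2\t0.4", path)
  v <- read_freq_tsv(path)
  expect_equal(unname(v), c(0.6, 0.4))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("clade\tvalue\nclade1\t0.6", bad)
  expect_error(read_freq_tsv(bad), "frequency")
  na_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines("clade\tfrequency\nclade1\t0.6\nclade2\tNA", na_file)
  expect_error(read_freq_tsv(na_file), "row")
})

cli_path <- system.file("cli", "ydemos.R", package = "ydemos")

run_cli <- function(args, dir) {
  out <- suppressWarnings(
    system2("Rscript", c(cli_path, args), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

test_that("command-line admixture runs are byte-identical across calls", {
  dir <- withr::local_tempdir()
  j1 <- file.path(dir, "a1.json"); t1 <- file.path(dir, "a1.tsv")
  j2 <- file.path(dir, "a2.json"); t2 <- file.path(dir, "a2.tsv")
  r1 <- run_cli(c("admix-mc", "--iters", "1000", "--top-k", "20",
                  "--seed", "1", "--out-json", j1, "--out-tsv", t1), dir)
  expect_equal(r1$status, 0L)
  r2 <- run_cli(c("admix-mc", "--iters", "1000", "--top-k", "20",
                  "--seed", "1", "--out-json", j2, "--out-tsv", t2), dir)
  expect_identical(readLines(j1), readLines(j2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("synth, nj and clades subcommands chain into clade recovery", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "s.vcf")
  labels <- file.path(dir, "truth.tsv")
  tree <- file.path(dir, "nj.nwk")
  clades <- file.path(dir, "clades.tsv")
  expect_equal(run_cli(c("synth", "--samples", "60", "--snps", "1500",
                         "--seed", "5", "--out-vcf", vcf,
                         "--out-labels", labels), dir)$status, 0L)
  expect_equal(run_cli(c("nj", "--vcf", vcf, "--out-tree", tree),
                       dir)$status, 0L)
  truth <- read.delim(labels)
  k <- length(unique(truth$clade))
  expect_equal(run_cli(c("clades", "--tree", tree, "--k", k,
                         "--out", clades), dir)$status, 0L)
  found <- read.delim(clades)
  merged <- merge(truth, found, by = "sample")
  expect_equal(partition_agreement(merged$clade.x, merged$clade.y), 1)
})

test_that("unknown subcommands exit nonzero", {
  dir <- withr::local_tempdir()
  expect_gt(run_cli("frobnicate", dir)$status, 0)
})
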