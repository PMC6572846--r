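#' Simulate-and-detect replication study
#'
#' Runs the end-to-end pipeline `n_runs` times: simulate a genealogy under
#' the demographic model, split it at the root, keep the major clade
#' (> 50% of tips; a tie is flagged and the run skipped), drop the full SNP
#' budget on the major-clade subtree, rebuild the genealogy from the SNP
#' data (p-distance + UPGMA), calibrate it to years with the matched
#' per-column clock (one mutation per column over the subtree's total
#' branch length, times the generation time), estimate a skyline, and apply
#' the detection rule.  Failures in any run are recorded, never abort the
#' study.
#'
#' Per-run seeds are derived from the master seed by a fixed counter
#' scheme, `(seed + 1000003 * run) mod (2^31 - 1)`, so any single run can
#' be reproduced in isolation and the detection count does not depend on
#' execution order.
#'
#' @param model a [demographic_model()]; defaults to [jomon_model()].
#' @param n_runs number of replicate runs.
#' @param sample_size chromosomes sampled per run.
#' @param n_snps SNP budget dropped on the major-clade subtree.
#' @param rule a [detection_rule()].
#' @param estimator `"generalized"` (default; deterministic and fast),
#'   `"bayesian"`, or `"classical"`.
#' @param generation_time years per generation (default 25).
#' @param seed master seed.
#' @param n_groups group count for the Bayesian estimator.
#' @param output_dir optional directory; when given, each run's calibrated
#'   genealogy (newick), skyline (TSV) and the study report (JSON,
#'   embedding the full configuration and seeds) are written there.
#' @return an object of class `study_report`: list with `runs` (data frame:
#'   run, seed, n_major, detected, error), `detection_count`, `n_effective`
#'   (runs that produced a verdict) and `config`.
#' @examples
#' \donttest{
#' rep <- run_detection_study(n_runs = 2, sample_size = 60, n_snps = 2000,
#'                            seed = 1)
#' rep$detection_count
#' }
#' @export
run_detection_study <- function(model = jomon_model(), n_runs = 10L,
                                sample_size = 200L, n_snps = 28254L,
                                rule = detection_rule(),
                                estimator = c("generalized", "bayesian",
                                              "classical"),
                                generation_time = 25, seed = 1L,
                                n_groups = 10L, output_dir = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(n_runs >= 1, sample_size >= 2, n_snps >= 1, generation_time > 0)
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  runs <- data.frame(run = seq_len(n_runs),
                     seed = (seed + 1000003 * seq_len(n_runs)) %%
                       (2^31 - 1),
                     n_major = NA_integer_, detected = NA,
                     error = NA_character_)
  for (r in seq_len(n_runs)) {
    res <- tryCatch({
      out <- run_single_detection(model, sample_size, n_snps, rule,
                                  estimator, generation_time,
                                  run_seed = runs$seed[r],
                                  n_groups = n_groups)
      if (!is.null(output_dir)) {
        write_newick(out$genealogy,
                     file.path(output_dir, sprintf("run%03d_tree.nwk", r)))
        write_skyline(out$skyline,
                      file.path(output_dir, sprintf("run%03d_skyline.tsv", r)))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      runs$error[r] <- conditionMessage(res)
    } else {
      runs$n_major[r] <- res$n_major
      runs$detected[r] <- res$detected
    }
  }
  report <- structure(list(
    runs = runs,
    detection_count = sum(runs$detected, na.rm = TRUE),
    n_effective = sum(!is.na(runs$detected)),
    config = list(model = unclass(model), n_runs = n_runs,
                  sample_size = sample_size, n_snps = n_snps,
                  rule = unclass(rule), estimator = estimator,
                  generation_time = generation_time, seed = seed,
                  n_groups = n_groups)), class = "study_report")
  if (!is.null(output_dir))
    jsonlite::write_json(report_to_list(report),
                         file.path(output_dir, "study_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

run_single_detection <- function(model, sample_size, n_snps, rule,
                                 estimator, generation_time, run_seed,
                                 n_groups) {
  set.seed(run_seed)
  gen <- simulate_genealogy(model, sample_size)
  sub <- major_clade(gen)
  if (is.null(sub)) stop("no major clade: root splits the sample evenly")
  mat <- drop_mutations(sub, n_snps)
  # matched clock: the fixed budget puts one mutation per column over the
  # subtree's total branch length, so the per-column rate per year is
  # 1 / (total length in generations * generation time)
  total_len <- sum(sub$edge.length)
  clock <- clock_model(per_column_rate = 1 / (total_len * generation_time))
  tree <- calibrate_tree(upgma(p_distance(mat)), clock)
  est <- switch(estimator,
    classical = classical_skyline(tree),
    generalized = generalized_skyline(tree),
    bayesian = bayesian_skyline(tree, n_groups = n_groups,
                                seed = run_seed)$skyline)
  list(n_major = ape::Ntip(sub), detected = detect_change(est, rule),
       skyline = est, genealogy = tree)
}

report_to_list <- function(report) {
  list(config = report$config,
       detection_count = report$detection_count,
       n_effective = report$n_effective,
       runs = report$runs)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Detection study: %d run(s), estimator '%s'\n",
              nrow(x$runs), x$config$estimator))
  cat(sprintf("Pattern detected in %d of %d effective runs\n",
              x$detection_count, x$n_effective))
  failed <- sum(!is.na(x$runs$error))
  if (failed) cat(sprintf("%d run(s) failed or were skipped\n", failed))
  invisible(x)
}

#' Run the admixture Monte Carlo and persist results
#'
#' Convenience wrapper over [run_mc()] that accepts frequency vectors or
#' TSV paths (two columns: `clade`, `frequency`) and optionally writes the
#' result as JSON plus a TSV of the retained top-k sets.
#'
#' @param y,z clade-frequency vectors, or paths to TSV files.
#' @inheritParams run_mc
#' @param out_json,out_tsv optional output paths.
#' @return the `mc_result`, invisibly when files are written.
#' @export
run_admixture <- function(y, z, alpha = 0.12, n_iter = 1e8, top_k = 20L,
                          seed = NULL, out_json = NULL, out_tsv = NULL) {
  if (is.character(y)) y <- read_freq_tsv(y)
  if (is.character(z)) z <- read_freq_tsv(z)
  res <- run_mc(y, z, alpha = alpha, n_iter = n_iter, top_k = top_k,
                seed = seed)
  if (!is.null(out_json)) {
    jsonlite::write_json(list(
      alpha = alpha, n_iter = n_iter, top_k = top_k, seed = seed,
      si_threshold = res$si_threshold, top_si = res$top_si,
      mean_freqs = as.list(stats::setNames(res$mean_freqs,
                                           paste0("clade",
                                                  seq_along(res$mean_freqs))))),
      out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(out_tsv)) {
    df <- data.frame(rank = seq_along(res$top_si), si = res$top_si,
                     res$top_x)
    names(df)[-(1:2)] <- paste0("clade", seq_len(ncol(res$top_x)))
    write.table(df, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.null(out_json) && is.null(out_tsv)) res else invisible(res)
}

#' Read a clade-frequency vector from TSV
#'
#' Expects columns `clade` and `frequency`; rows are ordered by the file.
#'
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_freq_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("clade", "frequency") %in% names(df)))
    stop("frequency TSV must have 'clade' and 'frequency' columns; ",
         "problem in file '", path, "'")
  if (any(is.na(df$frequency)))
    stop("missing frequency in row(s) ",
         paste(which(is.na(df$frequency)), collapse = ", "),
         " of '", path, "'")
  stats::setNames(df$frequency, df$clade)
}
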