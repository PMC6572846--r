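# ydemos

Inference of male population history from Y-chromosome clade frequencies
and genealogies.

The package is built for a recurring situation in human population
genetics: a present-day population is an admixture of an extinct (or
unsampled) source and a well-sampled one, its non-recombining Y
chromosomes fall into a handful of deeply divergent clades, and the
questions are (i) what the clade composition of the unsampled source was
and (ii) how its male effective population size changed through time.
The motivating system is the Japanese archipelago — indigenous Jomon
hunter-gatherers admixing with continental Yayoi immigrants — but every
component is parameterized and reusable.

## What it computes

**Admixture Monte Carlo.** With observed clade frequencies `y` in the
admixed population and `z` in the sampled source, the unknown source
vector `x` enters through

    w_i = alpha * x_i + (1 - alpha) * z_i,       alpha = 0.12 by default

and candidate `x` drawn as normalized uniforms are scored by the
similarity index

    SI = sum_i |w_i - y_i| / (w_i + y_i).

`run_mc()` streams 10^8 draws in vectorized chunks, retains the top 20 by
ascending SI, and reports their mean as the estimate of `x`.
`min_si_search()` bounds the attainable SI independently by simplex
optimization.

**Coalescent simulation.** `simulate_genealogy()` draws Kingman
genealogies under piecewise-constant demography (sizes in gene copies;
rate k(k−1)/2N per generation); `drop_mutations()` places an exact SNP
budget on branches (infinite sites); `jomon_model()` packages the
three-event history (N = 10,000; ×0.112 at 80 gen, ×3.58 at 120 gen,
×0.172 at 580 gen).

**Trees.** p-distance, neighbor joining, UPGMA, column-bootstrap
supports, and a longest-edge clade cutter (`cut_clades()`), plus haploid
VCF and newick I/O.

**Skylines.** Classical (per-interval), generalized (AICc-chosen
epsilon-pooling), and Bayesian (collapsed MCMC with ESS-monitored chains
and 95% HPD bands) estimators of effective size through time, a per-SNP
column clock (`clock_rate(mu, reliable_sites, n_snps)`), and a
windowed bottleneck-and-recovery detector (`detect_change()`).

**The study.** `run_detection_study()` chains simulate → major-clade
extraction → SNP dropping → UPGMA + clock calibration → skyline →
detection, with per-run derived seeds and per-run artifact output.

See `vignettes/ydemos-methods.Rmd` for the models, conventions and
validation design.

## Worked example

```r
library(ydemos)

tab <- east_asian_freqs()          # published 7-clade frequency table
res <- run_mc(tab[, "Mainland Japanese"], tab[, "Korean"], alpha = 0.12,
              n_iter = 1e6, top_k = 20, seed = 1)
res
#> Admixture Monte Carlo: 1e+06 draws, top 20 by similarity index
#> SI threshold (largest retained): 3.3164
#> Mean source-population clade frequencies:
#> [1] 0.5408 0.2594 0.0558 0.0244 0.0430 0.0405 0.0361
```

The mean of the 20 best-matching draws estimates the source population's
clade frequencies; the SI threshold is the score of the worst retained
draw.  At this demonstration scale (10^6 draws) the clade-1 estimate is
~54%; at the full 10^8 scale the retained set concentrates much closer to
the optimum and typical runs put clade 1 near 71–72%, clade 2 near
14–18% and clade 3 near 2–4% — i.e. the unsampled source was strongly
dominated by clade 1 even though the admixed population carries it at
only 35%.

```r
rep <- run_detection_study(n_runs = 10, seed = 1, estimator = "generalized")
rep
#> Detection study: 10 run(s), estimator 'generalized'
#> Pattern detected in 10 of 10 effective runs
```

Each run simulates 200 chromosomes under the three-event history, keeps
the major clade of the genealogy, rebuilds and calibrates its tree from
28,254 simulated SNPs, and asks whether the skyline shows the crash at
3,000 years before present followed by the recovery at 2,000 — here the
pattern is recovered in all ten replicates despite the analysis seeing
only the major clade.

A command-line front end with the same operations is installed at
`inst/cli/ydemos.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ydemos.R",package="ydemos"))')" \
    admix-mc --iters 1000000 --top-k 20 --seed 1
```

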