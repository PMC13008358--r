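# acripr

Analysis of mRNA N4-acetylcytidine (ac4C) epitranscriptomes from acRIP-seq
coverage, in transcript space.

acRIP-seq sequences an antibody-enriched (acRIP) library alongside a
matched input; an acetylated site shows up as a fragment-scale (~200 nt)
enrichment of acRIP reads on its transcript. `acripr` takes paired
per-window count tracks and a lightweight transcript annotation
(5'UTR/CDS/3'UTR segment lengths) and carries the analysis from windows to
biology:

* **Peak calling** — per-window Poisson enrichment test against the
  input-derived background `λ = (input + 1) · N_acRIP / N_input`,
  Benjamini–Hochberg correction, and the screen **FE > 2, adjusted
  p < 0.05**, where FE is the library-size-normalised acRIP/input ratio.
  Significant windows merge into peaks with summed counts, recomputed FE,
  and a summit at the maximal acRIP window.
* **Reliability filtering** — a peak must recur (≥ 1 nt overlap, single
  linkage) in at least 2 of 3 biological replicates; synaptosome
  transcripts must additionally appear in ≥ 2 of 3 external synaptosome
  reference lists.
* **Transcript statistics** — cumulative fold enrichment
  `ΣFE = Σ_peaks FE` per transcript, and the pseudocount fold change
  `FC = (ΣFE_case + 1) / (ΣFE_ref + 1)`.
* **Classification** — **MISA** (memory-induced synaptic ac4C): FC > 2 at
  day 6 but not at days 1 or 20 of a memory time course; **NASA**
  (NAT10-dependent synaptic ac4C): *diminished* (FE < 1 or peaks lost in
  the *Nat10* knockout) or *downregulated* (detectable but FC > 2 vs
  control); plus exact set-overlap arithmetic between the two.
* **Profiles and distributions** — summit metagenes over length-normalised
  5'UTR|CDS|3'UTR bins, chi-square tests of summit region usage, TPM
  expression with a detection cutoff of TPM > 1, two-sample
  Kolmogorov–Smirnov comparisons of cumulative ΣFE curves, quartile
  summaries.
* **Motifs** — ZOOPS k-mer counting with hypergeometric enrichment against
  a background (supplied, or first-order Markov-generated), BH-adjusted
  over the full 4^k family; IUPAC-degenerate queries supported in
  matching.
* **Synthetic experiments** — `sim_config()` / `simulate_experiment()`
  generate complete paired-track experiments with planted ground truth
  (acetylated transcripts, memory-responsive and NAT10-dependent subsets,
  per-peak knockout fates) for end-to-end validation; generation is a pure
  function of the seed.

Everything is tibble-in/tibble-out and pipe-friendly, with broom-style
`tidy()`/`glance()` accessors and ggplot2 `plot_*()`/`autoplot()` helpers.

## Worked example

Simulate a memory time course (control/memory × days 1, 6, 20 × 3
replicates over 1,000 transcripts) and run the full pipeline:

```r
library(acripr)
library(dplyr)

cfg <- sim_config(seed = 1)
ex  <- simulate_experiment(cfg, memory_design(3))
run <- run_ac4c_pipeline(ex$tracks, ex$annotation)
run
#> <ac4c_run>
#>   peaks/replicate: control.day1.rep1=1244, control.day1.rep2=1207, ...
#>   consensus: control.day1=912, control.day6=909, control.day20=918,
#>              memory.day1=921, memory.day6=907, memory.day20=920
#>   MISA transcripts: 182
```

Each replicate yields ~1,200 screened peaks; the 2-of-3 consensus keeps
~910 reliable peak regions per condition/day. 182 transcripts show the
day-6-specific upregulation that defines MISA. The day-6 ΣFE
distributions separate clearly while the flanking days do not:

```r
run$ks_day6
#> # A tibble: 1 × 2
#>       D        p
#>   <dbl>    <dbl>
#> 1 0.159 2.10e-11

tidy(run) |> filter(is_misa) |> head(3)
#> # A tibble: 3 × 5
#>   transcript_id fc_d1 fc_d6 fc_d20 is_misa
#>   <chr>         <dbl> <dbl>  <dbl> <lgl>
#> 1 tx0007        1.12   2.74  1.00  TRUE
#> 2 tx0025        0.954  2.45  1.03  TRUE
#> 3 tx0028        0.997  2.56  0.972 TRUE
```

The fold-change pattern — near 1 at days 1 and 20, above the cutoff of 2
at day 6 — is exactly the memory-specific signature the classifier
requires. `plot_metagene(run$metagene)` shows the CDS-dominated summit
density, and `plot_cumulative_fe()` draws the cumulative ΣFE curves that
the KS test compares.

A thin command-line wrapper for shell use lives at
`inst/scripts/ac4c.R` (subcommands `simulate`, `callpeaks`, `run`).

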