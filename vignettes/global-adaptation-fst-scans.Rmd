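---
title: "Global adaptation, selective sweeps, and F_ST outliers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global adaptation, selective sweeps, and F_ST outliers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sweepscan)
```

## The scientific question

Genome scans for local adaptation look for windows whose between-population
differentiation (F_ST) is extreme relative to the genome-wide distribution.
The implicit assumption is that such outliers mark alleles under spatially
*varying* selection. But species-wide ("global") adaptation — the routine
fixation of unconditionally beneficial mutations — also perturbs F_ST in
structured populations, in two ways:

* **Lag-type outliers.** A new beneficial mutation sweeps up in its deme of
  origin before migration establishes it elsewhere. During this lag the
  deme frequencies diverge transiently, and a sample taken mid-sweep shows
  a localized F_ST peak.
* **Bierne-type outliers.** During the sweep, recombination places the
  beneficial allele on different haplotype backgrounds in different demes.
  After fixation, the differentiated hitchhiking backgrounds remain as an
  F_ST peak that decays by migration.

How often should we expect such false signals? A back-of-envelope for
*Drosophila melanogaster* fixes the scale: with a proportion of adaptive
nonsynonymous substitutions \(\alpha \approx 0.5\), \(L = 15\) Mbp of
nonsynonymous sites, divergence \(d = 0.0067\) substitutions/bp over
\(T = 14\times 10^6\) generations, adaptive substitutions occur at rate
\(\alpha L d / T \approx 0.0035\) per generation — one every ~280
generations. With \(2 N_e s_a = 250\) and \(N_e = 10^6\), a sweeping allele
needs \(\sim\!10^5\) generations to fix and spends
\(\ln[p_{hi}(1-p_{lo})/(p_{lo}(1-p_{hi}))]/s \approx 22{,}200\) generations
between frequencies 0.2 and 0.8, so roughly \(22{,}200/280 \approx 80\)
incomplete sweeps are in flight at any time. Global adaptation is not a
rare nuisance; it is a steady-state property of large populations.

This package implements that calculation, a two-deme forward simulator of
the competing processes, a windowed F_ST / \(\pi_W\) / \(d_{XY}\) genome
scan, and an outlier-calling pipeline with a neutral null, so that the
lag/Bierne/local-adaptation/drift alternatives can be generated, detected
and compared under controlled conditions.

## The simulation model

`wf_run()` simulates two Wright–Fisher demes of `n_per_deme` diploids.
Each generation consists of:

1. **Migration.** `Poisson(Nm)` random individual pair-swaps between demes,
   so each deme receives an expected `Nm` immigrants. Under this convention
   the two-deme Weir–Cockerham F_ST equilibrates near \(1/(1+8Nm)\):
   0.11 at `Nm = 1` and 0.012 at `Nm = 10`. (The coalescent argument: the
   within-deme pair coalescence time is \(4N\) generations regardless of
   migration, the between-deme time is \(4N + 1/(2m)\) with
   \(m = Nm/N\), and the estimator converges to
   \((\pi_b-\pi_w)/\pi_b\).)
2. **Selection and reproduction.** Parents are drawn within demes with
   probability proportional to multiplicative semidominant fitness:
   genotype fitness \(1\), \(1+s/2\), \(1+s\) per selected mutation, with
   deme-specific \(s\) for spatially antagonistic alleles. Each offspring
   receives two gametes built with `Poisson(rec * L)` uniformly placed
   crossovers.
3. **Mutation.** `Poisson(mu * L)` new mutations per gamete at uniform
   continuous positions (duplicates re-drawn). Inside gene-like regions a
   fraction `p_a` is beneficial with homozygous effects
   \(s \sim \text{Exponential}(\bar S_a)\); elsewhere all mutations are
   neutral. In `local_antagonistic` mode no beneficial mutations arise;
   instead a single allele with effects \(+s\) / \(-s\) in demes 1/2 is
   introduced (and re-introduced on loss) by the run controller.

Migration precedes selection within a generation; the order is immaterial
at these rates but fixed for reproducibility. Burn-in runs neutrally for
`10 * 2 Ne` generations (`Ne = 2 n_per_deme` metapopulation diploids)
before selection is switched on, which is enough for both F_ST (which
equilibrates on the fast timescale \(\sim 1/(2m + 1/2N)\)) and diversity
(timescale \(\sim 4N\)) at the package's default scale. Replicates may
fork from a shared burn-in state (`wf_burn_in()`); forks are separated by
a main phase of at least `2 Ne` generations, several times the F_ST
decorrelation time, before sampling.

Stop conditions implement the sampling protocols of the scenario
comparison: `stop_at_lag(0.5)` samples when a beneficial mutation first
enters the band around 50% metapopulation frequency; `stop_at_fixation
(0.99)` when one exceeds 99% in both demes; `stop_local_established()`
after the antagonistic allele has segregated `5 Ne` generations. A stop
condition that cannot be met raises an explicit timeout error.

## Summary statistics

`window_scan()` computes, in sliding (default 10 kb / 500 bp step) or
gene-centered windows:

* **Weir–Cockerham \(\theta\)** from haplotype counts, combining sites as
  a ratio of sums (stable for low-SNP windows); windows without SNPs are
  reported as `NA`, never 0, and are excluded from outlier testing.
* **\(\pi_W\)**: within-deme mean pairwise differences per site,
  \(\sum_s 2p(1-p)\,n/(n-1) / L\), normalised by the full window length.
* **\(d_{XY}\)**: between-deme mean pairwise differences per site,
  \(\sum_s [p_1(1-p_2)+p_2(1-p_1)] / L\).

Statistics are computed from sampled haplotypes (the simulator's gametes
are exchangeable), not diploid genotypes. All intervals are 0-based and
half-open.

## Outlier calling and classification

`build_null()` pools window F_ST from neutral replicates with matching
demography and computes empirical percentile thresholds (R type-7
inclusive linear interpolation, fixed for bit-reproducibility); a
percentile `q` requires at least `10/(1-q/100)` windows. `call_outliers()`
flags windows strictly above the threshold. For simulated data,
`classify_outliers()` attributes each call: *lag* if a segregating
beneficial mutation at metapopulation frequency in (0.05, 0.95) lies
within one window size of the window center; otherwise *bierne* if a
beneficial mutation fixed within the last `0.5 Ne` generations does;
*drift* for neutral simulations; otherwise *unclassified*. The radius and
horizon are configurable; no operational rule is canonical, so both are
documented choices. `outlier_rate()` reports outliers per 10,000 tested
windows, with a bootstrap that resamples whole replicate datasets, not
windows.

## The three experiments and the desk scale

All experiments run, by default, in a self-consistent "desk world":
`N = 200` diploids per deme, a 1 Mbp chromosome with ten 5 kb gene-like
regions (5% functional, mirroring a 25/500 Mbp ratio), and
`mu = rec = 2.5e-7` (\(4N_e\mu = 4\times10^{-4}\) per site, giving
realistic SNP densities in 10 kb windows). Full-scale populations
(5000/deme, hundreds of Mbp) use the same code; only the parameters
change. Problem sizes below were chosen so each experiment completes in
minutes on a single core.

**Sweep time course** (`experiment_single_sweep()`): one replicate under
recurrent beneficial input, scanned every `Ne/4` generations — the
Manhattan-plot-over-time view in which lag peaks rise, dissipate after
fixation, and reappear elsewhere.

**Outlier-rate grid** (`experiment_outlier_rates()`): cells over
\((\bar S_a, p_a, Nm)\). Desk defaults: 100 replicate datasets per cell
forked from shared burn-ins with 400-generation selection phases,
gene-centered test windows, and a null of ~120,000 sliding windows from
60 neutral forks. Because the desk genome has a far smaller mutational
target than a real genome, the beneficial fractions (e.g.
\(p_a \in \{0.02, 0.1\}\)) are much larger than literature values; the
cells preserve the *contrasts* (5x in \(p_a\), 5x in \(\bar S_a\),
10x in Nm) rather than absolute rates, and the headline DFE cell keeps
\(2N\bar S_a = 200\), the scaled strength corresponding to
\(\bar S_a = 0.02\) at 5000 diploids per deme. Expected behaviour, which
the test suite asserts: rates *decrease* with migration, *increase* with
\(\bar S_a\) and \(p_a\), decrease with threshold stringency, and the
neutral null self-calibrates to 1 outlier per 10,000 windows at the
99.99th percentile. Absolute reference rates (13 and 3 per 10,000 at the
99.99th percentile, 36 and 18 at the 99.9th) belong to the full-scale
configuration and are not desk targets. Each cell also reports its
realized \(\alpha\) (beneficial / all gene-region substitutions), which
shows the degeneracy between DFE shapes: cells with similar \(\alpha\)
can have very different outlier rates.

**Scenario profiles** (`experiment_profiles()`): collects 20 F_ST
outliers per scenario (lag, bierne, local, neutral) and aggregates
F_ST, \(\pi_W\), \(d_{XY}\) in 10 kb distance bins within 100 kb of the
causal site (outlier window center for drift). The desk calibration of
this experiment differs deliberately from the grid:

* `s_a = 0.5` (not the full-scale 0.05): the lag signature is governed by
  the ratio of selection to the per-lineage migration rate,
  \(s/m\) (~125 at 5000/deme); at 200/deme, `s_a = 0.5` restores
  \(s/m = 50\) so sweeps visibly outrun migration. With the
  literal 0.05 at desk scale the demes stay coupled and no lag peak
  clears the null.
* `rec = 2.5e-6` (10x the mutation rate): the hitchhiking footprint
  scales as \(\sim s/(r \ln 4Ns)\); this keeps it near 30–60 kb — wider
  than one window, far smaller than the genome — so troughs are localized
  within the 100 kb flanks.
* 50 haplotypes per deme and a 99th-percentile threshold: window-F_ST
  sampling noise, and hence the null tail, shrinks with sample size, and
  on a ~2000-window desk genome the 99th percentile plays the role the
  99.99th plays on a half-million-window genome (it still admits only
  drift extremes, at a rate that makes 20 neutral outliers collectable).

The expected signatures, asserted as sign tests across outliers: lag —
\(\pi_W\) reduced, \(d_{XY}\) flat; bierne — both reduced; local —
\(d_{XY}\) elevated (the allele is a localized barrier to gene flow);
neutral — no systematic perturbation.

## The analytic module

`fixation_prob()` is Kimura's \(u = (1-e^{-2s_{het}})/(1-e^{-4Ns_{het}})\)
with the exact neutral limit \(1/2N\). `sweep_duration()` returns the
logistic transit time between two frequencies and the conditional
fixation time of a new mutation. Two conventions matter here:

* The scaled strength "\(2N_e s_a = 250\)" is interpreted as a *logistic
  growth rate* \(s = 1.25\times10^{-4}\) for the sweeping allele (the
  heterozygous advantage of a semidominant allele). This calibration
  reproduces both rounded Drosophila figures (97,500 and 22,200
  generations); the homozygous-rate reading gives times twice as long.
* The default fixation time is the asymptotic
  \((2/s)(\ln(2Ns) + \gamma)\). The exact diffusion answer, available as
  `fixation_method = "quadrature"` (numerical integration of the
  conditional sojourn density), is ~11% *longer* at \(2Ns = 250\) —
  and matches a direct Wright–Fisher Monte Carlo (697 ± 12 vs 703 at
  \(N = 500\), \(s_{het} = 0.01\)), so the asymptotic form should be read
  as the calibration consistent with those rounded figures, the quadrature
  as the precise diffusion value.

`predict_alpha()` maps a DFE \((p_a, \bar S_a)\) and population size to
the long-run adaptive proportion of substitutions
\(\alpha = p_a E[u] / (p_a E[u] + (1-p_a)/2N)\), with the DFE expectation
taken by adaptive quadrature; it is monotone in both DFE parameters, and
many \((p_a, \bar S_a)\) pairs give the same \(\alpha\) — the degeneracy
the grid experiment quantifies in terms of outlier rates.

## Numerical and design choices

* **Reproducibility.** All randomness flows through `derive_seed(master,
  stage, index)`; the engine is seeded per phase; identical seeds give
  bit-identical samples, and `run_manifest()` / `rerun_manifest()` round
  trip a complete run. Consecutive replicate indices are guaranteed
  distinct seeds.
* **Ties and interpolation.** Null thresholds use R's type-7 quantile;
  outliers must exceed the threshold strictly; windows are half-open so a
  site belongs to exactly one non-overlapping window.
* **Degenerate inputs.** Zero-SNP windows yield `NA` F_ST (propagated,
  excluded from rates); `pi_within()` requires two haplotypes; `d_xy()`
  one per deme; a never-satisfiable stop condition raises a timeout
  rather than returning silently.
* **Fitness floor.** Multiplicative fitness is floored at 0 (relevant
  only for strong antagonistic homozygotes).
* **Fixed selected sites** are recorded in the substitution archive with
  their fixation generation (used by the Bierne classification) rather
  than as monomorphic matrix columns.
* **Classification split.** At desk scale most classified outliers in the
  grid experiment are lag-type (the post-fixation Bierne signal decays
  within ~\(1/2m\) = 100 generations, a window the 400-generation
  sampling interval rarely catches); the roughly even lag/Bierne split
  reported at full scale is not reproduced at desk scale and is not
  asserted.

## What the synthetic data do and do not emulate

The generator reproduces the study conditions: two demes, uniform
mutation and recombination, gene-like regions, exponential beneficial
DFE, semidominance, hard sweeps from new mutations only. It does not
include deleterious or conditionally neutral mutations, soft or parallel
sweeps, more than two demes or continuous space, non-equilibrium
demography, or variable recombination — so passing tests show that the
*method* behaves as described under the model's assumptions, not that
real genomes are free of those complications. In particular, background
selection can mimic the Bierne-type signature, and soft sweeps blur the
lag-type one; both caveats carry over to any application to real data.

## Known limitations

* Desk-scale replicate counts put only modest numbers of outliers behind
  each rate estimate; orderings are robust, absolute rates are not
  comparable with the full-scale values.
* The Weir–Cockerham estimator is computed from haplotypes; genotype-based
  estimates from unphased data would differ slightly.
* The structured-coalescent F_ST calibration is exact only for the
  symmetric two-deme island model implemented here.
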