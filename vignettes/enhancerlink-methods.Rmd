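---
title: "Methods: enhancer calling, gene linking and TF inference in enhancerlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer calling, gene linking and TF inference in enhancerlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`enhancerlink` infers cancer-altered distal enhancers and their downstream
consequences from two paired molecular readouts: an Infinium HM450-style DNA
methylation matrix (beta values, the methylated fraction M/(M+U) at each CpG
probe) and a gene-level expression matrix (RSEM-like normalized abundances),
over a cohort of tumor and normal samples. The pipeline has five inferential
stages, each exposed as an exported function and orchestrated by
`run_pipeline()`:

1. **Probe universe** (`build_probe_universe`): distal probes (strictly more
   than 2 kb from every annotated TSS) partitioned into enhancer probes
   (CpG falls inside an active-enhancer chromHMM state or eRNA region) and
   the non-enhancer remainder, which serves as the permutation null pool.
2. **Differential methylation** (`call_diff_probes`): extreme-quintile
   tumor-vs-normal comparison per probe.
3. **Target-gene linking** (`find_pairs`): rank tests of expression against
   methylation extremes for the 20 nearest genes, corrected by a
   permutation-based empirical p-value.
4. **Motif analysis** (`scan_windows`, `motif_enrichment`): PWM scanning of
   ±100 bp probe windows with exact score p-values, followed by per-probe
   odds-ratio enrichment.
5. **Upstream TF inference** (`rank_tfs`, `resolve_family`): association of
   TF expression with average motif-adjacent methylation, resolved against
   the motif's DNA-binding family.

# The statistical model, stage by stage

## Extreme-quintile differential methylation

Tumor cohorts are heterogeneous: a methylation change confined to one
molecular subtype is diluted in a whole-cohort mean comparison. The method
therefore compares the *lower quintile* of tumor betas (the 20 % least
methylated tumors at that probe) with the lower quintile of normals, using
a one-tailed Welch t-test of the null mu_tumor >= mu_normal. A probe is
called hypomethylated when the Benjamini–Hochberg adjusted p-value is below
0.01 *and* the effect delta = mu_normal − mu_tumor exceeds 0.3.
Hypermethylation mirrors this with upper quintiles and the opposite tail.

Assumptions and choices:

* **Group size** is `max(1, floor(fraction * n))` per group; the floor rule
  with a clamp to 1 is deterministic and safe for small normal panels
  (e.g. 20 normals yield groups of 4). Rounding is exposed via `fraction`.
* **Welch, not pooled.** Quintile groups from tumors and normals have no
  reason to share a variance; `pooled_var = TRUE` is available for exact
  comparison against pooled-variance implementations.
* **Ties** in beta values are broken by lexicographic sample id, making the
  quintile membership (and hence every downstream number) reproducible.
* **Missing betas** are dropped per probe before quantile selection; no
  imputation is ever performed.
* **Degenerate probes** (both quintile groups constant): p = 0.5 when
  the groups are equal, else the tail is saturated at 0 or 1.
* BH adjustment runs across exactly the probes tested in the cohort and
  direction at hand — not the whole array — because cohorts are processed
  independently.

The delta floor of 0.3 is on the beta scale (a fraction in [0, 1]); it
demands a shift visible to the assay well above technical noise.

## Probe–gene linking with a permutation empirical p

For each called probe that passes a variability filter (at least 5 % of all
samples with beta above 0.3 for the hypo direction — i.e. some samples must
actually *be* methylated for a loss to be observable; the rule is mirrored
below 0.3 for hyper), the ten nearest TSSs on each side on the same
chromosome are candidate targets: exactly 20 rank tests per probe.
Distance is unstranded |TSS − CpG|, ranks break ties by gene id.

For a candidate pair, samples are split into the **M group** (top 20 % by
beta at the probe) and the **U group** (bottom 20 %), and a one-sided
Mann–Whitney U test evaluates the null that expression in M is at least
that in U. The rank test makes every downstream quantity invariant to
monotone transforms of expression, so matrices are stored untransformed
(log2(x + 1) would change nothing but plots).

Raw p-values are *not* BH-corrected: neighbouring enhancer probes are
co-methylated, so the tests are far from independent. Instead the gene is
held fixed and the identical test is repeated with `nperm` random probes
drawn from the **distal non-enhancer pool** (enhancer probes would
themselves be co-regulated and would deflate the null), giving permutation
p-values Pp and the empirical p with a pseudo-count of one:

```
p_e = (num(Pp <= p_r) + 1) / (nperm + 1)
```

Pairs with `p_e < 0.001` are reported; with the method's default
`nperm = 10000` the attainable floor is 1/10001. Runs scaled to
`nperm = 1000` keep the floor (1/1001) just under the threshold, so the
default `pe_max` remains meaningful; anything below `nperm = 1000` cannot
produce a reportable pair at the default threshold.

Numerical and design choices:

* **U-test implementation** (`u_test`): exact lower tail via the Wilcoxon
  distribution when the combined group size is at most 12 and no ties are
  present; otherwise a normal approximation with midranks, tie correction
  and continuity correction. The same routine, vectorised over probes,
  produces the permutation p-values, so `Pp <= p_r` compares
  like-with-like.
* **Permutation scope.** Each pair draws its own permutation probes
  (`perm_scope = "pair"`); `"probe"` lets the 20 genes of one probe share a
  draw. Because a pool probe's p-value against a fixed gene is
  deterministic, the implementation caches per-gene p-values over the whole
  pool and lets each pair sample indices — bit-identical to the naive
  procedure at a fraction of the cost.
* **Sampling** is without replacement when the pool is at least `nperm`,
  else with replacement (logged). A small pool coarsens the attainable
  permutation p floor and therefore inflates borderline calls; pools of
  1,000+ probes behave well in simulation.

## Clustering and pair characterization

Called probes within 500 bp chain into enhancer regions by single linkage
(`cluster_probes`). `distance_null_histogram` compares the pair-distance
distribution against 1,000 null datasets of 1,000 random distal probes each
paired with one random candidate; `nearest_rank_profile` tabulates, over
strictly one-to-one pairs, how often the linked gene is the nearest, second
nearest, and so on; `loop_overlap_enrichment` counts pairs whose probe and
TSS fall in opposite anchors of a chromatin loop and compares with 100
random pair sets that preserve the per-probe link-count multiset
(mean ± 1.96 SD band).

## Motif scanning and enrichment

Windows of ±100 bp around each enhancer-probe CpG are scanned on both
strands with each PWM. Scoring is log2 likelihood ratio against a 0-order
background (uniform by default; configurable). A pseudo-frequency
`p_adj = (p + 0.001 * bg) / 1.001` keeps zero-probability bases finite.
Match significance is the exact tail probability of the window score under
the background model, computed by dynamic programming over scores quantized
to 1/1000 of the attainable score range — the standard accuracy/size
trade-off; positions are reported at `p < 1e-4`. Scanning uses the
quantized matrix itself, so reported p-values are exact for the scores
reported. N bases make a position unscorable and it is skipped.

Enrichment of a probe set (the gene-linked probes) against the full
enhancer-probe background is per-probe binarized: `a` counts set probes
with at least one occurrence, `c` the same in the background (the set is a
subset of the background, so the comparison is against overall frequency):

```
OR = (p/(1-p)) / (P/(1-P)),  p = a/(a+b),  P = c/(c+d)
SD = sqrt(1/a + 1/b + 1/c + 1/d)
lower CI = exp(ln(OR) - z * SD)
```

A motif is enriched when the lower CI exceeds 1.1 and `a >= 10`. The
default `z = 1.96` gives the conventional Wald 95 % lower bound; `z = 1`
reproduces a plain one-SD bound for comparison with implementations that
omit the multiplier. Any zero cell makes the motif unevaluable (reported,
not flagged).

## Upstream TF ranking

For each enriched motif, the per-sample average beta over the paired probes
carrying that motif forms a methylation profile. Samples split into M/U
groups on this profile (top/bottom 20 %), and each TF in the supplied list
is tested for lower expression in M (the same one-sided U test). TFs rank
by −log10(p), ties broken by gene id; the top `ceil(0.05 * n_tested)`
(ceiling: inclusive and deterministic) are candidate regulators. The
denominator is the number of TFs actually measurable in the expression
matrix (missing TFs are logged and skipped). `resolve_family` then reports
the top three TFs plus every member of the motif's binding family, flagging
the best-ranked family member only if it reaches the top 5 % — motifs are
shared within families, so expression must disambiguate the member.

The packaged TF list and family map come from the synthetic generator; real
analyses must supply a curated TF census and family table.

# The synthetic cohort generator

`generate_cohort()` emulates the minimal statistical structure the pipeline
assumes, with every planted event recorded in a truth table:

* **Subtype-restricted hypomethylation.** Normals are Beta-distributed
  around probe-specific baselines (drivers: 0.75–0.90); tumors in a planted
  subtype (default 40 % of 100 tumors) are shifted down by `delta_planted`
  (default 0.45) at the 50 driver probes. The Beta concentration of 100
  (SD about 0.04 at beta 0.8) reflects typical within-group array
  dispersion; means are parameterized so values respect [0, 1] without
  clipping artifacts.
* **Anti-correlated targets.** Each driver's planted target gene (candidate
  rank 3 by default — deliberately not the nearest gene, since the nearest
  TSS is the true target only a minority of the time) gains
  `link_effect * (1 - beta)` over its baseline plus Gaussian noise.
* **Motif structure.** A high-information 10-bp consensus is embedded in
  80 % of driver windows and 5 % of other enhancer windows, on a random
  strand at a random offset, in an otherwise uniform random genome.
* **Driver TF.** One TF's expression decreases with the mean driver-probe
  beta at a signal-to-noise ratio of about 2; 200 decoy TFs are pure noise.
* **Layout.** Probes sit 5 kb apart (windows can never overlap); gene TSSs
  sit between probes with ±400 bp jitter, always more than 2 kb from every
  CpG, so the whole manifest is distal and candidate ranks are
  unambiguous. Driver probes are separated by at least
  `n_per_side + target_rank + 1` probe slots: anything closer would put one
  driver's planted target inside a neighbouring driver's candidate window,
  where the shared subtype makes it *genuinely* anti-correlated with both
  probes and the truth table ill-defined.
* Everything is drawn from a single seeded stream: the same `sim_config`
  reproduces byte-identical files.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: co-methylation blocks along the genome,
copy-number and purity confounding, cell-type mixture in normals,
non-uniform genomic base composition, probe cross-reactivity, and batch
structure. The generator validates the inferential machinery, not the
biology.

`generate_null_cohort()` zeroes every planted effect; it underlies the
type-I checks (no differential calls at the default thresholds; the
fraction of candidates with `p_e < alpha` tracks alpha).

# Problem sizes used in the packaged checks

The default cohort is 100 tumors / 20 normals, 2,000 probes on two
synthetic chromosomes (about 900 enhancer probes, about 1,100 permutation
pool probes), 50 drivers, 5 PWMs, 201 TFs. Tests that only exercise one
stage use a 300-probe variant. Permutations run at `nperm = 1000` (scaled
from the 10,000 default, keeping the empirical-p floor below the pair
threshold); the TF stability check repeats ranking over 20 seeds.

# Known limitations

* The quintile t-test treats quintile groups as independent samples; the
  selection step makes the test anti-conservative in principle, which is
  why the delta floor carries much of the specificity burden.
* The empirical p resolution is bounded by `1/(nperm + 1)`; threshold and
  permutation count must be chosen together.
* Only 0-order background models are supported in scanning; CpG-rich
  regions will show elevated chance hit rates for CG-containing motifs.
* TF ranking reflects transcript abundance; regulators controlled
  post-transcriptionally can rank poorly despite genuine activity.
* Trans interactions (different chromosome, or beyond the 10th gene per
  side) are out of scope by construction.
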