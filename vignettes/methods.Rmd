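---
title: "Breed composition and ROH: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed composition and ROH: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gbcroh` estimates genomic breed composition (GBC) and runs-of-homozygosity
(ROH) inbreeding from SNP genotypes. This vignette is the package's account
of the underlying models, the parameters that matter, what the synthetic
data generator does and does not emulate, and the numerical decisions baked
into the implementation.

## The admixture model for breed composition

An animal's dosage genotype at SNP `k`, `g_k ∈ {0, 1, 2}`, counts copies of
allele A. Given reference allele-A frequencies `x_jk` for breeds
`j = 1..T`, the animal's genome is modeled as a mixture with weights
`w = (w_1..w_T)`, `w_j ≥ 0`, `Σ w_j = 1`. The mixture frequency at SNP `k`
is `f_k = Σ_j w_j x_jk`, and genotypes are assumed Hardy–Weinberg draws at
`f_k`, independent across SNPs:

```
Pr(g_k | f_k) = (1 - f_k)^2,  2 f_k (1 - f_k),  f_k^2    for g_k = 0, 1, 2
l(w) = Σ_k [ g_k ln f_k + (2 - g_k) ln(1 - f_k) ] + C,   C = Σ_k ln C(2, g_k)
```

`C` collects the binomial coefficients (`ln 2` per heterozygote) and does
not depend on `w`; the implementation carries it so that `l` equals the
direct sum of log genotype probabilities. Missing genotypes contribute
nothing. Two modeling caveats follow from the construction:

* Weights measure *identity-in-state*, not identity-by-descent. Because
  breeds share ancestry, a genuine purebred rarely scores exactly 1.0 for
  its own breed — small weights leak into related breeds. This motivates
  both the nullification filter and a purity cut-off below 1.
* Independence across SNPs ignores linkage disequilibrium; the likelihood
  is a composite likelihood, fine for point estimation but not for
  likelihood-ratio inference. The package never interprets `l` beyond
  ranking fits.

### Optimization

The simplex constraint is handled by a softmax reparameterization
`w_j = exp(θ_j) / Σ exp(θ_m)` optimized with BFGS (`stats::optim`) using
the analytic gradient; the softmax is smooth, keeps iterates strictly
inside the simplex, and lets a standard quasi-Newton method do the work.
Initialization is at uniform weights; on a non-converged fit up to 5
random restarts (`N(0, 1)` on the θ scale) are tried and the best
likelihood kept, with the convergence flag reported either way. The
softmax has one redundant direction (adding a constant to θ leaves `w`
unchanged); BFGS tolerates the flat direction, and estimates are reported
on the `w` scale where the redundancy vanishes.

After convergence the breed set is pruned: the smallest non-zero weight is
dropped and the remaining breeds refitted; the reduction is accepted while
the log-likelihood falls by less than `prune_tol` (default `1e-3`). The
threshold is deliberately small — it removes only breeds whose weight is
statistically indistinguishable from zero — and is exposed as
configuration because "does not significantly improve the fit" admits no
single canonical value.

Mixture frequencies are clamped to `[ε, 1 - ε]`, `ε = 1e-6` (configurable),
so monomorphic SNPs cannot produce infinite log terms.

### Classification parameters

| parameter | default | meaning |
|---|---|---|
| `nullify_threshold` | 0.01 | weights below 1% are zeroed, survivors rescaled to sum 1 |
| `cutoff` | 0.94 | purebred iff filtered focal-breed weight ≥ cutoff (inclusive) |
| `cross threshold` | 0.05 | two-breed typing: zero weights below 5%, require exactly the two parents to survive |

The nullification filter is why a `GBC = 1` rule and a `GBC ≥ 0.94` rule
can classify identically: an animal estimated at 0.995 reports exactly 1
after filtering. The change-point helper (`gbc_change_point`) locates the
departure from the purebred plateau on the sorted GBC curve by
single-breakpoint least squares — an exhaustive scan over all splits
minimizing within-segment squared error, which is deterministic and, for
one breakpoint, identical to binary segmentation. Whether the published
analyses operated on sorted values or an index scale is not stated
anywhere we could check; sorting first is the convention here, and the
returned value is the first value of the upper segment.

## The ROH scanner

Five criteria define a run: (1) length ≥ 1 Mb; (2) density ≥ 1 SNP/100 kb
and no inter-SNP gap > 1 Mb; (3) a 50-SNP window sliding one SNP at a
time; (4) ≤ 1 heterozygous and ≤ 2 missing calls per window; (5) ≥ 50
homozygous SNPs. The scanner computes, per SNP, the fraction of covering
windows that satisfy (4); SNPs with fraction ≥ `window_hit_fraction`
(default 0.05, the conventional PLINK window threshold, which the source
protocol leaves unstated) and a non-heterozygous call are run-eligible.
Maximal eligible stretches are split at gaps > 1 Mb and then filtered by
(1), (2) and (5).

Consequences of this construction worth knowing:

* A final segment can contain missing calls but never a heterozygous call:
  heterozygotes are individually ineligible, so they always break runs. No
  additional segment-level heterozygote cap is applied (none is defined in
  the five criteria; PLINK's equivalent cap is unlimited by default).
* The first and last ~2 SNPs of a true autozygous block typically score
  below the 0.05 window fraction (few of their covering windows lie fully
  inside the block), so detected boundaries sit a couple of SNP spacings
  inside the truth — about 100 kb at 50 kb spacing. Recovery tests budget
  for this.
* Chromosomes with fewer SNPs than the window are scanned as one truncated
  window and flagged; with ≥ 50 SNPs, every SNP is covered by at least one
  full window, so no special edge rule is needed beyond using the windows
  that exist.
* Segment length is `end - start + 1` bp, reported in Mb at 2 decimals
  (rounding convention ours; none is published).

The scan requires a map density comfortably above 1 SNP/100 kb: on a
~190 kb-spacing map the density criterion is unsatisfiable by
construction, which is why the pipeline's simulated ROH map uses ~51 kb
spacing (2,450 SNPs per 125 Mb chromosome, 44,100 genome-wide) while
GBC-oriented examples use the sparser 11,700-SNP scale.

## Inbreeding, length classes, and dating

`F_ROH = Σ L_ROH / L_genome`. The denominator defaults to the SNP-covered
autosome span, `Σ_chrom (last - first + 1)` (simulated maps carry their
true chromosome length instead), with an explicit override for users who
prefer an assembly length; published analyses rarely state their
denominator, so the package makes it inspectable (`genome_length()`).
Length classes are half-open `[1,5), [5,10), [10,20), [20,40), [40,∞)` Mb
— published tables that print both "≤5" and "1~5" for the first class are
ambiguous at exactly 5 Mb, and the half-open rule resolves the tie
deterministically upward. Per-class `F_ROH` uses the same denominator as
the overall coefficient, so class values sum exactly to the total.

Dating uses the exponential law for autozygous segment length: a segment
from an ancestor `g` generations back has mean length `100/(2g)` cM.
With the 1 cM ≡ 1 Mb shortcut adopted throughout (no recombination map
input), `g = 100 / (2 · mean Mb)`, reported exactly and rounded half away
from zero. The inversion is exact only for the *mean of segments of a
common age*; applying it to a length-class mean (segments of mixed ages,
truncated to the class window) is the conventional approximation and can
disagree with naive expectation by a generation — e.g. a 6.72 Mb class
mean gives 7.44 → 7.

## ROH islands

Per-SNP incidence counts animals with a segment covering the SNP.
The island threshold is the `1 - top_fraction` quantile (default top 1%)
of incidence percents, linear interpolation (R quantile type 7); SNPs *at
or above* the threshold qualify ("over the threshold" is read inclusively;
the alternative strict reading changes nothing except at exact ties).
Qualifying SNPs merge into islands when map-adjacent — one below-threshold
SNP splits, and no physical gap allowance is applied by default because
none is defined in the protocols this follows (`max_internal_gap_bp` is
the config hook). Annotation overlap normalizes BED (0-based half-open)
and GFF3 (1-based inclusive) to 1-based inclusive internally and requires
≥ 1 bp intersection.

## The synthetic-data generator

The generator produces every input with known ground truth. What it
emulates:

* **Correlated breed panels.** Hierarchical Balding–Nichols draws: per
  SNP an ancestral frequency `p ~ Uniform(0.05, 0.95)`, then down each
  branch `child ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`. Defaults
  `fst = c(0.18, 0.03–0.04)` give within-cluster frequency correlations
  near 0.95 and cross-cluster near 0.65 — the two-cluster
  indigenous/western structure. The base-frequency floor of 0.05 avoids
  monomorphic SNPs that would destabilize the likelihood's logs.
* **Genotypes.** Purebreds are `Binomial(2, x_k)` (HWE); crosses draw
  each allele's breed of origin Bernoulli at the design proportion (F1:
  one allele from each parent, origin exactly 0.5) and return realized
  origin fractions; autozygous genomes plant non-overlapping segments
  with `Exponential(mean_seg_len_mb)` lengths (1 cM ≡ 1 Mb) until planted
  coverage reaches `target_F`, copying both alleles from one sampled
  haplotype. A candidate segment is planted only if it moves coverage
  closer to the target, so realized coverage is unbiased to well within
  ±0.01; segments below 0.5 Mb are redrawn (invisible to any scanner at
  realistic densities). Missingness is uniform at random.
* **Scale.** The default genome is 18 autosomes × 125 Mb = 2,250 Mb; at
  a mean per-animal ROH total near 200 Mb this denominator yields
  `F_ROH ≈ 0.09`, the regime the defaults target. The autosomal length
  behind published coefficients is an inference, hence configurable.

What it does **not** emulate — and what passing tests therefore do not
show about real data: linkage disequilibrium outside planted segments
(background homozygosity is locus-independent), ascertainment bias of
commercial chips, genotyping error (only missingness), real recombination
maps (cM ≡ Mb), mutation inside autozygous segments, and family
structure. In particular, false-positive ROH from chance homozygosity are
*rarer* in these simulations than on a real chip with LD, so scanner
specificity on real data is not certified by these tests.

## Determinism and reproducibility

Every generator takes an explicit seed and runs it in a local RNG scope
(the caller's RNG stream is untouched); identical seeds reproduce outputs
bit-for-bit. The pipeline derives stage seeds by fixed offsets from one
master seed and writes a manifest with MD5 checksums of every output; a
rerun with the same configuration reproduces identical checksums.
Deterministic tie-breaks: change-point scan takes the first minimizing
split; hierarchical clustering inherits `hclust`'s label-order tie
handling; panel selection allocates SNPs by largest remainder and picks
the nearest SNP to each grid point in grid order.

## Problem sizes in the test-suite and acceptance script

Simulation checks run at sizes chosen to make the statistical assertions
sharp but the suite quick: GBC recovery at M = 5,000 over 20 seeds
(mean absolute F1/backcross error ≈ 0.03, asserted ≤ 0.05), scanner
recovery on 400 Mb genomes at 40–50 kb spacing (≥ 95% of planted bases,
observed ≈ 99.8%), `F_ROH` recovery at targets 0.05/0.10/0.20 (±0.02),
island recovery of a 3 Mb region shared by 40% of 30 animals (10/10
seeds), and grid-search verification of the optimizer for T ≤ 3 at 0.01
resolution. The whole suite runs in well under a minute on one core;
`scripts/acceptance.R` in a few seconds.

## Known limitations

* Reference frequencies are fixed inputs; there is no joint estimation of
  frequencies and ancestry (ADMIXTURE-style), no supervised update of the
  panel, and no handling of a breed absent from the reference set beyond
  the classification falling below the cut-off.
* The HWE QC test is the 1-df chi-square (chosen for determinism and
  speed); at very small counts an exact test would be preferable.
* No genotype imputation; QC plus simulated missingness stand in for it.
* VCF input is out of scope for this version; PLINK text/binary only.
* Composite-likelihood caveat above: no standard errors on GBC estimates.
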