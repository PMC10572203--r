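# gbcroh

Genomic breed composition and runs-of-homozygosity analysis for SNP
genotype data.

Livestock conservation programs face two recurring questions about a herd
genotyped on a SNP chip: *how pure is each animal with respect to a set of
reference breeds*, and *how inbred is it*. `gbcroh` answers both with a
single reproducible pipeline aimed at breed-conservation geneticists and
animal-breeding researchers:

* **Genomic breed composition (GBC).** Each animal's genome is modeled as
  a mixture of `T` reference breeds with known allele-A frequencies
  `x_jk`. With mixture frequency `f_k = Σ_j w_j x_jk` and Hardy–Weinberg
  genotype probabilities `Pr(g_k | f_k) = (1-f_k)², 2f_k(1-f_k), f_k²`,
  the admixture weights `w` (non-negative, `Σ w_j = 1`) maximize

  `l(w) = Σ_k [ g_k ln f_k + (2 - g_k) ln(1 - f_k) ] + C`

  via BFGS on a softmax reparameterization, followed by backward pruning
  of breeds that do not significantly improve the fit. A 1% nullification
  filter and a ≥ 0.94 cut-off classify purebreds; a 5% filter with
  two-breed rescaling types F1/F2/backcross animals; least-squares
  change-point analysis of the sorted GBC curve motivates the cut-off.
* **Runs of homozygosity (ROH).** A from-scratch sliding-window scanner
  (50-SNP windows, ≤ 1 heterozygote and ≤ 2 missing calls per window,
  ≥ 1 Mb, ≥ 50 homozygous SNPs, ≥ 1 SNP/100 kb, ≤ 1 Mb gaps) detects
  homozygous segments; summaries report five length classes
  ([1,5), [5,10), [10,20), [20,40), ≥ 40 Mb), the genomic inbreeding
  coefficient `F_ROH = Σ L_ROH / L_genome`, per-chromosome coverage, and
  segment age via the exponential segment-length law
  `g = 100 / (2 · mean length in cM)` with 1 cM ≡ 1 Mb.
* **ROH islands.** Per-SNP incidence across animals, a top-1% threshold,
  merging of adjacent above-threshold SNPs, and overlap of islands with
  user-supplied BED/GFF3 annotation.
* **Synthetic data with ground truth.** Hierarchical Balding–Nichols
  breed frequency panels, Hardy–Weinberg purebred and F1/F2/backcross
  genotypes with known breed origin, and genomes with planted autozygous
  segments (exponential lengths) — plus PLINK PED/MAP and BED/BIM/FAM
  input/output.

## Worked example

```r
library(gbcroh)

map   <- gen_marker_map(n_chrom = 4, snps_per_chrom = 2000,
                        chrom_length = 100e6, seed = 1)
freqs <- gen_breed_frequencies(map, tree = list(c("NX", "SZL"), c("DC", "LR")),
                               fst = c(0.18, 0.04), seed = 2)
round(breed_frequency_correlation(freqs), 2)
#>       NX  SZL   DC   LR
#> NX  1.00 0.94 0.64 0.64
#> SZL 0.94 1.00 0.64 0.64
#> DC  0.64 0.64 1.00 0.94
#> LR  0.64 0.64 0.94 1.00
```

Two tight breed clusters: frequencies correlate at 0.94 within a cluster
and 0.64 across — the indigenous-versus-western pattern the generator is
built to emulate.

```r
az  <- gen_autozygous_genomes(map, freqs["NX", ], n_animals = 5,
                              target_F = 0.10, mean_seg_len_mb = 8, seed = 3)
est <- estimate_gbc(az$gm$geno[1, ], freqs)
round(nullify_rescale(est$weights, 0.01), 3)
#>  NX SZL  DC  LR
#>   1   0   0   0
classify_purebred(nullify_rescale(est$weights, 0.01), "NX", cutoff = 0.94)
#> [1] "purebred"
```

The first animal, simulated from the NX frequency row, is estimated at
100% NX after the 1% filter and classified purebred at the 0.94 cut-off.

```r
segs <- detect_roh(az$gm)
head(segs[, c("animal", "chromosome", "start", "end", "n_snps", "length_mb")], 3)
#>    animal chromosome    start      end n_snps length_mb
#> 1 animal1          1 51325000 64275000    260     12.95
#> 2 animal1          2 16825000 20225000     69      3.40
#> 3 animal1          2 77425000 83725000    127      6.30
f_roh(segs[segs$animal == "animal1", ], genome_length(map))
#> [1] 0.1155
summarize_roh(segs, n_animals = 5)$table
#>      class  N  N_pct mean_length_mb total_length_pct
#> 1   1-5 Mb  6  26.09           3.10             8.49
#> 2  5-10 Mb  9  39.13           7.42            30.48
#> 3 10-20 Mb  6  26.09          13.87            37.99
#> 4 20-40 Mb  2   8.70          25.23            23.04
#> 5   >40 Mb  0   0.00           0.00             0.00
#> 6      All 23 100.00           9.52           100.00
generations_from_length(3.2)
#>    exact generations
#> 1 15.625          16
```

The scanner recovers the planted segments; animal 1's `F_ROH` of 0.1155
sits near the planted target of 0.10 (detected runs extend slightly into
chance homozygosity at segment edges). The class table gives counts,
count shares, mean lengths and length shares per class; a 3.2 Mb mean
segment length dates the corresponding autozygosity to a common ancestor
roughly 16 generations back.

The full pipeline (simulate → QC → GBC → classify → ROH → statistics →
islands → structure) runs from one configuration:

```r
run_pipeline(pipeline_config(seed = 7), "run1")
```

writing tab-separated stage outputs plus a `manifest.json` with checksums;
a rerun with the same configuration reproduces identical checksums. A thin
command-line wrapper lives at `inst/cli/gbcroh.R`
(`Rscript gbcroh.R all --config cfg.yaml --out rundir`).

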