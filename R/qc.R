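#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit test of the genotype counts
#' (n_AA, n_Aa, n_aa) against Hardy-Weinberg proportions at the observed
#' allele frequency. Monomorphic SNPs fit HWE perfectly (p = 1).
#'
#' @param n2,n1,n0 counts of dosage-2, dosage-1 and dosage-0 genotypes.
#' @return data.frame with `chisq` and `p` per SNP (vectorized).
#' @examples
#' hwe_chisq(50, 0, 50) # all homozygotes: chisq = 100
#' @export
hwe_chisq <- function(n2, n1, n0) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e2 <- n * p^2
  e1 <- n * 2 * p * (1 - p)
  e0 <- n * (1 - p)^2
  chisq <- ifelse(p == 0 | p == 1, 0,
                  (n2 - e2)^2 / e2 + (n1 - e1)^2 / e1 + (n0 - e0)^2 / e0)
  data.frame(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Quality-control filtering of a genotype matrix
#'
#' Applies, in order: (1) animal call-rate filter, (2) SNP call-rate filter,
#' (3) SNP Hardy-Weinberg filter (chi-square p below `hwe_alpha`). No
#' minor-allele-frequency pruning is performed: MAF pruning removes the
#' near-monomorphic SNPs that runs of homozygosity are made of and biases
#' ROH detection downward.
#'
#' @param gm a [genotype_matrix].
#' @param snp_call_rate minimum SNP call rate (default 0.95).
#' @param ind_call_rate minimum animal call rate (default 0.90).
#' @param hwe_alpha HWE p-value threshold (default 1e-6).
#' @return list with `gm` (filtered [genotype_matrix]) and `report` (a
#'   `qc_report`: thresholds, per-rule removal counts, removed ids).
#' @export
qc_filter <- function(gm, snp_call_rate = 0.95, ind_call_rate = 0.90,
                      hwe_alpha = 1e-6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (snp_call_rate <= 0 || snp_call_rate > 1 || ind_call_rate <= 0 || ind_call_rate > 1)
    stop("call-rate thresholds must lie in (0, 1]")
  g <- gm$geno
  n_anim0 <- nrow(g); n_snp0 <- ncol(g)

  ind_cr <- rowMeans(!is.na(g))
  drop_animal <- ind_cr < ind_call_rate
  g <- g[!drop_animal, , drop = FALSE]

  snp_cr <- colMeans(!is.na(g))
  drop_cr <- snp_cr < snp_call_rate

  n2 <- colSums(g == 2, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n0 <- colSums(g == 0, na.rm = TRUE)
  hw <- hwe_chisq(n2, n1, n0)
  drop_hwe <- !drop_cr & !is.na(hw$p) & hw$p < hwe_alpha

  keep_snp <- !(drop_cr | drop_hwe)
  if (!any(keep_snp) || nrow(g) == 0)
    stop("QC removed every SNP or every animal; nothing left to analyse")

  map <- gm$map[keep_snp, , drop = FALSE]
  attr(map, "chrom_length") <- attr(gm$map, "chrom_length")
  class(map) <- c("marker_map", "data.frame")
  out <- genotype_matrix(g[, keep_snp, drop = FALSE], map,
                         gm$ids[!drop_animal])
  report <- structure(list(
    thresholds = c(snp_call_rate = snp_call_rate, ind_call_rate = ind_call_rate,
                   hwe_alpha = hwe_alpha),
    n_animals_in = n_anim0, n_snps_in = n_snp0,
    animals_removed_call_rate = sum(drop_animal),
    snps_removed_call_rate = sum(drop_cr),
    snps_removed_hwe = sum(drop_hwe),
    removed_animals = gm$ids[drop_animal],
    removed_snps = gm$map$snp_id[!keep_snp]
  ), class = "qc_report")
  list(gm = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_animals_in, "animals,", x$n_snps_in, "SNPs in\n")
  cat("  animals removed (call rate <", x$thresholds["ind_call_rate"], "):",
      x$animals_removed_call_rate, "\n")
  cat("  SNPs removed (call rate <", x$thresholds["snp_call_rate"], "):",
      x$snps_removed_call_rate, "\n")
  cat("  SNPs removed (HWE p <", x$thresholds["hwe_alpha"], "):",
      x$snps_removed_hwe, "\n")
  invisible(x)
}

#' Select a uniformly spaced SNP panel
#'
#' Greedy down-sampling of a marker map to `K` SNPs spread as evenly as
#' possible in physical distance. SNPs are allocated to chromosomes
#' proportionally to chromosome span (largest-remainder rounding, at least
#' one per chromosome), then each chromosome's allocation picks, for every
#' point of an ideal even grid, the nearest not-yet-chosen SNP.
#'
#' @param map a `marker_map`.
#' @param K target panel size; must satisfy `n_chrom <= K <= nrow(map)`.
#' @return the subset `marker_map` (row order preserved).
#' @export
uniform_panel_select <- function(map, K) {
  check_marker_map(map)
  chroms <- unique(map$chromosome)
  M <- nrow(map)
  if (K > M) stop("K (", K, ") exceeds map size (", M, ")")
  if (K < length(chroms))
    stop("K (", K, ") is below the chromosome count (", length(chroms),
         "); cannot keep at least one SNP per chromosome")
  spans <- vapply(chroms, function(ch) {
    p <- map$position[map$chromosome == ch]
    as.numeric(max(p) - min(p) + 1)
  }, numeric(1))
  # largest-remainder allocation, floor of 1 per chromosome
  quota <- K * spans / sum(spans)
  alloc <- pmax(1L, floor(quota))
  while (sum(alloc) > K) {  # floor-of-1 may overshoot on tiny K
    i <- which.max(alloc - quota)
    alloc[i] <- alloc[i] - 1L
  }
  rem <- quota - alloc
  while (sum(alloc) < K) {
    i <- which.max(rem)
    alloc[i] <- alloc[i] + 1L
    rem[i] <- -Inf
  }
  keep <- logical(M)
  for (ci in seq_along(chroms)) {
    idx <- which(map$chromosome == chroms[ci])
    pos <- map$position[idx]
    k <- alloc[ci]
    n_avail <- length(idx)
    if (k >= n_avail) { keep[idx] <- TRUE; next }
    grid <- seq(min(pos), max(pos), length.out = k)
    chosen <- integer(0)
    for (gpt in grid) {
      ord <- order(abs(pos - gpt))
      pick <- ord[!(ord %in% chosen)][1]
      chosen <- c(chosen, pick)
    }
    keep[idx[chosen]] <- TRUE
  }
  out <- map[keep, , drop = FALSE]
  attr(out, "chrom_length") <- attr(map, "chrom_length")
  class(out) <- c("marker_map", "data.frame")
  out
}

#' Restrict a genotype matrix to a SNP subset
#'
#' @param gm a [genotype_matrix].
#' @param panel a `marker_map` whose `snp_id`s are a subset of `gm`'s.
#' @return a [genotype_matrix] on the panel's SNPs.
#' @export
subset_panel <- function(gm, panel) {
  idx <- match(panel$snp_id, gm$map$snp_id)
  if (anyNA(idx)) stop("panel contains SNPs absent from the genotype matrix")
  map <- gm$map[idx, , drop = FALSE]
  attr(map, "chrom_length") <- attr(gm$map, "chrom_length")
  class(map) <- c("marker_map", "data.frame")
  genotype_matrix(gm$geno[, idx, drop = FALSE], map, gm$ids)
}
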