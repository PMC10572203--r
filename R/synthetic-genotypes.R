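#' Cross design descriptor
#'
#' Describes a two-breed cross and its expected breed-origin proportions:
#' F1 and F2 expect (0.5, 0.5), a backcross to breed A (`BC_A`) expects
#' (0.75, 0.25) and to breed B (`BC_B`) (0.25, 0.75).
#'
#' @param breedA,breedB parental breed labels.
#' @param type one of `"F1"`, `"F2"`, `"BC_A"`, `"BC_B"`.
#' @return A `cross_design` list with `breedA`, `breedB`, `type`,
#'   `expected` (named pair summing to 1).
#' @export
cross_design <- function(breedA, breedB, type = c("F1", "F2", "BC_A", "BC_B")) {
  type <- match.arg(type)
  expected <- switch(type,
    F1 = c(0.5, 0.5), F2 = c(0.5, 0.5),
    BC_A = c(0.75, 0.25), BC_B = c(0.25, 0.75))
  names(expected) <- c(breedA, breedB)
  structure(list(breedA = breedA, breedB = breedB, type = type,
                 expected = expected), class = "cross_design")
}

#' Simulate purebred genotypes under Hardy-Weinberg equilibrium
#'
#' Each animal's dosage at SNP k is drawn `Binomial(2, x_k)` where `x_k` is
#' the breed's allele-A frequency; calls are then masked missing uniformly
#' at random at `missing_rate`.
#'
#' @param freqs_row numeric vector of allele-A frequencies, one per SNP of
#'   `map`.
#' @param map a `marker_map`.
#' @param n_animals number of animals.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param seed integer seed.
#' @param ids optional animal ids.
#' @return a [genotype_matrix].
#' @export
gen_purebred_genotypes <- function(freqs_row, map, n_animals, missing_rate = 0,
                                   seed = NULL, ids = NULL) {
  check_marker_map(map)
  if (length(freqs_row) != nrow(map))
    stop("frequency row length (", length(freqs_row), ") does not match map (", nrow(map), ")")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  M <- nrow(map)
  with_seed(seed, {
    g <- matrix(rbinom(n_animals * M, 2L, rep(freqs_row, each = n_animals)),
                nrow = n_animals, ncol = M)
    if (missing_rate > 0)
      g[runif(length(g)) < missing_rate] <- NA_integer_
    genotype_matrix(g, map, ids)
  })
}

#' Simulate two-breed crossbred genotypes with known breed origin
#'
#' F1 animals receive one allele drawn from each parental breed's frequency
#' at every SNP, so the true origin proportion is exactly (0.5, 0.5). For
#' F2 and backcross animals each of the 2M alleles first draws its breed of
#' origin `Bernoulli(p_A)` with `p_A` the design's expected breed-A
#' proportion, then the allele from that breed's frequency; the realized
#' per-animal breed-A fraction is returned alongside the genotypes.
#'
#' @param freqsA,freqsB parental allele-A frequency rows aligned to `map`.
#' @param map a `marker_map`.
#' @param design a [cross_design].
#' @param n_animals number of animals.
#' @param seed integer seed.
#' @param ids optional animal ids.
#' @return list with `gm` (a [genotype_matrix]) and `origin` (data.frame:
#'   `animal`, `fracA` = realized breed-A allele fraction).
#' @export
gen_cross_genotypes <- function(freqsA, freqsB, map, design, n_animals,
                                seed = NULL, ids = NULL) {
  check_marker_map(map)
  stopifnot(inherits(design, "cross_design"))
  M <- nrow(map)
  if (length(freqsA) != M || length(freqsB) != M)
    stop("parental frequency rows must match the map")
  with_seed(seed, {
    pA <- unname(design$expected[1])
    g <- matrix(0L, n_animals, M)
    fracA <- numeric(n_animals)
    for (i in seq_len(n_animals)) {
      if (design$type == "F1") {
        a1 <- rbinom(M, 1L, freqsA)
        a2 <- rbinom(M, 1L, freqsB)
        fracA[i] <- 0.5
      } else {
        o1 <- rbinom(M, 1L, pA)   # 1 = breed A origin
        o2 <- rbinom(M, 1L, pA)
        a1 <- rbinom(M, 1L, ifelse(o1 == 1L, freqsA, freqsB))
        a2 <- rbinom(M, 1L, ifelse(o2 == 1L, freqsA, freqsB))
        fracA[i] <- (sum(o1) + sum(o2)) / (2 * M)
      }
      g[i, ] <- a1 + a2
    }
    gm <- genotype_matrix(g, map, ids)
    list(gm = gm,
         origin = data.frame(animal = gm$ids, fracA = fracA))
  })
}

#' Simulate genomes with planted autozygous segments
#'
#' Background genotypes are Hardy-Weinberg draws from `base_freqs` (as in
#' [gen_purebred_genotypes]). Autozygous segments are then planted per
#' animal: segment lengths are drawn `Exponential(mean = mean_seg_len_mb)`
#' (1 cM is equated to 1 Mb throughout, so a mean of `100/(2g)` Mb
#' corresponds to a common ancestor `g` generations back), placed uniformly
#' on chromosomes without overlap until the planted fraction of the genome
#' reaches `target_F`. Within a planted segment both alleles are copied
#' from a single sampled haplotype, forcing homozygosity at every covered
#' SNP; the covered SNP's dosage is `2 * Bernoulli(x_k)`.
#'
#' @param map a `marker_map` (its [chrom_lengths] define the genome length).
#' @param base_freqs allele-A frequency row aligned to `map`.
#' @param n_animals number of animals.
#' @param target_F desired autozygous genome fraction in `[0, 1)`.
#' @param mean_seg_len_mb mean planted segment length, Mb.
#' @param min_seg_len_mb segments shorter than this are redrawn (default 0.5
#'   Mb; sub-SNP-scale segments are invisible to any scanner).
#' @param missing_rate per-call missing probability applied after planting.
#' @param seed integer seed.
#' @param max_tries placement attempts per animal before giving up with a
#'   coverage-shortfall warning.
#' @return list with `gm` (a [genotype_matrix]) and `truth` (data.frame:
#'   `animal`, `chromosome`, `start`, `end`, `length_bp` of every planted
#'   segment).
#' @export
gen_autozygous_genomes <- function(map, base_freqs, n_animals, target_F,
                                   mean_seg_len_mb = 10, min_seg_len_mb = 0.5,
                                   missing_rate = 0, seed = NULL,
                                   max_tries = 2000L) {
  check_marker_map(map)
  if (target_F < 0 || target_F >= 1) stop("target_F must be in [0, 1)")
  if (mean_seg_len_mb <= 0) stop("mean_seg_len_mb must be positive")
  cl <- chrom_lengths(map)
  chroms <- as.numeric(names(cl))
  L_genome <- sum(cl)
  M <- nrow(map)
  with_seed(seed, {
    g <- matrix(rbinom(n_animals * M, 2L, rep(base_freqs, each = n_animals)),
                nrow = n_animals, ncol = M)
    truth <- vector("list", n_animals)
    for (i in seq_len(n_animals)) {
      if (target_F == 0) { truth[[i]] <- NULL; next }
      placed <- lapply(chroms, function(...) NULL)
      names(placed) <- names(cl)
      covered <- 0
      tries <- 0L
      segs <- list()
      while (covered / L_genome < target_F && tries < max_tries) {
        tries <- tries + 1L
        len <- rexp(1, rate = 1 / (mean_seg_len_mb * 1e6))
        if (len < min_seg_len_mb * 1e6) next
        chr_i <- sample.int(length(chroms), 1L, prob = cl)
        chr <- chroms[chr_i]
        if (len >= cl[chr_i]) next
        start <- floor(runif(1, 1, cl[chr_i] - len))
        end <- floor(start + len)
        prev <- placed[[chr_i]]
        if (!is.null(prev) && any(start <= prev[, 2] & end >= prev[, 1])) next
        # avoid overshoot: only plant segments that bring the realized
        # coverage closer to the target (over-long draws are redrawn)
        new_cov <- covered + (end - start + 1)
        if (abs(new_cov / L_genome - target_F) > abs(covered / L_genome - target_F))
          next
        placed[[chr_i]] <- rbind(prev, c(start, end))
        idx <- which(map$chromosome == chr & map$position >= start & map$position <= end)
        if (length(idx)) g[i, idx] <- 2L * rbinom(length(idx), 1L, base_freqs[idx])
        covered <- covered + (end - start + 1)
        segs[[length(segs) + 1L]] <- data.frame(
          animal = i, chromosome = chr, start = start, end = end,
          length_bp = end - start + 1)
      }
      shortfall <- target_F - covered / L_genome
      if (shortfall > max(0.005, mean_seg_len_mb * 1e6 / L_genome))
        warning(sprintf("animal %d: reached autozygous coverage %.4f < target %.4f",
                        i, covered / L_genome, target_F))
      truth[[i]] <- if (length(segs)) do.call(rbind, segs) else NULL
    }
    if (missing_rate > 0)
      g[runif(length(g)) < missing_rate] <- NA_integer_
    gm <- genotype_matrix(g, map)
    tr <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    if (is.null(tr))
      tr <- data.frame(animal = integer(), chromosome = numeric(),
                       start = numeric(), end = numeric(), length_bp = numeric())
    tr$animal <- gm$ids[tr$animal]
    rownames(tr) <- NULL
    list(gm = gm, truth = tr)
  })
}
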