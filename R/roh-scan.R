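#' ROH scan parameters
#'
#' Bundles the five run-of-homozygosity criteria used by the scanner:
#' (1) minimum run length (default 1 Mb); (2) minimum SNP density of one
#' SNP per 100 kb and maximum gap between consecutive SNPs of 1 Mb;
#' (3) a 50-SNP sliding window moving one SNP at a time; (4) at most one
#' heterozygous and two missing calls per window; (5) at least 50
#' homozygous SNPs per run.
#'
#' @param min_length_bp minimum run length (bp).
#' @param min_snps minimum number of homozygous SNPs in a run.
#' @param window_snps sliding-window size in SNPs.
#' @param max_het_per_window heterozygous calls tolerated per window.
#' @param max_missing_per_window missing calls tolerated per window.
#' @param max_gap_bp maximum gap between consecutive SNPs in a run (bp).
#' @param density_bp_per_snp maximum average bp per SNP in a run (100 kb =
#'   at least one SNP per 100 kb).
#' @param window_hit_fraction minimum fraction of homozygous-eligible
#'   windows covering a SNP for it to enter a run (default 0.05).
#' @return a `roh_params` list.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 50L, window_snps = 50L,
                       max_het_per_window = 1L, max_missing_per_window = 2L,
                       max_gap_bp = 1e6, density_bp_per_snp = 1e5,
                       window_hit_fraction = 0.05) {
  p <- list(min_length_bp = min_length_bp, min_snps = min_snps,
            window_snps = window_snps, max_het_per_window = max_het_per_window,
            max_missing_per_window = max_missing_per_window,
            max_gap_bp = max_gap_bp, density_bp_per_snp = density_bp_per_snp,
            window_hit_fraction = window_hit_fraction)
  if (any(vapply(p[c(1:3, 6:7)], function(v) v <= 0, logical(1))))
    stop("lengths, counts and density bounds must be positive")
  structure(p, class = "roh_params")
}

#' Sliding-window homozygosity scores for one chromosome of one animal
#'
#' Slides a `window_snps`-wide window one SNP at a time; a window is a
#' "hit" when it contains at most `max_het_per_window` heterozygous and
#' `max_missing_per_window` missing calls. Each SNP's score is the fraction
#' of hit windows among the windows that cover it; SNPs near chromosome
#' ends are scored over the windows that exist. A chromosome with fewer
#' SNPs than the window size is scanned as a single truncated window and
#' flagged via the `"truncated"` attribute.
#'
#' @param g dosage vector of one animal on one chromosome, position order.
#' @param params a [roh_params].
#' @return numeric vector of per-SNP hit fractions (attribute `truncated`).
#' @export
window_scan <- function(g, params = roh_params()) {
  n <- length(g)
  w <- min(params$window_snps, n)
  truncated <- n < params$window_snps
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  nw <- n - w + 1L
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  hts <- ch[(w + 1):(n + 1)] - ch[1:nw]
  mss <- cm[(w + 1):(n + 1)] - cm[1:nw]
  hit <- as.integer(hts <= params$max_het_per_window &
                    mss <= params$max_missing_per_window)
  # SNP i is covered by windows starting in [i-w+1, i] (clipped to [1, nw])
  chit <- c(0L, cumsum(hit))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  frac <- (chit[hi + 1L] - chit[lo]) / (hi - lo + 1L)
  attr(frac, "truncated") <- truncated
  frac
}

#' Assemble ROH segments on one chromosome of one animal
#'
#' SNPs are run-eligible when their window hit fraction reaches
#' `window_hit_fraction` and their own call is not heterozygous (missing
#' calls may sit inside a run). Maximal stretches of eligible SNPs are
#' split wherever the gap between consecutive SNPs exceeds `max_gap_bp`,
#' and surviving stretches are kept only if they meet the minimum length,
#' minimum homozygous-SNP count and minimum density criteria.
#'
#' @param frac per-SNP hit fractions from [window_scan].
#' @param g dosage vector (same order).
#' @param pos physical positions (bp, strictly increasing).
#' @param params a [roh_params].
#' @return data.frame of segments: `start`, `end`, `n_snps`,
#'   `n_homozygous`, `length_bp` (possibly zero rows).
#' @export
call_segments <- function(frac, g, pos, params = roh_params()) {
  n <- length(g)
  stopifnot(length(frac) == n, length(pos) == n)
  eligible <- frac >= params$window_hit_fraction & (is.na(g) | g != 1L)
  out <- list()
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    idx <- i0:i1
    gaps <- diff(pos[idx])
    cut_after <- which(gaps > params$max_gap_bp)
    piece_start <- c(i0, idx[cut_after + 1L])
    piece_end <- c(idx[cut_after], i1)
    for (p_i in seq_along(piece_start)) {
      a <- piece_start[p_i]; b <- piece_end[p_i]
      len <- pos[b] - pos[a] + 1
      n_snps <- b - a + 1L
      n_hom <- sum(g[a:b] %in% c(0L, 2L))
      if (len >= params$min_length_bp &&
          n_hom >= params$min_snps &&
          len / n_snps <= params$density_bp_per_snp)
        out[[length(out) + 1L]] <- data.frame(
          start = pos[a], end = pos[b], n_snps = n_snps,
          n_homozygous = n_hom, length_bp = len)
    }
  }
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(), n_snps = integer(),
                      n_homozygous = integer(), length_bp = numeric()))
  do.call(rbind, out)
}

#' Detect runs of homozygosity in a genotype matrix
#'
#' Runs [window_scan] and [call_segments] over every animal and chromosome
#' and concatenates the results in deterministic (animal, chromosome,
#' start) order.
#'
#' @param gm a (QC'd) [genotype_matrix].
#' @param params a [roh_params].
#' @return data.frame of segments: `animal`, `chromosome`, `start`, `end`,
#'   `n_snps`, `n_homozygous`, `length_bp`, `length_mb` (2 decimals).
#' @export
detect_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  map <- gm$map
  chroms <- unique(map$chromosome)
  chrom_idx <- lapply(chroms, function(ch) which(map$chromosome == ch))
  out <- list()
  for (i in seq_len(nrow(gm$geno))) {
    for (ci in seq_along(chroms)) {
      idx <- chrom_idx[[ci]]
      g <- gm$geno[i, idx]
      pos <- map$position[idx]
      frac <- window_scan(g, params)
      segs <- call_segments(frac, g, pos, params)
      if (nrow(segs))
        out[[length(out) + 1L]] <- cbind(
          data.frame(animal = gm$ids[i], chromosome = chroms[ci]), segs)
    }
  }
  if (!length(out))
    return(data.frame(animal = character(), chromosome = numeric(),
                      start = numeric(), end = numeric(), n_snps = integer(),
                      n_homozygous = integer(), length_bp = numeric(),
                      length_mb = numeric()))
  segs <- do.call(rbind, out)
  segs <- segs[order(match(segs$animal, gm$ids), segs$chromosome, segs$start), ]
  rownames(segs) <- NULL
  segs$length_mb <- round(segs$length_bp / 1e6, 2)
  segs
}

#' Write an ROH segment table
#'
#' Tab-separated, column-compatible with the essentials of a PLINK `.hom`
#' file (`animal`, `chromosome`, `start`, `end`, `n_snps`, `length_mb`).
#'
#' @param segments output of [detect_roh].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_roh <- function(segments, path) {
  data.table::fwrite(segments, path, sep = "\t")
  invisible(path)
}

#' @rdname write_roh
#' @export
read_roh <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
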