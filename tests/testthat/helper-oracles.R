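# Independent oracles used across the suite. These re-derive expectations
# by brute force / enumeration and never share code with the implementation.

# Naive window enumeration: per-SNP fraction of hit windows, double loop.
oracle_window_scan <- function(g, window = 50L, max_het = 1L, max_miss = 2L) {
  n <- length(g)
  w <- min(window, n)
  nw <- n - w + 1L
  hit <- logical(nw)
  for (s in seq_len(nw)) {
    win <- g[s:(s + w - 1L)]
    hit[s] <- sum(win == 1L, na.rm = TRUE) <= max_het && sum(is.na(win)) <= max_miss
  }
  vapply(seq_len(n), function(i) {
    ss <- intersect(seq_len(nw), (i - w + 1L):i)
    mean(hit[ss])
  }, numeric(1))
}

# Exhaustive simplex grid search of the admixture log-likelihood (T <= 3).
oracle_grid_argmax <- function(g_vec, freqs, step = 0.01) {
  keep <- !is.na(g_vec)
  g <- g_vec[keep]
  X <- t(freqs[, keep, drop = FALSE])
  T_br <- nrow(freqs)
  ll <- function(w) {
    f <- pmin(pmax(as.vector(X %*% w), 1e-6), 1 - 1e-6)
    sum(g * log(f) + (2 - g) * log(1 - f))
  }
  grid1 <- seq(0, 1, by = step)
  best <- -Inf; best_w <- NULL
  if (T_br == 2) {
    for (a in grid1) {
      v <- ll(c(a, 1 - a))
      if (v > best) { best <- v; best_w <- c(a, 1 - a) }
    }
  } else if (T_br == 3) {
    for (a in grid1) for (b in seq(0, 1 - a, by = step)) {
      v <- ll(c(a, b, 1 - a - b))
      if (v > best) { best <- v; best_w <- c(a, b, 1 - a - b) }
    }
  } else stop("oracle supports T <= 3")
  list(w = setNames(best_w, rownames(freqs)), loglik = best)
}

# Brute force over all single breakpoints of a sorted sequence, least squares.
oracle_single_breakpoint <- function(x) {
  n <- length(x)
  sse <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  best <- Inf; best_k <- NA
  for (k in 1:(n - 1)) {
    s <- sse(x[1:k]) + sse(x[(k + 1):n])
    if (s < best) { best <- s; best_k <- k }
  }
  best_k + 1L  # first index of the upper segment
}

# Re-validate every emitted ROH segment against the five criteria directly
# from the raw genotypes. Returns TRUE when all segments pass.
oracle_validate_segments <- function(segs, gm, params = roh_params()) {
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    idx <- which(gm$map$chromosome == s$chromosome &
                 gm$map$position >= s$start & gm$map$position <= s$end)
    g <- gm$geno[s$animal, idx]
    pos <- gm$map$position[idx]
    if (s$length_bp != s$end - s$start + 1) return(FALSE)
    if (s$length_bp < params$min_length_bp) return(FALSE)              # (1)
    if (s$length_bp / length(idx) > params$density_bp_per_snp) return(FALSE) # (2) density
    if (length(idx) > 1 && any(diff(pos) > params$max_gap_bp)) return(FALSE) # (2) gap
    if (any(g == 1L, na.rm = TRUE)) return(FALSE)  # run of homozygous calls
    if (sum(g %in% c(0L, 2L)) < params$min_snps) return(FALSE)         # (5)
    if (sum(g %in% c(0L, 2L)) != s$n_homozygous) return(FALSE)
  }
  TRUE
}

# Shared small fixture: two correlated breed clusters on a dense map.
make_two_cluster_panel <- function(seed, n_chrom = 2L, snps_per_chrom = 1000L,
                                   chrom_length = 50e6,
                                   fst = c(0.2, 0.03)) {
  map <- gen_marker_map(n_chrom, snps_per_chrom, chrom_length, seed = seed)
  freqs <- gen_breed_frequencies(
    map, list(c("NX", "SZL"), c("DC", "LR")), fst = fst, seed = seed + 1L)
  list(map = map, freqs = freqs)
}
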