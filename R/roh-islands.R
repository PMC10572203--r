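#' Per-SNP ROH incidence across animals
#'
#' Counts, for every SNP of the map, the number of animals having at least
#' one ROH segment whose `[start, end]` span covers the SNP's position, and
#' expresses it as a percentage of `n_animals`.
#'
#' @param segments segment table from [detect_roh].
#' @param map the `marker_map` the segments were called on.
#' @param n_animals number of animals scanned.
#' @return data.frame: `snp_id`, `chromosome`, `position`, `count`,
#'   `incidence_pct`.
#' @export
snp_incidence <- function(segments, map, n_animals) {
  check_marker_map(map)
  counts <- integer(nrow(map))
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    pos <- map$position[idx]
    s <- segments[segments$chromosome == ch, , drop = FALSE]
    if (!nrow(s)) next
    # an animal may carry several disjoint segments; they cannot double-count
    # a SNP because segments of one animal on one chromosome never overlap
    delta <- integer(length(idx) + 1L)
    lo <- findInterval(s$start - 0.5, pos) + 1L   # first SNP >= start
    hi <- findInterval(s$end, pos)                # last SNP <= end
    ok <- lo <= hi
    for (k in which(ok)) {
      delta[lo[k]] <- delta[lo[k]] + 1L
      delta[hi[k] + 1L] <- delta[hi[k] + 1L] - 1L
    }
    counts[idx] <- cumsum(delta[seq_along(idx)])
  }
  data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
             position = map$position, count = counts,
             incidence_pct = 100 * counts / n_animals)
}

#' ROH-island incidence threshold
#'
#' The `(1 - top_fraction)` empirical quantile (linear interpolation) of
#' the per-SNP incidence percentages; SNPs at or above the threshold
#' qualify for island membership. When every incidence is equal the
#' threshold degenerates to that common value and all SNPs qualify (a
#' warning is raised).
#'
#' @param incidence output of [snp_incidence] (or a numeric vector of
#'   incidence percentages).
#' @param top_fraction fraction of SNPs targeted (default 0.01 = top 1%).
#' @return scalar threshold on the percentage scale.
#' @export
island_threshold <- function(incidence, top_fraction = 0.01) {
  pct <- if (is.data.frame(incidence)) incidence$incidence_pct else incidence
  if (!length(pct)) stop("empty incidence set")
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0, 1]")
  if (diff(range(pct)) == 0) {
    warning("all SNP incidences are equal; every SNP qualifies")
    return(pct[1])
  }
  unname(quantile(pct, probs = 1 - top_fraction, type = 7))
}

#' Merge qualifying SNPs into ROH islands
#'
#' Maximal runs of map-adjacent qualifying SNPs (no intervening
#' below-threshold SNP on the map) are merged into islands; a single
#' below-threshold SNP breaks a run. An optional physical-gap cap splits
#' runs whose consecutive qualifying SNPs are further apart than
#' `max_internal_gap_bp`.
#'
#' @param incidence output of [snp_incidence].
#' @param threshold incidence threshold (percent); SNPs with
#'   `incidence_pct >= threshold` qualify.
#' @param max_internal_gap_bp optional bp cap between consecutive island
#'   SNPs (default `Inf`: map adjacency only).
#' @return data.frame: `chromosome`, `start`, `end`, `n_snps`,
#'   `length_mb`, `mean_incidence_pct`.
#' @export
merge_islands <- function(incidence, threshold, max_internal_gap_bp = Inf) {
  out <- list()
  for (ch in unique(incidence$chromosome)) {
    d <- incidence[incidence$chromosome == ch, , drop = FALSE]
    qual <- d$incidence_pct >= threshold
    if (!any(qual)) next
    r <- rle(qual)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      gaps <- diff(d$position[idx])
      cut_after <- which(gaps > max_internal_gap_bp)
      p_start <- c(idx[1], idx[cut_after + 1L])
      p_end <- c(idx[cut_after], idx[length(idx)])
      for (k in seq_along(p_start)) {
        ii <- p_start[k]:p_end[k]
        out[[length(out) + 1L]] <- data.frame(
          chromosome = ch,
          start = d$position[ii[1]],
          end = d$position[ii[length(ii)]],
          n_snps = length(ii),
          length_mb = round((d$position[ii[length(ii)]] - d$position[ii[1]] + 1) / 1e6, 2),
          mean_incidence_pct = round(mean(d$incidence_pct[ii]), 2))
      }
    }
  }
  if (!length(out))
    return(data.frame(chromosome = numeric(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      length_mb = numeric(), mean_incidence_pct = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$start), , drop = FALSE]
}

#' Detect ROH islands
#'
#' Convenience wrapper: incidence, top-fraction threshold, merge.
#'
#' @inheritParams snp_incidence
#' @inheritParams island_threshold
#' @inheritParams merge_islands
#' @return list: `incidence`, `threshold`, `islands`.
#' @export
detect_islands <- function(segments, map, n_animals, top_fraction = 0.01,
                           max_internal_gap_bp = Inf) {
  inc <- snp_incidence(segments, map, n_animals)
  thr <- island_threshold(inc, top_fraction)
  list(incidence = inc, threshold = thr,
       islands = merge_islands(inc, thr, max_internal_gap_bp))
}

#' Overlap ROH islands with annotation intervals
#'
#' Reads a BED or GFF3 file of features (genes, QTL, ...) and reports, for
#' every island, the features intersecting it by at least one base pair.
#' BED's 0-based half-open and GFF3's 1-based inclusive coordinates are
#' both normalized to 1-based inclusive internally, so equivalent records
#' in either format give identical overlap verdicts. Features on
#' chromosomes absent from the island table are skipped (their count is
#' reported).
#'
#' @param islands island table from [merge_islands] / [detect_islands].
#' @param annotation path to a `.bed`, `.gff`/`.gff3`/`.gtf` file, or a
#'   data.frame with columns `chromosome`, `start`, `end`, `name`
#'   (1-based inclusive).
#' @return data.frame: one row per (island, overlapping feature) pair with
#'   island coordinates, `feature`, `feature_start`, `feature_end`;
#'   attribute `n_skipped_chromosomes` counts skipped features.
#' @export
annotate_islands <- function(islands, annotation) {
  feats <- if (is.data.frame(annotation)) annotation else read_annotation(annotation)
  island_chr <- as.character(islands$chromosome)
  known <- as.character(feats$chromosome) %in% unique(island_chr)
  n_skip <- sum(!known)
  if (n_skip) warning(n_skip, " features on chromosomes without islands were skipped")
  feats <- feats[known, , drop = FALSE]
  gr_isl <- GenomicRanges::GRanges(island_chr,
                                   IRanges::IRanges(islands$start, islands$end))
  gr_ft <- GenomicRanges::GRanges(as.character(feats$chromosome),
                                  IRanges::IRanges(feats$start, feats$end))
  ov <- GenomicRanges::findOverlaps(gr_isl, gr_ft)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    chromosome = islands$chromosome[qi],
    island_start = islands$start[qi],
    island_end = islands$end[qi],
    feature = feats$name[si],
    feature_start = feats$start[si],
    feature_end = feats$end[si])
  attr(out, "n_skipped_chromosomes") <- n_skip
  out
}

# Read BED / GFF3 features into a 1-based inclusive data.frame.
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gr <- if (ext == "bed") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF")
  nm <- if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$name)) as.character(gr$name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else as.character(seq_along(gr))
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = nm)
}
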