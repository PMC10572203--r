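#' Default ROH length-class scheme
#'
#' Five half-open bins over segment length in Mb: [1,5), [5,10), [10,20),
#' [20,40), [40, Inf). A segment of exactly 5 Mb falls in the 5-10 class.
#'
#' @param breaks_mb ascending class boundaries in Mb (first = scheme floor).
#' @return a `length_class_scheme`: list with `breaks_mb` and `labels`.
#' @export
length_class_scheme <- function(breaks_mb = c(1, 5, 10, 20, 40)) {
  stopifnot(all(diff(breaks_mb) > 0))
  n <- length(breaks_mb)
  labels <- c(sprintf("%g-%g Mb", breaks_mb[-n], breaks_mb[-1]),
              sprintf(">%g Mb", breaks_mb[n]))
  structure(list(breaks_mb = breaks_mb, labels = labels),
            class = "length_class_scheme")
}

#' Assign ROH segments to length classes
#'
#' Half-open `[low, high)` assignment on length in Mb.
#'
#' @param segments segment data.frame with `length_bp` (or `length_mb`).
#' @param scheme a [length_class_scheme].
#' @return factor of class labels, one per segment.
#' @export
bin_segments <- function(segments, scheme = length_class_scheme()) {
  len_mb <- if (!is.null(segments$length_bp)) segments$length_bp / 1e6
            else segments$length_mb
  if (any(len_mb < scheme$breaks_mb[1]))
    stop("segment shorter than the scheme floor (", scheme$breaks_mb[1], " Mb)")
  idx <- findInterval(len_mb, scheme$breaks_mb)   # [low, high)
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' ROH-based genomic inbreeding coefficient
#'
#' `F_ROH = sum(L_ROH) / L_genome`: the fraction of the autosomal genome
#' covered by an animal's runs of homozygosity.
#'
#' @param segments segments of one animal (data.frame with `length_bp`).
#' @param L_genome autosomal genome length in bp.
#' @return scalar in `[0, 1]`.
#' @export
f_roh <- function(segments, L_genome) {
  if (L_genome <= 0) stop("L_genome must be positive")
  sum(segments$length_bp) / L_genome
}

#' Genome length implied by a marker map
#'
#' Default `L_genome` denominator: the sum over chromosomes of the
#' SNP-covered span (or the simulated chromosome length when the map
#' carries one). Override with an explicit value when the true assembly
#' length is known.
#'
#' @param map a `marker_map`.
#' @return total autosomal length in bp.
#' @export
genome_length <- function(map) sum(chrom_lengths(map))

#' Per-animal inbreeding table
#'
#' For each animal: overall F_ROH, F_ROH restricted to each length class
#' (same denominator, so class values sum to the overall value), and
#' F_ROH per chromosome (per-chromosome denominator).
#'
#' @param segments segment table from [detect_roh].
#' @param animals animal ids to report (animals without segments get 0).
#' @param map the `marker_map` the segments were called on.
#' @param L_genome genome length override in bp (default [genome_length]).
#' @param scheme a [length_class_scheme].
#' @return list: `overall` (data.frame `animal`, `f_roh`, one column per
#'   class), `by_chromosome` (animals x chromosomes matrix).
#' @export
inbreeding_table <- function(segments, animals, map,
                             L_genome = genome_length(map),
                             scheme = length_class_scheme()) {
  cl <- chrom_lengths(map)
  cls <- if (nrow(segments)) bin_segments(segments, scheme) else factor(character(), levels = scheme$labels)
  per_class <- sapply(scheme$labels, function(lb) {
    s <- segments[cls == lb, , drop = FALSE]
    v <- tapply(s$length_bp, factor(s$animal, levels = animals), sum)
    ifelse(is.na(v), 0, v) / L_genome
  })
  per_class <- matrix(per_class, nrow = length(animals),
                      dimnames = list(animals, scheme$labels))
  tot <- tapply(segments$length_bp, factor(segments$animal, levels = animals), sum)
  tot <- ifelse(is.na(tot), 0, tot) / L_genome
  by_chr <- sapply(names(cl), function(ch) {
    s <- segments[segments$chromosome == as.numeric(ch), , drop = FALSE]
    v <- tapply(s$length_bp, factor(s$animal, levels = animals), sum)
    ifelse(is.na(v), 0, v) / cl[[ch]]
  })
  by_chr <- matrix(by_chr, nrow = length(animals),
                   dimnames = list(animals, names(cl)))
  overall <- data.frame(animal = animals, f_roh = as.numeric(tot),
                        check.names = FALSE)
  overall <- cbind(overall, as.data.frame(per_class, check.names = FALSE))
  rownames(overall) <- NULL
  list(overall = overall, by_chromosome = by_chr)
}

#' Summarize ROH length classes from class counts and mean lengths
#'
#' Aggregation identities used by the class summary: overall mean length
#' `sum(N * Mean_L) / sum(N)`, class count share `N%`, class share of the
#' summed length `TL%`, mean ROH count per animal `sum(N) / n_animals` and
#' mean total ROH length per animal `sum(N * Mean_L) / n_animals`. Feeding
#' a published class table (counts + class mean lengths) through this
#' reproduces its overall row and per-animal averages.
#'
#' @param class_n segment count per class.
#' @param class_mean_mb mean segment length per class (Mb).
#' @param n_animals number of animals summarized.
#' @param labels class labels.
#' @return list: `table` (per-class and `All` rows of `N`, `N_pct`,
#'   `mean_length_mb`, `total_length_pct`), `per_animal` (`mean_n_roh`,
#'   `mean_total_length_mb`).
#' @export
roh_class_summary <- function(class_n, class_mean_mb, n_animals,
                              labels = length_class_scheme()$labels) {
  stopifnot(length(class_n) == length(class_mean_mb))
  tl <- class_n * class_mean_mb
  tab <- data.frame(
    class = c(labels, "All"),
    N = c(class_n, sum(class_n)),
    N_pct = round(100 * c(class_n, sum(class_n)) / sum(class_n), 2),
    mean_length_mb = round(c(class_mean_mb, sum(tl) / sum(class_n)), 2),
    total_length_pct = round(100 * c(tl, sum(tl)) / sum(tl), 2))
  list(table = tab,
       per_animal = c(mean_n_roh = round(sum(class_n) / n_animals, 2),
                      mean_total_length_mb = round(sum(tl) / n_animals, 1)))
}

#' Summarize detected ROH segments by length class
#'
#' Bins segments with [bin_segments] and reports, per class and overall:
#' count, count share, mean length and share of total ROH length, plus
#' per-animal averages (mean ROH count and mean total length).
#'
#' @param segments segment table from [detect_roh].
#' @param n_animals number of animals scanned (animals with zero segments
#'   still count in the per-animal averages).
#' @param scheme a [length_class_scheme].
#' @return as [roh_class_summary].
#' @export
summarize_roh <- function(segments, n_animals, scheme = length_class_scheme()) {
  if (!nrow(segments)) stop("no segments to summarize")
  cls <- bin_segments(segments, scheme)
  n <- as.numeric(table(cls))
  mean_mb <- tapply(segments$length_bp / 1e6, cls, mean)
  mean_mb <- ifelse(is.na(mean_mb), 0, mean_mb)
  keep <- n > 0
  roh_class_summary(n, as.numeric(mean_mb), n_animals, labels = scheme$labels)
}

#' Per-chromosome ROH coverage
#'
#' For each chromosome: number of segments, share of the total ROH length,
#' and the fraction of the chromosome covered by the union of segments
#' across all animals (overlaps between animals merged, so the value is
#' the covered proportion of the chromosome, not a per-animal average).
#'
#' @param segments segment table.
#' @param map the `marker_map` (chromosome extents via [chrom_lengths]).
#' @return data.frame: `chromosome`, `n_segments`, `share_of_total_pct`,
#'   `union_coverage_pct`.
#' @export
chromosome_coverage <- function(segments, map) {
  cl <- chrom_lengths(map)
  tot <- sum(segments$length_bp)
  out <- lapply(names(cl), function(ch) {
    s <- segments[segments$chromosome == as.numeric(ch), , drop = FALSE]
    if (nrow(s) && any(s$end > cl[[ch]]))
      stop("segment beyond chromosome ", ch, " extent")
    cov <- if (nrow(s)) sum(interval_union_length(s$start, s$end)) else 0
    data.frame(chromosome = as.numeric(ch), n_segments = nrow(s),
               share_of_total_pct = if (tot > 0) round(100 * sum(s$length_bp) / tot, 2) else 0,
               union_coverage_pct = round(100 * cov / cl[[ch]], 2))
  })
  do.call(rbind, out)
}

# total length of the union of 1-based inclusive intervals
interval_union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1) cur_e <- max(cur_e, end[i])
    else { tot <- tot + (cur_e - cur_s + 1); cur_s <- start[i]; cur_e <- end[i] }
  }
  tot + (cur_e - cur_s + 1)
}

#' Generations to the common ancestor from mean segment length
#'
#' The length of an autozygous segment inherited from an ancestor `g`
#' generations back is exponentially distributed with mean `100/(2g)` cM;
#' equating 1 cM with 1 Mb gives `g = 100 / (2 * mean length in Mb)`.
#' The integer report rounds half away from zero.
#'
#' @param mean_len_mb mean segment length in Mb (vectorized).
#' @return data.frame with `exact` and `generations` (integer).
#' @examples
#' generations_from_length(3.09) # about 16 generations
#' @export
generations_from_length <- function(mean_len_mb) {
  if (any(mean_len_mb <= 0)) stop("mean length must be positive")
  exact <- 100 / (2 * mean_len_mb)
  data.frame(exact = exact,
             generations = as.integer(sign(exact) * floor(abs(exact) + 0.5)))
}
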