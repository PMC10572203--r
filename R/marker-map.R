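#' Build a synthetic autosomal marker map
#'
#' Generates a SNP map over `n_chrom` autosomes of equal physical length,
#' either exactly evenly spaced or with random jitter around the even grid.
#' Positions are strictly increasing within each chromosome and confined to
#' `[1, chrom_length]`. Sex chromosomes are never generated: all downstream
#' analyses (ROH, F_ROH) are defined on autosomes only.
#'
#' @param n_chrom number of autosomes (default 18, a pig-like karyotype).
#' @param snps_per_chrom markers per chromosome.
#' @param chrom_length chromosome length in base pairs (default 125 Mb).
#' @param spacing `"uniform"` for an exact even grid, `"jittered"` to
#'   perturb each interior position uniformly within half the grid step.
#' @param seed integer seed; identical seeds give byte-identical maps.
#' @return A `marker_map` data.frame with columns `snp_id`, `chromosome`,
#'   `position`, carrying the per-chromosome length as attribute
#'   `chrom_length`.
#' @examples
#' map <- gen_marker_map(2, 100, 10e6, seed = 1)
#' head(map)
#' @export
gen_marker_map <- function(n_chrom = 18L, snps_per_chrom = 650L,
                           chrom_length = 125e6, spacing = c("uniform", "jittered"),
                           seed = NULL) {
  spacing <- match.arg(spacing)
  if (n_chrom < 1L || snps_per_chrom < 2L || chrom_length <= snps_per_chrom)
    stop("need n_chrom >= 1, snps_per_chrom >= 2 and a chromosome longer than its SNP count")
  with_seed(seed, {
    step <- chrom_length / snps_per_chrom
    per_chrom <- lapply(seq_len(n_chrom), function(chr) {
      pos <- round(step / 2 + step * (seq_len(snps_per_chrom) - 1L))
      if (spacing == "jittered") {
        jit <- runif(snps_per_chrom, -step / 2 + 1, step / 2 - 1)
        pos <- round(pos + jit)
      }
      pos <- pmin(pmax(pos, 1), chrom_length)
      pos <- sort(unique(pos))
      # jitter collisions are re-spread deterministically
      while (length(pos) < snps_per_chrom) {
        extra <- setdiff(round(seq(1, chrom_length, length.out = snps_per_chrom * 2)), pos)
        pos <- sort(c(pos, extra[seq_len(snps_per_chrom - length(pos))]))
      }
      data.frame(
        snp_id = sprintf("snp%d_%d", chr, seq_len(snps_per_chrom)),
        chromosome = chr,
        position = pos
      )
    })
    map <- do.call(rbind, per_chrom)
    rownames(map) <- NULL
    attr(map, "chrom_length") <- chrom_length
    class(map) <- c("marker_map", "data.frame")
    map
  })
}

# Validate the marker-map contract used throughout the package.
check_marker_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("snp_id", "chromosome", "position") %in% names(map)))
  ok <- tapply(map$position, map$chromosome, function(p) all(diff(p) > 0))
  if (!all(unlist(ok)))
    stop("marker map positions must be strictly increasing within chromosomes")
  invisible(map)
}

#' Per-chromosome physical lengths of a map
#'
#' Returns, for every chromosome in the map, the length used as that
#' chromosome's extent: the `chrom_length` attribute when the map was
#' simulated, otherwise the SNP-covered span (last minus first position + 1).
#'
#' @param map a `marker_map`.
#' @return named numeric vector of lengths in bp, one per chromosome.
#' @export
chrom_lengths <- function(map) {
  check_marker_map(map)
  cl <- attr(map, "chrom_length")
  chroms <- sort(unique(map$chromosome))
  if (!is.null(cl))
    return(setNames(rep(as.numeric(cl), length(chroms)), chroms))
  out <- vapply(chroms, function(ch) {
    p <- map$position[map$chromosome == ch]
    max(p) - min(p) + 1
  }, numeric(1))
  setNames(out, chroms)
}

#' Genotype matrix container
#'
#' Couples an animals-by-SNPs matrix of allele-A dosages (0, 1, 2, or `NA`
#' for missing) with its [marker map][gen_marker_map].
#'
#' @param geno integer matrix, animals in rows, SNPs in columns; values in
#'   \{0, 1, 2, NA\}.
#' @param map `marker_map` whose rows match the columns of `geno`.
#' @param ids animal identifiers (default `animal1..N`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `map`, `ids`.
#' @export
genotype_matrix <- function(geno, map, ids = NULL) {
  check_marker_map(map)
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map))
    stop("genotype columns (", ncol(geno), ") do not match map length (", nrow(map), ")")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("dosage codes must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  if (is.null(ids)) ids <- sprintf("animal%d", seq_len(nrow(geno)))
  rownames(geno) <- ids
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map, ids = ids), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "animals x", ncol(x$geno), "SNPs on",
      length(unique(x$map$chromosome)), "chromosomes;",
      sprintf("%.2f%%", 100 * mean(is.na(x$geno))), "missing\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)
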