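#' Breed allele-frequency correlation matrix
#'
#' Pairwise Pearson correlations between breeds' allele-A frequency
#' vectors. Breeds that diverged recently (low drift between them) show
#' high correlation; breeds across a deep split are nearly uncorrelated.
#'
#' @param freqs breeds-by-SNPs allele-A frequency matrix (>= 2 SNPs).
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   rows give `NA` entries with a warning.
#' @export
breed_frequency_correlation <- function(freqs) {
  check_freq_table(freqs)
  if (ncol(freqs) < 2) stop("need at least 2 SNPs")
  sds <- apply(freqs, 1, stats::sd)
  if (any(sds == 0))
    warning("zero-variance frequency vector(s): ",
            paste(rownames(freqs)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  suppressWarnings(cor(t(freqs)))
}

#' Hierarchical clustering of breeds
#'
#' Agglomerative clustering of breeds on the distance `1 - r` (r = Pearson
#' correlation of allele-A frequencies) with average linkage. Ties are
#' broken deterministically by breed label order (the input order of the
#' correlation matrix).
#'
#' @param corr a breed correlation matrix.
#' @return an `hclust` object.
#' @export
cluster_breeds <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  d <- as.dist(1 - corr)
  hclust(d, method = "average")
}

#' Write a breed dendrogram in Newick format
#'
#' @param hc `hclust` from [cluster_breeds].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}

#' Principal component analysis of genotypes
#'
#' Mean-centers each SNP's dosages (missing calls replaced by the SNP
#' mean, i.e. they contribute nothing after centering) and computes scores
#' on the first `k` components by singular value decomposition. Dosages
#' are not variance-standardized by default; set `scale. = TRUE` for
#' unit-variance scaling.
#'
#' @param gm a [genotype_matrix].
#' @param k number of components (`<= min(N, M)`; silently truncated to
#'   the matrix rank with a warning).
#' @param scale. standardize SNPs to unit variance (default `FALSE`).
#' @return list: `scores` (N x k, animal rownames), `explained` (variance
#'   fractions, non-increasing), `sdev`.
#' @export
pca_genotypes <- function(gm, k = 2L, scale. = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  if (k > min(dim(g))) stop("k exceeds min(animals, SNPs)")
  cm <- colMeans(g, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- cm[j]
  storage.mode(g) <- "double"
  if (scale.) {
    sds <- apply(g, 2, stats::sd)
    keep <- sds > 0
    g <- g[, keep, drop = FALSE]
    cm <- cm[keep]
  }
  pc <- prcomp(g, center = TRUE, scale. = scale.)
  rank <- sum(pc$sdev > 1e-12)
  if (k > max(rank, 1L)) {
    warning("k = ", k, " exceeds the matrix rank (", rank, "); truncated")
    k <- max(rank, 1L)
  }
  tot <- sum(pc$sdev^2)
  explained <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = explained,
       sdev = pc$sdev[seq_len(k)])
}
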