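#' Simulate correlated breed allele frequencies (hierarchical Balding-Nichols)
#'
#' Draws an allele-A frequency table for a set of breeds related by a nested
#' grouping. Ancestral frequencies are drawn per SNP from
#' `Uniform(base[1], base[2])`; descending each branch of the grouping, the
#' child frequency is drawn from the Balding-Nichols Beta distribution
#' around the parent frequency `p` with drift parameter `F`:
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. Breeds under a low-drift common node end
#' up with strongly correlated frequency vectors (e.g. an indigenous cluster),
#' while breeds separated by a high-drift split are nearly uncorrelated —
#' the structure seen between Chinese indigenous and Western pig breeds.
#'
#' @param map a `marker_map`; one frequency per breed per SNP.
#' @param tree nested breed grouping: a (possibly nested) list whose leaves
#'   are breed names, e.g. `list(list("NX","SZL","BM"), list("DC","LR","YK"))`.
#'   A plain character vector is treated as a flat grouping.
#' @param fst drift per tree depth: `fst[d]` applies to every branch from
#'   depth `d-1` to depth `d` (root = depth 0). Recycled if shorter than the
#'   tree depth. All values in `[0, 1)`; `F = 0` is the no-drift limit
#'   (child equals parent).
#' @param base range of the ancestral frequency distribution; the default
#'   `c(0.05, 0.95)` avoids monomorphic SNPs whose log-likelihood
#'   contributions are degenerate.
#' @param seed integer seed.
#' @return A breeds-by-SNPs numeric matrix in `[0,1]` with breed rownames
#'   and SNP-id colnames (a breed frequency table).
#' @examples
#' map <- gen_marker_map(1, 50, 5e6, seed = 1)
#' fr <- gen_breed_frequencies(map, list(c("A", "B"), "C"), fst = c(0.2, 0.02), seed = 1)
#' cor(fr["A", ], fr["B", ]) # high: siblings under a low-drift node
#' @export
gen_breed_frequencies <- function(map, tree, fst = c(0.15, 0.03),
                                  base = c(0.05, 0.95), seed = NULL) {
  check_marker_map(map)
  if (is.character(tree)) tree <- as.list(tree)
  if (any(fst < 0 | fst >= 1)) stop("drift parameters must lie in [0, 1)")
  M <- nrow(map)
  with_seed(seed, {
    p0 <- runif(M, base[1], base[2])
    rows <- recurse_bn(tree, p0, fst, depth = 1L)
    freqs <- do.call(rbind, rows)
    colnames(freqs) <- map$snp_id
    freqs
  })
}

# Balding-Nichols draw of a child frequency vector around parent p.
bn_draw <- function(p, f) {
  if (f == 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  rbeta(length(p), a, b)
}

recurse_bn <- function(node, p_parent, fst, depth) {
  f <- fst[min(depth, length(fst))]
  if (is.character(node)) {        # leaf (possibly several sibling leaves)
    out <- lapply(node, function(nm) bn_draw(p_parent, f))
    names(out) <- node
    return(out)
  }
  out <- list()
  for (child in node) {
    if (is.character(child) && length(child) == 1L) {
      out[[child]] <- bn_draw(p_parent, f)
    } else {
      p_node <- bn_draw(p_parent, f)
      if (is.character(child)) {
        kids <- recurse_bn(as.list(child), p_node, fst, depth + 1L)
      } else {
        kids <- recurse_bn(child, p_node, fst, depth + 1L)
      }
      out <- c(out, kids)
    }
  }
  out
}

# Validate a breed frequency table against a map.
check_freq_table <- function(freqs, map = NULL) {
  stopifnot(is.matrix(freqs), !is.null(rownames(freqs)))
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  if (!is.null(map) && ncol(freqs) != nrow(map))
    stop("frequency table has ", ncol(freqs), " SNPs but map has ", nrow(map))
  invisible(freqs)
}

#' Write / read a breed frequency table
#'
#' Tab-separated text: one row per breed, header row of SNP ids, first
#' column `breed`.
#'
#' @param freqs breeds-by-SNPs matrix.
#' @param path file path.
#' @return `read_freq_table` returns the matrix; `write_freq_table` its path,
#'   invisibly.
#' @export
write_freq_table <- function(freqs, path) {
  check_freq_table(freqs)
  df <- data.frame(breed = rownames(freqs), freqs, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  check_freq_table(m)
  m
}
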