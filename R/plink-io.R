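#' Read PLINK genotypes as allele-A dosages
#'
#' Supports the text (PED/MAP) and binary (BED/BIM/FAM, SNP-major) layouts.
#' Dosage is the count of the A1 allele: for the binary dialect A1 is taken
#' from the BIM file; for the text dialect A1 is the `allele_a` argument
#' (the literal allele letter to count, default `"A"`). `0` alleles are the
#' missing code. No strand flipping is attempted: allele A/B labels are one
#' strand designation, and the caller's frequency table must use the same.
#'
#' @param prefix path prefix: `<prefix>.ped/.map` or `<prefix>.bed/.bim/.fam`.
#' @param dialect `"text"` or `"binary"`.
#' @param allele_a allele counted as dosage in the text dialect.
#' @return a [genotype_matrix].
#' @export
read_plink <- function(prefix, dialect = c("text", "binary"), allele_a = "A") {
  dialect <- match.arg(dialect)
  if (dialect == "text") read_plink_text(prefix, allele_a) else read_plink_bed(prefix)
}

read_plink_map <- function(path) {
  mp <- data.table::fread(path, header = FALSE, data.table = FALSE)
  map <- data.frame(snp_id = as.character(mp[[2]]),
                    chromosome = as.numeric(mp[[1]]),
                    position = as.numeric(mp[[4]]))
  class(map) <- c("marker_map", "data.frame")
  check_marker_map(map)
  map
}

read_plink_text <- function(prefix, allele_a = "A") {
  map <- read_plink_map(paste0(prefix, ".map"))
  ped <- data.table::fread(paste0(prefix, ".ped"), header = FALSE,
                           colClasses = "character", data.table = FALSE)
  M <- nrow(map)
  if (ncol(ped) != 6 + 2 * M)
    stop("PED has ", ncol(ped) - 6, " allele columns for ", M, " mapped SNPs")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, 2 * M, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * M, by = 2), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  g <- (a1 == allele_a) + (a2 == allele_a)
  g[miss] <- NA_integer_
  genotype_matrix(g, map, ids)
}

read_plink_bed <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE, data.table = FALSE)
  map <- data.frame(snp_id = as.character(bim[[2]]),
                    chromosome = as.numeric(bim[[1]]),
                    position = as.numeric(bim[[4]]))
  class(map) <- c("marker_map", "data.frame")
  check_marker_map(map)
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character", data.table = FALSE)
  N <- nrow(fam); M <- nrow(map)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bps <- ceiling(N / 4)                       # bytes per SNP
  body <- raw[-(1:3)]
  if (length(body) != bps * M)
    stop(".bed payload is ", length(body), " bytes; expected ", bps * M)
  # 2-bit codes, little-endian within each byte:
  # 00 -> A1/A1 (dosage 2), 10 -> het (1), 11 -> A2/A2 (0), 01 -> missing
  lut <- c(2L, NA_integer_, 1L, 0L)           # index by code + 1
  ints <- as.integer(body)
  codes <- matrix(NA_integer_, nrow = 4 * bps, ncol = M)
  m <- matrix(ints, nrow = bps, ncol = M)
  for (k in 0:3)
    codes[seq(k + 1, 4 * bps, by = 4), ] <- bitwAnd(m %/% (4L^k), 3L)
  g <- matrix(lut[codes[seq_len(N), , drop = FALSE] + 1L], nrow = N, ncol = M)
  genotype_matrix(g, map, fam[[2]])
}

#' Write a genotype matrix in PLINK format
#'
#' The text dialect writes alleles as `A`/`B` with `0 0` for missing calls;
#' the binary dialect writes a SNP-major `.bed` with `A1 = A`, `A2 = B`, so
#' a round trip through either dialect preserves dosages exactly.
#'
#' @param gm a [genotype_matrix].
#' @param prefix output path prefix.
#' @param dialect `"text"` or `"binary"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix, dialect = c("text", "binary")) {
  dialect <- match.arg(dialect)
  map <- gm$map
  map_df <- data.frame(map$chromosome, map$snp_id, 0, map$position)
  if (dialect == "text") {
    data.table::fwrite(map_df, paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
    g <- gm$geno
    N <- nrow(g); M <- ncol(g)
    a1 <- matrix("B", N, M); a2 <- matrix("B", N, M)
    a1[g >= 1] <- "A"
    a2[g == 2] <- "A"
    a1[is.na(g)] <- "0"; a2[is.na(g)] <- "0"
    inter <- matrix("", N, 2 * M)
    inter[, seq(1, 2 * M, 2)] <- a1
    inter[, seq(2, 2 * M, 2)] <- a2
    ped <- cbind(gm$ids, gm$ids, "0", "0", "0", "-9", inter)
    data.table::fwrite(as.data.frame(ped), paste0(prefix, ".ped"),
                       sep = " ", col.names = FALSE)
  } else {
    data.table::fwrite(cbind(map_df[, 1:4], "A", "B"), paste0(prefix, ".bim"),
                       sep = "\t", col.names = FALSE)
    fam <- data.frame(gm$ids, gm$ids, 0, 0, 0, -9)
    data.table::fwrite(fam, paste0(prefix, ".fam"), sep = " ", col.names = FALSE)
    g <- gm$geno
    N <- nrow(g); M <- ncol(g)
    code <- matrix(3L, N, M)                   # A2/A2
    code[g == 1] <- 2L
    code[g == 2] <- 0L
    code[is.na(g)] <- 1L
    bps <- ceiling(N / 4)
    padded <- matrix(0L, 4 * bps, M)
    padded[seq_len(N), ] <- code
    bytes <- matrix(0L, bps, M)
    for (k in 0:3)
      bytes <- bytes + padded[seq(k + 1, 4 * bps, by = 4), , drop = FALSE] * 4L^k
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
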