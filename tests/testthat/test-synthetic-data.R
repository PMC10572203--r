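test_that("marker maps are sorted, bounded, evenly spaced and deterministic", {
  map <- gen_marker_map(1, 100, 10e6, spacing = "uniform", seed = 1)
  expect_equal(nrow(map), 100)
  expect_true(all(map$position >= 1 & map$position <= 10e6))
  sp <- diff(map$position)
  expect_true(all(abs(sp - 1e5) < 2))  # ~100 kb between consecutive SNPs

  big <- gen_marker_map(18, 650, 125e6, seed = 2)
  expect_equal(nrow(big), 18 * 650)   # 11,700 SNPs, mid-density panel scale
  expect_equal(length(unique(big$chromosome)), 18)

  expect_identical(gen_marker_map(3, 50, 5e6, spacing = "jittered", seed = 9),
                   gen_marker_map(3, 50, 5e6, spacing = "jittered", seed = 9))
  for (ch in 1:3) {
    p <- gen_marker_map(3, 50, 5e6, spacing = "jittered", seed = 9)
    expect_true(all(diff(p$position[p$chromosome == ch]) > 0))
  }
  expect_error(gen_marker_map(0, 10, 1e6), "n_chrom")
  expect_error(gen_marker_map(1, 1, 1e6), "n_chrom")
})

test_that("Balding-Nichols frequencies respect limits, bounds and the cluster structure", {
  map <- gen_marker_map(1, 400, 40e6, seed = 3)
  # no-drift limit: every breed equals the ancestral draw
  fr0 <- gen_breed_frequencies(map, list(c("A", "B"), c("C", "D")),
                               fst = c(0, 0), seed = 4)
  expect_equal(fr0["A", ], fr0["C", ], ignore_attr = TRUE)
  expect_equal(fr0["B", ], fr0["D", ], ignore_attr = TRUE)
  # support
  fr <- gen_breed_frequencies(map, list(c("A", "B"), c("C", "D")),
                              fst = c(0.25, 0.03), seed = 5)
  expect_true(all(fr >= 0 & fr <= 1))
  # within-cluster correlation beats cross-cluster correlation, 10 seeds
  within <- cross <- numeric(10)
  for (s in 1:10) {
    f <- gen_breed_frequencies(map, list(c("A", "B"), c("C", "D")),
                               fst = c(0.25, 0.03), seed = 100 + s)
    within[s] <- cor(f["A", ], f["B", ])
    cross[s] <- cor(f["A", ], f["C", ])
  }
  expect_true(all(within > cross))
  expect_error(gen_breed_frequencies(map, list("A"), fst = 1), "drift")
})

test_that("purebred genotypes are HWE binomial draws with controlled missingness", {
  map <- gen_marker_map(1, 300, 30e6, seed = 6)
  x <- rep(1, 300)
  gm1 <- gen_purebred_genotypes(x, map, 10, seed = 7)
  expect_true(all(gm1$geno == 2L))  # degenerate frequency
  x <- gen_breed_frequencies(map, list("A"), fst = 0.1, seed = 8)["A", ]
  gm <- gen_purebred_genotypes(x, map, 500, seed = 9)
  expect_false(anyNA(gm$geno))      # missing_rate = 0
  # realized allele-A frequency within 3 binomial SEs per SNP
  xhat <- colMeans(gm$geno) / 2
  se <- sqrt(x * (1 - x) / (2 * 500))
  expect_true(all(abs(xhat - x) <= 3 * se + 1e-12))
  gm_miss <- gen_purebred_genotypes(x, map, 200, missing_rate = 0.1, seed = 10)
  expect_gt(mean(is.na(gm_miss$geno)), 0.08)
  expect_lt(mean(is.na(gm_miss$geno)), 0.12)
  expect_error(gen_purebred_genotypes(x[-1], map, 5), "match the map|does not match")
})

test_that("HWE chi-square rejection rate on purebred output is near nominal", {
  map <- gen_marker_map(1, 1000, 100e6, seed = 11)
  x <- runif(1000, 0.2, 0.8)
  gm <- gen_purebred_genotypes(x, map, 500, seed = 12)
  n2 <- colSums(gm$geno == 2); n1 <- colSums(gm$geno == 1); n0 <- colSums(gm$geno == 0)
  rej <- mean(hwe_chisq(n2, n1, n0)$p < 0.05)
  expect_gt(rej, 0.02)  # 5% +- Monte-Carlo/asymptotic slack over 1,000 SNPs
  expect_lt(rej, 0.08)
})

test_that("cross genotypes carry the designed breed-origin proportions", {
  map <- gen_marker_map(2, 2500, 125e6, seed = 13)  # M = 5000
  fr <- gen_breed_frequencies(map, list("A", "B"), fst = 0.3, seed = 14)
  f1 <- gen_cross_genotypes(fr["A", ], fr["B", ], map,
                            cross_design("A", "B", "F1"), 5, seed = 15)
  expect_true(all(f1$origin$fracA == 0.5))  # exact by construction
  bc <- gen_cross_genotypes(fr["A", ], fr["B", ], map,
                            cross_design("A", "B", "BC_A"), 10, seed = 16)
  se <- sqrt(0.75 * 0.25 / (2 * 5000))
  expect_true(all(abs(bc$origin$fracA - 0.75) <= 3 * se))
  # F2 mean heterozygosity sits between the parents' HWE values
  f2 <- gen_cross_genotypes(fr["A", ], fr["B", ], map,
                            cross_design("A", "B", "F2"), 30, seed = 17)
  hetA <- mean(2 * fr["A", ] * (1 - fr["A", ]))
  hetB <- mean(2 * fr["B", ] * (1 - fr["B", ]))
  het_f2 <- mean(f2$gm$geno == 1)
  # brute-force expectation from the frequencies: each allele is an
  # independent 50/50 breed mixture draw
  pmix_het <- mean({
    pa <- fr["A", ]; pb <- fr["B", ]
    p1 <- 0.5 * pa + 0.5 * pb
    2 * p1 * (1 - p1)
  })
  expect_gt(het_f2, min(hetA, hetB))
  expect_equal(het_f2, pmix_het, tolerance = 0.02)
  expect_error(cross_design("A", "B", "F3"), "arg")
})

test_that("planted autozygous segments hit the target coverage and length law", {
  map <- gen_marker_map(3, 1500, 125e6, seed = 18)  # 375 Mb genome
  x <- gen_breed_frequencies(map, list("A"), fst = 0.1, seed = 19)["A", ]
  expect_equal(nrow(gen_autozygous_genomes(map, x, 2, 0, seed = 20)$truth), 0)
  az <- gen_autozygous_genomes(map, x, 60, target_F = 0.10,
                               mean_seg_len_mb = 8, seed = 21)
  cov <- tapply(az$truth$length_bp, az$truth$animal, sum) / (3 * 125e6)
  expect_lt(abs(mean(cov) - 0.10), 0.01)
  # per animal, segments never overlap
  by_ac <- split(az$truth, paste(az$truth$animal, az$truth$chromosome))
  for (d in by_ac) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
  # planted-truth conservation: every planted interval fully homozygous
  for (i in sample(nrow(az$truth), 50)) {
    s <- az$truth[i, ]
    idx <- which(map$chromosome == s$chromosome &
                 map$position >= s$start & map$position <= s$end)
    expect_true(all(az$gm$geno[s$animal, idx] %in% c(0L, 2L)))
  }
  # exponential mean: planted lengths (untruncated part) near the target mean
  lens <- az$truth$length_bp / 1e6
  expect_gt(length(lens), 200)
  # lengths below 0.5 Mb are redrawn, so compare to the truncated-exp mean
  mu <- 8; trunc_mean <- mu + 0.5   # E[L | L > 0.5] for Exp(mean 8)
  expect_equal(mean(lens), trunc_mean, tolerance = 3 * mu / sqrt(length(lens)))
})

test_that("synthetic outputs are reproducible bit-for-bit under a fixed seed", {
  map <- gen_marker_map(2, 200, 20e6, seed = 22)
  x <- runif(400, 0.1, 0.9)
  a <- gen_autozygous_genomes(map, x, 3, 0.1, 5, seed = 23)
  b <- gen_autozygous_genomes(map, x, 3, 0.1, 5, seed = 23)
  expect_identical(a$gm$geno, b$gm$geno)
  expect_identical(a$truth, b$truth)
  g1 <- gen_cross_genotypes(x, rev(x), map, cross_design("A", "B", "F2"), 4, seed = 24)
  g2 <- gen_cross_genotypes(x, rev(x), map, cross_design("A", "B", "F2"), 4, seed = 24)
  expect_identical(g1$gm$geno, g2$gm$geno)
})
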