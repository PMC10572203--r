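test_that("genotype probabilities and mixture frequencies follow HWE algebra", {
  expect_equal(genotype_prob(1, 0.5), 0.5)
  expect_equal(genotype_prob(0, 0), 1)
  expect_equal(genotype_prob(2, 0.3), 0.09)
  expect_equal(genotype_prob(c(0, 1, 2), 0.4), c(0.36, 0.48, 0.16))

  expect_equal(mixture_freq(c(1, 0), c(0.4, 0.9)), 0.4)
  expect_equal(mixture_freq(c(0.5, 0.5), c(0.2, 0.6)), 0.4)
  for (w1 in c(0, 0.3, 1))  # convexity: constant columns are fixed points
    expect_equal(mixture_freq(c(w1, 1 - w1), c(0.7, 0.7)), 0.7)
  expect_equal(mixture_freq(c(1, 0), c(0, 1)), 1e-6)  # clamping
})

test_that("the admixture log-likelihood matches the direct product form", {
  # single heterozygous SNP at f = 0.5: ln(2 * 0.5 * 0.5)
  fr <- matrix(0.5, 1, 1, dimnames = list("A", NULL))
  expect_equal(admixture_loglik(1L, fr, 1), log(0.5))
  # additivity under SNP duplication
  fr2 <- matrix(runif(10, 0.2, 0.8), 2, 5, dimnames = list(c("A", "B"), NULL))
  g <- c(0L, 1L, 2L, 1L, 0L)
  w <- c(0.3, 0.7)
  l1 <- admixture_loglik(g, fr2, w)
  l2 <- admixture_loglik(c(g, g), cbind(fr2, fr2), w)
  expect_equal(l2, 2 * l1)
  # oracle: direct sum of ln Pr(g | f) over random inputs
  for (s in 1:5) {
    set.seed(50 + s)
    Tb <- sample(2:4, 1); M <- 50
    fr <- matrix(runif(Tb * M, 0.05, 0.95), Tb, M,
                 dimnames = list(paste0("b", 1:Tb), NULL))
    w <- as.numeric(rmultinom(1, 100, rep(1, Tb))) / 100
    g <- sample(0:2, M, replace = TRUE)
    g[sample(M, 5)] <- NA
    f <- as.vector(crossprod(fr, w))
    direct <- sum(log(genotype_prob(g[!is.na(g)], f[!is.na(g)])))
    expect_equal(admixture_loglik(g, fr, w), direct, tolerance = 1e-10)
  }
  expect_error(admixture_loglik(c(NA, NA), fr2[, 1:2], w), "non-missing")
})

test_that("BFGS admixture estimates match the exhaustive grid-search oracle", {
  map <- gen_marker_map(1, 800, 80e6, seed = 60)
  fr <- gen_breed_frequencies(map, list("A", "B", "C"), fst = 0.15, seed = 61)
  # a trivially degenerate simplex
  one <- estimate_gbc(rep(1L, 800), fr["A", , drop = FALSE])
  expect_identical(unname(one$weights), 1)
  for (s in 1:4) {
    cg <- gen_cross_genotypes(fr["A", ], fr["B", ], map,
                              cross_design("A", "B", "F2"), 1, seed = 70 + s)
    est <- estimate_gbc(cg$gm$geno[1, ], fr, prune_tol = 0)  # no pruning
    oracle <- oracle_grid_argmax(cg$gm$geno[1, ], fr, step = 0.01)
    expect_true(all(abs(est$raw_weights - oracle$w) <= 0.015))
    expect_gte(est$loglik - log(2) * sum(cg$gm$geno[1, ] == 1), oracle$loglik - 1e-6)
  }
})

test_that("purebred and F1 simulations recover their admixture weights", {
  map <- gen_marker_map(2, 1000, 100e6, seed = 62)  # M = 2,000
  fr <- gen_breed_frequencies(map, list("A", "B", "C", "D"), fst = 0.25, seed = 63)
  pb <- gen_purebred_genotypes(fr["B", ], map, 2, seed = 64)
  for (i in 1:2) {
    est <- estimate_gbc(pb$geno[i, ], fr)
    expect_gte(est$weights[["B"]], 0.99)
    expect_true(est$converged)
  }
  map5 <- gen_marker_map(2, 2500, 125e6, seed = 65)  # M = 5,000
  fr5 <- gen_breed_frequencies(map5, list("A", "B", "C", "D"), fst = 0.25, seed = 66)
  f1 <- gen_cross_genotypes(fr5["A", ], fr5["C", ], map5,
                            cross_design("A", "C", "F1"), 2, seed = 67)
  for (i in 1:2) {
    est <- estimate_gbc(f1$gm$geno[i, ], fr5)
    expect_lt(abs(est$weights[["A"]] - 0.5), 0.05)
    expect_lt(abs(est$weights[["C"]] - 0.5), 0.05)
  }
})

test_that("estimated weights always improve on the uniform start and sum to one", {
  map <- gen_marker_map(1, 500, 50e6, seed = 68)
  fr <- gen_breed_frequencies(map, list(c("A", "B"), "C"), fst = c(0.2, 0.05), seed = 69)
  for (s in 1:6) {
    g <- gen_purebred_genotypes(fr[sample(3, 1), ], map, 1, seed = 80 + s)$geno[1, ]
    est <- estimate_gbc(g, fr)
    expect_equal(sum(est$weights), 1, tolerance = 1e-8)
    expect_true(all(est$weights >= 0))
    uniform <- admixture_loglik(g, fr, rep(1 / 3, 3))
    expect_gte(est$loglik, uniform)
  }
})

test_that("nullification zeroes sub-threshold weights and rescales the rest", {
  expect_equal(unname(nullify_rescale(c(0.995, 0.005), 0.01)), c(1, 0))
  expect_equal(unname(nullify_rescale(c(0.5, 0.5), 0.01)), c(0.5, 0.5))
  expect_equal(unname(nullify_rescale(c(0.90, 0.06, 0.04), 0.05)),
               c(0.9375, 0.0625, 0))
  expect_error(nullify_rescale(c(0.004, 0.003), 0.01), "threshold")
})

test_that("purebred classification is boundary-inclusive", {
  w <- c(NX = 0.94, DC = 0.06)
  expect_equal(classify_purebred(w, "NX", 0.94), "purebred")
  expect_equal(classify_purebred(c(NX = 0.93, DC = 0.07), "NX", 0.94), "crossbred")
  expect_equal(classify_purebred(c(NX = 1), "NX", 1), "purebred")
  expect_error(classify_purebred(w, "ZZ"), "unknown breed")
})

test_that("two-breed typing rescales qualifying pairs and rejects others", {
  r <- two_breed_composition(c(DC = 0.32, NX = 0.64, LR = 0.04), "DC", "NX", 0.05)
  expect_true(r$is_cross)
  expect_equal(unname(r$fractions), c(1, 2) / 3)
  r2 <- two_breed_composition(c(NX = 1, DC = 0, LR = 0), "DC", "NX")
  expect_false(r2$is_cross)  # zero weight for one parent
  r3 <- two_breed_composition(c(DC = 0.4, NX = 0.4, LR = 0.2), "DC", "NX")
  expect_false(r3$is_cross)  # a third breed survives
  # F1 simulation lands near 50/50, inside the envelope seen in field crosses
  map <- gen_marker_map(2, 1500, 125e6, seed = 90)
  fr <- gen_breed_frequencies(map, list(c("NX", "SZL"), c("DC", "LR")),
                              fst = c(0.2, 0.05), seed = 91)
  f1 <- gen_cross_genotypes(fr["DC", ], fr["NX", ], map,
                            cross_design("DC", "NX", "F1"), 3, seed = 92)
  for (i in 1:3) {
    est <- estimate_gbc(f1$gm$geno[i, ], fr)
    ty <- two_breed_composition(est$weights, "DC", "NX", 0.05)
    expect_true(ty$is_cross)
    expect_gt(ty$fractions[["DC"]], 0.16)
    expect_lt(ty$fractions[["DC"]], 0.62)
    expect_lt(abs(ty$fractions[["DC"]] - 0.5), 0.08)
  }
})

test_that("admixture error shrinks as the panel grows", {
  fr_big <- gen_breed_frequencies(gen_marker_map(2, 2500, 125e6, seed = 93),
                                  list("A", "B"), fst = 0.2, seed = 94)
  err <- sapply(c(500, 5000), function(M) {
    idx <- seq_len(M)
    fr <- fr_big[, idx, drop = FALSE]
    e <- numeric(6)
    for (s in 1:6) {
      map_s <- gen_marker_map(1, M, M * 5e4, seed = 95)
      bc <- gen_cross_genotypes(fr["A", idx], fr["B", idx], map_s,
                                cross_design("A", "B", "BC_A"), 1, seed = 200 + s)
      est <- estimate_gbc(bc$gm$geno[1, ], fr)
      e[s] <- abs(est$weights[["A"]] - bc$origin$fracA[1])
    }
    mean(e)
  })
  expect_lt(err[2], err[1])
})

test_that("exact-purity calls become rarer as the panel grows", {
  # animals carrying a trace (2%) of foreign ancestry: a small panel cannot
  # resolve the trace (estimate collapses to exactly 1.0 after the 1%
  # filter) while a large panel detects it, so purity calls get stricter
  # with panel size
  map <- gen_marker_map(2, 2000, 125e6, seed = 96)
  fr <- gen_breed_frequencies(map, list("NX", "DC"), fst = 0.25, seed = 97)
  fmix <- 0.98 * fr["NX", ] + 0.02 * fr["DC", ]
  n_exact <- function(M, seed) {
    idx <- seq_len(M)
    fr_m <- fr[, idx, drop = FALSE]
    gm <- gen_purebred_genotypes(fmix, map, 6, seed = seed)  # HWE at mixture freq
    cnt <- 0
    for (i in 1:6) {
      est <- estimate_gbc(gm$geno[i, idx], fr_m)
      w <- nullify_rescale(est$weights, 0.01)
      if (w[["NX"]] == 1) cnt <- cnt + 1
    }
    cnt
  }
  small <- mean(sapply(1:5, function(s) n_exact(400, 300 + s)))
  large <- mean(sapply(1:5, function(s) n_exact(4000, 300 + s)))
  expect_lte(large, small)
})
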