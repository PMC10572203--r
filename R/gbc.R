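#' Genotype probability under Hardy-Weinberg equilibrium
#'
#' Probability of an allele-A dosage given the mixture allele-A frequency
#' `f`: `(1-f)^2`, `2f(1-f)` or `f^2` for dosage 0, 1, 2.
#'
#' @param g dosage in \{0, 1, 2\} (vectorized).
#' @param f allele-A frequency (vectorized).
#' @return probability vector.
#' @examples
#' genotype_prob(1, 0.5) # 0.5
#' @export
genotype_prob <- function(g, f) {
  stopifnot(all(g %in% 0:2), all(f >= 0 & f <= 1))
  ifelse(g == 0, (1 - f)^2, ifelse(g == 1, 2 * f * (1 - f), f^2))
}

#' Mixture allele frequency at one SNP
#'
#' Weighted allele-A frequency `f = sum_j w_j x_j` across reference breeds,
#' clamped to `[eps, 1 - eps]` so downstream log terms stay finite at
#' monomorphic SNPs.
#'
#' @param w admixture weight vector (non-negative, summing to 1).
#' @param x_col per-breed allele-A frequencies at the SNP.
#' @param eps clamping bound (default 1e-6).
#' @return scalar frequency.
#' @export
mixture_freq <- function(w, x_col, eps = 1e-6) {
  if (length(w) != length(x_col)) stop("weight and frequency lengths differ")
  min(max(sum(w * x_col), eps), 1 - eps)
}

#' Admixture log-likelihood of one animal
#'
#' `l = sum_k [ g_k ln f_k + (2 - g_k) ln(1 - f_k) ] + C` over non-missing
#' SNPs, with `f_k` the weighted (and clamped) mixture frequency and
#' `C = sum_k ln choose(2, g_k)` the weight-independent binomial constant
#' (`ln 2` for each heterozygote), so the value equals the direct sum of
#' `ln Pr(g_k | f_k)` Hardy-Weinberg genotype probabilities.
#'
#' @param g_vec dosage vector (`NA` = missing, skipped).
#' @param freqs breeds-by-SNPs allele-A frequency matrix.
#' @param w admixture weights over the breeds (rows of `freqs`).
#' @param eps frequency clamping bound.
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(g_vec, freqs, w, eps = 1e-6) {
  if (length(g_vec) != ncol(freqs))
    stop("genotype vector length (", length(g_vec),
         ") does not match frequency table SNPs (", ncol(freqs), ")")
  keep <- !is.na(g_vec)
  if (!any(keep)) stop("animal has no non-missing genotype")
  g <- g_vec[keep]
  f <- as.vector(crossprod(freqs[, keep, drop = FALSE], w))
  f <- pmin(pmax(f, eps), 1 - eps)
  sum(g * log(f) + (2 - g) * log(1 - f)) + log(2) * sum(g == 1)
}

# negative log-likelihood and gradient on the softmax scale (closures over
# the genotype vector and SNPs-by-breeds frequency matrix)
gbc_objective <- function(g, X, eps) {
  negloglik <- function(theta) {
    w <- exp(theta - max(theta)); w <- w / sum(w)
    f <- as.vector(X %*% w)
    f <- pmin(pmax(f, eps), 1 - eps)
    -sum(g * log(f) + (2 - g) * log(1 - f))
  }
  neggrad <- function(theta) {
    w <- exp(theta - max(theta)); w <- w / sum(w)
    f <- as.vector(X %*% w)
    cl <- f < eps | f > 1 - eps
    f <- pmin(pmax(f, eps), 1 - eps)
    dldf <- g / f - (2 - g) / (1 - f)
    dldf[cl] <- 0
    dldw <- as.vector(crossprod(X, dldf))
    # softmax Jacobian: dw_j/dtheta_m = w_j (1[j=m] - w_m)
    -(w * (dldw - sum(dldw * w)))
  }
  list(negloglik = negloglik, neggrad = neggrad)
}

#' Estimate genomic breed composition for one animal
#'
#' Maximizes the admixture log-likelihood over the breed simplex. The
#' simplex constraint (non-negative weights summing to one) is enforced by
#' a softmax reparameterization optimized with unconstrained BFGS, started
#' from uniform weights with random restarts on non-convergence. After
#' convergence the weight set is pruned: the smallest non-zero weight is
#' zeroed and the remaining breeds refitted; the reduction is kept while
#' the log-likelihood drop stays below `prune_tol`, yielding a concise
#' mixing set without breeds that do not significantly improve the fit.
#'
#' @param g_vec dosage vector for one animal (`NA` = missing).
#' @param freqs breeds-by-SNPs allele-A frequency matrix with breed rownames.
#' @param prune_tol log-likelihood drop below which a breed is pruned
#'   (default 1e-3).
#' @param eps frequency clamping bound (default 1e-6).
#' @param max_restarts random restarts if BFGS does not converge.
#' @param seed optional seed for the restart draws.
#' @return A `gbc_result` list: `weights` (pruned, summing to 1, named by
#'   breed), `raw_weights` (before pruning), `loglik`, `converged`,
#'   `n_snps` used.
#' @examples
#' map <- gen_marker_map(1, 400, 40e6, seed = 2)
#' fr <- gen_breed_frequencies(map, c("A", "B"), fst = 0.3, seed = 2)
#' gm <- gen_purebred_genotypes(fr["A", ], map, 1, seed = 3)
#' estimate_gbc(gm$geno[1, ], fr)$weights
#' @export
estimate_gbc <- function(g_vec, freqs, prune_tol = 1e-3, eps = 1e-6,
                         max_restarts = 5L, seed = NULL) {
  check_freq_table(freqs)
  breeds <- rownames(freqs)
  T_br <- nrow(freqs)
  keep <- !is.na(g_vec)
  if (!any(keep)) stop("animal has no non-missing genotype")
  g <- as.numeric(g_vec[keep])
  X <- t(freqs[, keep, drop = FALSE])          # SNPs x breeds
  const <- log(2) * sum(g == 1)

  if (T_br == 1L) {
    w <- setNames(1, breeds)
    ll <- sum(g * log(pmin(pmax(X[, 1], eps), 1 - eps)) +
              (2 - g) * log(1 - pmin(pmax(X[, 1], eps), 1 - eps))) + const
    return(structure(list(weights = w, raw_weights = w, loglik = ll,
                          converged = TRUE, n_snps = length(g)),
                     class = "gbc_result"))
  }

  fit_subset <- function(cols, theta0 = NULL) {
    Xs <- X[, cols, drop = FALSE]
    if (length(cols) == 1L) {
      f <- pmin(pmax(Xs[, 1], eps), 1 - eps)
      return(list(w = 1, ll = sum(g * log(f) + (2 - g) * log(1 - f)),
                  conv = TRUE))
    }
    if (is.null(theta0)) theta0 <- rep(0, length(cols))
    obj <- gbc_objective(g, Xs, eps)
    opt <- optim(theta0, obj$negloglik, obj$neggrad,
                 method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    w <- exp(opt$par - max(opt$par)); w <- w / sum(w)
    list(w = w, ll = -opt$value, conv = opt$convergence == 0)
  }

  fit <- with_seed(seed, {
    f0 <- fit_subset(seq_len(T_br))
    r <- 0L
    while (!f0$conv && r < max_restarts) {
      r <- r + 1L
      f1 <- fit_subset(seq_len(T_br), theta0 = stats::rnorm(T_br, sd = 1))
      if (f1$ll > f0$ll || f1$conv) f0 <- f1
    }
    f0
  })
  raw <- numeric(T_br); raw[seq_len(T_br)] <- fit$w
  names(raw) <- breeds

  # backward pruning of breeds that do not significantly improve the fit
  active <- seq_len(T_br)
  w_act <- fit$w
  ll_act <- fit$ll
  conv <- fit$conv
  repeat {
    if (length(active) == 1L) break
    drop_i <- which.min(w_act)
    cand <- active[-drop_i]
    f_new <- fit_subset(cand)
    if (ll_act - f_new$ll < prune_tol) {
      active <- cand
      w_act <- f_new$w
      ll_act <- f_new$ll
      conv <- conv && f_new$conv
    } else break
  }
  w <- numeric(T_br)
  w[active] <- w_act
  names(w) <- breeds
  structure(list(weights = w, raw_weights = raw, loglik = ll_act + const,
                 converged = conv, n_snps = length(g)),
            class = "gbc_result")
}

#' @export
print.gbc_result <- function(x, ...) {
  cat("GBC estimate over", length(x$weights), "breeds (",
      x$n_snps, "SNPs ): logLik =", format(x$loglik, digits = 8),
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(round(x$weights[x$weights > 0], 4))
  invisible(x)
}

#' Estimate GBC for every animal of a genotype matrix
#'
#' @param gm a [genotype_matrix] whose SNPs match `freqs` columns.
#' @param freqs breeds-by-SNPs allele-A frequency matrix.
#' @param nullify_threshold weights below this are zeroed and the rest
#'   rescaled (default 0.01); see [nullify_rescale].
#' @param ... passed to [estimate_gbc].
#' @return data.frame with one row per animal: filtered weights per breed,
#'   `loglik`, `converged`.
#' @export
estimate_gbc_all <- function(gm, freqs, nullify_threshold = 0.01, ...) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_freq_table(freqs, gm$map)
  res <- lapply(seq_len(nrow(gm$geno)), function(i) {
    r <- estimate_gbc(gm$geno[i, ], freqs, ...)
    w <- nullify_rescale(r$weights, nullify_threshold)
    c(w, loglik = r$loglik, converged = as.numeric(r$converged))
  })
  out <- as.data.frame(do.call(rbind, res))
  out$converged <- out$converged == 1
  cbind(data.frame(animal = gm$ids), out)
}

#' Nullify small admixture components and rescale
#'
#' Weights strictly below `threshold` are set to zero and the survivors
#' rescaled to sum to one. Removing noise components below 1% makes an
#' animal estimated at 99.5% for its breed report exactly 100%, which is
#' why a GBC = 1 rule and a GBC >= 0.94 rule can classify identically.
#'
#' @param w admixture weight vector.
#' @param threshold nullification threshold in `[0, 1)`.
#' @return rescaled weight vector.
#' @examples
#' nullify_rescale(c(0.995, 0.005), 0.01) # 1, 0
#' @export
nullify_rescale <- function(w, threshold = 0.01) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  w2 <- ifelse(w < threshold, 0, w)
  s <- sum(w2)
  if (s == 0) stop("every component fell below the nullification threshold")
  w2 / s
}

#' Classify an animal as purebred or crossbred
#'
#' Purebred if and only if the (filtered) weight of the named breed is at
#' least `cutoff` (boundary inclusive).
#'
#' @param w named (filtered) admixture weight vector, or a `gbc_result`.
#' @param breed breed label to test.
#' @param cutoff purity cut-off in `(0, 1]` (default 0.94).
#' @return `"purebred"` or `"crossbred"`.
#' @export
classify_purebred <- function(w, breed, cutoff = 0.94) {
  if (inherits(w, "gbc_result")) w <- w$weights
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (!breed %in% names(w)) stop("unknown breed label: ", breed)
  if (w[[breed]] >= cutoff) "purebred" else "crossbred"
}

#' Type an animal as a two-breed cross
#'
#' Nullifies all components below `threshold` (default 5%); the animal
#' qualifies as an A-by-B cross if and only if exactly the two named breeds
#' survive with non-zero weight. Qualifying animals get their two weights
#' rescaled to sum to one (the two-breed genomic contributions).
#'
#' @param w named admixture weight vector or `gbc_result`.
#' @param breedA,breedB the two parental breeds (distinct).
#' @param threshold nullification threshold (default 0.05).
#' @return list: `is_cross` (logical), and when `TRUE` `fractions` (named
#'   pair summing to 1); when `FALSE` a `reason` string.
#' @examples
#' two_breed_composition(c(DC = 0.32, NX = 0.64, LR = 0.04), "DC", "NX")
#' @export
two_breed_composition <- function(w, breedA, breedB, threshold = 0.05) {
  if (inherits(w, "gbc_result")) w <- w$weights
  if (breedA == breedB) stop("breedA and breedB must differ")
  if (!all(c(breedA, breedB) %in% names(w)))
    stop("breed labels absent from the weight vector")
  w2 <- ifelse(w < threshold, 0, w)
  names(w2) <- names(w)
  nz <- names(w2)[w2 > 0]
  if (length(setdiff(nz, c(breedA, breedB))) > 0)
    return(list(is_cross = FALSE,
                reason = paste("other breeds retain weight:",
                               paste(setdiff(nz, c(breedA, breedB)), collapse = ", "))))
  if (!all(c(breedA, breedB) %in% nz))
    return(list(is_cross = FALSE,
                reason = paste("zero weight for",
                               paste(setdiff(c(breedA, breedB), nz), collapse = ", "))))
  fr <- w2[c(breedA, breedB)] / sum(w2[c(breedA, breedB)])
  list(is_cross = TRUE, fractions = fr)
}

#' Change point of a sorted GBC curve
#'
#' Finds the single breakpoint of a non-decreasing GBC sequence by
#' least-squares segmentation: the split minimizing the total within-segment
#' sum of squared deviations. Used to locate where estimated purity departs
#' from the purebred plateau and hence to motivate a purity cut-off. The
#' value returned is the first value of the upper (plateau-side) segment.
#'
#' @param gbc_values numeric vector, sorted ascending (at least 10 values).
#' @return list: `index` (first index of the upper segment), `value` (GBC
#'   at that index), or `NULL` for a constant sequence (no change point).
#' @export
gbc_change_point <- function(gbc_values) {
  n <- length(gbc_values)
  if (n < 10) stop("need at least 10 values")
  if (is.unsorted(gbc_values)) stop("values must be sorted ascending")
  x <- gbc_values
  if (diff(range(x)) == 0) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  best <- Inf; best_k <- NA_integer_
  for (k in 1:(n - 1)) {           # left segment = 1..k
    sl <- cs[k]; sl2 <- cs2[k]
    sr <- cs[n] - sl; sr2 <- cs2[n] - sl2
    sse <- (sl2 - sl^2 / k) + (sr2 - sr^2 / (n - k))
    if (sse < best) { best <- sse; best_k <- k }
  }
  list(index = best_k + 1L, value = x[best_k + 1L])
}
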