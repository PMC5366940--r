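# Shared fixtures and independent reference implementations ("oracles")
# used across the test files. Oracles deliberately use different code paths
# (optim/BFGS, glm, manual arithmetic) from the package internals they check.

# quick hand-built methylome sample
make_sample <- function(id, chrom, pos, meth, unmeth,
                        strand = "+", context = "CG",
                        sex = "unknown", genotype = NA, site = NA) {
  methylome_sample(id, cytosine_calls(chrom, pos, strand, context,
                                      meth, unmeth),
                   sex = sex, genotype = genotype, site = site)
}

# small fast genome/cohort for integration-style tests
tiny_layout <- function(seed = 1, n_chrom = 2, chrom_length = 20000,
                        genes = c(0, 3)) {
  build_genome(n_chrom = n_chrom, chrom_length = chrom_length,
               genes_per_chrom = genes, seed = seed)
}

tiny_cohort <- function(seed = 1, nf = 4, nm = 4, ...) {
  cohort_spec(n_female = nf, n_male = nm, seed = seed, ...)
}

# reference ridge-penalized logistic criterion via BFGS with analytic
# gradient (independent of the package's IRLS)
ref_ridge_fit <- function(X, y, lambda, pen = c(0, rep(1, ncol(X) - 1L))) {
  fn <- function(b) {
    eta <- drop(X %*% b)
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      lambda * sum(pen * b^2)
  }
  gr <- function(b) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    drop(crossprod(X, p - y)) + 2 * lambda * pen * b
  }
  o <- optim(rep(0, ncol(X)), fn, gr, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-15))
  list(criterion = o$value, beta = o$par)
}

# criterion of a cluster given members+signs (columns of standardized Xs)
ref_cluster_crit <- function(Xs, y, members, signs, lambda) {
  z <- if (length(members) == 1L) signs * Xs[, members] else
    rowMeans(sweep(Xs[, members, drop = FALSE], 2, signs, "*"))
  ref_ridge_fit(cbind(1, z), y, lambda)$criterion
}

# brute-force greedy forward selection with recurrent pruning: the same
# search rule as the package but with exhaustive candidate evaluation and
# BFGS fits throughout. Returns the first-cluster criterion and members.
ref_greedy_cluster <- function(Xs, y, lambda, max_size = 3, tol = 1e-12) {
  p <- ncol(Xs)
  members <- integer(0); signs <- numeric(0)
  crit <- ref_ridge_fit(cbind(1, rep(0, nrow(Xs))), y, lambda,
                        pen = c(0, 1))$criterion
  repeat {
    if (length(members) >= max_size) break
    best <- crit - tol; bm <- NA; bs <- NA
    for (j in setdiff(seq_len(p), members)) for (s in c(1, -1)) {
      cc <- ref_cluster_crit(Xs, y, c(members, j), c(signs, s), lambda)
      if (cc < best) { best <- cc; bm <- j; bs <- s }
    }
    if (is.na(bm)) break
    members <- c(members, bm); signs <- c(signs, bs); crit <- best
    while (length(members) >= 2) {
      best <- crit - tol; bj <- NA
      for (j in seq_along(members)) {
        cc <- ref_cluster_crit(Xs, y, members[-j], signs[-j], lambda)
        if (cc < best) { best <- cc; bj <- j }
      }
      if (is.na(bj)) break
      members <- members[-bj]; signs <- signs[-bj]; crit <- best
    }
  }
  list(criterion = crit, members = members, signs = signs)
}

# exhaustive enumeration of all clusters of size <= max_size with
# orientations; returns the minimum criterion
ref_enum_best <- function(Xs, y, lambda, max_size = 3) {
  p <- ncol(Xs); best <- Inf
  for (k in seq_len(max_size)) {
    combs <- utils::combn(p, k)
    sgns <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
    for (ci in seq_len(ncol(combs))) for (si in seq_len(nrow(sgns))) {
      cc <- ref_cluster_crit(Xs, y, combs[, ci], sgns[si, ], lambda)
      if (cc < best) best <- cc
    }
  }
  best
}
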