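# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Beta MLE by three-stage grid refinement over (alpha, beta).
oracle_beta_grid <- function(x, lo = 0.1, hi = 20) {
  ll <- function(a, b) sum(stats::dbeta(x, a, b, log = TRUE))
  a_rng <- c(lo, hi); b_rng <- c(lo, hi)
  best <- c(NA, NA)
  for (stage in 1:4) {
    as <- seq(a_rng[1], a_rng[2], length.out = 41)
    bs <- seq(b_rng[1], b_rng[2], length.out = 41)
    grid <- expand.grid(a = as, b = bs)
    vals <- mapply(ll, grid$a, grid$b)
    best <- unlist(grid[which.max(vals), ])
    da <- diff(a_rng) / 40; db <- diff(b_rng) / 40
    a_rng <- c(max(1e-3, best[1] - da), best[1] + da)
    b_rng <- c(max(1e-3, best[2] - db), best[2] + db)
  }
  unname(best)
}

# Dirichlet-multinomial MLE by direct numerical maximization of the
# log-likelihood written as exact rising-factorial sums (stable for the
# small per-row totals here, and independent of the package's digamma
# fixed-point formulation), with the analytic gradient.
oracle_dm_optim <- function(counts) {
  k <- rowSums(counts)
  kmax <- max(k)
  nll <- function(loga) {
    a <- exp(loga); A <- sum(a)
    ll <- 0
    for (t in 0:(kmax - 1)) {
      ll <- ll - sum(k > t) * log(A + t)
      for (c in seq_along(a)) {
        ll <- ll + sum(counts[, c] > t) * log(a[c] + t)
      }
    }
    -ll
  }
  grad <- function(loga) {
    a <- exp(loga); A <- sum(a)
    g <- numeric(length(a))
    dA <- 0
    for (t in 0:(kmax - 1)) {
      dA <- dA + sum(k > t) / (A + t)
      for (c in seq_along(a)) {
        g[c] <- g[c] + sum(counts[, c] > t) / (a[c] + t)
      }
    }
    -(a * (g - dA))
  }
  p0 <- colSums(counts) / sum(counts)
  fit <- stats::optim(log(pmax(p0, 1e-3) * 3), nll, gr = grad,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  exp(fit$par)
}

# All-pairs (unwindowed) adjusted-r2 LD scores via an explicit double loop.
oracle_ld_scores <- function(dosages) {
  m <- ncol(dosages); n <- nrow(dosages)
  l <- numeric(m)
  for (j in seq_len(m)) {
    tot <- 0
    for (k in seq_len(m)) {
      r2 <- stats::cor(dosages[, j], dosages[, k])^2
      tot <- tot + r2 - (1 - r2) / (n - 2)
    }
    l[j] <- tot
  }
  l
}

# Greedy clumping re-implemented as an iterative re-scan over a working
# copy of the table.
oracle_clump <- function(ss, p_threshold, window_bp) {
  work <- data.frame(snp = ss$SNP, chr = ss$CHR, bp = ss$BP, p = ss$P,
                     stringsAsFactors = FALSE)
  work <- work[work$p < p_threshold, , drop = FALSE]
  leads <- character(0)
  while (nrow(work) > 0) {
    ord <- order(work$p, work$chr, work$bp, work$snp)
    work <- work[ord, , drop = FALSE]
    lead <- work[1, ]
    leads <- c(leads, lead$snp)
    work <- work[!(work$chr == lead$chr &
                     abs(work$bp - lead$bp) <= window_bp), , drop = FALSE]
  }
  leads
}

# Effective-tests formula evaluated through an independently coded path.
oracle_meff_galwey <- function(R) {
  ev <- base::eigen(R)$values
  ev[ev < 0] <- 0
  (sum(sqrt(ev)))^2 / sum(ev)
}

# Two-loop sums-of-squares one-way ICC.
oracle_icc_twoloop <- function(m) {
  n <- nrow(m); r <- ncol(m)
  grand <- mean(m)
  ssb <- 0; ssw <- 0
  for (i in seq_len(n)) {
    mi <- mean(m[i, ])
    ssb <- ssb + r * (mi - grand)^2
    for (j in seq_len(r)) ssw <- ssw + (m[i, j] - mi)^2
  }
  msb <- ssb / (n - 1); msw <- ssw / (n * (r - 1))
  s2b <- max(0, (msb - msw) / r)
  s2b / (s2b + msw)
}

# Least-squares residuals via explicit normal equations.
oracle_residualize <- function(y, X) {
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  drop(y - Xi %*% beta)
}

# Dirichlet and Dirichlet-multinomial samplers for fixtures.
r_dirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}

r_dm_counts <- function(n, alpha, k) {
  p <- r_dirichlet(n, alpha)
  t(vapply(seq_len(n), function(i) {
    drop(stats::rmultinom(1, k[i], p[i, ]))
  }, integer(length(alpha))))
}
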