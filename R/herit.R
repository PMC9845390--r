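# SNP heritability: LD score regression on summary statistics, with
# Haseman-Elston regression on individual-level data as a cross-check.

#' Compute windowed LD scores from a genotype matrix
#'
#' For each SNP j, l_j is the sum over SNPs k within `window_bp` of j (same
#' chromosome, self included) of the adjusted squared correlation
#' r2_adj = r2 - (1 - r2)/(N - 2), which is unbiased for the population r2
#' at r2 = 0 and equals 1 for the self term.
#'
#' @param g `genotype_matrix`.
#' @param window_bp window radius in base pairs (0 gives self-only scores
#'   of exactly 1).
#' @return data frame of class `ld_score_table`: snp, ld_score, window_bp.
#' @export
compute_ld_scores <- function(g, window_bp = 1e6) {
  d <- g$dosages
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 individuals", call. = FALSE)
  sds <- apply(d, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance SNP; filter before computing LD scores", call. = FALSE)
  m <- ncol(d)
  bp <- g$map$bp
  chr <- g$map$chr
  r2 <- stats::cor(d)^2
  adj <- r2 - (1 - r2) / (n - 2)
  within <- outer(bp, bp, function(a, b) abs(a - b) <= window_bp) &
    outer(chr, chr, "==")
  adj[!within] <- 0
  l <- rowSums(adj)
  data.frame(snp = g$map$snp, ld_score = pmax(l, 1e-8),
             window_bp = window_bp, stringsAsFactors = FALSE) |>
    structure(class = c("ld_score_table", "data.frame"))
}

#' LD score regression heritability
#'
#' Weighted least-squares regression of per-SNP chi-square statistics on LD
#' scores with a free intercept; the slope b yields h2 = b * M / N. Weights
#' are 1/max(l_j, 1); the slope standard error is a delete-one-block
#' jackknife over contiguous SNP blocks (robust to the LD correlation of
#' neighbouring chi-squares), and the reported p-value is the one-sided
#' Wald test of h2 > 0.
#'
#' @param ss `sumstats` for one phenotype.
#' @param ld `ld_score_table` covering the same SNPs.
#' @param M number of SNPs the heritability is referred to (defaults to the
#'   number of regression SNPs).
#' @param n_blocks number of contiguous SNP blocks for the jackknife
#'   standard error.
#' @return object of class `h2_estimate` with fields `h2`, `se`,
#'   `intercept`, `p`, `N`, `M`, `method = "ldsc"`, `phenotype`.
#' @export
ldsc_h2 <- function(ss, ld, M = NULL, n_blocks = 20) {
  idx <- match(ss$SNP, ld$snp)
  if (anyNA(idx)) stop("LD scores missing for some summary-statistic SNPs", call. = FALSE)
  ord <- order(ss$CHR, ss$BP)
  l <- ld$ld_score[idx][ord]
  chisq <- ss$CHISQ[ord]
  m <- length(chisq)
  if (m < 10L) stop("fewer than 10 SNPs for LD score regression", call. = FALSE)
  N <- ss$N[1]
  if (is.null(M)) M <- m
  w <- 1 / pmax(l, 1)
  X <- cbind(1, l)
  wls_slope <- function(keep) {
    XtWX <- crossprod(X[keep, , drop = FALSE], w[keep] * X[keep, , drop = FALSE])
    drop(solve(XtWX, crossprod(X[keep, , drop = FALSE], w[keep] * chisq[keep])))
  }
  b <- wls_slope(rep(TRUE, m))
  # delete-one-block jackknife over position-contiguous blocks
  n_blocks <- max(2L, min(n_blocks, floor(m / 5)))
  blk <- cut(seq_len(m), n_blocks, labels = FALSE)
  theta <- vapply(seq_len(n_blocks),
                  function(bk) wls_slope(blk != bk), numeric(2))
  jk <- sqrt((n_blocks - 1) / n_blocks *
               rowSums((theta - rowMeans(theta))^2))
  slope <- b[2]
  h2 <- slope * M / N
  se <- jk[2] * M / N
  p <- stats::pnorm(h2 / se, lower.tail = FALSE)
  structure(list(h2 = h2, se = se, intercept = b[1], intercept_se = jk[1],
                 p = max(p, 1e-300),
                 N = N, M = M, method = "ldsc",
                 phenotype = attr(ss, "phenotype")),
            class = "h2_estimate")
}

#' Haseman-Elston regression heritability
#'
#' Builds the genomic relationship matrix from allele-frequency-
#' standardised dosages, A = Z Z' / M, and regresses the phenotype
#' cross-products y_i y_j on A_ij over all pairs i < j; the slope estimates
#' h2 on the standardised-phenotype scale. The standard error is a
#' delete-one-individual jackknife.
#'
#' @param y numeric phenotype (standardised internally).
#' @param g `genotype_matrix`, or a pre-computed GRM via `grm`.
#' @param grm optional pre-computed GRM (individuals x individuals).
#' @param phenotype phenotype id recorded on the result.
#' @return object of class `h2_estimate` (method `"he"`).
#' @export
he_regression <- function(y, g = NULL, grm = NULL, phenotype = "phenotype") {
  if (is.null(grm)) grm <- make_grm(g)
  n <- length(y)
  if (n != nrow(grm)) stop("phenotype/GRM size mismatch", call. = FALSE)
  if (n < 50L) warning("fewer than 50 individuals: unstable estimate")
  y <- as.vector(scale(y))
  A <- grm
  diag(A) <- 0
  Ay <- drop(A %*% y)
  yy_quad <- sum(y * Ay)              # 2 * sum_{i<j} A_ij y_i y_j
  A2row <- rowSums(A^2)               # per-individual sum of squared entries
  Sxy <- yy_quad / 2
  Sxx <- sum(A2row) / 2
  slope <- Sxy / Sxx
  # delete-one jackknife: pairs touching i leave the sums
  r_xy <- y * Ay
  r_xx <- A2row
  slope_i <- (Sxy - r_xy) / (Sxx - r_xx)
  se <- sqrt((n - 1) / n * sum((slope_i - mean(slope_i))^2))
  p <- stats::pnorm(slope / se, lower.tail = FALSE)
  structure(list(h2 = slope, se = se, intercept = NA_real_,
                 p = max(p, 1e-300), N = n,
                 M = if (!is.null(g)) ncol(g$dosages) else NA_integer_,
                 method = "he", phenotype = phenotype),
            class = "h2_estimate")
}

#' Genomic relationship matrix
#'
#' A_ij = (1/M) sum_m (g_im - 2 f_m)(g_jm - 2 f_m) / (2 f_m (1 - f_m)) with
#' empirical allele frequencies f_m.
#'
#' @param g `genotype_matrix`.
#' @return individuals x individuals GRM.
#' @export
make_grm <- function(g) {
  d <- g$dosages
  f <- colMeans(d) / 2
  if (any(f <= 0 | f >= 1)) stop("monomorphic SNP; filter first", call. = FALSE)
  z <- sweep(sweep(d, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  tcrossprod(z) / ncol(d)
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2_estimate [%s, %s]: h2 = %.4f (se %.4f), p = %.3g",
              x$phenotype, x$method, x$h2, x$se, x$p))
  if (x$method == "ldsc") cat(sprintf(", intercept = %.3f", x$intercept))
  cat(sprintf(", N = %d, M = %d\n", x$N, x$M))
  invisible(x)
}

#' Collect heritability estimates into a table
#' @param estimates list of `h2_estimate` objects.
#' @return data frame: phenotype, h2, se, intercept, p, N, M, method.
#' @export
h2_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(phenotype = e$phenotype, h2 = e$h2, se = e$se,
               intercept = e$intercept, p = e$p, N = e$N, M = e$M,
               method = e$method, stringsAsFactors = FALSE)
  }))
}
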