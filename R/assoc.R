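# Covariate-adjusted per-SNP association scans producing LD-score-
# regression-ready summary statistics.

#' Residualize a phenotype on covariates
#'
#' Least-squares residuals of the phenotype on the covariate columns plus
#' an intercept. Factor covariates must be pre-encoded as numeric columns.
#'
#' @param y numeric phenotype vector.
#' @param covariates numeric matrix/data frame of covariate columns, or
#'   NULL for intercept only (mean centering).
#' @return numeric residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) return(y - mean(y))
  X <- as.matrix(covariates)
  if (!is.numeric(X)) stop("covariates must be numeric (pre-encode factors)", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in phenotype or covariates", call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qx$pivot[(qx$rank + 1):ncol(Xi)]]
    stop(sprintf("rank-deficient covariate design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  qr.resid(qx, y)
}

# Residualize every column of a matrix on the covariate design (shared QR).
residualize_matrix <- function(M, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    return(sweep(M, 2, colMeans(M)))
  }
  X <- cbind(1, as.matrix(covariates))
  qx <- qr(X)
  M - qr.fitted(qx, M)
}

#' Per-SNP association scan
#'
#' Filters SNPs on minor allele frequency, minor allele count and
#' missingness, then tests each remaining SNP against the phenotype with
#' both phenotype and dosages residualized on the covariates
#' (Frisch-Waugh-Lovell, so each test equals the joint regression with the
#' covariates included). Emits beta, SE, chi-square and p per SNP in
#' LD-score-regression-ready layout.
#'
#' @param y numeric phenotype vector aligned with the genotype rows.
#' @param g `genotype_matrix`.
#' @param covariates numeric covariate matrix (or NULL).
#' @param maf_min minor allele frequency must exceed this (default 0.005).
#' @param mac_min minor allele count must exceed this (default 10).
#' @param miss_max missingness fraction must be below this (default 0.10).
#' @param phenotype phenotype id recorded on the result.
#' @return object of class `sumstats`: data frame with columns SNP, CHR,
#'   BP, A1, A2, N, BETA, SE, CHISQ, P; attributes `phenotype` and
#'   `covariates`.
#' @export
run_gwas <- function(y, g, covariates = NULL, maf_min = 0.005, mac_min = 10,
                     miss_max = 0.10, phenotype = "phenotype") {
  d <- g$dosages
  if (length(y) != nrow(d)) stop("phenotype/genotype row mismatch", call. = FALSE)
  miss <- colMeans(is.na(d))
  ac <- colSums(d, na.rm = TRUE)
  nobs <- colSums(!is.na(d))
  f <- ac / (2 * nobs)
  maf <- pmin(f, 1 - f)
  mac <- pmin(ac, 2 * nobs - ac)
  keep <- maf > maf_min & mac > mac_min & miss < miss_max
  mono <- apply(d[, keep, drop = FALSE], 2, stats::sd, na.rm = TRUE) == 0
  if (any(mono)) {
    message(sprintf("dropping %d zero-variance SNP(s) after filtering", sum(mono)))
    keep[keep][mono] <- FALSE
  }
  if (!any(keep)) stop("no SNPs pass the filters", call. = FALSE)
  dk <- d[, keep, drop = FALSE]
  if (anyNA(dk)) {
    # mean-impute residual missingness (rate already bounded by miss_max)
    for (j in which(colSums(is.na(dk)) > 0)) {
      dk[is.na(dk[, j]), j] <- mean(dk[, j], na.rm = TRUE)
    }
  }
  n_covar <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  res <- gwas_core(residualize(y, covariates),
                   residualize_matrix(dk, covariates),
                   n_covar = n_covar)
  map <- g$map[keep, , drop = FALSE]
  ss <- data.frame(SNP = map$snp, CHR = map$chr, BP = map$bp,
                   A1 = map$a1, A2 = map$a2, N = length(y),
                   BETA = res$beta, SE = res$se, CHISQ = res$chisq,
                   P = res$p, stringsAsFactors = FALSE, row.names = NULL)
  structure(ss, class = c("sumstats", "data.frame"),
            phenotype = phenotype,
            covariates = if (is.null(covariates)) character(0) else
              colnames(as.matrix(covariates)))
}

# Core scan on pre-residualized phenotype and dosage matrix. Degrees of
# freedom account for the intercept, the SNP, and the covariates projected
# out, so the chi-square equals the joint fit's.
gwas_core <- function(y_res, g_res, n_covar = 0) {
  n <- length(y_res)
  sxx <- colSums(g_res^2)
  sxy <- drop(crossprod(g_res, y_res))
  beta <- sxy / sxx
  df <- n - n_covar - 2
  rss <- sum(y_res^2) - beta * sxy
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  chisq <- (beta / se)^2
  list(beta = beta, se = se, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats [%s]: %d SNPs, N = %d, lambda_GC = %.3f\n",
              attr(x, "phenotype"), nrow(x), x$N[1],
              stats::median(x$CHISQ) / stats::qchisq(0.5, 1)))
  invisible(x)
}

#' Write summary statistics in LDSC-style layout
#'
#' Whitespace/tab-delimited file with header
#' `SNP CHR BP A1 A2 N BETA SE CHISQ P`.
#'
#' @param ss `sumstats`.
#' @param path output path (a `.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(ss, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary statistics written by [write_sumstats()]
#' @param path file path.
#' @param phenotype phenotype id to attach.
#' @return `sumstats` object.
#' @export
read_sumstats <- function(path, phenotype = NA_character_) {
  ss <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  structure(ss, class = c("sumstats", "data.frame"), phenotype = phenotype,
            covariates = character(0))
}
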