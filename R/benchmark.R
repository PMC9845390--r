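# Crude-vs-EB comparison logic: effective number of independent phenotypes,
# significance filtering, win rates overall and by ICC quartile, locus
# clumping and locus-level concordance.

#' Effective number of independent phenotypes
#'
#' Residualizes the phenotype columns on covariates (if given),
#' standardises them, and applies an eigenvalue formula to the correlation
#' matrix. The default `"galwey"` method uses
#' meff = (sum sqrt(lambda))^2 / sum(lambda) over the non-negative
#' eigenvalues; `"li_ji"` uses sum over eigenvalues of
#' I(lambda >= 1) + (lambda - floor(lambda)). The multiple-testing
#' threshold is 0.05 / meff.
#'
#' @param x numeric matrix of phenotype columns (individuals x phenotypes),
#'   or a correlation matrix (square, symmetric, unit diagonal).
#' @param covariates optional numeric covariate matrix (ignored when `x` is
#'   already a correlation matrix).
#' @param method `"galwey"` or `"li_ji"`.
#' @param alpha family-wise error rate for the threshold (default 0.05).
#' @return object of class `meff_result` with fields `m_observed`,
#'   `eigenvalues`, `meff`, `method`, `threshold`.
#' @export
effective_tests <- function(x, covariates = NULL, method = c("galwey", "li_ji"),
                            alpha = 0.05) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 phenotype columns", call. = FALSE)
  is_cor <- nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x), tolerance = 1e-8)) &&
    isTRUE(all.equal(unname(diag(x)), rep(1, ncol(x)), tolerance = 1e-8))
  if (is_cor) {
    R <- x
  } else {
    if (anyNA(x)) stop("complete cases required", call. = FALSE)
    if (!is.null(covariates)) x <- residualize_matrix(x, covariates)
    R <- stats::cor(x)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-6 * max(abs(ev)))) {
    stop("input is not positive semi-definite within tolerance", call. = FALSE)
  }
  ev <- pmax(ev, 0)
  meff <- switch(method,
    galwey = sum(sqrt(ev))^2 / sum(ev),
    li_ji = sum(as.numeric(ev >= 1) + (ev - floor(ev)))
  )
  structure(list(m_observed = ncol(R), eigenvalues = ev, meff = meff,
                 method = method, threshold = alpha / meff),
            class = "meff_result")
}

#' @export
print.meff_result <- function(x, ...) {
  cat(sprintf("meff_result (%s): %d phenotypes, meff = %.2f, threshold = %.3g\n",
              x$method, x$m_observed, x$meff, x$threshold))
  invisible(x)
}

#' Significance threshold from an effective number of tests
#'
#' @param meff effective number of independent phenotypes (a number or a
#'   `meff_result`).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / meff`.
#' @export
significance_threshold <- function(meff, alpha = 0.05) {
  if (inherits(meff, "meff_result")) meff <- meff$meff
  alpha / meff
}

#' Filter crude/EB phenotype pairs on heritability significance
#'
#' Keeps a (crude, EB) pair iff at least one version's heritability Wald
#' p-value falls below the effective-tests threshold.
#'
#' @param pairs data frame with one row per item: columns `item`, `class`,
#'   `crude_h2`, `crude_se`, `crude_p`, `eb_h2`, `eb_se`, `eb_p`.
#' @param meff `meff_result` or numeric effective test count.
#' @param alpha family-wise error rate.
#' @return the retained rows of `pairs`, with the threshold as an attribute.
#' @export
significance_filter <- function(pairs, meff, alpha = 0.05) {
  need <- c("item", "class", "crude_h2", "crude_p", "eb_h2", "eb_p")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` must have both versions per item (crude_* and eb_* columns)",
         call. = FALSE)
  }
  if (anyNA(pairs$crude_p) || anyNA(pairs$eb_p)) {
    stop("missing partner version p-value", call. = FALSE)
  }
  thr <- significance_threshold(meff, alpha)
  keep <- pmin(pairs$crude_p, pairs$eb_p) < thr
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Compare crude and EB heritability per phenotype
#'
#' Assigns a winner per retained pair (`"eb"`, `"crude"`, or `"equal"` when
#' |crude h2 - EB h2| < `tie_tol`), stratifies items into empirical ICC
#' quartiles within each phenotype class, and summarises EB win rates
#' overall, by class and by quartile, plus the Pearson correlation of ICC
#' with crude heritability overall and by class.
#'
#' @param pairs retained pairs from [significance_filter()].
#' @param icc data frame with columns `item`, `icc`.
#' @param tie_tol tie tolerance on the heritability difference.
#' @return object of class `eb_benchmark`: list with `table` (per-item
#'   comparison), `win_rates` (overall/by class), `quartile_rates` (by
#'   class x ICC quartile), `icc_h2_cor` (overall and by class).
#' @export
compare_versions <- function(pairs, icc, tie_tol = 1e-6) {
  idx <- match(pairs$item, icc$item)
  if (anyNA(idx)) {
    stop(sprintf("icc missing for item(s): %s",
                 paste(utils::head(pairs$item[is.na(idx)], 5), collapse = ", ")),
         call. = FALSE)
  }
  tab <- pairs
  tab$icc <- icc$icc[idx]
  d <- tab$eb_h2 - tab$crude_h2
  tab$winner <- ifelse(abs(d) < tie_tol, "equal", ifelse(d > 0, "eb", "crude"))
  tab$icc_quartile <- rep(NA_integer_, nrow(tab))
  for (cl in unique(tab$class)) {
    i <- tab$class == cl
    if (sum(i) < 4L) {
      warning(sprintf("fewer than 4 items in class '%s'; quartiles skipped", cl))
      next
    }
    qs <- stats::quantile(tab$icc[i], c(0.25, 0.5, 0.75), names = FALSE)
    tab$icc_quartile[i] <- findInterval(tab$icc[i], qs, left.open = TRUE) + 1L
  }
  cls <- if (nrow(tab)) unique(tab$class) else character(0)
  win_rate <- function(w) if (length(w)) mean(w == "eb") else NA_real_
  rates <- data.frame(
    stratum = c("overall", if (length(cls)) paste0("class:", cls)),
    n = c(nrow(tab), vapply(cls, function(cl) sum(tab$class == cl), numeric(1))),
    eb_win_rate = c(win_rate(tab$winner),
                    vapply(cls, function(cl) win_rate(tab$winner[tab$class == cl]),
                           numeric(1))),
    stringsAsFactors = FALSE, row.names = NULL)
  qrates <- do.call(rbind, lapply(cls, function(cl) {
    i <- tab$class == cl & !is.na(tab$icc_quartile)
    if (!any(i)) return(NULL)
    do.call(rbind, lapply(1:4, function(qq) {
      j <- i & tab$icc_quartile == qq
      data.frame(class = cl, quartile = qq, n = sum(j),
                 eb_win_rate = win_rate(tab$winner[j]),
                 stringsAsFactors = FALSE)
    }))
  }))
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  cors <- c(overall = safe_cor(tab$icc, tab$crude_h2))
  for (cl in cls) {
    i <- tab$class == cl
    cors[paste0("class:", cl)] <- safe_cor(tab$icc[i], tab$crude_h2[i])
  }
  structure(list(table = tab, win_rates = rates, quartile_rates = qrates,
                 icc_h2_cor = cors),
            class = "eb_benchmark")
}

#' @export
print.eb_benchmark <- function(x, ...) {
  cat(sprintf("eb_benchmark: %d retained phenotype pairs\n", nrow(x$table)))
  cat("EB win rates:\n")
  print(x$win_rates, row.names = FALSE)
  if (!is.null(x$quartile_rates)) {
    cat("by ICC quartile:\n")
    print(x$quartile_rates, row.names = FALSE)
  }
  cat("ICC vs crude-h2 Pearson correlation:\n")
  print(round(x$icc_h2_cor, 3))
  invisible(x)
}

#' Diagnostic scatter plots for a benchmark
#'
#' Crude vs EB heritability (with the identity line) and ICC vs crude
#' heritability, coloured by winner.
#'
#' @param x `eb_benchmark`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.eb_benchmark <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cols <- c(crude = "#1b9e77", eb = "#d95f02", equal = "grey50")
  graphics::plot(tab$crude_h2, tab$eb_h2, col = cols[tab$winner], pch = 19,
                 xlab = "crude h2", ylab = "EB h2", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(tab$crude_h2, tab$icc, col = cols[tab$winner], pch = 19,
                 xlab = "crude h2", ylab = "ICC", ...)
  graphics::legend("bottomright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}

#' Greedy clumping of significant SNPs into independent loci
#'
#' Repeatedly takes the smallest-p SNP below `p_threshold` not yet absorbed
#' into a locus, emits it as a lead SNP, and absorbs all SNPs within
#' `window_bp` of it (radius) on the same chromosome. Ties are broken
#' deterministically by (p, chr, bp, SNP id). The output is invariant to
#' input row order.
#'
#' @param ss `sumstats` (or any data frame with SNP, CHR, BP, P).
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param window_bp window radius around each lead SNP (default 500 kb).
#' @param phenotype,version labels recorded on each locus.
#' @return data frame of loci: lead_snp, chr, bp, p, phenotype, version,
#'   window_start, window_end. Zero rows when nothing is significant.
#' @export
clump_loci <- function(ss, p_threshold = 5e-8, window_bp = 5e5,
                       phenotype = attr(ss, "phenotype"), version = NA_character_) {
  sig <- ss[ss$P < p_threshold, c("SNP", "CHR", "BP", "P"), drop = FALSE]
  empty <- data.frame(lead_snp = character(0), chr = character(0),
                      bp = integer(0), p = numeric(0),
                      phenotype = character(0), version = character(0),
                      window_start = numeric(0), window_end = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  sig <- sig[order(sig$P, sig$CHR, sig$BP, sig$SNP), , drop = FALSE]
  taken <- rep(FALSE, nrow(sig))
  out <- list()
  repeat {
    i <- which(!taken)
    if (!length(i)) break
    lead <- i[1]
    absorb <- !taken & sig$CHR == sig$CHR[lead] &
      abs(sig$BP - sig$BP[lead]) <= window_bp
    taken[absorb] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      lead_snp = sig$SNP[lead], chr = sig$CHR[lead], bp = sig$BP[lead],
      p = sig$P[lead],
      phenotype = if (is.null(phenotype)) NA_character_ else phenotype,
      version = version,
      window_start = sig$BP[lead] - window_bp,
      window_end = sig$BP[lead] + window_bp,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Locus-level concordance between crude and EB versions
#'
#' Collapses the loci of both versions of each phenotype into shared
#' windows (greedy, strongest lead first), compares the best lead p per
#' version within each window, and calls the window concordant iff the
#' smaller p belongs to the version with the higher heritability for that
#' phenotype. Also reports concordance within the top-25% and top-10%
#' strata of the absolute percent difference in heritability (symmetric
#' mean denominator).
#'
#' @param crude_loci,eb_loci locus data frames from [clump_loci()], with
#'   the `phenotype` column set.
#' @param h2_pairs data frame with columns `item`, `crude_h2`, `eb_h2`.
#' @param window_bp collapse radius (default 500 kb).
#' @return object of class `locus_concordance`: list with `windows` (one
#'   row per collapsed window), `n_windows`, `concordance` (overall
#'   fraction, NA-flagged as absent when no windows), `strata` (top-25% and
#'   top-10% fractions).
#' @export
locus_concordance <- function(crude_loci, eb_loci, h2_pairs, window_bp = 5e5) {
  if (nrow(crude_loci)) crude_loci$version <- "crude"
  if (nrow(eb_loci)) eb_loci$version <- "eb"
  all_loci <- rbind(crude_loci, eb_loci)
  empty <- structure(list(windows = NULL, n_windows = 0L,
                          concordance = NA_real_,
                          strata = c(top25 = NA_real_, top10 = NA_real_)),
                     class = "locus_concordance")
  if (nrow(all_loci) == 0L) return(empty)
  rows <- list()
  for (ph in unique(all_loci$phenotype)) {
    li <- all_loci[all_loci$phenotype == ph, , drop = FALSE]
    li <- li[order(li$p, li$chr, li$bp, li$lead_snp), , drop = FALSE]
    hp <- h2_pairs[h2_pairs$item == ph, , drop = FALSE]
    if (nrow(hp) != 1L) {
      stop(sprintf("need exactly one h2 pair for phenotype '%s'", ph), call. = FALSE)
    }
    taken <- rep(FALSE, nrow(li))
    repeat {
      i <- which(!taken)
      if (!length(i)) break
      lead <- i[1]
      inwin <- !taken & li$chr == li$chr[lead] &
        abs(li$bp - li$bp[lead]) <= window_bp
      taken[inwin] <- TRUE
      pc <- suppressWarnings(min(li$p[inwin & li$version == "crude"]))
      pe <- suppressWarnings(min(li$p[inwin & li$version == "eb"]))
      stronger <- if (pc < pe) "crude" else if (pe < pc) "eb" else "equal"
      higher_h2 <- if (hp$crude_h2 > hp$eb_h2) "crude" else
        if (hp$eb_h2 > hp$crude_h2) "eb" else "equal"
      pdiff <- 200 * abs(hp$crude_h2 - hp$eb_h2) /
        (abs(hp$crude_h2) + abs(hp$eb_h2))
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, chr = li$chr[lead], bp = li$bp[lead],
        lead_snp = li$lead_snp[lead], p_crude = pc, p_eb = pe,
        stronger = stronger, higher_h2 = higher_h2,
        concordant = stronger == higher_h2, h2_pct_diff = pdiff,
        stringsAsFactors = FALSE)
    }
  }
  win <- do.call(rbind, rows)
  conc <- mean(win$concordant)
  strata <- vapply(c(top25 = 0.75, top10 = 0.90), function(q) {
    cut <- stats::quantile(win$h2_pct_diff, q, names = FALSE)
    i <- win$h2_pct_diff >= cut
    if (any(i)) mean(win$concordant[i]) else NA_real_
  }, numeric(1))
  structure(list(windows = win, n_windows = nrow(win), concordance = conc,
                 strata = strata),
            class = "locus_concordance")
}

#' @export
print.locus_concordance <- function(x, ...) {
  if (x$n_windows == 0L) {
    cat("locus_concordance: no significant loci (concordance absent)\n")
    return(invisible(x))
  }
  cat(sprintf("locus_concordance: %d windows, %.1f%% concordant (top-25%%: %.1f%%, top-10%%: %.1f%%)\n",
              x$n_windows, 100 * x$concordance,
              100 * x$strata[["top25"]], 100 * x$strata[["top10"]]))
  invisible(x)
}
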