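# Crude and Empirical Bayes phenotype derivation: zero-one-inflated beta
# priors for consumption proportions (beta-binomial posterior mean) and
# Dirichlet-multinomial priors for portion-count averages.

#' Crude proportion and average for one individual
#'
#' The crude proportion is the number of questionnaires on which the item
#' was consumed over the number of questionnaires taken. The crude average
#' is the mean quantity over ALL questionnaires taken, counting 0 for
#' questionnaires without consumption.
#'
#' @param consumed 0/1 vector, one entry per questionnaire taken.
#' @param quantity optional numeric vector of quantities (0 when not
#'   consumed), same length.
#' @return list with `proportion` and (if quantities given) `average`,
#'   plus `s` (times consumed) and `k` (questionnaires taken).
#' @export
derive_crude <- function(consumed, quantity = NULL) {
  k <- length(consumed)
  if (k < 1L) stop("individual with zero questionnaires", call. = FALSE)
  s <- sum(consumed != 0)
  out <- list(proportion = s / k, s = s, k = k)
  if (!is.null(quantity)) {
    if (length(quantity) != k) stop("quantity/consumed length mismatch", call. = FALSE)
    out$average <- mean(quantity)
  }
  out
}

# ---- zero-one inflated beta prior ----------------------------------------

#' Fit a zero-one-inflated beta distribution to crude proportions
#'
#' The point masses at exactly 0 and 1 are estimated as empirical
#' fractions; (alpha, beta) is the maximum-likelihood beta fit to the
#' strictly interior values, initialised by method of moments and iterated
#' by Newton's method to gradient norm below 1e-8 (on the mean
#' log-likelihood scale). The inflation masses are reported but do not
#' enter the Empirical Bayes update, which consumes alpha and beta only.
#'
#' @param x proportions in `[0, 1]`.
#' @param min_interior minimum number of interior observations for the fit
#'   to be considered converged (default 50).
#' @param item optional item id recorded on the prior.
#' @return object of class `beta_prior` with fields `alpha`, `beta`, `p0`,
#'   `p1`, `converged`, `n_interior`, `mean_obs` (mean of all values, used
#'   for donor matching) and `donor_item` (NA unless substituted).
#' @export
fit_zoib <- function(x, min_interior = 50, item = NA_character_) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop("need at least one observation", call. = FALSE)
  if (any(x < 0 | x > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  p0 <- mean(x == 0); p1 <- mean(x == 1)
  xi <- x[x > 0 & x < 1]
  prior <- structure(list(alpha = NA_real_, beta = NA_real_, p0 = p0, p1 = p1,
                          converged = FALSE, n_interior = length(xi),
                          mean_obs = mean(x), donor_item = NA_character_,
                          item = item),
                     class = "beta_prior")
  if (length(xi) < 2L) return(prior)
  fit <- beta_mle(xi)
  prior$alpha <- fit$alpha; prior$beta <- fit$beta
  prior$converged <- fit$converged && length(xi) >= min_interior
  prior
}

# Newton-Raphson beta MLE from sufficient statistics.
beta_mle <- function(x, tol = 1e-8, maxit = 200) {
  mlx <- mean(log(x)); ml1x <- mean(log1p(-x))
  m <- mean(x); v <- stats::var(x)
  if (is.finite(v) && v > 0 && v < m * (1 - m)) {
    s0 <- m * (1 - m) / v - 1
    par <- c(m * s0, (1 - m) * s0)
  } else {
    par <- c(1, 1)
  }
  ll <- function(p) (p[1] - 1) * mlx + (p[2] - 1) * ml1x - lbeta(p[1], p[2])
  gr <- function(p) {
    d <- digamma(p[1] + p[2])
    c(mlx - digamma(p[1]) + d, ml1x - digamma(p[2]) + d)
  }
  conv <- FALSE
  for (it in seq_len(maxit)) {
    g <- gr(par)
    if (max(abs(g)) < tol) { conv <- TRUE; break }
    tab <- trigamma(par[1] + par[2])
    H <- matrix(c(tab - trigamma(par[1]), tab,
                  tab, tab - trigamma(par[2])), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    new <- par - step
    # damp steps that leave the parameter space or reduce the likelihood
    h <- 1
    while (h > 1e-10 && (any(new <= 0) || ll(new) < ll(par) - 1e-12)) {
      h <- h / 2
      new <- par - h * step
    }
    if (h <= 1e-10) break
    par <- new
  }
  list(alpha = par[1], beta = par[2], converged = conv && all(is.finite(par)))
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf(
    "beta_prior%s: alpha=%.4g beta=%.4g p0=%.3f p1=%.3f (n_interior=%d, %s%s)\n",
    if (is.na(x$item)) "" else sprintf(" [%s]", x$item),
    x$alpha, x$beta, x$p0, x$p1, x$n_interior,
    if (x$converged) "converged" else "NOT converged",
    if (is.na(x$donor_item)) "" else sprintf(", donor=%s", x$donor_item)))
  invisible(x)
}

#' @export
coef.beta_prior <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' Empirical Bayes proportion (beta-binomial posterior mean)
#'
#' Returns (s + alpha) / (k + alpha + beta): the posterior mean consumption
#' probability under a Beta(alpha, beta) prior after observing s
#' consumptions in k questionnaires. Equals the convex combination
#' w * (s/k) + (1 - w) * alpha/(alpha + beta) with w = k/(k + alpha + beta),
#' so the update always lies between the crude proportion and the prior
#' mean, with shrinkage vanishing as k grows.
#'
#' @param s number of questionnaires with consumption (vectorised).
#' @param k number of questionnaires taken (vectorised).
#' @param prior `beta_prior` (must be converged or donor-substituted).
#' @return numeric vector of EB proportions.
#' @export
eb_proportion <- function(s, k, prior) {
  if (!inherits(prior, "beta_prior")) stop("`prior` must be a beta_prior", call. = FALSE)
  if (!prior$converged) {
    stop("prior did not converge; substitute a donor first", call. = FALSE)
  }
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  if (any(s < 0) || any(s > k)) stop("need 0 <= s <= k", call. = FALSE)
  (s + prior$alpha) / (k + prior$alpha + prior$beta)
}

#' @export
predict.beta_prior <- function(object, s, k, ...) eb_proportion(s, k, object)

# ---- Dirichlet-multinomial prior -----------------------------------------

#' Fit a Dirichlet-multinomial prior to per-individual category counts
#'
#' Maximum-likelihood concentration parameters via the standard fixed-point
#' iteration, moment-matched initialisation, run until the change in
#' log-likelihood falls below `tol`. Rows are individuals; columns are the
#' possible response categories (e.g. portion counts 0, 1, 2, ...); each
#' row sums to that individual's number of questionnaires.
#'
#' @param counts integer matrix (individuals x categories).
#' @param values numeric category values (strictly increasing), defaults to
#'   numeric column names of `counts`.
#' @param tol convergence tolerance on successive log-likelihood (1e-8).
#' @param maxit maximum fixed-point iterations.
#' @param item optional item id recorded on the prior.
#' @return object of class `dm_prior` with fields `category_values`,
#'   `alpha` (concentration vector), `alpha_sum`, `converged`, `loglik`,
#'   `iterations`, `mean_obs` (observed mean value, used for donor
#'   matching), `donor_item`.
#' @export
fit_dirichlet_multinomial <- function(counts, values = NULL, tol = 1e-8,
                                      maxit = 50000, item = NA_character_) {
  counts <- as.matrix(counts)
  if (is.null(values)) {
    values <- suppressWarnings(as.numeric(colnames(counts)))
    if (anyNA(values)) stop("supply `values` or numeric column names", call. = FALSE)
  }
  if (length(values) != ncol(counts)) stop("values/column mismatch", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE)) {
    stop("`values` must be strictly increasing", call. = FALSE)
  }
  k <- rowSums(counts)
  counts <- counts[k >= 1, , drop = FALSE]
  k <- k[k >= 1]
  n <- nrow(counts)
  if (n < 1L) stop("no rows with at least one questionnaire", call. = FALSE)
  tot <- colSums(counts)
  mean_obs <- sum(values * tot) / sum(tot)
  prior <- structure(list(category_values = values, alpha = rep(NA_real_, length(values)),
                          alpha_sum = NA_real_, converged = FALSE,
                          loglik = NA_real_, iterations = 0L,
                          mean_obs = mean_obs, donor_item = NA_character_,
                          item = item),
                     class = "dm_prior")
  if (sum(tot > 0) < 2L) return(prior)  # single occupied category: no fit

  kmax <- max(k)
  # sufficient statistics: cnt_ct[t+1, c] = #rows with count t in category c;
  # kcnt[t] = #rows with row sum t
  cnt_ct <- vapply(seq_len(ncol(counts)),
                   function(c) tabulate(counts[, c] + 1L, nbins = kmax + 1L),
                   integer(kmax + 1L))
  kcnt <- tabulate(k, nbins = kmax)
  tvals <- 0:kmax

  loglik <- function(a) {
    A <- sum(a)
    llk <- sum(kcnt * (lgamma(A) - lgamma(seq_len(kmax) + A)))
    llc <- sum(vapply(seq_along(a), function(c)
      sum(cnt_ct[, c] * (lgamma(tvals + a[c]) - lgamma(a[c]))), numeric(1)))
    llk + llc
  }

  # moment-matched init: within-row category match rate determines the
  # overdispersion 1/(1 + alpha_sum)
  p <- tot / sum(tot)
  pairs <- sum(k * (k - 1))
  if (pairs > 0) {
    W <- sum(counts * (counts - 1)) / pairs
    sp2 <- sum(p^2)
    A0 <- if (W > sp2 + 1e-12 && W < 1) (1 - W) / (W - sp2) else 50
  } else {
    A0 <- 50
  }
  A0 <- min(max(A0, 0.05), 1e4)
  a <- pmax(p, 1e-6) * A0

  ll_old <- loglik(a)
  conv <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    A <- sum(a)
    den <- sum(kcnt * (digamma(seq_len(kmax) + A) - digamma(A)))
    num <- vapply(seq_along(a), function(c)
      sum(cnt_ct[, c] * (digamma(tvals + a[c]) - digamma(a[c]))), numeric(1))
    a_new <- a * num / den
    a_new[!is.finite(a_new) | a_new <= 0] <- 1e-10
    ll_new <- loglik(a_new)
    a <- a_new
    if (is.finite(ll_new) && abs(ll_new - ll_old) < tol) {
      ll_old <- ll_new; conv <- TRUE; break
    }
    ll_old <- ll_new
  }
  prior$alpha <- a
  prior$alpha_sum <- sum(a)
  prior$converged <- conv && all(is.finite(a)) && all(a > 0)
  prior$loglik <- ll_old
  prior$iterations <- it
  prior
}

#' @export
print.dm_prior <- function(x, ...) {
  cat(sprintf("dm_prior%s: %d categories, alpha_sum=%.4g (%s%s)\n",
              if (is.na(x$item)) "" else sprintf(" [%s]", x$item),
              length(x$category_values), x$alpha_sum,
              if (x$converged) "converged" else "NOT converged",
              if (is.na(x$donor_item)) "" else sprintf(", donor=%s", x$donor_item)))
  if (x$converged) {
    print(stats::setNames(round(x$alpha, 4), x$category_values))
  }
  invisible(x)
}

#' @export
coef.dm_prior <- function(object, ...) {
  stats::setNames(object$alpha, object$category_values)
}

#' Empirical Bayes average (Dirichlet-multinomial posterior mean)
#'
#' Returns sum_c value_c * (count_c + alpha_c) / (k + alpha_sum): each
#' response category's posterior weight times its value, summed over the
#' total number of questionnaires plus the sum of the alpha estimates.
#' Equals the convex combination of the crude average (weight
#' k/(k + alpha_sum)) and the prior mean value.
#'
#' @param counts integer vector (one individual) or matrix (individuals x
#'   categories) of per-category response counts.
#' @param k questionnaires taken (row sums of `counts`).
#' @param prior `dm_prior`.
#' @return numeric EB average(s).
#' @export
eb_average <- function(counts, k, prior) {
  if (!inherits(prior, "dm_prior")) stop("`prior` must be a dm_prior", call. = FALSE)
  if (!prior$converged) {
    stop("prior did not converge; substitute a donor first", call. = FALSE)
  }
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (ncol(counts) != length(prior$alpha)) {
    stop("count/category length mismatch", call. = FALSE)
  }
  if (any(abs(rowSums(counts) - k) > 1e-9)) {
    stop("row sums of `counts` must equal `k`", call. = FALSE)
  }
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  num <- sweep(counts, 2, prior$alpha, "+") %*% prior$category_values
  drop(num) / (k + prior$alpha_sum)
}

#' @export
predict.dm_prior <- function(object, counts, k, ...) eb_average(counts, k, object)

# ---- donor substitution ---------------------------------------------------

# Replace non-converged priors by the configured donor, or by the converged
# prior with the most similar observed mean. Hard error when nothing is
# available.
substitute_donors <- function(priors, donor_map = NULL) {
  conv <- vapply(priors, function(p) isTRUE(p$converged), logical(1))
  if (all(conv)) return(priors)
  if (!any(conv)) stop("no converged prior available as donor", call. = FALSE)
  means <- vapply(priors, function(p) p$mean_obs, numeric(1))
  for (nm in names(priors)[!conv]) {
    donor <- donor_map[[nm]]
    if (is.null(donor)) {
      cand <- names(priors)[conv]
      donor <- cand[which.min(abs(means[cand] - means[nm]))]
    }
    if (!donor %in% names(priors) || !isTRUE(priors[[donor]]$converged)) {
      stop(sprintf("no converged donor for item '%s'", nm), call. = FALSE)
    }
    dp <- priors[[donor]]
    p <- priors[[nm]]
    if (inherits(p, "beta_prior")) {
      p$alpha <- dp$alpha; p$beta <- dp$beta
    } else {
      # map donor concentrations onto the recipient's category grid by
      # value (exact copy when the grids coincide)
      p$alpha <- stats::approx(dp$category_values, dp$alpha,
                               xout = p$category_values, rule = 2)$y
      p$alpha_sum <- sum(p$alpha)
    }
    p$converged <- TRUE
    p$donor_item <- donor
    priors[[nm]] <- p
  }
  priors
}

# ---- phenotype table ------------------------------------------------------

#' Build the per-individual crude and EB phenotype table
#'
#' For every item, derives a crude and an EB proportion; for every
#' quantity/continuous item additionally a crude and an EB average, giving
#' `2 * n_items + 2 * n_continuous` phenotype columns. Priors are fitted
#' from the data unless supplied; non-converged priors are substituted by
#' donors (configured or nearest observed mean).
#'
#' @param q filtered questionnaire data frame with one indicator column per
#'   item id and a `<id>_qty` column per quantity item.
#' @param items data frame with columns `id` and `kind` (`"binary"` or
#'   `"quantity"`/`"continuous"`), e.g. from [dietary_items()].
#' @param min_interior minimum interior observations for prior convergence.
#' @param donor_map named list mapping non-converging item ids to donor
#'   item ids.
#' @param precision digits for rounding quantity values into response
#'   categories (default 0: integer grid).
#' @return object of class `phenotype_table`: list with `phenotypes` (data
#'   frame: id, k, phenotype columns), `beta_priors`, `dm_priors`, `items`.
#' @export
build_phenotype_table <- function(q, items, min_interior = 50,
                                  donor_map = NULL, precision = 0) {
  if (nrow(items) == 0L) stop("empty item inventory", call. = FALSE)
  kind <- ifelse(items$kind == "continuous", "quantity", items$kind)
  if (!all(kind %in% c("binary", "quantity"))) {
    stop("item kinds must be binary or quantity/continuous", call. = FALSE)
  }
  ids <- unique(q$id)
  k <- as.integer(table(factor(q$id, levels = ids)))
  names(k) <- ids
  idf <- factor(q$id, levels = ids)

  pheno <- data.frame(id = ids, k = k, stringsAsFactors = FALSE,
                      row.names = NULL)
  beta_priors <- list()
  dm_priors <- list()

  # consumption counts for every item
  for (j in seq_along(items$id)) {
    it <- items$id[j]
    if (!it %in% names(q)) stop(sprintf("missing item column '%s'", it), call. = FALSE)
    s <- as.vector(rowsum(as.numeric(q[[it]] != 0), idf))
    pheno[[paste0(it, "_crude_prop")]] <- s / k
    attr(pheno, "s")[[it]] <- s
  }
  # fit zero-one-inflated beta priors on the crude proportions
  for (it in items$id) {
    beta_priors[[it]] <- fit_zoib(pheno[[paste0(it, "_crude_prop")]],
                                  min_interior = min_interior, item = it)
  }
  beta_priors <- substitute_donors(beta_priors, donor_map)
  for (j in seq_along(items$id)) {
    it <- items$id[j]
    s <- attr(pheno, "s")[[it]]
    pheno[[paste0(it, "_eb_prop")]] <- eb_proportion(s, k, beta_priors[[it]])
  }

  # quantity items: category counts, crude and EB averages
  for (j in which(kind == "quantity")) {
    it <- items$id[j]
    qcol <- paste0(it, "_qty")
    if (!qcol %in% names(q)) stop(sprintf("missing quantity column '%s'", qcol), call. = FALSE)
    v <- round(as.numeric(q[[qcol]]), precision)
    vals <- sort(unique(v))
    cnt <- t(vapply(split(v, idf),
                    function(x) tabulate(match(x, vals), nbins = length(vals)),
                    integer(length(vals))))
    colnames(cnt) <- as.character(vals)
    pheno[[paste0(it, "_crude_avg")]] <- as.vector(cnt %*% vals) / k
    dm_priors[[it]] <- fit_dirichlet_multinomial(cnt, values = vals, item = it)
    attr(pheno, "counts")[[it]] <- cnt
  }
  if (length(dm_priors)) {
    dm_priors <- substitute_donors(dm_priors, donor_map)
    for (it in names(dm_priors)) {
      cnt <- attr(pheno, "counts")[[it]]
      pheno[[paste0(it, "_eb_avg")]] <- eb_average(cnt, k, dm_priors[[it]])
    }
  }
  attr(pheno, "s") <- NULL
  attr(pheno, "counts") <- NULL
  structure(list(phenotypes = pheno, beta_priors = beta_priors,
                 dm_priors = dm_priors,
                 items = data.frame(id = items$id, kind = kind,
                                    stringsAsFactors = FALSE)),
            class = "phenotype_table")
}

#' Phenotype column names of a phenotype table
#' @param pt `phenotype_table`.
#' @return character vector of derived phenotype column names (excludes the
#'   `id` and `k` bookkeeping columns).
#' @export
phenotype_columns <- function(pt) {
  setdiff(names(pt$phenotypes), c("id", "k"))
}

#' @export
print.phenotype_table <- function(x, ...) {
  nb <- sum(x$items$kind == "binary"); nq <- sum(x$items$kind == "quantity")
  cat(sprintf(
    "phenotype_table: %d individuals, %d items (%d binary, %d quantity), %d phenotype columns\n",
    nrow(x$phenotypes), nrow(x$items), nb, nq, length(phenotype_columns(x))))
  invisible(x)
}

#' Write fitted priors as TSV
#'
#' @param pt `phenotype_table`.
#' @param prefix path prefix; writes `<prefix>_beta_priors.tsv` and (when
#'   quantity items exist) `<prefix>_dm_priors.tsv`.
#' @return written paths, invisibly.
#' @export
write_priors <- function(pt, prefix) {
  bp <- do.call(rbind, lapply(names(pt$beta_priors), function(nm) {
    p <- pt$beta_priors[[nm]]
    data.frame(item = nm, alpha = p$alpha, beta = p$beta, p0 = p$p0, p1 = p$p1,
               converged = p$converged, donor = p$donor_item,
               stringsAsFactors = FALSE)
  }))
  paths <- paste0(prefix, "_beta_priors.tsv")
  write_tsv(bp, paths)
  if (length(pt$dm_priors)) {
    dm <- do.call(rbind, lapply(names(pt$dm_priors), function(nm) {
      p <- pt$dm_priors[[nm]]
      data.frame(item = nm, value = p$category_values, alpha = p$alpha,
                 stringsAsFactors = FALSE)
    }))
    p2 <- paste0(prefix, "_dm_priors.tsv")
    write_tsv(dm, p2)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
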