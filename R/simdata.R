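# Synthetic cohort generator: genotypes with LD, heritable latent dietary
# traits, and repeated 24-hour-recall style questionnaires with controllable
# questionnaire-to-questionnaire reliability (one-way ICC).

#' Completion counts for one to five questionnaires
#'
#' Number of individuals completing exactly 1, 2, 3, 4 and 5 repeated
#' 24-hour recall questionnaires in the cohort the generator emulates.
#' Used (proportionally) as the default distribution of questionnaires
#' per person.
#'
#' @format Named integer vector of length 5 (names `"1"`..`"5"`).
#' @export
completion_counts <- c(`1` = 81081L, `2` = 46893L, `3` = 31818L,
                       `4` = 15000L, `5` = 2066L)

#' Summarise a completion-count configuration
#'
#' Given per-count completion numbers (individuals completing exactly
#' 1..5 questionnaires), returns the total cohort size, the number of
#' individuals with at least two questionnaires, and their percentage share.
#'
#' @param counts numeric vector of length 5; counts for k = 1..5.
#' @return list with `total`, `repeat_total` (k >= 2), and
#'   `repeat_pct` (percentage of `total`).
#' @export
completion_summary <- function(counts = completion_counts) {
  if (length(counts) != 5L || any(counts < 0)) {
    stop("`counts` must be 5 non-negative numbers (k = 1..5)", call. = FALSE)
  }
  total <- sum(counts)
  rep2 <- sum(counts[2:5])
  list(total = total, repeat_total = rep2, repeat_pct = 100 * rep2 / total)
}

#' Simulate additive genotype dosages with autoregressive LD
#'
#' Draws two latent haplotypes per individual from a first-order
#' autoregressive Gaussian process along the (single, synthetic) chromosome
#' with adjacent-site correlation `ld_rho`, dichotomises each site at the
#' quantile of its drawn allele frequency, and sums the two haplotypes to an
#' additive dosage in \{0, 1, 2\}. Because sites are dichotomised at
#' different allele-frequency quantiles, realised pairwise LD (and hence the
#' LD score profile) varies along the chromosome even though the latent
#' field has constant correlation.
#'
#' The latent field is piecewise: recombination hotspots occur at each
#' inter-SNP gap with probability `recomb_prob`, and the haplotype
#' correlation across a hotspot gap is zero. This yields LD blocks of
#' geometric length and, together with the allele-frequency heterogeneity,
#' an LD-score profile that varies along the chromosome as in real
#' genotype data (without it, every SNP would carry the same LD score and
#' LD-score-based heritability regression would be unidentifiable).
#'
#' SNP positions are laid out at a fixed 1 kb spacing, 1-based.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param n_snps number of SNPs (>= 1).
#' @param maf_range length-2 interval in (0, 0.5] from which per-SNP allele
#'   frequencies are drawn uniformly.
#' @param ld_rho adjacent-site haplotype correlation in `[0, 1)` within an
#'   LD block.
#' @param recomb_prob per-gap probability of a recombination hotspot
#'   (independent blocks); 0 recovers a homogeneous AR(1) field.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return object of class `genotype_matrix`: list with `dosages`
#'   (individuals x SNPs integer matrix), `map` (data frame: snp, chr, bp,
#'   a1, a2, freq) and `individuals` (character IDs).
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5),
                               ld_rho = 0.9, recomb_prob = 0.10, seed = 1L) {
  if (n_individuals < 2) stop("`n_individuals` must be >= 2", call. = FALSE)
  if (n_snps < 1) stop("`n_snps` must be >= 1", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("`maf_range` must be an interval within (0, 0.5]", call. = FALSE)
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("`ld_rho` must be in [0, 1)", call. = FALSE)

  with_seed(seed, {
    n <- as.integer(n_individuals); m <- as.integer(n_snps)
    freq <- stats::runif(m, maf_range[1], maf_range[2])
    thr <- stats::qnorm(freq)
    # per-gap haplotype correlation: ld_rho within a block, 0 at hotspots
    rho_gap <- if (m > 1) {
      ifelse(stats::runif(m - 1) < recomb_prob, 0, ld_rho)
    } else {
      numeric(0)
    }
    hap <- function() {
      z <- matrix(0, n, m)
      z[, 1] <- stats::rnorm(n)
      if (m > 1) {
        s <- sqrt(1 - rho_gap^2)
        for (j in 2:m) {
          z[, j] <- rho_gap[j - 1] * z[, j - 1] + s[j - 1] * stats::rnorm(n)
        }
      }
      # allele carried where the latent value falls below the freq quantile
      sweep(z, 2, thr, "<") * 1L
    }
    dos <- hap() + hap()
    storage.mode(dos) <- "integer"
    ids <- sprintf("ind%05d", seq_len(n))
    snps <- sprintf("snp%05d", seq_len(m))
    dimnames(dos) <- list(ids, snps)
    map <- data.frame(snp = snps, chr = "1", bp = 1000L * seq_len(m),
                      a1 = "A", a2 = "G", freq = freq,
                      stringsAsFactors = FALSE)
    structure(list(dosages = dos, map = map, individuals = ids),
              class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (chr %s, %d-%d bp)\n",
              nrow(x$dosages), ncol(x$dosages), x$map$chr[1],
              min(x$map$bp), max(x$map$bp)))
  invisible(x)
}

# Column-standardised dosage matrix (empirical mean/sd).
standardize_dosages <- function(g) {
  d <- g$dosages
  mu <- colMeans(d)
  sd <- apply(d, 2, stats::sd)
  if (any(sd == 0)) stop("zero-variance SNP in genotype matrix", call. = FALSE)
  scale(d, center = mu, scale = sd)
}

#' Define the dietary item inventory of a trait model
#'
#' Each item is either `binary` (yes/no consumption) or `quantity`
#' (consumption plus a portion count on an integer grid, e.g. cups).
#'
#' @param id character item identifiers.
#' @param kind `"binary"` or `"quantity"` per item.
#' @param mu baseline consumption log-odds per item.
#' @param icc target one-way ICC of the raw item in `[0, 1]`.
#' @param h2 liability heritability of the item's latent trait in `[0, 1]`.
#' @param qmax maximum portion count for quantity items (integer grid
#'   0..qmax; 0 means not consumed).
#' @param log_rate baseline log portion rate for quantity items.
#' @param noise_frac fraction of the person-level effect that is independent
#'   person noise rather than the heritable liability (keeps person-level
#'   heritability below the liability heritability).
#' @return data frame of item definitions.
#' @export
dietary_items <- function(id, kind, mu, icc, h2,
                          qmax = 10L, log_rate = log(2), noise_frac = 0.2) {
  kind <- rep_len(kind, length(id))
  stopifnot(all(kind %in% c("binary", "quantity")))
  if (any(icc < 0 | icc > 1)) stop("`icc` targets must be in [0,1]", call. = FALSE)
  if (any(h2 < 0 | h2 > 1)) stop("`h2` targets must be in [0,1]", call. = FALSE)
  data.frame(id = as.character(id), kind = kind,
             mu = rep_len(mu, length(id)), icc = rep_len(icc, length(id)),
             h2 = rep_len(h2, length(id)), qmax = rep_len(as.integer(qmax), length(id)),
             log_rate = rep_len(log_rate, length(id)),
             noise_frac = rep_len(noise_frac, length(id)),
             stringsAsFactors = FALSE)
}

#' A small example item inventory
#'
#' Two habitual beverage-style items (high reliability, one with portion
#' counts) and two episodic food-style items (low reliability).
#'
#' @return item definition data frame (see [dietary_items()]).
#' @export
example_items <- function() {
  dietary_items(
    id   = c("coffee", "coffee_cups", "chocolate", "snack_portions"),
    kind = c("binary", "quantity", "binary", "quantity"),
    mu   = c(qlogis(0.75), qlogis(0.75), qlogis(0.30), qlogis(0.30)),
    icc  = c(0.75, 0.60, 0.20, 0.15),
    h2   = c(0.50, 0.50, 0.50, 0.50)
  )
}

#' Item inventory spanning a reliability gradient
#'
#' Builds a set of binary consumption items split into a low-reliability
#' (episodic, lower baseline consumption) and a high-reliability (habitual,
#' higher baseline consumption) group, for benchmarking shrinkage against
#' crude derivations across the ICC spectrum.
#'
#' @param n_low,n_high number of items in each group.
#' @param icc_low,icc_high length-2 ICC ranges for the two groups (targets
#'   are equally spaced within each range).
#' @param h2 liability heritability shared by all items.
#' @param mu_low,mu_high baseline consumption log-odds for the two groups.
#' @return item definition data frame.
#' @export
reliability_gradient_items <- function(n_low = 20, n_high = 20,
                                       icc_low = c(0.15, 0.30),
                                       icc_high = c(0.85, 0.95),
                                       h2 = 0.6,
                                       mu_low = qlogis(0.30),
                                       mu_high = qlogis(0.75)) {
  dietary_items(
    id   = c(sprintf("episodic%02d", seq_len(n_low)),
             sprintf("habitual%02d", seq_len(n_high))),
    kind = "binary",
    mu   = c(rep(mu_low, n_low), rep(mu_high, n_high)),
    icc  = c(seq(icc_low[1], icc_low[2], length.out = n_low),
             seq(icc_high[1], icc_high[2], length.out = n_high)),
    h2   = h2
  )
}

#' Construct a trait model
#'
#' Bundles the item inventory with the genetic architecture used by
#' [simulate_latent_traits()] and [simulate_questionnaires()].
#'
#' @param items item definition data frame from [dietary_items()].
#' @param n_causal number of causal SNPs per item (defaults to all SNPs,
#'   i.e. a dense architecture).
#' @param seed integer seed for causal-weight draws and questionnaire noise.
#' @return object of class `trait_model`.
#' @export
trait_model <- function(items, n_causal = NULL, seed = 1L) {
  needed <- c("id", "kind", "mu", "icc", "h2", "qmax", "log_rate", "noise_frac")
  if (!all(needed %in% names(items))) {
    stop("`items` must come from dietary_items()", call. = FALSE)
  }
  structure(list(items = items, n_causal = n_causal, seed = as.integer(seed)),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("trait_model: %d items (%d binary, %d quantity), seed %d\n",
              nrow(x$items), sum(x$items$kind == "binary"),
              sum(x$items$kind == "quantity"), x$seed))
  invisible(x)
}

#' Simulate heritable latent liabilities per item
#'
#' For each item, draws normal effect weights on `n_causal` SNPs and forms
#' the liability L = genetic value + environmental residual. The genetic
#' component is rescaled to have sample variance exactly `h2` and the
#' residual, orthogonalised against it, to `1 - h2`, so the realised
#' in-sample heritability of each liability equals its target.
#'
#' @param g `genotype_matrix` from [simulate_genotypes()].
#' @param model `trait_model`.
#' @return object of class `latent_traits`: list with `liability` and
#'   `genetic` (individuals x items matrices), `h2` (targets), `causal`
#'   (list of causal SNP ids per item).
#' @export
simulate_latent_traits <- function(g, model) {
  items <- model$items
  m <- ncol(g$dosages); n <- nrow(g$dosages)
  n_causal <- if (is.null(model$n_causal)) m else as.integer(model$n_causal)
  if (n_causal > m) stop("`n_causal` must be <= number of SNPs", call. = FALSE)
  if (any(items$h2 > 1)) stop("h2 targets must be <= 1", call. = FALSE)
  z <- standardize_dosages(g)
  with_seed(derive_seed(model$seed, "latent"), {
    L <- G <- matrix(0, n, nrow(items),
                     dimnames = list(g$individuals, items$id))
    causal <- vector("list", nrow(items)); names(causal) <- items$id
    for (j in seq_len(nrow(items))) {
      h2 <- items$h2[j]
      idx <- sort(sample.int(m, n_causal))
      causal[[j]] <- colnames(z)[idx]
      w <- stats::rnorm(n_causal)
      gv <- drop(z[, idx, drop = FALSE] %*% w)
      e <- stats::rnorm(n)
      if (h2 > 0) {
        gv <- gv - mean(gv)
        gv <- gv * sqrt(h2) / stats::sd(gv)
      } else {
        gv <- rep(0, n)
      }
      if (h2 < 1) {
        e <- e - mean(e)
        if (h2 > 0) e <- e - gv * sum(e * gv) / sum(gv^2)
        e <- e * sqrt(1 - h2) / stats::sd(e)
      } else {
        e <- rep(0, n)
      }
      G[, j] <- gv
      L[, j] <- gv + e
    }
    structure(list(liability = L, genetic = G, h2 = items$h2, causal = causal),
              class = "latent_traits")
  })
}

# ---- ICC calibration ------------------------------------------------------

# Deterministic standard-normal grid used for expected-ICC integrals.
.icc_grid <- function(n = 2001L) stats::qnorm(stats::ppoints(n))

# Moments of a Poisson truncated to 1..qmax.
trunc_pois_moments <- function(lambda, qmax) {
  q <- seq_len(qmax)
  pm <- outer(lambda, q, function(l, k) stats::dpois(k, l))
  tot <- rowSums(pm)
  tot[tot <= 0] <- NA  # degenerate lambda ~ 0; handled by caller
  m1 <- rowSums(sweep(pm, 2, q, "*")) / tot
  m2 <- rowSums(sweep(pm, 2, q^2, "*")) / tot
  m1[is.na(m1)] <- 1; m2[is.na(m2)] <- 1  # lambda -> 0 mass concentrates at 1
  list(m1 = m1, m2 = m2)
}

# Expected one-way ICC of a raw item at person-effect multiplier t,
# integrating over a standard-normal person latent.
expected_item_icc <- function(item, t, grid = .icc_grid()) {
  p <- stats::plogis(item$mu + t * grid)
  if (item$kind == "binary") {
    between <- mean((p - mean(p))^2)
    within <- mean(p * (1 - p))
  } else {
    lam <- exp(item$log_rate + 0.5 * t * grid)
    mom <- trunc_pois_moments(lam, item$qmax)
    e1 <- p * mom$m1
    e2 <- p * mom$m2
    between <- mean((e1 - mean(e1))^2)
    within <- mean(e2 - e1^2)
  }
  between / (between + within)
}

# Solve for the person-effect multiplier that yields the target ICC
# (1-D search; expected ICC within 0.01 of target, or error).
calibrate_item <- function(item, t_max = 60) {
  target <- item$icc
  if (target >= 0.999) return(list(t = Inf, deterministic = TRUE))
  if (target <= 1e-8) return(list(t = 0, deterministic = FALSE))
  f <- function(t) expected_item_icc(item, t) - target
  if (f(t_max) < 0) {
    stop(sprintf("icc target %.3f unattainable for item '%s'", target, item$id),
         call. = FALSE)
  }
  t <- stats::uniroot(f, c(1e-6, t_max), tol = 1e-6)$root
  if (abs(expected_item_icc(item, t) - target) > 0.01) {
    stop(sprintf("icc calibration failed for item '%s'", item$id), call. = FALSE)
  }
  list(t = t, deterministic = FALSE)
}

# ---- questionnaire simulation --------------------------------------------

#' Simulate repeated 24-hour-recall questionnaires
#'
#' Per individual, the number of questionnaires k is drawn from
#' `k_weights` (default proportional to [completion_counts]). For each item
#' a person-level effect (a mixture of the item's heritable liability and
#' independent person noise) sets the day-level consumption probability via
#' a logistic model; quantity items additionally draw a portion count from
#' a truncated Poisson on 1..qmax with a log-linear person rate. The
#' person-effect scale is calibrated numerically per item so the expected
#' one-way ICC of the raw item equals its target. A configurable fraction
#' of records violates each quality-control rule to exercise the filters.
#'
#' @param latents `latent_traits` from [simulate_latent_traits()].
#' @param model `trait_model` (same one used for the latents).
#' @param k_weights positive weights over 1..5 questionnaires per person.
#' @param seed integer seed.
#' @param qc_violation_rate per-rule probability that a record is made to
#'   violate that QC rule.
#' @return list with `questionnaires` (long-format data frame: one row per
#'   individual x questionnaire, QC fields plus one indicator column per
#'   item and one `<item>_qty` column per quantity item), `k` (named vector
#'   of questionnaire counts) and `calibration` (per-item person-effect
#'   multipliers).
#' @export
simulate_questionnaires <- function(latents, model, k_weights = NULL,
                                    seed = 1L, qc_violation_rate = 0.02) {
  items <- model$items
  if (nrow(items) == 0L) stop("trait model has zero items", call. = FALSE)
  if (is.null(k_weights)) k_weights <- as.numeric(completion_counts)
  if (length(k_weights) != 5L || any(k_weights < 0) || sum(k_weights) <= 0) {
    stop("`k_weights` must be 5 non-negative weights with positive sum",
         call. = FALSE)
  }
  n <- nrow(latents$liability)
  ids <- rownames(latents$liability)
  calib <- lapply(seq_len(nrow(items)), function(j) calibrate_item(items[j, ]))
  names(calib) <- items$id

  with_seed(derive_seed(seed, "questionnaires"), {
    k <- sample.int(5L, n, replace = TRUE, prob = k_weights / sum(k_weights))
    names(k) <- ids
    row_id <- rep(seq_len(n), k)
    q_idx <- sequence(k)
    nr <- length(row_id)

    # person-level latent per item: mixture of liability and person noise
    eta <- matrix(0, n, nrow(items))
    for (j in seq_len(nrow(items))) {
      vu <- items$noise_frac[j]
      eta[, j] <- sqrt(1 - vu) * latents$liability[, items$id[j]] +
        sqrt(vu) * stats::rnorm(n)
    }

    qt <- data.frame(id = ids[row_id], q = q_idx, stringsAsFactors = FALSE)
    # questionnaire-level administrative fields
    qt$energy_kj <- pmin(pmax(stats::rlnorm(nr, log(8000), 0.22), 1100), 17500)
    qt$typical_diet <- 1L
    qt$completed <- 1L
    qt$duration_min <- pmin(pmax(stats::rlnorm(nr, log(12), 0.35), 5.5), 90)
    qt$hour <- sample(6:23, nr, replace = TRUE)
    qt$weekend <- stats::rbinom(nr, 1L, 3 / 7)
    qt$pregnant_yr <- 0L
    qt$cancer_yr <- 0L

    # inject QC violations, one independent draw per rule
    viol <- function() stats::runif(nr) < qc_violation_rate
    i <- viol(); qt$energy_kj[i] <- stats::runif(sum(i), 200, 995)
    i <- viol(); qt$energy_kj[i] <- stats::runif(sum(i), 20500, 23000)
    i <- viol(); qt$typical_diet[i] <- 0L
    i <- viol(); qt$duration_min[i] <- stats::runif(sum(i), 0.5, 4.5)
    i <- viol(); qt$completed[i] <- 0L
    i <- viol(); qt$pregnant_yr[i] <- 1L
    i <- viol(); qt$cancer_yr[i] <- 1L

    for (j in seq_len(nrow(items))) {
      it <- items[j, ]
      cj <- calib[[j]]
      e_row <- eta[row_id, j]
      if (is.infinite(cj$t)) {
        # fully reliable item: responses are a deterministic function of the
        # person effect, so repeats within a person are identical
        cons <- as.integer(it$mu + e_row > 0)
        if (it$kind == "quantity") {
          qv <- pmin(it$qmax, 1L + floor(stats::pnorm(e_row) * it$qmax))
          qt[[paste0(it$id, "_qty")]] <- ifelse(cons == 1L, qv, 0L)
        }
        qt[[it$id]] <- cons
      } else {
        p <- stats::plogis(it$mu + cj$t * e_row)
        cons <- stats::rbinom(nr, 1L, p)
        if (it$kind == "quantity") {
          lam <- exp(it$log_rate + 0.5 * cj$t * e_row)
          qv <- sample_trunc_pois(lam, it$qmax)
          qt[[paste0(it$id, "_qty")]] <- ifelse(cons == 1L, qv, 0L)
        }
        qt[[it$id]] <- cons
      }
    }
    # column order: admin fields, then per-item indicator (+ quantity)
    admin <- c("id", "q", "energy_kj", "typical_diet", "completed",
               "duration_min", "hour", "weekend", "pregnant_yr", "cancer_yr")
    icols <- unlist(lapply(seq_len(nrow(items)), function(j) {
      if (items$kind[j] == "quantity") c(items$id[j], paste0(items$id[j], "_qty"))
      else items$id[j]
    }))
    qt <- qt[, c(admin, icols)]
    list(questionnaires = qt, k = k,
         calibration = vapply(calib, function(x) x$t, numeric(1)))
  })
}

# Vectorised draw from a Poisson truncated to 1..qmax.
sample_trunc_pois <- function(lambda, qmax) {
  q <- seq_len(qmax)
  pm <- outer(lambda, q, function(l, k) stats::dpois(k, l))
  tot <- rowSums(pm)
  zero <- tot <= 0
  pm[zero, ] <- 0; pm[zero, 1] <- 1; tot[zero] <- 1
  cum <- pm / tot
  for (j in 2:qmax) cum[, j] <- cum[, j] + cum[, j - 1]
  u <- stats::runif(length(lambda))
  1L + as.integer(rowSums(u > cum + 1e-15))
}

#' Simulate per-individual covariates
#'
#' Sex, age and assessment-centre style covariates to accompany a simulated
#' cohort.
#'
#' @param ids character individual IDs.
#' @param seed integer seed.
#' @return data frame: id, sex (`"F"`/`"M"`), age_months, center (factor
#'   label).
#' @export
simulate_covariates <- function(ids, seed = 1L) {
  with_seed(derive_seed(seed, "covariates"), {
    n <- length(ids)
    data.frame(
      id = ids,
      sex = sample(c("F", "M"), n, replace = TRUE),
      age_months = round(stats::rnorm(n, 680, 90)),
      center = sample(paste0("center", 1:4), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Write a simulated genotype set to TSV files
#'
#' Emits `<prefix>_dosages.tsv` (one row per individual, columns = SNP ids),
#' `<prefix>_snps.tsv` (snp, chr, bp, a1, a2, freq).
#'
#' @param g `genotype_matrix`.
#' @param prefix file path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_genotypes <- function(g, prefix) {
  dpath <- paste0(prefix, "_dosages.tsv")
  d <- data.frame(id = g$individuals, g$dosages, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write_tsv(d, dpath)
  mpath <- paste0(prefix, "_snps.tsv")
  write_tsv(g$map, mpath)
  invisible(c(dpath, mpath))
}

#' Write the ground-truth sidecar of a simulation
#'
#' Records the simulated truth (per-item heritability and ICC targets,
#' causal SNP ids) in a YAML sidecar next to the generated tables.
#'
#' @param model `trait_model`.
#' @param latents `latent_traits`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(model, latents, path) {
  truth <- list(
    items = lapply(seq_len(nrow(model$items)), function(j) {
      list(id = model$items$id[j], kind = model$items$kind[j],
           h2 = model$items$h2[j], icc = model$items$icc[j],
           causal = latents$causal[[model$items$id[j]]])
    })
  )
  yaml::write_yaml(truth, path)
  invisible(path)
}
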