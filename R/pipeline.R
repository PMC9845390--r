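# Configuration and orchestration: simulate -> qc -> derive -> icc -> gwas
# -> h2 -> benchmark, with TSV interfaces between stages and a manifest of
# everything written.

.default_config <- function() {
  list(
    seed = 1L,
    simulation = list(
      N = 500L, M = 500L, ld_rho = 0.9, recomb_prob = 0.10,
      maf_range = c(0.05, 0.5),
      n_causal = NULL, items = "example", k_weights = as.numeric(completion_counts),
      qc_violation_rate = 0.02
    ),
    qc = list(
      energy_min_kj = 1000, energy_max_kj_male = 20000,
      energy_max_kj_female = 18000, min_duration_min = 5,
      require_typical_diet = TRUE, require_completion = TRUE,
      exclude_pregnancy = TRUE, exclude_cancer = TRUE
    ),
    derivation = list(precision = 0, min_interior = 50, donor_map = NULL),
    genetics = list(
      maf_min = 0.005, mac_min = 10, miss_max = 0.10,
      ld_window_bp = 1e6, clump_window_bp = 5e5, p_threshold = 5e-8,
      meff_method = "galwey", h2_method = "ldsc"
    ),
    output_dir = NULL
  )
}

# Keys that must be given explicitly whenever their block is present.
.required_in_block <- list(simulation = c("N", "M"))

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys, checks that required
#' keys are present in any block the file provides, and fills documented
#' defaults for everything else. A minimal file containing only `seed`
#' yields the full default configuration.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated configuration list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- .default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- def
  for (block in names(raw)) {
    if (is.list(def[[block]]) && !is.null(names(def[[block]]))) {
      bad <- setdiff(names(raw[[block]]), names(def[[block]]))
      if (length(bad)) {
        stop(sprintf("unknown configuration key(s): %s",
                     paste(paste(block, bad, sep = "."), collapse = ", ")),
             call. = FALSE)
      }
      req <- .required_in_block[[block]]
      miss <- setdiff(req, names(raw[[block]]))
      if (length(miss)) {
        stop(sprintf("missing required key(s): %s",
                     paste(paste(block, miss, sep = "."), collapse = ", ")),
             call. = FALSE)
      }
      cfg[[block]] <- utils::modifyList(def[[block]], raw[[block]],
                                        keep.null = TRUE)
    } else {
      cfg[block] <- list(raw[[block]])  # NULL-safe assignment
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#' @param cfg `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_items <- function(sim) {
  if (is.data.frame(sim$items)) return(sim$items)
  if (identical(sim$items, "example")) return(example_items())
  if (is.list(sim$items)) {
    if (!length(sim$items)) {
      stop("no items defined: nothing to derive", call. = FALSE)
    }
    return(do.call(rbind, lapply(sim$items, function(it) {
      do.call(dietary_items, it)
    })))
  }
  stop("config error at derivation stage: no items defined", call. = FALSE)
}

.stage <- function(name, expr) {
  message(sprintf("[%s] starting", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full benchmarking pipeline
#'
#' Executes simulate, qc, derive, icc, gwas, h2 and benchmark stages from a
#' single configuration; fully deterministic given the configured seed
#' (each stage consumes a named sub-stream). When `output_dir` is set in
#' the configuration, every stage's tables are written as TSV and listed in
#' the returned manifest with their row counts.
#'
#' @param cfg `pipeline_config` from [load_config()], or a list accepted by
#'   it.
#' @return list with the per-stage results (`genotypes`, `questionnaires`,
#'   `qc_report`, `phenotypes`, `icc`, `h2`, `pairs`, `meff`, `benchmark`,
#'   `loci`, `concordance`) and `manifest` (data frame: file, rows).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- load_config(cfg)
  outdir <- cfg$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  manifest <- list()
  emit <- function(x, name) {
    if (!is.null(outdir)) {
      path <- file.path(outdir, paste0(name, ".tsv"))
      write_tsv(x, path)
      manifest[[length(manifest) + 1L]] <<- data.frame(
        file = path, rows = nrow(x), stringsAsFactors = FALSE)
    }
    invisible(x)
  }

  sim <- cfg$simulation
  items <- .stage("simulate", config_items(sim))
  g <- .stage("simulate", simulate_genotypes(
    sim$N, sim$M, maf_range = sim$maf_range, ld_rho = sim$ld_rho,
    recomb_prob = sim$recomb_prob,
    seed = derive_seed(cfg$seed, "genotypes")))
  model <- trait_model(items, n_causal = sim$n_causal,
                       seed = derive_seed(cfg$seed, "traits"))
  latents <- .stage("simulate", simulate_latent_traits(g, model))
  qsim <- .stage("simulate", simulate_questionnaires(
    latents, model, k_weights = sim$k_weights,
    seed = derive_seed(cfg$seed, "quest"),
    qc_violation_rate = sim$qc_violation_rate))
  covar <- simulate_covariates(g$individuals, seed = derive_seed(cfg$seed, "covar"))
  message(sprintf("[simulate] %d individuals, %d SNPs, %d questionnaire records",
                  sim$N, sim$M, nrow(qsim$questionnaires)))
  emit(qsim$questionnaires, "questionnaires")
  emit(covar, "covariates")
  if (!is.null(outdir)) {
    paths <- write_genotypes(g, file.path(outdir, "genotypes"))
    for (p in paths) {
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = p, rows = if (grepl("snps", p)) nrow(g$map) else length(g$individuals),
        stringsAsFactors = FALSE)
    }
    write_ground_truth(model, latents, file.path(outdir, "ground_truth.yaml"))
  }

  qcres <- .stage("qc", filter_questionnaires(
    qsim$questionnaires, covar, do.call(qc_config, cfg$qc)))
  message(sprintf("[qc] %d records in, %d out (%d individuals)",
                  qcres$report$records_in, qcres$report$records_out,
                  qcres$report$individuals_out))
  emit(qc_report_table(qcres$report), "qc_report")
  emit(qcres$questionnaires, "questionnaires_filtered")

  pt <- .stage("derive", build_phenotype_table(
    qcres$questionnaires, items,
    min_interior = cfg$derivation$min_interior,
    donor_map = cfg$derivation$donor_map,
    precision = cfg$derivation$precision))
  message(sprintf("[derive] %d individuals x %d phenotype columns",
                  nrow(pt$phenotypes), length(phenotype_columns(pt))))
  emit(pt$phenotypes, "phenotypes")
  if (!is.null(outdir)) write_priors(pt, file.path(outdir, "priors"))

  # raw-item reliability: indicator ICC for every item (used by proportion
  # phenotypes) and quantity ICC for quantity items (used by averages)
  icc_ind <- .stage("icc", icc_by_item(
    qcres$questionnaires,
    data.frame(id = items$id, kind = "binary", stringsAsFactors = FALSE)))
  icc_qty <- NULL
  qitems <- items[items$kind %in% c("quantity", "continuous"), , drop = FALSE]
  if (nrow(qitems)) {
    icc_qty <- .stage("icc", icc_by_item(qcres$questionnaires, qitems))
  }
  message(sprintf("[icc] %d items on %d complete-case subjects",
                  nrow(icc_ind), icc_ind$n_subjects[1]))
  emit(icc_ind, "icc_indicator")
  if (!is.null(icc_qty)) emit(icc_qty, "icc_quantity")

  # covariate design for the genetic model
  gen <- cfg$genetics
  X <- .stage("gwas", gwas_covariates(qcres$questionnaires, covar, g))
  ids <- pt$phenotypes$id
  ridx <- match(ids, g$individuals)
  cols <- phenotype_columns(pt)
  ss_list <- .stage("gwas", {
    lapply(stats::setNames(cols, cols), function(cl) {
      run_gwas(pt$phenotypes[[cl]], subset_genotypes(g, ridx),
               covariates = X[ridx, , drop = FALSE],
               maf_min = gen$maf_min, mac_min = gen$mac_min,
               miss_max = gen$miss_max, phenotype = cl)
    })
  })
  message(sprintf("[gwas] %d scans x %d SNPs, N = %d",
                  length(ss_list), nrow(ss_list[[1]]), length(ids)))
  if (!is.null(outdir)) {
    ssdir <- file.path(outdir, "sumstats")
    dir.create(ssdir, showWarnings = FALSE)
    for (cl in cols) {
      p <- file.path(ssdir, paste0(cl, ".sumstats"))
      write_sumstats(ss_list[[cl]], p)
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = p, rows = nrow(ss_list[[cl]]), stringsAsFactors = FALSE)
    }
  }

  h2s <- .stage("h2", {
    gsub_ <- subset_genotypes(g, ridx)
    if (gen$h2_method == "ldsc") {
      ld <- compute_ld_scores(gsub_, window_bp = gen$ld_window_bp)
      lapply(ss_list, function(ss) ldsc_h2(ss, ld))
    } else {
      grm <- make_grm(gsub_)
      lapply(cols, function(cl) {
        he_regression(residualize(pt$phenotypes[[cl]], X[ridx, , drop = FALSE]),
                      grm = grm, phenotype = cl)
      }) |> stats::setNames(cols)
    }
  })
  h2tab <- h2_table(h2s)
  message(sprintf("[h2] %d estimates (%s), median h2 = %.3f",
                  nrow(h2tab), gen$h2_method, stats::median(h2tab$h2)))
  emit(h2tab, "h2")

  bench <- .stage("benchmark", {
    meff <- effective_tests(as.matrix(pt$phenotypes[cols]),
                            covariates = X[ridx, , drop = FALSE],
                            method = gen$meff_method)
    pairs <- build_h2_pairs(h2tab, pt$items)
    icc_lookup <- rbind(
      data.frame(item = paste0(icc_ind$item, "_prop"), icc = icc_ind$icc,
                 stringsAsFactors = FALSE),
      if (!is.null(icc_qty))
        data.frame(item = paste0(icc_qty$item, "_avg"), icc = icc_qty$icc,
                   stringsAsFactors = FALSE))
    retained <- significance_filter(pairs, meff)
    cmp <- compare_versions(retained, icc_lookup)
    loci <- do.call(rbind, lapply(names(ss_list), function(cl) {
      v <- if (grepl("_crude_", cl)) "crude" else "eb"
      ph <- sub("_(crude|eb)_", "_", cl)
      clump_loci(ss_list[[cl]], p_threshold = gen$p_threshold,
                 window_bp = gen$clump_window_bp, phenotype = ph, version = v)
    }))
    conc <- locus_concordance(loci[loci$version == "crude", , drop = FALSE],
                              loci[loci$version == "eb", , drop = FALSE],
                              pairs[, c("item", "crude_h2", "eb_h2")],
                              window_bp = gen$clump_window_bp)
    list(meff = meff, pairs = pairs, retained = retained, cmp = cmp,
         loci = loci, conc = conc)
  })
  message(sprintf("[benchmark] meff = %.2f, %d/%d pairs retained, %d loci",
                  bench$meff$meff, nrow(bench$retained), nrow(bench$pairs),
                  nrow(bench$loci)))
  emit(bench$cmp$table, "comparison")
  emit(bench$cmp$win_rates, "win_rates")
  if (!is.null(bench$cmp$quartile_rates)) emit(bench$cmp$quartile_rates, "quartile_rates")
  emit(bench$loci, "loci")
  if (bench$conc$n_windows > 0) emit(bench$conc$windows, "concordance_windows")
  if (!is.null(outdir)) {
    summary_path <- file.path(outdir, "benchmark_summary.yaml")
    yaml::write_yaml(list(
      meff = bench$meff$meff,
      threshold = significance_threshold(bench$meff),
      pairs_total = nrow(bench$pairs),
      pairs_retained = nrow(bench$retained),
      eb_win_rates = bench$cmp$win_rates,
      icc_h2_correlation = as.list(bench$cmp$icc_h2_cor),
      loci = nrow(bench$loci),
      concordance_windows = bench$conc$n_windows,
      concordance = if (bench$conc$n_windows > 0) bench$conc$concordance else "absent"
    ), summary_path)
    manifest[[length(manifest) + 1L]] <- data.frame(
      file = summary_path, rows = NA_integer_, stringsAsFactors = FALSE)
  }

  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(file = character(0), rows = integer(0))
  list(genotypes = g, model = model, latents = latents,
       questionnaires = qcres$questionnaires, qc_report = qcres$report,
       covariates = covar, phenotypes = pt,
       icc = icc_ind, icc_quantity = icc_qty,
       sumstats = ss_list, h2 = h2tab, meff = bench$meff,
       pairs = bench$pairs, retained = bench$retained,
       benchmark = bench$cmp, loci = bench$loci, concordance = bench$conc,
       manifest = manifest)
}

# Row-subset a genotype matrix (individual alignment).
subset_genotypes <- function(g, idx) {
  structure(list(dosages = g$dosages[idx, , drop = FALSE], map = g$map,
                 individuals = g$individuals[idx]),
            class = "genotype_matrix")
}

# Covariate design for the genetic model: sex, age, age^2, centre factor
# (one-hot, reference dropped), weekend proportion, mean duration
# winsorized at 25 min, number of questionnaires, two genotype PCs.
gwas_covariates <- function(q, covar, g) {
  ids <- g$individuals
  rs <- rowsum(cbind(one = rep(1, nrow(q)), wk = q$weekend,
                     dur = pmin(q$duration_min, 25)), q$id)
  idx <- match(ids, rownames(rs))
  kq <- rs[idx, "one"]
  wk <- rs[idx, "wk"] / kq
  dur <- rs[idx, "dur"] / kq
  ci <- match(ids, covar$id)
  sex <- as.numeric(covar$sex[ci] == "M")
  age <- covar$age_months[ci]
  centers <- sort(unique(covar$center))
  Xc <- vapply(centers[-1], function(cc) as.numeric(covar$center[ci] == cc),
               numeric(length(ids)))
  colnames(Xc) <- paste0("center_", centers[-1])
  # two genotype principal components via the SNP-space eigenbasis
  z <- standardize_dosages(g)
  ev <- eigen(crossprod(z) / nrow(z), symmetric = TRUE)
  pcs <- z %*% ev$vectors[, 1:2, drop = FALSE]
  colnames(pcs) <- c("pc1", "pc2")
  X <- cbind(sex = sex, age = age, age2 = age^2, Xc,
             weekend_prop = wk, duration_w25 = dur, n_quest = kq, pcs)
  # individuals filtered out entirely have no questionnaire aggregates;
  # their rows are only used when they re-enter downstream, so zero-fill
  X[is.na(X)] <- 0
  X
}

# One row per item-derived phenotype pair: proportion pairs for every item,
# average pairs for quantity items.
build_h2_pairs <- function(h2tab, items) {
  rows <- list()
  grab <- function(col) {
    i <- match(col, h2tab$phenotype)
    if (is.na(i)) stop(sprintf("missing h2 estimate for '%s'", col), call. = FALSE)
    h2tab[i, ]
  }
  for (j in seq_len(nrow(items))) {
    it <- items$id[j]
    cr <- grab(paste0(it, "_crude_prop")); eb <- grab(paste0(it, "_eb_prop"))
    rows[[length(rows) + 1L]] <- data.frame(
      item = paste0(it, "_prop"), class = "proportion",
      crude_h2 = cr$h2, crude_se = cr$se, crude_p = cr$p,
      eb_h2 = eb$h2, eb_se = eb$se, eb_p = eb$p, stringsAsFactors = FALSE)
    if (items$kind[j] == "quantity") {
      cr <- grab(paste0(it, "_crude_avg")); eb <- grab(paste0(it, "_eb_avg"))
      rows[[length(rows) + 1L]] <- data.frame(
        item = paste0(it, "_avg"), class = "average",
        crude_h2 = cr$h2, crude_se = cr$se, crude_p = cr$p,
        eb_h2 = eb$h2, eb_se = eb$se, eb_p = eb$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
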