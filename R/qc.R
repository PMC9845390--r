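# Per-questionnaire credibility filters and item encoding.

#' Quality-control configuration for 24HR questionnaires
#'
#' Thresholds follow the conventional credibility rules for repeated
#' 24-hour recalls: plausible total energy (sex-specific upper bound),
#' typical-diet and completion flags, a minimum completion duration, and
#' pregnancy/cancer exclusions within the year.
#'
#' @param energy_min_kj minimum credible total energy (kJ), inclusive.
#' @param energy_max_kj_male,energy_max_kj_female sex-specific maxima (kJ),
#'   inclusive.
#' @param min_duration_min minimum completion duration (minutes), inclusive.
#' @param require_typical_diet,require_completion require the respective
#'   flags to be set.
#' @param exclude_pregnancy,exclude_cancer drop records flagged for
#'   pregnancy/cancer within a year of the questionnaire.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(energy_min_kj = 1000,
                      energy_max_kj_male = 20000,
                      energy_max_kj_female = 18000,
                      min_duration_min = 5,
                      require_typical_diet = TRUE,
                      require_completion = TRUE,
                      exclude_pregnancy = TRUE,
                      exclude_cancer = TRUE) {
  if (energy_min_kj >= energy_max_kj_male || energy_min_kj >= energy_max_kj_female) {
    stop("`energy_min_kj` must be below both maxima", call. = FALSE)
  }
  if (min_duration_min < 0) stop("`min_duration_min` must be >= 0", call. = FALSE)
  structure(list(energy_min_kj = energy_min_kj,
                 energy_max_kj_male = energy_max_kj_male,
                 energy_max_kj_female = energy_max_kj_female,
                 min_duration_min = min_duration_min,
                 require_typical_diet = require_typical_diet,
                 require_completion = require_completion,
                 exclude_pregnancy = exclude_pregnancy,
                 exclude_cancer = exclude_cancer),
            class = "qc_config")
}

# Fixed first-failure attribution order; the retained set is order-invariant,
# only the per-rule counts in the report depend on it.
.qc_rules <- c("energy_low", "energy_high", "typical_diet", "duration",
               "completion", "pregnancy", "cancer")

#' Filter questionnaires by credibility rules
#'
#' A record is retained iff its energy lies in the sex-specific credible
#' interval, the typical-diet and completion flags pass, the duration meets
#' the minimum, and the pregnancy/cancer exclusions pass. All thresholds are
#' inclusive. Exclusion counts are attributed to each record's first failing
#' rule in the fixed order energy-low, energy-high, typical-diet, duration,
#' completion, pregnancy, cancer.
#'
#' @param q long-format questionnaire data frame (see
#'   [simulate_questionnaires()]); must contain `id`, `energy_kj`,
#'   `typical_diet`, `completed`, `duration_min`, `pregnant_yr`, `cancer_yr`.
#' @param sex data frame with columns `id` and `sex` (`"M"`/`"F"`), one row
#'   per individual.
#' @param cfg `qc_config`.
#' @return list with `questionnaires` (retained rows) and `report`
#'   (class `qc_report`: per-rule first-failure counts, records in/out,
#'   individuals remaining).
#' @export
filter_questionnaires <- function(q, sex, cfg = qc_config()) {
  if (nrow(q) == 0L) {
    rep0 <- structure(list(excluded = stats::setNames(integer(length(.qc_rules)),
                                                      .qc_rules),
                           records_in = 0L, records_out = 0L,
                           individuals_out = 0L),
                      class = "qc_report")
    return(list(questionnaires = q, report = rep0))
  }
  sx <- sex$sex[match(q$id, sex$id)]
  if (anyNA(sx)) {
    miss <- unique(q$id[is.na(sx)])
    stop(sprintf("missing sex for individual(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  emax <- ifelse(sx == "M", cfg$energy_max_kj_male, cfg$energy_max_kj_female)
  fails <- cbind(
    energy_low  = q$energy_kj < cfg$energy_min_kj,
    energy_high = q$energy_kj > emax,
    typical_diet = cfg$require_typical_diet & q$typical_diet != 1,
    duration    = q$duration_min < cfg$min_duration_min,
    completion  = cfg$require_completion & q$completed != 1,
    pregnancy   = cfg$exclude_pregnancy & q$pregnant_yr == 1,
    cancer      = cfg$exclude_cancer & q$cancer_yr == 1
  )
  keep <- rowSums(fails) == 0L
  first_fail <- apply(fails, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  excl <- stats::setNames(tabulate(first_fail, nbins = length(.qc_rules)),
                          .qc_rules)
  out <- q[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(list(excluded = excl,
                           records_in = nrow(q),
                           records_out = nrow(out),
                           individuals_out = length(unique(out$id))),
                      class = "qc_report")
  list(questionnaires = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d records in, %d out (%d individuals remaining)\n",
              x$records_in, x$records_out, x$individuals_out))
  for (r in names(x$excluded)) {
    if (x$excluded[[r]] > 0)
      cat(sprintf("  excluded by %-12s %d\n", paste0(r, ":"), x$excluded[[r]]))
  }
  invisible(x)
}

#' Convert a QC report to a one-row data frame
#' @param report `qc_report`.
#' @return data frame with one column per rule plus totals.
#' @export
qc_report_table <- function(report) {
  data.frame(as.list(report$excluded),
             records_in = report$records_in,
             records_out = report$records_out,
             individuals_out = report$individuals_out)
}

#' Define an item for encoding
#'
#' @param id item identifier (column name in the questionnaire table).
#' @param kind `"binary"`, `"continuous"` or `"categorical"`.
#' @param options for categorical items, the response options; each becomes
#'   its own 1/0 column named `id.option`.
#' @param combined optional named list for categorical items: each entry is
#'   a set of options collapsed into an extra 1/0 column named
#'   `id.<name>` that is 1 when any member option was selected.
#' @return object of class `item_definition`.
#' @export
item_definition <- function(id, kind, options = NULL, combined = NULL) {
  if (!kind %in% c("binary", "continuous", "categorical")) {
    stop(sprintf("unknown item kind '%s'", kind), call. = FALSE)
  }
  if (kind == "categorical" && length(options) < 1L) {
    stop("categorical items need at least one option", call. = FALSE)
  }
  structure(list(id = id, kind = kind, options = options, combined = combined),
            class = "item_definition")
}

#' Encode raw item responses to analysis columns
#'
#' Binary items are passed through as 1/0; missing responses within a
#' completed questionnaire are coded as not consumed (0). Each categorical
#' response option becomes a distinct 1/0 column (`id.option`), plus any
#' configured combined columns. Continuous quantities pass through
#' unchanged.
#'
#' @param q questionnaire data frame.
#' @param items list of [item_definition()] objects.
#' @return data frame with `id`, `q` and the encoded item columns.
#' @export
encode_items <- function(q, items) {
  out <- q[, c("id", "q"), drop = FALSE]
  for (it in items) {
    if (!inherits(it, "item_definition")) {
      stop("`items` must be item_definition objects", call. = FALSE)
    }
    if (!it$id %in% names(q)) {
      stop(sprintf("item column '%s' not found", it$id), call. = FALSE)
    }
    v <- q[[it$id]]
    if (it$kind == "binary") {
      x <- as.integer(v %in% c(1, "1", TRUE, "yes"))
      out[[it$id]] <- x
    } else if (it$kind == "continuous") {
      x <- as.numeric(v)
      x[is.na(x)] <- 0
      out[[it$id]] <- x
    } else {
      for (op in it$options) {
        out[[paste(it$id, op, sep = ".")]] <- as.integer(!is.na(v) & v == op)
      }
      for (nm in names(it$combined)) {
        member <- it$combined[[nm]]
        out[[paste(it$id, nm, sep = ".")]] <-
          as.integer(!is.na(v) & v %in% member)
      }
    }
  }
  out
}
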