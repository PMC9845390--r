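# One-way random-effects intraclass correlation for raw questionnaire items.

#' One-way intraclass correlation, ICC(1,1)
#'
#' Computes the one-way random-effects ANOVA decomposition on a complete
#' subjects x ratings matrix and returns
#' ICC = between-subject variance / (between-subject variance +
#' within-subject variance), with the between-subject variance component
#' clamped at zero so the estimate stays in `[0, 1]`.
#'
#' @param values numeric matrix, one row per subject, one column per
#'   rating/questionnaire (complete cases only; any missing value is an
#'   error instructing complete-case subsetting).
#' @param item optional item id recorded on the estimate.
#' @return object of class `icc_estimate` with fields `icc`,
#'   `sigma2_between`, `sigma2_within`, `n_subjects`, `n_ratings`, `item`.
#' @export
icc_oneway <- function(values, item = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (ncol(values) < 2L) stop("need at least 2 ratings per subject", call. = FALSE)
  if (anyNA(values)) {
    stop("missing ratings present; subset to complete cases first", call. = FALSE)
  }
  n <- nrow(values); r <- ncol(values)
  subj_means <- rowMeans(values)
  grand <- mean(values)
  msb <- r * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((values - subj_means)^2) / (n * (r - 1))
  if (msb == 0 && msw == 0) stop("zero total variance", call. = FALSE)
  s2b <- max(0, (msb - msw) / r)
  icc <- s2b / (s2b + msw)
  structure(list(icc = icc, sigma2_between = s2b, sigma2_within = msw,
                 n_subjects = n, n_ratings = r, item = item),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("icc_estimate%s: ICC = %.4f (between %.4g, within %.4g; %d subjects x %d ratings)\n",
              if (is.na(x$item)) "" else sprintf(" [%s]", x$item),
              x$icc, x$sigma2_between, x$sigma2_within,
              x$n_subjects, x$n_ratings))
  invisible(x)
}

#' ICC for every raw item from complete five-questionnaire subjects
#'
#' Subsets the filtered questionnaire table to individuals with exactly
#' `n_ratings` retained questionnaires and computes [icc_oneway()] on the
#' raw per-questionnaire values of each item (the 0/1 indicator for binary
#' items, the recorded quantity for quantity items).
#'
#' @param q filtered questionnaire data frame.
#' @param items item data frame with columns `id`, `kind`.
#' @param n_ratings ratings required per subject (default 5).
#' @return data frame: item, icc, sigma2_between, sigma2_within,
#'   n_subjects, n_ratings.
#' @export
icc_by_item <- function(q, items, n_ratings = 5L) {
  cnt <- table(q$id)
  keep <- names(cnt)[cnt == n_ratings]
  if (length(keep) < 2L) {
    stop(sprintf("fewer than 2 individuals with %d retained questionnaires",
                 n_ratings), call. = FALSE)
  }
  qs <- q[q$id %in% keep, , drop = FALSE]
  qs <- qs[order(qs$id, qs$q), , drop = FALSE]
  kind <- ifelse(items$kind == "continuous", "quantity", items$kind)
  rows <- lapply(seq_along(items$id), function(j) {
    col <- if (kind[j] == "quantity") paste0(items$id[j], "_qty") else items$id[j]
    m <- matrix(as.numeric(qs[[col]]), ncol = n_ratings, byrow = TRUE)
    est <- icc_oneway(m, item = items$id[j])
    data.frame(item = items$id[j], icc = est$icc,
               sigma2_between = est$sigma2_between,
               sigma2_within = est$sigma2_within,
               n_subjects = est$n_subjects, n_ratings = est$n_ratings,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
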