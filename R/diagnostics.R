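#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Exact two-sided confidence interval for a binomial proportion, obtained
#' by inverting the binomial tail probabilities (beta-quantile form, as in
#' `stats::binom.test`). At the boundaries the interval takes the closed
#' forms: for `x = n` the lower limit is `(alpha/2)^(1/n)`, mirrored for
#' `x = 0`.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)` as proportions.
#' @export
#' @examples
#' clopper_pearson(25, 25)  # lower limit (0.025)^(1/25) = 0.8628
clopper_pearson <- function(successes, n, level = 0.95) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  if (length(successes) != 1L || is.na(successes) ||
      successes < 0 || successes > n) {
    stop("`successes` must be in [0, n]", call. = FALSE)
  }
  ci <- binom.test(round(successes), round(n), conf.level = level)$conf.int
  c(ci_low = ci[1], ci_high = ci[2])
}

check_cohort_frame <- function(samples) {
  need <- c("sample_id", "group", "ln_a_over_n")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("`samples` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  samples
}

#' Diagnostic accuracy report against gold-standard labels
#'
#' Classifies every sample at the cutoff, tabulates the confusion matrix
#' against the gold-standard `group` labels (`AD` = positive class,
#' `nonADD` = negative class), and attaches exact binomial confidence
#' intervals to sensitivity, specificity, predictive values, and accuracy.
#' Healthy controls must not be present: the reference subjects that define
#' the cutoff are unequivocal by definition and are excluded from
#' specificity, so their presence is an error, not a silent drop.
#'
#' @param samples Data frame with columns `sample_id`, `group` (values
#'   `"AD"` / `"nonADD"`), `ln_a_over_n`.
#' @param cutoff A [percentile_cutoff()] model or numeric cutoff.
#' @param level Confidence level for the intervals (default 0.95).
#' @return A `diagnostic_report` list: confusion counts `tp`, `fp`, `fn`,
#'   `tn`; a `statistics` data frame (statistic, value %, CI low %, CI
#'   high %); and a per-sample `calls` data frame.
#' @export
#' @examples
#' cohort <- rbind(load_fixture_cohort("table1"), load_fixture_cohort("table2"))
#' confusion_report(cohort, 6.98)$tp
confusion_report <- function(samples, cutoff, level = 0.95) {
  samples <- check_cohort_frame(samples)
  if (nrow(samples) > 0 && !all(samples$group %in% c("AD", "nonADD"))) {
    bad <- setdiff(unique(samples$group), c("AD", "nonADD"))
    stop("samples with group(s) ", paste(bad, collapse = ", "),
         " present; controls are excluded from accuracy determinations",
         call. = FALSE)
  }
  if (inherits(cutoff, "cutoff_model")) cutoff <- cutoff$cutoff_2dp
  calls <- if (nrow(samples) > 0) classify_score(samples$ln_a_over_n, cutoff)
           else character(0)
  gold_pos <- samples$group == "AD"
  call_pos <- calls == "AD"
  tp <- sum(gold_pos & call_pos)
  fn <- sum(gold_pos & !call_pos)
  fp <- sum(!gold_pos & call_pos)
  tn <- sum(!gold_pos & !call_pos)

  prop_row <- function(name, num, den) {
    if (den == 0) {
      return(data.frame(statistic = name, value = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    ci <- clopper_pearson(num, den, level)
    data.frame(statistic = name, value = 100 * num / den,
               ci_low = 100 * ci[["ci_low"]], ci_high = 100 * ci[["ci_high"]])
  }
  stats <- rbind(
    prop_row("sensitivity", tp, tp + fn),
    prop_row("specificity", tn, tn + fp),
    prop_row("ppv", tp, tp + fp),
    prop_row("npv", tn, tn + fn),
    prop_row("accuracy", tp + tn, nrow(samples))
  )
  rownames(stats) <- NULL
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         cutoff = cutoff, level = level, statistics = stats,
         calls = data.frame(
           sample_id = samples$sample_id,
           score = samples$ln_a_over_n,
           call = calls,
           gold_label = samples$group,
           correct = (calls == "AD") == gold_pos)),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report at cutoff %.2f>\n", x$cutoff))
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  s <- x$statistics
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.2f%%  (%.2f to %.2f)\n", s$statistic[i],
                s$value[i], s$ci_low[i], s$ci_high[i]))
  }
  invisible(x)
}

#' Serialise a diagnostic report as JSON
#'
#' @param report A [confusion_report()] result.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "diagnostic_report"))
  out <- list(
    cutoff = report$cutoff,
    confusion = list(tp = report$tp, fn = report$fn, fp = report$fp,
                     tn = report$tn),
    statistics = report$statistics
  )
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Gaussian summaries of the group score distributions
#'
#' Fits a Gaussian to each diagnostic group's `Ln(A/N)` values (sample mean
#' and standard deviation, the maximum-likelihood fit) and places the
#' buffer-zone boundary four standard deviations from each group mean
#' toward the inter-group gap. For plotting, density-adaptive histogram
#' breaks are provided as equal-count (quantile) bins with `ceiling(sqrt(n))`
#' bins, so bin width is inversely proportional to the local density of
#' points.
#'
#' @param samples Data frame with columns `group` and `ln_a_over_n`;
#'   typically the AD and nonADD cohorts combined.
#' @param n_min Minimum group size (default 3).
#' @return List of `group_distribution` records, one per group present:
#'   `group`, `n`, `mean`, `sd`, `buffer_low` (mean - 4 sd), `buffer_high`
#'   (mean + 4 sd), `breaks`, and `degenerate` (TRUE when sd is 0).
#' @export
#' @examples
#' cohort <- rbind(load_fixture_cohort("table1"), load_fixture_cohort("table2"))
#' fits <- fit_group_distributions(cohort)
#' fits[["AD"]]$mean
fit_group_distributions <- function(samples, n_min = 3L) {
  samples <- check_cohort_frame(samples)
  groups <- split(samples$ln_a_over_n, samples$group)
  out <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) < n_min) {
      stop(sprintf("group %s has %d samples, need at least %d",
                   g, length(x), n_min), call. = FALSE)
    }
    m <- mean(x)
    s <- sd(x)
    nb <- ceiling(sqrt(length(x)))
    br <- unique(quantile(x, probs = seq(0, 1, length.out = nb + 1),
                          names = FALSE))
    structure(
      list(group = g, n = length(x), mean = m, sd = s,
           buffer_low = m - 4 * s, buffer_high = m + 4 * s,
           breaks = br, degenerate = s == 0),
      class = "group_distribution"
    )
  })
  names(out) <- names(groups)
  out
}
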