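#' Specification for a synthetic patient cohort
#'
#' Per-group Gaussian models of the plate-level `Ln(A/N)` biomarker. The
#' default means and standard deviations are the sample statistics of the
#' packaged AD, non-ADD, and healthy-control cohort tables, so the default
#' generator emulates the statistical structure of the study populations.
#'
#' @param n_per_group Named integer vector of group sizes; names from
#'   `"AD"`, `"nonADD"`, `"AHC"`. Default `(25, 21, 27)`, the study sizes.
#' @param group_means,group_sds Named numeric vectors over the same groups.
#'   Defaults: fitted from the packaged cohort tables.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(n_per_group = c(AD = 10, nonADD = 10), seed = 7)
cohort_spec <- function(n_per_group = c(AD = 25L, nonADD = 21L, AHC = 27L),
                        group_means = NULL, group_sds = NULL, seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% c("AD", "nonADD", "AHC"))) {
    stop("`n_per_group` must be named with groups among AD, nonADD, AHC",
         call. = FALSE)
  }
  if (any(n_per_group < 0)) stop("group sizes must be >= 0", call. = FALSE)
  if (is.null(group_means) || is.null(group_sds)) {
    fits <- fixture_group_stats()
    if (is.null(group_means)) group_means <- fits$mean[groups]
    if (is.null(group_sds)) group_sds <- fits$sd[groups]
  }
  if (!all(groups %in% names(group_means)) ||
      !all(groups %in% names(group_sds))) {
    stop("`group_means` and `group_sds` must cover every group in ",
         "`n_per_group`", call. = FALSE)
  }
  if (any(group_sds[groups] < 0)) stop("group sds must be >= 0",
                                       call. = FALSE)
  structure(
    list(n_per_group = setNames(as.integer(n_per_group), groups),
         group_means = group_means[groups], group_sds = group_sds[groups],
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Sample mean/sd of Ln(A/N) per group across the three packaged tables.
fixture_group_stats <- function() {
  tabs <- rbind(load_fixture_cohort("table1"), load_fixture_cohort("table2"),
                load_fixture_cohort("table3"))
  sp <- split(tabs$ln_a_over_n, tabs$group)
  list(mean = vapply(sp, mean, numeric(1)), sd = vapply(sp, sd, numeric(1)))
}

#' Generate a synthetic cohort of biomarker values
#'
#' Draws each group's `Ln(A/N)` values independently from its Gaussian in
#' the [cohort_spec()], under a per-group stream derived from the root
#' seed. The result uses the same schema as the packaged cohort tables, so
#' it can be fed to [confusion_report()] and [fit_group_distributions()]
#' unchanged.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `sample_id`, `source`, `age`, `gender`,
#'   `group`, `validation`, `comorbidity`, `ln_a_over_n`. Zero rows when
#'   all group sizes are 0.
#' @export
#' @examples
#' head(generate_cohort(cohort_spec(c(AD = 5, nonADD = 5), seed = 3)))
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  parts <- lapply(names(spec$n_per_group), function(g) {
    n <- spec$n_per_group[[g]]
    if (n == 0L) return(NULL)
    vals <- with_local_seed(derive_seed(spec$seed, "cohort", g),
                            rnorm(n, spec$group_means[[g]],
                                  spec$group_sds[[g]]))
    data.frame(
      sample_id = sprintf("SIM-%s-%03d", g, seq_len(n)),
      source = "synthetic", age = NA_integer_, gender = NA_character_,
      group = g, validation = "synthetic", comorbidity = 0L,
      ln_a_over_n = vals
    )
  })
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0L) {
    return(data.frame(
      sample_id = character(0), source = character(0), age = integer(0),
      gender = character(0), group = character(0), validation = character(0),
      comorbidity = integer(0), ln_a_over_n = numeric(0)))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
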