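# md5 sums of the packaged cohort tables, frozen at packaging time so a
# corrupted or locally edited fixture fails loudly instead of silently
# shifting the cutoff.
FIXTURE_MD5 <- c(
  table1 = "d9fcebea0f57fb71f9bc0798fb856995",
  table2 = "0849a634c2d3afa0c56e8b1241ccff0c",
  table3 = "4e77928c02585c2efdf71cc5a9296450"
)

fixture_file <- function(table_id) {
  fname <- switch(table_id,
    table1 = "table1_ad_cohort.csv",
    table2 = "table2_nonadd_cohort.csv",
    table3 = "table3_control_cohort.csv"
  )
  path <- system.file("extdata", fname, package = "miassay")
  if (!nzchar(path)) stop("fixture ", fname, " not found in package",
                          call. = FALSE)
  path
}

#' Load a packaged cohort table
#'
#' The three study cohorts are shipped with the package: `table1` — the 25
#' autopsy/genetically validated AD samples; `table2` — the 21 validated
#' non-AD-dementia samples; `table3` — the 27 apparently healthy controls
#' whose values define the reference interval. Each row carries the sample
#' identity, demographics, validation method, comorbidity count, and the
#' plate-level `Ln(A/N)`. File integrity is verified against a frozen md5
#' sum before parsing.
#'
#' @param table_id One of `"table1"`, `"table2"`, `"table3"`.
#' @return Data frame with columns `sample_id`, `source`, `age`, `gender`,
#'   `group` (`AD` / `nonADD` / `AHC`), `validation`, `comorbidity`,
#'   `ln_a_over_n`.
#' @export
#' @examples
#' ahc <- load_fixture_cohort("table3")
#' nrow(ahc)  # 27
load_fixture_cohort <- function(table_id = c("table1", "table2", "table3")) {
  table_id <- match.arg(table_id)
  path <- fixture_file(table_id)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(FIXTURE_MD5[[table_id]]))) {
    stop(sprintf("fixture %s is corrupted: md5 %s, expected %s",
                 basename(path), md5, FIXTURE_MD5[[table_id]]),
         call. = FALSE)
  }
  df <- read.csv(path, colClasses = c(
    sample_id = "character", source = "character", age = "integer",
    gender = "character", group = "character", validation = "character",
    comorbidity = "integer", ln_a_over_n = "numeric"))
  df
}
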