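#!/usr/bin/env Rscript

# Step 4 — cohort simulation and parameter recovery.
#
# Draws replicate synthetic cohorts from per-group Gaussians whose means
# and standard deviations are the sample statistics of the packaged AD and
# non-AD-dementia tables, then checks that the generator recovers those
# inputs (empirical replicate-averaged group means within 3 standard
# errors) and reports how often perfect separation at the 6.98 cutoff
# occurs under Gaussian sampling — a reminder that the printed cohorts'
# perfect split is a finite-sample observation, not a property the
# generator enforces.
#
# Writes: results/cohort_recovery.csv

suppressPackageStartupMessages(library(miassay))
dir.create("results", showWarnings = FALSE)

t1 <- load_fixture_cohort("table1")
t2 <- load_fixture_cohort("table2")
mu <- c(AD = mean(t1$ln_a_over_n), nonADD = mean(t2$ln_a_over_n))
sg <- c(AD = sd(t1$ln_a_over_n), nonADD = sd(t2$ln_a_over_n))
nn <- c(AD = 25L, nonADD = 21L)
reps <- 1000L

sums <- c(AD = 0, nonADD = 0)
perfect <- 0L
for (r in seq_len(reps)) {
  co <- generate_cohort(cohort_spec(n_per_group = nn, group_means = mu,
                                    group_sds = sg, seed = r))
  m <- tapply(co$ln_a_over_n, co$group, mean)
  sums <- sums + m[names(sums)]
  rep_r <- confusion_report(co, 6.98)
  if (rep_r$fn == 0L && rep_r$fp == 0L) perfect <- perfect + 1L
}
emp <- sums / reps
se <- sg / sqrt(as.numeric(nn)) / sqrt(reps)

tab <- data.frame(group = names(mu), input_mean = unname(mu),
                  input_sd = unname(sg), recovered_mean = unname(emp),
                  se_of_recovered = unname(se),
                  z = unname((emp - mu) / se))
write.csv(tab, "results/cohort_recovery.csv", row.names = FALSE)
print(tab, digits = 5, row.names = FALSE)
cat(sprintf("\nperfect separation at 6.98 in %d / %d Gaussian replicate cohorts (%.1f%%)\n",
            perfect, reps, 100 * perfect / reps))
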