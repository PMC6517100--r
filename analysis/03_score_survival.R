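#!/usr/bin/env Rscript
# The headline analysis on one simulated cohort, then its replication
# probability: composite pro-inflammatory score (profile + Iba1 intensity
# + area, each min-max scaled over the pooled cohort), WT vs MUT score
# comparison, and median-split overall-survival comparison; finally the
# frequency over many cohort draws with which every IDH-mutant tumor
# lands in the high-score group.

suppressMessages(library(gammscope))

dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_config(seed = 20260920))
scores <- composite_score(cohort)
write_cohort_csv(as.data.frame(scores), "results/score_table.csv")

mut <- scores$genotype == "IDH_MUT"
cmp <- compare_groups(scores$score[mut], scores$score[!mut])
cat(sprintf("Composite score: MUT %.1f±%.1f vs WT %.1f±%.1f units (p = %.3g)\n",
            cmp$mean_a, cmp$sd_a, cmp$mean_b, cmp$sd_b, cmp$p))

surv <- compare_survival(scores)
cat(sprintf(
  "Median split: high %.0f±%.0f days (n=%d) vs low %.0f±%.0f days (n=%d), p = %.3g\n",
  surv$mean_high, surv$sd_high, surv$n_high,
  surv$mean_low, surv$sd_low, surv$n_low, surv$p))
cat("MUT tumors in the high group:", sum(scores$group[mut] == "high"),
    "of", sum(mut), "\n")

# replication probability of the qualitative pattern over cohort draws
n_draws <- 500
pattern <- vapply(seq_len(n_draws), function(s) {
  st <- composite_score(generate_cohort(cohort_config(seed = s)))
  m <- st$genotype == "IDH_MUT"
  c(all_mut_high = all(st$group[m] == "high"),
    mut_scores_higher = mean(st$score[m]) > mean(st$score[!m]))
}, logical(2))
summary_tab <- data.frame(
  pattern = rownames(pattern),
  rate = rowMeans(pattern),
  n_draws = n_draws)
write_cohort_csv(summary_tab, "results/score_pattern_rates.csv")
cat(sprintf(
  "Over %d cohort draws: MUT mean score higher in %.0f%%, all MUT in the high group in %.0f%%\n",
  n_draws, 100 * summary_tab$rate[2], 100 * summary_tab$rate[1]))
cat("Wrote results/score_table.csv and results/score_pattern_rates.csv\n")
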