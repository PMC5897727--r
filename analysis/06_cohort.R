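#!/usr/bin/env Rscript
# End-to-end two-group phantom cohort mimicking the control versus
# Vangl2-disrupted comparison: nine "control" embryos (ML border anisotropy
# a = 1.5, ML-concentrated cell orientations) versus nine "mutant" embryos
# (a = 1.0, dispersed orientations), run blind to genotype through peel ->
# project -> morphometry -> polarity, then unblinded for the group
# statistics.

suppressMessages(library(pnpolarity))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

ctrl <- function() sheet_phantom_params(border_anisotropy_a = 1.5,
                                        orientation_mean_deg = 0,
                                        orientation_kappa = 4,
                                        border_cv = 0.2, seed = 1L)
mut <- function() sheet_phantom_params(border_anisotropy_a = 1.0,
                                       orientation_kappa = 0,
                                       border_cv = 0.2, seed = 1L)
man <- phantom_cohort_manifest(9, ctrl(), mut(), seed = seed + 9L)
cfg <- run_config(enrichment_k = 1.25, out_dir = "results/cohort")
res <- suppressMessages(run_pipeline(
  man, cfg, params_for = function(g) if (g == "control") ctrl() else mut()))

print(res)
cat("\nper-genotype enrichment scores:\n")
print(aggregate(enrichment_score ~ genotype, res$embryo_table,
                function(x) c(mean = mean(x), sd = sd(x))), digits = 3)
cat(sprintf("\ntwo-sample t on embryo scores: t = %.2f, p = %.3g (%s)\n",
            res$stats$enrichment_between$t, res$stats$enrichment_between$p,
            res$stats$enrichment_between$variance_rule_used))
for (g in c("control", "mutant"))
  cat(sprintf("one-sample t vs 1 (%s): p = %.3g\n", g,
              res$stats[[paste0("enrichment_vs_1_", g)]]$p))
ml <- tapply(res$profile_table$orientation_deg < 30,
             res$profile_table$genotype, mean)
cat(sprintf("\nML-oriented (<30 deg) profile fraction: control %.0f%%, mutant %.0f%%\n",
            100 * ml[["control"]], 100 * ml[["mutant"]]))
cat(sprintf("profile-orientation chi-square p = %.3g; cell-orientation chi-square p = %.3g\n",
            res$stats$profile_orientation_between$p,
            res$stats$cell_orientation_between$p))
cat("\nThe control group shows the ML-polarised junctional pattern (score > 1,\n")
cat("ML-biased supracellular profiles); the mutant group does not. Detection\n")
cat(sprintf("used enrichment threshold k = %.2f (reported with the results).\n",
            cfg$enrichment_k))
cat("Stage tables in results/cohort/.\n")
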