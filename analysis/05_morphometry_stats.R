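#!/usr/bin/env Rscript
# Validate tissue-scale morphometry (neuropore dimensions, fold elevation,
# basal:apical ratio, ablation widening) and the statistical machinery
# (angular chi-square, t-tests, ANOVA, regression slope comparison).

suppressMessages(library(pnpolarity))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
dir.create("results", showWarnings = FALSE)
rows <- list()
chk <- function(name, value, expected, tol) {
  ok <- abs(value - expected) <= tol
  rows[[length(rows) + 1L]] <<- data.frame(check = name, value = value,
                                           expected = expected, pass = ok)
  cat(sprintf("%-38s %10.4f (expected %.4f) %s\n", name, value, expected,
              if (ok) "ok" else "FAIL"))
}

for (e in c(30, -15, 0)) {
  cs <- generate_cross_section(e, seed = seed)
  lm <- extract_section_landmarks(cs$image, cs$spacing)
  chk(paste0("fold_elevation_", e, "um"),
      fold_elevation(section_landmarks(lm$ventral_apical_midline,
                                       lm$fold_tips)), e, 1)
}
th <- seq(0, pi, length.out = 2001)
sl <- section_landmarks(c(0, 0), rbind(c(-50, 0), c(50, 0)),
                        apical_curve = cbind(seq(-50, 50,
                                                 length.out = 101), 0),
                        basal_curve = cbind(50 * cos(th), 50 * sin(th)))
chk("basal_apical_semicircle", basal_apical_ratio(sl), pi / 2, 1e-3)
for (w in c(0, 40, -10)) {
  ab <- generate_ablation_pair(100, w, seed = seed)
  chk(paste0("ablation_widening_", w, "um"),
      ablation_widening(ab$pre, ab$post,
                        rc_level_um = ab$truth$canthus_rc_um,
                        spacing = ab$spacing)$widening, w, 1)
}

suppressWarnings(
  chk("chi_square_concentrated",
      chi_square_vs_random(c(10, 0, 0, 0, 0, 0))$chi2, 50, 1e-9))
chk("two_sample_t_pooled",
    two_sample_t(c(1, 2, 3), c(4, 5, 6), "pooled")$t, -3 / sqrt(2 / 3), 1e-9)
chk("anova_F", anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$F,
    3, 1e-9)
set.seed(seed)
x <- 1:6
r <- regression_slope_tests(x, x + rnorm(6, 0, 0.05),
                            x, -x + rnorm(6, 0, 0.05))
chk("opposite_slopes_detected", as.numeric(r$p_slopes_equal < 0.001), 1, 0)

df <- do.call(rbind, rows)
write_table(df, "results/morphometry_stats_checks.csv")
cat(sprintf("\n%d/%d checks passed\n", sum(df$pass), nrow(df)))
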