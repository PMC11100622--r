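# Statistical comparisons across conditions and assembly of the final
# report bundle (results/report.json, results/report.md).

source("analysis/00_config.R")

thermal <- read.csv(file.path(RESULTS, "thermal_summary.csv"))
slopes <- read.csv(file.path(RESULTS, "phase_slopes.csv"))
delays <- read.csv(file.path(RESULTS, "delays.csv"))
cells <- read.csv(file.path(RESULTS, "ih_cells.csv"))

pick <- function(df, cond, col) df[df$condition == cond, col]

# paired comparisons, saline vs cesium, within preparation
q10_cmp <- paired_compare(pick(thermal, "saline", "q10"),
                          pick(thermal, "cs", "q10"))
delay_cmp <- paired_compare(pick(delays, "saline", "delay"),
                            pick(delays, "cs", "delay"))
jag_dec_cmp <- paired_compare(pick(thermal, "cs", "p_dec_during_inc"),
                              pick(thermal, "saline", "p_dec_during_inc"))
jag_inc_cmp <- paired_compare(pick(thermal, "cs", "p_inc_during_stable"),
                              pick(thermal, "saline", "p_inc_during_stable"))

# repeated-measures ANOVA on the 21-11 degC frequency change over the
# three conditions, with Tukey contrasts when significant
rm_fit <- rm_anova_tukey(thermal$delta_f, thermal$condition,
                         thermal$prep)

# phase-constancy slopes: one-sample-style test against zero per phase
# and condition (5 phases x 2 conditions), Bonferroni over the family
slope_tests <- list()
for (cond in c("saline", "cs")) {
  for (ph in unique(slopes$phase)) {
    s <- slopes$slope_per_10C[slopes$condition == cond &
                                slopes$phase == ph]
    slope_tests[[paste(cond, ph, sep = "_")]] <-
      paired_compare(s, numeric(length(s)))
  }
}
p_adj <- bonferroni(vapply(slope_tests, `[[`, numeric(1), "p_value"),
                    m = 10)
slope_table <- data.frame(
  test = names(slope_tests),
  mean_slope_per_10C = vapply(names(slope_tests), function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    cond <- parts[1]
    ph <- paste(parts[-1], collapse = "_")
    mean(slopes$slope_per_10C[slopes$condition == cond &
                                slopes$phase == ph])
  }, numeric(1)),
  p_adjusted = p_adj, row.names = NULL)

cc11 <- cells[cells$temp_c == 11, ]
block11 <- percent_block(cc11$delta_saline, cc11$delta_cs)

report <- build_report(list(
  q10_saline_vs_cs = q10_cmp,
  delay_saline_vs_cs = delay_cmp,
  jag_dec_cs_vs_saline = jag_dec_cmp,
  jag_inc_cs_vs_saline = jag_inc_cmp,
  delta_f_rm_anova = rm_fit,
  phase_constancy = slope_table,
  ih_block_11C = list(mean = block11$mean, sd = block11$sd,
                      n = block11$n)),
  out_dir = RESULTS)

message("report written to ", file.path(RESULTS, "report.{json,md}"))
message(sprintf("Q10 saline vs cesium: %s p = %.3g",
                q10_cmp$test_name, q10_cmp$p_value))
message(sprintf("delta f ANOVA: F(%d,%d) = %.2f, p = %.3g",
                rm_fit$df1, rm_fit$df2, rm_fit$f_statistic,
                rm_fit$p_value))
if (!is.null(rm_fit$tukey)) print(rm_fit$tukey, digits = 3)
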