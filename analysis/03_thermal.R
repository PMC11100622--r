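# Temperature-response analysis per preparation and condition: holding
# means, Q10 fits, 21-vs-11 degC frequency differences, jag
# classification, and phase-constancy slopes.

source("analysis/00_config.R")

rows <- list()
slope_rows <- list()
for (cond in CONDITIONS) {
  for (prep in seq_len(N_PREPARATIONS)) {
    cyc <- read_cycles_csv(file.path(prep_dir(cond, prep), "cycles.csv"))
    hm <- holding_means(cyc)
    q <- fit_q10(hm)
    jc <- classify_jags(cyc)
    rows[[paste(cond, prep)]] <- data.frame(
      condition = cond, prep = prep, q10 = q$q10, f11 = q$f_ref,
      delta_f = delta_f(hm),
      p_dec_during_inc = jc$p_dec_during_inc,
      p_inc_during_stable = jc$p_inc_during_stable)

    # mean phase per holding temperature -> phase-constancy slope
    targets <- hm$target_c
    nearest <- targets[vapply(cyc$temp_c,
                              function(x) which.min(abs(targets - x)), 1L)]
    keep <- abs(cyc$temp_c - nearest) <= 0.3
    for (ph in c("pd_off", "lp_on", "lp_off", "py_on", "py_off")) {
      mp <- tapply(cyc[[ph]][keep], nearest[keep], mean, na.rm = TRUE)
      f <- fit_phase_slope(as.numeric(names(mp)), as.numeric(mp), ph)
      slope_rows[[paste(cond, prep, ph)]] <- data.frame(
        condition = cond, prep = prep, phase = ph,
        slope_per_10C = f$slope_per_10C)
    }
  }
}
thermal <- do.call(rbind, rows)
slopes <- do.call(rbind, slope_rows)
write.csv(thermal, file.path(RESULTS, "thermal_summary.csv"),
          row.names = FALSE)
write.csv(slopes, file.path(RESULTS, "phase_slopes.csv"),
          row.names = FALSE)

for (cond in CONDITIONS) {
  t <- thermal[thermal$condition == cond, ]
  message(sprintf(
    "%-7s: Q10 %.2f +/- %.2f | delta f(21-11) %.2f Hz | P(dec|inc) %.3f | P(inc|stable) %.3f",
    cond, mean(t$q10), sd(t$q10), mean(t$delta_f),
    mean(t$p_dec_during_inc), mean(t$p_inc_during_stable)))
}
lp_off <- slopes[slopes$phase == "lp_off", ]
message(sprintf(
  "LP OFF advance per 10 degC: saline %.3f, cesium %.3f",
  -mean(lp_off$slope_per_10C[lp_off$condition == "saline"]),
  -mean(lp_off$slope_per_10C[lp_off$condition == "cs"])))
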