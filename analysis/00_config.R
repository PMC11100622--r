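# Shared configuration for the analysis scripts. Each numbered script
# is a thin driver over the pyloric package; run them in order from the
# repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_phases.R
#   ...
# Raw simulated recordings go under scratch/ (bulky, regenerable);
# summary tables and reports go under results/.

library(pyloric)

SEED <- 20260930L
N_PREPARATIONS <- 6L          # paired preparations per condition set
CONDITIONS <- c("saline", "cs", "cs_ptx")
SCRATCH <- "scratch/sim"
RESULTS <- "results"

dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

protocol <- temperature_protocol()   # 11 -> 21 degC, 2 degC steps, 4 min

prep_dir <- function(condition, prep) {
  file.path(SCRATCH, sprintf("%s_prep%02d", condition, prep))
}

# one seed per (condition, preparation), derived from the master seed
prep_seed <- function(condition, prep) {
  SEED + 1000L * match(condition, CONDITIONS) + prep
}
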