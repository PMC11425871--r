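# Shared configuration for the numbered analysis drivers. Source()d by
# each script; all stage outputs live under results/run/.
library(neo3d)

master_seed <- 20240926L

cfg <- run_config(
  input_dir = "results/input",
  outdir = "results/run",
  cell_lines = c("ESC", "FIB"), # embryonic-stem-cell-like / fibroblast-like
  bin_size_bp = 500000L,
  nucleus_radius = 10,
  n_steps = 5000L,
  baseline = "surrogate",
  cv_kind = "kfold", n_folds = 5L, n_repeats = 20L,
  seed = master_seed)

dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
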