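# End-to-end orchestration: simulate inputs, then run
# curate -> map -> compartments -> reconstruct (per cell line) ->
# featurize -> evaluate, writing stage outputs and a hashed manifest.

#' Default run configuration
#'
#' @param input_dir directory holding the pipeline inputs (as written by
#'   [simulate_inputs()] or user-supplied files of the same formats).
#' @param outdir output directory for stage results.
#' @param cell_lines the two cell-line names whose contact maps
#'   (`contacts_<name>.tsv`) are expected in `input_dir`.
#' @param bin_size_bp genomic bin size (default 500 kb).
#' @param nucleus_radius nuclear radius for reconstruction.
#' @param n_steps optimisation steps per reconstruction.
#' @param baseline "surrogate" to score peptides with the built-in scorer,
#'   or a path to a baseline score TSV.
#' @param baseline_mode provenance label when `baseline` is a path.
#' @param methods classifiers to evaluate.
#' @param cv_kind,n_folds,n_repeats cross-validation scheme.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, outdir,
                       cell_lines = c("ESC", "FIB"),
                       bin_size_bp = 500000L, nucleus_radius = 10,
                       n_steps = 2000L,
                       baseline = "surrogate", baseline_mode = "surrogate",
                       methods = c("KNN", "SVM", "LR"),
                       cv_kind = "kfold", n_folds = 5L, n_repeats = 10L,
                       seed = 1L) {
  structure(list(input_dir = input_dir, outdir = outdir,
                 cell_lines = cell_lines, bin_size_bp = as.integer(bin_size_bp),
                 nucleus_radius = nucleus_radius, n_steps = as.integer(n_steps),
                 baseline = baseline, baseline_mode = baseline_mode,
                 methods = methods, cv_kind = cv_kind,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file with any subset of [run_config()]'s fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

.validate_config <- function(config) {
  need <- c(assays = file.path(config$input_dir, "assays.tsv"),
            fasta = file.path(config$input_dir, "proteins.fasta"),
            bed = file.path(config$input_dir, "genes.bed"))
  for (cl in config$cell_lines)
    need[paste0("contacts_", cl)] <-
      file.path(config$input_dir, paste0("contacts_", cl, ".tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    abort_input("missing input file(s): ",
                paste(sprintf("%s (%s)", names(missing), missing),
                      collapse = ", "))
  need
}

#' Simulate a complete pipeline input bundle
#'
#' Wraps the synthetic-world generators and writes every file [run_pipeline()]
#' consumes into `config$input_dir`.
#'
#' @param config a [run_config()].
#' @param n_chains,beads_per_chain,n_genes,n_peptides world sizes.
#' @param effect_params logistic label model coefficients.
#' @param depth total expected Hi-C count.
#' @return Invisibly, the `synthetic_world`.
#' @export
simulate_inputs <- function(config, n_chains = 6L, beads_per_chain = 25L,
                            n_genes = 60L, n_peptides = 500L,
                            effect_params = list(b0 = 0, b_base = 0.5,
                                                 b_rad = -2),
                            depth = 1e6) {
  if (n_peptides < 1L) abort_input("n_peptides must be >= 1")
  world <- simulate_world(
    n_chains = n_chains, beads_per_chain = beads_per_chain,
    bond_length = 1, nucleus_radius = config$nucleus_radius,
    cell_lines = config$cell_lines, n_genes = n_genes,
    n_peptides = n_peptides, alpha = 1, depth = depth,
    effect_params = effect_params,
    seed = derive_seed(config$seed, "simulate"))
  write_world(world, config$input_dir)
  invisible(world)
}

#' Run the full analysis pipeline
#'
#' Stages: curate assay records; map curated peptides to loci and bins;
#' compute compartment-degree activity and radial targets per chromosome;
#' reconstruct one 3D structure per cell line; assemble the 9-feature
#' table; evaluate the classifiers against the baseline. Every stage
#' writes its table under `config$outdir`, and a manifest records each
#' output file with an MD5 content hash, per-stage row counts and the
#' derived seeds.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the curated data, feature table,
#'   comparison table and manifest path.
#' @export
run_pipeline <- function(config) {
  paths <- .validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, ...) manifest[[stage]] <<- list(...)

  # 1. curation
  raw <- read_assay_tsv(paths[["assays"]])
  cur <- curate(raw, curation_config())
  curated_path <- file.path(config$outdir, "curated.tsv")
  write_curated_tsv(cur, curated_path)
  note("curate", rows_in = nrow(raw), rows_out = nrow(cur$full_dataset),
       file = curated_path)

  # 2. mapping
  ann <- load_annotation(paths[["fasta"]], paths[["bed"]])
  mapped <- map_peptides(cur$full_dataset, ann, config$bin_size_bp)
  mapped_path <- file.path(config$outdir, "mapped.tsv")
  utils::write.table(mapped, mapped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("map", rows_out = nrow(mapped),
       n_unmapped = attr(mapped, "n_unmapped"), file = mapped_path)

  # 3-4. compartments + reconstruction per cell line
  structures <- list()
  for (cl in config$cell_lines) {
    maps <- read_contacts_coo(paths[[paste0("contacts_", cl)]],
                              config$bin_size_bp)
    profiles <- lapply(maps, function(m)
      assign_radial_targets(compartment_degree(m), config$nucleus_radius))
    cfg <- reconstruction_config(
      n_steps = config$n_steps,
      seed = derive_seed(config$seed, paste0("reconstruct_", cl)))
    st <- suppressWarnings(
      reconstruct(maps, profiles, cfg, config$nucleus_radius, cell_line = cl))
    st_path <- file.path(config$outdir, paste0("structure_", cl, ".tsv"))
    write_structure_tsv(st, st_path)
    structures[[cl]] <- st
    note(paste0("reconstruct_", cl), beads = sum(vapply(st$chains, nrow, 1L)),
         final_energy = attr(st, "final_energy"),
         converged = attr(st, "converged"), file = st_path)
  }

  # 5. features
  scores <- if (identical(config$baseline, "surrogate")) {
    surrogate_score_table(mapped$peptide, mapped$allele)
  } else {
    load_baseline_scores(config$baseline, config$baseline_mode)
  }
  features <- assemble_features(mapped, structures, scores)
  feat_path <- file.path(config$outdir, "features.tsv")
  write_feature_tsv(features, feat_path)
  note("featurize", rows_out = nrow(features),
       dropped = attr(features, "dropped"), file = feat_path)

  # 6. evaluation
  scheme <- cv_scheme(config$cv_kind, config$n_folds, config$n_repeats,
                      seed = derive_seed(config$seed, "cv"))
  report <- evaluate_methods(features, config$methods, scheme,
                             seed = derive_seed(config$seed, "clf"))
  base_scores <- features$score
  comparison <- compare_methods(base_scores, report,
                                setting = paste(attr(scores, "mode") %||%
                                                  "surrogate",
                                                config$cv_kind, sep = ","))
  metrics_path <- file.path(config$outdir, "metrics.tsv")
  utils::write.table(format(comparison, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     metrics_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("evaluate", methods = paste(config$methods, collapse = ","),
       file = metrics_path)

  # manifest with content hashes
  files <- vapply(manifest, function(m) m$file, "")
  man <- data.frame(stage = names(manifest), file = basename(files),
                    md5 = unname(tools::md5sum(files)),
                    stringsAsFactors = FALSE)
  man_path <- file.path(config$outdir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(curated = cur, mapped = mapped, features = features,
                 report = report, comparison = comparison,
                 manifest = man, manifest_path = man_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
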