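#!/usr/bin/env Rscript
# Stage 5: assemble the 9-feature table.
#
# One row per peptide that has a locus, a bead in both cell-line
# structures and a baseline score: surrogate baseline score, <x, y, z>
# from each structure, and the two radial positions.
source("analysis/00_config.R")

mapped <- utils::read.table(file.path(cfg$outdir, "mapped.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
structures <- lapply(cfg$cell_lines, function(cl)
  read_structure_tsv(file.path(cfg$outdir, paste0("structure_", cl, ".tsv"))))
scores <- surrogate_score_table(mapped$peptide, mapped$allele)
ft <- assemble_features(mapped, structures, scores)
write_feature_tsv(ft, file.path(cfg$outdir, "features.tsv"))

cat(sprintf("Feature table: %d rows x %d features\n",
            nrow(ft), length(attr(ft, "feature_names"))))
cat("Dropped by reason:\n")
print(attr(ft, "dropped"))
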