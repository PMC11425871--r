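#!/usr/bin/env Rscript
# Stage 2: curate raw T-cell assay records into a labelled peptide dataset.
#
# Human class-II records, peptide length 11-30, canonical residues only;
# identical (peptide, allele) records merged by pooling assay counts;
# labels from the strict 70%/30% positive-rate rule; unknown alleles get
# the default DRB1*01:01.
source("analysis/00_config.R")

raw <- read_assay_tsv(file.path(cfg$input_dir, "assays.tsv"))
cur <- curate(raw, curation_config())
write_curated_tsv(cur, file.path(cfg$outdir, "curated.tsv"))

cat(sprintf("Curated %d raw records -> %d labelled peptides (%d with known allele)\n",
            nrow(raw), nrow(cur$full_dataset), nrow(cur$known_allele_dataset)))
cat("Exclusions by reason:\n")
print(cur$report)
cat(sprintf("Class balance: %d positive / %d negative\n",
            sum(cur$full_dataset$label == "positive"),
            sum(cur$full_dataset$label == "negative")))
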