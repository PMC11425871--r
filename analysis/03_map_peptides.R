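#!/usr/bin/env Rscript
# Stage 3: map curated peptides to genomic loci and 500 kb bins.
#
# Exact substring search against the protein FASTA, locus from the gene
# BED, bin from the locus midpoint.
source("analysis/00_config.R")

cur <- utils::read.table(file.path(cfg$outdir, "curated.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
ann <- load_annotation(file.path(cfg$input_dir, "proteins.fasta"),
                       file.path(cfg$input_dir, "genes.bed"))
mapped <- map_peptides(cur, ann, cfg$bin_size_bp)
utils::write.table(mapped, file.path(cfg$outdir, "mapped.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Mapped %d / %d peptides (%d unmapped dropped)\n",
            nrow(mapped), nrow(cur), attr(mapped, "n_unmapped")))
cat("Peptides per chromosome:\n")
print(table(mapped$chromosome))
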