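# neo3d — 3D-genome-augmented MHC-II neoantigen immunogenicity prediction

Peptides presented by MHC class II molecules trigger CD4+ T-cell
responses, but predicting which peptides are immunogenic from sequence
alone is unreliable — class-II ligands vary in length (11–30 residues) and
sequence baselines rarely clear AUC 0.6. `neo3d` implements an analysis
pipeline that asks whether the *genomic origin* of a peptide helps: the
DNA locus encoding each peptide is placed in reconstructed 3D genome
structures of two cell lines, and its chromatin coordinates and radial
nuclear position are added to a baseline predictor score before
classification.

The pipeline has six stages, each a package function driven by a numbered
script under `analysis/`:

1. **Curation** — T-cell assay records are filtered (human, class II,
   length 11–30, canonical residues), HLA allele names standardised to
   `locus*AA:BB`, identical (peptide, allele) records merged by pooling
   assay counts, and peptides labelled by positive rate: immuno-positive
   above 0.70, immuno-negative below 0.30, discarded in between. Unknown
   alleles default to `DRB1*01:01`.
2. **Genome mapping** — exact substring search of each peptide against a
   protein FASTA, locus from a gene BED, 500 kb bin from the locus
   midpoint.
3. **Compartment degree** — per chromosome, the Hi-C matrix is
   observed/expected-normalised and the leading eigenvector of its
   correlation matrix gives a per-bin chromatin-activity score (the A/B
   compartment signal).
4. **3D reconstruction** — one bead per 500 kb bin, one chain per
   chromosome; annealed gradient descent minimises harmonic bond +
   radial-bias + excluded-volume potentials, placing active bins nearer
   the nuclear center (optional pairwise contact-distance restraints).
5. **Feature assembly** — 9 features per peptide: baseline score,
   `<x, y, z>` in each cell-line structure, and the two radial positions
   `r = ||<x, y, z>||`.
6. **Evaluation** — KNN (K = 8), Gaussian-kernel SVM and logistic
   regression under repeated stratified 5-fold (or leave-one-out)
   cross-validation, reporting precision/recall/F1 at the best-F cutoff,
   AUPR and AUC, against the fixed baseline score.

Because the original inputs (a curated assay snapshot, a licensed
predictor, population Hi-C) cannot be redistributed, the package ships a
first-class synthetic-data module (`simulate_world()`) that generates
truth structures, power-law contact maps, gene annotations and labelled
peptide datasets from a declared logistic model — so every stage is
testable offline, including recovery of planted signal.

## Worked example

Run the staged analysis on a simulated study (1,000 peptides, two cell
lines, radial effect `b_rad = -2`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_curate.R
Rscript analysis/03_map_peptides.R
Rscript analysis/04_reconstruct.R
Rscript analysis/05_features.R
Rscript analysis/06_evaluate.R
```

Output of the final stage (means over 20 repeats of 5-fold CV):

```
     Method Precision Recall    F1  AUPR   AUC dAUC_mean dAUC_sd
   baseline     0.605  0.967 0.745 0.687 0.613     0.000 0.00000
 Plus3D-KNN     0.750  0.895 0.814 0.808 0.814     0.201 0.00936
 Plus3D-SVM     0.772  0.907 0.834 0.784 0.800     0.187 0.01412
  Plus3D-LR     0.739  0.902 0.812 0.739 0.746     0.133 0.01462
```

The baseline score alone reaches AUC 0.613 on the 159 labelled peptides
that survive curation; adding the six chromatin coordinates and two
radial positions lifts every classifier well above it (KNN gains 0.20
AUC), recovering the planted radial effect through the full pipeline —
curation, mapping, compartment estimation and reconstruction included.
Earlier stages print their own summaries (exclusion counts by reason,
mapping rate, per-cell-line radial-target fidelity and bond satisfaction).

The same run is available as a single call:

```r
library(neo3d)
cfg <- run_config(input_dir = "results/input", outdir = "results/run",
                  seed = 20240926L)
simulate_inputs(cfg, n_peptides = 1000L)
res <- run_pipeline(cfg)   # writes stage TSVs + an MD5-hashed manifest
res$comparison
```

All randomness derives from the one master seed; two runs with the same
seed produce byte-identical outputs.

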