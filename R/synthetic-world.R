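# Synthetic-world generators: ground-truth 3D structures, contact maps,
# gene annotations and labelled peptide assay records with the statistical
# structure the downstream analysis assumes. Everything is deterministic
# given (params, seed).

#' Generate a confined bead-on-string genome structure
#'
#' Builds one polymer chain per chromosome as a confined random walk:
#' consecutive beads are exactly `bond_length` apart, every bead lies within
#' `nucleus_radius` of the origin, and beads of the same chain keep a small
#' minimum separation so the walk is self-avoiding in style. A step that
#' violates confinement or separation is resampled (up to 1,000 attempts),
#' after which the whole chain is restarted.
#'
#' @param n_chains number of chromosomes (chains).
#' @param beads_per_chain beads (bins) per chain.
#' @param bond_length fixed distance between consecutive beads.
#' @param nucleus_radius confinement radius of the nucleus.
#' @param seed integer seed; the walk is bit-reproducible given it.
#' @param cell_line label stored on the structure.
#' @param bin_size_bp genomic size of one bead, default 500 kb.
#' @return A `genome_structure`: list with `cell_line`, `chains` (named list
#'   of n-by-3 coordinate matrices, one per chromosome, genomic order),
#'   `nucleus_radius`, `bin_size_bp`.
#' @export
gen_structure <- function(n_chains, beads_per_chain, bond_length,
                          nucleus_radius, seed,
                          cell_line = "synthetic", bin_size_bp = 500000L) {
  if (n_chains < 1L || beads_per_chain < 2L)
    abort_input("need n_chains >= 1 and beads_per_chain >= 2")
  if (bond_length <= 0 || nucleus_radius <= 0)
    abort_input("bond_length and nucleus_radius must be positive")
  if (bond_length >= 2 * nucleus_radius)
    abort_input("bond_length >= 2 * nucleus_radius: walk cannot stay confined")
  min_sep <- 0.3 * bond_length
  chains <- with_seed(seed, {
    lapply(seq_len(n_chains), function(ch) {
      repeat {
        coords <- .confined_walk(beads_per_chain, bond_length,
                                 nucleus_radius, min_sep)
        if (!is.null(coords)) break
      }
      dimnames(coords) <- list(NULL, c("x", "y", "z"))
      coords
    })
  })
  names(chains) <- paste0("chr", seq_len(n_chains))
  structure(
    list(cell_line = cell_line, chains = chains,
         nucleus_radius = nucleus_radius, bin_size_bp = as.integer(bin_size_bp)),
    class = "genome_structure")
}

# One attempt at a confined self-avoiding-style walk; NULL on failure.
.confined_walk <- function(n, bond, R, min_sep) {
  coords <- matrix(0, n, 3)
  # start uniform in nuclear volume (with a small margin), so chains -- and
  # hence gene loci -- span radial positions from center to periphery
  u <- stats::rnorm(3)
  coords[1L, ] <- u / sqrt(sum(u^2)) * (0.9 * R) * stats::runif(1)^(1 / 3)
  for (i in 2L:n) {
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      step <- stats::rnorm(3)
      step <- step / sqrt(sum(step^2)) * bond
      cand <- coords[i - 1L, ] + step
      if (sqrt(sum(cand^2)) > R) next
      if (i > 2L) {
        prev <- coords[seq_len(i - 2L), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        if (min(d2) < min_sep^2) next
      }
      coords[i, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) return(NULL) # restart chain
  }
  coords
}

#' @export
print.genome_structure <- function(x, ...) {
  cat(sprintf("genome_structure '%s': %d chain(s), %d beads, R = %g, bin = %d bp\n",
              x$cell_line, length(x$chains),
              sum(vapply(x$chains, nrow, 1L)), x$nucleus_radius, x$bin_size_bp))
  invisible(x)
}

#' Simulate Hi-C contact maps from a structure
#'
#' Intra-chromosomal expected counts follow a power law of 3D distance,
#' `lambda_ij` proportional to `d_ij^(-alpha)` for i != j, scaled so that
#' the total expected count over all chromosomes is `depth`. Observed counts
#' are Poisson draws, symmetrised, with zero diagonal.
#'
#' @param structure a `genome_structure`.
#' @param alpha distance decay exponent (> 0).
#' @param depth total expected count across the genome (> 0).
#' @param seed integer seed for the Poisson draws.
#' @return Named list of `contact_matrix` objects, one per chromosome. Each
#'   carries its expected-count matrix in attribute `"lambda"`.
#' @export
gen_contact_map <- function(structure, alpha, depth, seed) {
  stopifnot(inherits(structure, "genome_structure"))
  if (alpha <= 0 || depth <= 0) abort_input("alpha and depth must be positive")
  dists <- lapply(structure$chains, function(xyz) as.matrix(stats::dist(xyz)))
  for (chr in names(dists)) {
    d <- dists[[chr]]
    if (any(d[upper.tri(d)] == 0))
      abort_input("coincident beads (zero off-diagonal distance) in ", chr)
  }
  weights <- lapply(dists, function(d) {
    w <- d^(-alpha)
    diag(w) <- 0
    w
  })
  total_w <- sum(vapply(weights, function(w) sum(w[upper.tri(w)]), 1.0))
  maps <- with_seed(seed, {
    lapply(names(weights), function(chr) {
      # expected total count of unordered pair {i,j}; sums to depth genome-wide
      lam <- weights[[chr]] / total_w * depth
      n <- nrow(lam)
      counts <- matrix(0, n, n)
      ut <- upper.tri(lam)
      counts[ut] <- stats::rpois(sum(ut), lam[ut])
      counts <- counts + t(counts)
      cm <- contact_matrix(chr, counts, structure$bin_size_bp)
      attr(cm, "lambda") <- lam
      cm
    })
  })
  names(maps) <- names(weights)
  maps
}

# Fixed position-weight matrix for the surrogate baseline scorer: a
# deterministic 20 x 9 table, no RNG involved.
.surrogate_pwm <- function() {
  m <- outer(seq_along(AA_ALPHABET), 1:9,
             function(a, p) sin(0.7 * a * p) + 0.3 * cos(1.3 * a + p))
  rownames(m) <- AA_ALPHABET
  m
}

#' Surrogate baseline immunogenicity score
#'
#' A deterministic stand-in for a binding-affinity / eluted-ligand style
#' predictor: a fixed position-weight-matrix score over the peptide's
#' central 9-mer, min-max scaled to \[0, 1\] using the per-position extrema
#' of the matrix. Peptides shorter than 9 residues are rejected.
#'
#' @param peptides character vector of amino-acid strings (length >= 9).
#' @return Numeric scores in \[0, 1\].
#' @export
surrogate_baseline_score <- function(peptides) {
  pwm <- .surrogate_pwm()
  lo <- sum(apply(pwm, 2, min))
  hi <- sum(apply(pwm, 2, max))
  vapply(peptides, function(p) {
    n <- nchar(p)
    if (n < 9L) abort_input("peptide shorter than 9 residues: ", p)
    start <- (n - 9L) %/% 2L + 1L
    core <- strsplit(substr(p, start, start + 8L), "")[[1]]
    if (!all(core %in% AA_ALPHABET))
      abort_input("non-canonical residue in peptide: ", p)
    raw <- sum(pwm[cbind(match(core, AA_ALPHABET), 1:9)])
    (raw - lo) / (hi - lo)
  }, 1.0, USE.NAMES = FALSE)
}

#' Generate a gene annotation over a structure
#'
#' Places `n_genes` protein-coding genes uniformly on the structure's
#' chromosomes (coordinates 0-based half-open; a chromosome spans
#' `beads * bin_size_bp` bp) and draws random protein sequences from the
#' 20-letter alphabet. The genomic footprint is three bases per residue.
#'
#' @param structure a `genome_structure` giving chromosome extents.
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param protein_len integer range (min, max) of protein lengths.
#' @return data.frame (gene_id, chromosome, start_bp, end_bp, protein).
#' @export
gen_gene_table <- function(structure, n_genes, seed, protein_len = c(150L, 400L)) {
  stopifnot(inherits(structure, "genome_structure"), n_genes >= 1L)
  chroms <- names(structure$chains)
  nbins <- vapply(structure$chains, nrow, 1L)
  with_seed(seed, {
    chr_idx <- sample(length(chroms), n_genes, replace = TRUE)
    plen <- sample(seq(protein_len[1], protein_len[2]), n_genes, replace = TRUE)
    span <- 3L * plen
    chrom_len <- nbins[chr_idx] * structure$bin_size_bp
    start <- floor(stats::runif(n_genes) * pmax(1, chrom_len - span))
    protein <- vapply(plen, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), "")
    data.frame(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      chromosome = chroms[chr_idx],
      start_bp = as.numeric(start),
      end_bp = as.numeric(start + span),
      protein = protein,
      stringsAsFactors = FALSE)
  })
}

# HLA-II alleles the generator draws from, written in the varied raw styles
# seen in assay exports; the curation stage standardises them.
.raw_allele_pool <- c("HLA-DRB1*01:01", "DRB1_0401", "DRB1*07:01",
                      "HLA-DRB1-15-01", "DQB1*03:02", "DPB1_0401",
                      "DRB1*03:01")

#' Generate a labelled peptide assay dataset
#'
#' Cuts peptides of length 11-30 from the annotated proteins and draws
#' per-peptide assay outcomes from the declared logistic model: the
#' positive-assay probability is
#' `plogis(b0 + b_base * (s - mean(s)) + b_rad * (rbar - mean(rbar)))`,
#' where `s` is the surrogate baseline score of the peptide and `rbar` the
#' mean normalised radius (radius / nuclear radius) of its locus bead
#' across the supplied cell-line structures. The covariates are centred at
#' their means over the generated peptide set, so that `b0` controls the
#' class balance independently of the effect sizes and of the particular
#' structures drawn. A fraction of peptides is emitted as two separate records
#' (split assay counts) to exercise downstream merging, and a fraction
#' carries no allele annotation.
#'
#' @param structures named list of `genome_structure` objects (cell lines).
#' @param gene_table annotation from [gen_gene_table()].
#' @param n_peptides number of distinct peptides (>= 1).
#' @param effect_params list with `b0`, `b_base`, `b_rad`.
#' @param assays_per_peptide Bernoulli assay draws per peptide (>= 1).
#' @param seed integer seed.
#' @param unknown_allele_frac fraction of peptides with no allele recorded.
#' @param split_frac fraction of peptides split into two assay records.
#' @return data.frame of raw assay records (peptide, allele, n_positive,
#'   n_total, species, mhc_class) plus hidden truth columns (gene_id,
#'   baseline_score, mean_norm_radius, p_true) used only by tests.
#' @export
gen_peptide_dataset <- function(structures, gene_table, n_peptides,
                                effect_params = list(b0 = 0, b_base = 0.5,
                                                     b_rad = -2),
                                assays_per_peptide = 10L, seed = 1L,
                                unknown_allele_frac = 0.25, split_frac = 0.3) {
  if (n_peptides < 1L) abort_input("n_peptides must be >= 1")
  if (assays_per_peptide < 1L) abort_input("assays_per_peptide must be >= 1")
  usable <- gene_table[nchar(gene_table$protein) >= 11L, , drop = FALSE]
  if (nrow(usable) == 0L)
    abort_input("all proteins shorter than 11 residues; cannot cut peptides")
  stopifnot(is.list(structures), length(structures) >= 1L)

  with_seed(seed, {
    gi <- sample(nrow(usable), n_peptides, replace = TRUE)
    plen <- nchar(usable$protein[gi])
    len <- 11L + floor(stats::runif(n_peptides) * 20) # uniform on 11..30
    len <- pmin(len, plen)
    start <- 1L + floor(stats::runif(n_peptides) * (plen - len + 1))
    peptide <- substr(usable$protein[gi], start, start + len - 1L)

    s <- surrogate_baseline_score(peptide)
    mid_bp <- floor((usable$start_bp[gi] + usable$end_bp[gi]) / 2)
    rbar <- rowMeans(vapply(structures, function(st) {
      bin <- floor(mid_bp / st$bin_size_bp)
      vapply(seq_len(n_peptides), function(k) {
        b <- bead_lookup(st, usable$chromosome[gi[k]], bin[k])
        b["radius"] / st$nucleus_radius
      }, 1.0)
    }, numeric(n_peptides)))

    p <- stats::plogis(effect_params$b0 +
                         effect_params$b_base * (s - mean(s)) +
                         effect_params$b_rad * (rbar - mean(rbar)))
    npos <- stats::rbinom(n_peptides, assays_per_peptide, p)

    allele <- sample(.raw_allele_pool, n_peptides, replace = TRUE)
    allele[stats::runif(n_peptides) < unknown_allele_frac] <- ""
    split <- stats::runif(n_peptides) < split_frac & assays_per_peptide >= 2L

    rec <- function(idx, np, nt) data.frame(
      peptide = peptide[idx], allele = allele[idx],
      n_positive = np, n_total = nt,
      species = "Homo sapiens", mhc_class = "II",
      gene_id = usable$gene_id[gi[idx]],
      baseline_score = s[idx], mean_norm_radius = rbar[idx], p_true = p[idx],
      stringsAsFactors = FALSE)

    whole <- rec(which(!split), npos[!split], assays_per_peptide)
    halves <- NULL
    if (any(split)) {
      idx <- which(split)
      n1 <- assays_per_peptide %/% 2L
      # hypergeometric split of the drawn positives over the two records
      p1 <- stats::rhyper(length(idx), npos[idx],
                          assays_per_peptide - npos[idx], n1)
      halves <- rbind(rec(idx, p1, n1),
                      rec(idx, npos[idx] - p1, assays_per_peptide - n1))
    }
    out <- rbind(whole, halves)
    out[order(out$peptide, out$allele, -out$n_total), , drop = FALSE]
  })
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper bundling truth structures for each cell line, contact
#' maps derived from them, a gene annotation and a raw peptide assay table,
#' all from one seed.
#'
#' @param n_chains,beads_per_chain,bond_length,nucleus_radius walk geometry,
#'   see [gen_structure()].
#' @param cell_lines character vector of cell-line names (two by default,
#'   mirroring an embryonic-stem-cell / fibroblast pair).
#' @param n_genes,n_peptides annotation and dataset sizes.
#' @param alpha,depth contact-map parameters, see [gen_contact_map()].
#' @param effect_params,assays_per_peptide label model, see
#'   [gen_peptide_dataset()].
#' @param seed master seed; stage seeds are derived from it.
#' @return A `synthetic_world` list: `structures_truth`, `contact_maps`,
#'   `gene_table`, `peptide_table`, `effect_params`, `seed`.
#' @export
simulate_world <- function(n_chains = 6L, beads_per_chain = 25L,
                           bond_length = 1, nucleus_radius = 10,
                           cell_lines = c("ESC", "FIB"),
                           n_genes = 60L, n_peptides = 500L,
                           alpha = 1, depth = 1e6,
                           effect_params = list(b0 = 0, b_base = 0.5,
                                                b_rad = -2),
                           assays_per_peptide = 10L, seed = 1L) {
  structures <- lapply(seq_along(cell_lines), function(i)
    gen_structure(n_chains, beads_per_chain, bond_length, nucleus_radius,
                  seed = derive_seed(seed, paste0("structure_", i)),
                  cell_line = cell_lines[i]))
  names(structures) <- cell_lines
  maps <- lapply(seq_along(cell_lines), function(i)
    gen_contact_map(structures[[i]], alpha, depth,
                    seed = derive_seed(seed, paste0("contacts_", i))))
  names(maps) <- cell_lines
  genes <- gen_gene_table(structures[[1]], n_genes,
                          seed = derive_seed(seed, "genes"))
  peptides <- gen_peptide_dataset(structures, genes, n_peptides,
                                  effect_params, assays_per_peptide,
                                  seed = derive_seed(seed, "peptides"))
  structure(list(structures_truth = structures, contact_maps = maps,
                 gene_table = genes, peptide_table = peptides,
                 effect_params = effect_params, seed = seed),
            class = "synthetic_world")
}

#' Write a synthetic world to pipeline input files
#'
#' Emits every input format the pipeline consumes: assay records as TSV,
#' gene annotation as BED (0-based half-open) plus protein FASTA, contact
#' maps as COO TSV per cell line, and truth structures as structure TSV.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(assays = file.path(dir, "assays.tsv"),
                bed = file.path(dir, "genes.bed"),
                fasta = file.path(dir, "proteins.fasta"))
  assay_cols <- c("peptide", "allele", "n_positive", "n_total",
                  "species", "mhc_class")
  utils::write.table(world$peptide_table[, assay_cols], paths$assays,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- world$gene_table
  utils::write.table(
    data.frame(gt$chromosome, format(gt$start_bp, scientific = FALSE, trim = TRUE),
               format(gt$end_bp, scientific = FALSE, trim = TRUE), gt$gene_id),
    paths$bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(as.vector(rbind(paste0(">", gt$gene_id), gt$protein)), paths$fasta)
  for (cl in names(world$contact_maps)) {
    p <- file.path(dir, paste0("contacts_", cl, ".tsv"))
    write_contacts_coo(world$contact_maps[[cl]], p)
    paths[[paste0("contacts_", cl)]] <- p
  }
  for (cl in names(world$structures_truth)) {
    p <- file.path(dir, paste0("structure_", cl, ".tsv"))
    write_structure_tsv(world$structures_truth[[cl]], p)
    paths[[paste0("structure_", cl)]] <- p
  }
  invisible(paths)
}
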