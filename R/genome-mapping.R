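# Offline peptide-to-genome mapping: exact substring search of curated
# peptides against an annotated protein set (FASTA) with gene loci (BED),
# then 500 kb bin assignment by locus midpoint.

#' Load a protein annotation (FASTA + BED)
#'
#' Cross-references protein sequences (FASTA, one record per gene id) with
#' gene loci (BED, 0-based half-open, columns chrom/start/end/name). A BED
#' id without a FASTA record (or vice versa) is reported as unmatched and
#' excluded; a duplicated gene id in the BED is an error.
#'
#' @param fasta_path protein FASTA path.
#' @param bed_path gene BED path.
#' @return A `protein_annotation`: data.frame (gene_id, chromosome,
#'   start_bp, end_bp, protein) with attribute `unmatched` listing ids
#'   present on only one side.
#' @export
load_annotation <- function(fasta_path, bed_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  prot <- data.frame(gene_id = sub("\\s.*$", "", names(seqs)),
                     protein = as.character(seqs), stringsAsFactors = FALSE)
  if (anyDuplicated(prot$gene_id))
    abort_input("duplicate gene_id in FASTA: ",
                prot$gene_id[duplicated(prot$gene_id)][1])

  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 4L))
    abort_input("malformed BED line ", which(nf < 4L)[1],
                ": need at least 4 columns (chrom, start, end, name)")
  bed <- data.frame(
    chromosome = vapply(fields, `[`, "", 1L),
    start_bp = suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L))),
    end_bp = suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L))),
    gene_id = vapply(fields, `[`, "", 4L),
    stringsAsFactors = FALSE)
  bad <- which(!is.finite(bed$start_bp) | !is.finite(bed$end_bp))
  if (length(bad))
    abort_input("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(bed$end_bp <= bed$start_bp)
  if (length(bad))
    abort_input("BED line ", bad[1], ": end <= start")
  if (anyDuplicated(bed$gene_id))
    abort_input("duplicate gene_id in BED: ",
                bed$gene_id[duplicated(bed$gene_id)][1])

  ann <- merge(bed, prot, by = "gene_id", sort = TRUE)
  unmatched <- c(setdiff(bed$gene_id, prot$gene_id),
                 setdiff(prot$gene_id, bed$gene_id))
  ann <- ann[order(ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "unmatched") <- unmatched
  class(ann) <- c("protein_annotation", "data.frame")
  ann
}

#' Map one peptide to a genomic locus
#'
#' Exact substring search over all annotated proteins (the offline
#' equivalent of a stringent protein BLAST on literal epitopes). When a
#' peptide occurs in several genes the lexicographically smallest gene_id
#' wins; no hit returns NULL. A precomputed hit table (peptide -> gene_id)
#' can short-circuit the search for users who ran their own alignment.
#'
#' @param peptide amino-acid string (curated).
#' @param annotation a `protein_annotation`.
#' @param hit_table optional data.frame (peptide, gene_id) of precomputed
#'   hits.
#' @return list(chromosome, start_bp, end_bp, gene_id, match_quality) or
#'   NULL when no protein contains the peptide.
#' @export
map_peptide <- function(peptide, annotation, hit_table = NULL) {
  if (!is.null(hit_table)) {
    hit <- hit_table$gene_id[hit_table$peptide == peptide]
    if (length(hit)) {
      row <- annotation[annotation$gene_id == min(hit), , drop = FALSE]
      if (nrow(row) == 1L)
        return(list(chromosome = row$chromosome, start_bp = row$start_bp,
                    end_bp = row$end_bp, gene_id = row$gene_id,
                    match_quality = "exact"))
    }
    return(NULL)
  }
  hits <- which(vapply(annotation$protein,
                       function(p) grepl(peptide, p, fixed = TRUE),
                       TRUE, USE.NAMES = FALSE))
  if (length(hits) == 0L) return(NULL)
  row <- annotation[hits[order(annotation$gene_id[hits])[1L]], , drop = FALSE]
  list(chromosome = row$chromosome, start_bp = row$start_bp,
       end_bp = row$end_bp, gene_id = row$gene_id, match_quality = "exact")
}

#' Assign a locus to a genomic bin
#'
#' Bins are half-open fixed-size intervals; the locus is anchored by the
#' midpoint of its gene: `bin = floor(midpoint / bin_size_bp)`.
#'
#' @param locus list with chromosome, start_bp, end_bp (as returned by
#'   [map_peptide()]).
#' @param bin_size_bp bin size in bp (> 0).
#' @return list(chromosome, bin_index).
#' @export
locus_to_bin <- function(locus, bin_size_bp = 500000L) {
  if (bin_size_bp <= 0) abort_input("bin_size_bp must be positive")
  mid <- floor((locus$start_bp + locus$end_bp) / 2)
  list(chromosome = locus$chromosome,
       bin_index = as.integer(mid %/% bin_size_bp))
}

#' Map a curated peptide table to loci and bins
#'
#' Vectorised driver over [map_peptide()] and [locus_to_bin()]; unmapped
#' peptides are dropped with a logged count.
#'
#' @param curated data.frame with a `peptide` column (from [curate()]).
#' @param annotation a `protein_annotation`.
#' @param bin_size_bp bin size in bp.
#' @param hit_table optional precomputed hit table, see [map_peptide()].
#' @return data.frame of curated rows joined with (chromosome, start_bp,
#'   end_bp, gene_id, bin_index); attribute `n_unmapped` counts drops.
#' @export
map_peptides <- function(curated, annotation, bin_size_bp = 500000L,
                         hit_table = NULL) {
  loci <- lapply(curated$peptide, map_peptide, annotation = annotation,
                 hit_table = hit_table)
  mapped <- !vapply(loci, is.null, TRUE)
  out <- curated[mapped, , drop = FALSE]
  if (nrow(out)) {
    li <- loci[mapped]
    out$chromosome <- vapply(li, `[[`, "", "chromosome")
    out$start_bp <- vapply(li, `[[`, 1.0, "start_bp")
    out$end_bp <- vapply(li, `[[`, 1.0, "end_bp")
    out$gene_id <- vapply(li, `[[`, "", "gene_id")
    out$bin_index <- vapply(li, function(l)
      locus_to_bin(l, bin_size_bp)$bin_index, 1L)
  } else {
    out$chromosome <- character(0); out$start_bp <- numeric(0)
    out$end_bp <- numeric(0); out$gene_id <- character(0)
    out$bin_index <- integer(0)
  }
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}
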