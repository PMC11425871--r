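# Curation of raw T-cell assay records into labelled peptide datasets:
# species/class filtering, length and alphabet checks, HLA allele
# standardisation, record merging and positive-rate labelling.

#' Curation configuration
#'
#' Defaults follow the standard curation rules for MHC-II T-cell assay
#' data: human records of class II, peptide length 11-30, a peptide is
#' labelled immuno-positive when its positive-assay rate exceeds 0.70 and
#' immuno-negative when below 0.30 (rates in between are discarded as
#' ambiguous), and peptides without an allele annotation default to
#' DRB1*01:01.
#'
#' @param min_len,max_len peptide length bounds (residues).
#' @param pos_threshold,neg_threshold strict positive-rate thresholds.
#' @param default_allele allele assigned to unknown-allele peptides.
#' @param species_filter,mhc_class_filter record filters.
#' @param aggregate how to pool multiple records of one peptide-allele
#'   pair: "pooled" (sum counts, rate = sum pos / sum total) or "mean"
#'   (mean of per-record rates).
#' @return A `curation_config` list.
#' @export
curation_config <- function(min_len = 11L, max_len = 30L,
                            pos_threshold = 0.70, neg_threshold = 0.30,
                            default_allele = "DRB1*01:01",
                            species_filter = "Homo sapiens",
                            mhc_class_filter = "II",
                            aggregate = c("pooled", "mean")) {
  if (!(neg_threshold >= 0 && neg_threshold < pos_threshold &&
        pos_threshold <= 1))
    abort_input("need 0 <= neg_threshold < pos_threshold <= 1")
  if (min_len > max_len) abort_input("min_len > max_len")
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 pos_threshold = pos_threshold, neg_threshold = neg_threshold,
                 default_allele = default_allele,
                 species_filter = species_filter,
                 mhc_class_filter = mhc_class_filter,
                 aggregate = match.arg(aggregate)),
            class = "curation_config")
}

#' Screen peptides for non-canonical residues
#'
#' Uppercases each peptide and keeps those made solely of the 20 canonical
#' amino-acid letters; rejected entries report the first offending
#' character.
#'
#' @param peptides character vector.
#' @return list(kept = logical vector, peptide = uppercased peptides,
#'   reason = offending character or NA).
#' @export
check_illegal_peptides <- function(peptides) {
  up <- toupper(peptides)
  bad_char <- vapply(up, function(p) {
    ch <- strsplit(p, "")[[1]]
    bad <- ch[!(ch %in% AA_ALPHABET)]
    if (length(bad)) bad[1] else NA_character_
  }, "", USE.NAMES = FALSE)
  list(kept = is.na(bad_char) & nchar(up) > 0L, peptide = up,
       reason = bad_char)
}

#' Standardise an HLA allele name
#'
#' Accepts the separators `*`, `_`, `:`, `-` or none, an optional `HLA-`
#' prefix, and 1-2-digit (or fused 4-digit) group/protein fields, and
#' rewrites to the canonical `locus*AA:BB` form with two-digit zero
#' padding. Anything unparseable — including an empty string — maps to the
#' unknown marker `NA`.
#'
#' @param allele character vector of raw allele strings.
#' @return Character vector of standardised alleles, `NA` where unknown.
#' @export
modify_hla_type <- function(allele) {
  vapply(allele, function(a) {
    if (is.na(a)) return(NA_character_)
    a <- toupper(trimws(a))
    if (a == "") return(NA_character_)
    a <- sub("^HLA[-_*: ]", "", a)
    # locus = 2-3 letters + optional digit (DRB1, DQA1, DPB1, DR, ...)
    m <- regmatches(a, regexec(
      "^([A-Z]{2,3}[0-9]?)[*_:. -]?([0-9]{1,4})(?:[*_:. -]([0-9]{1,2}))?$", a))[[1]]
    if (length(m) == 0L) return(NA_character_)
    locus <- m[2]
    g1 <- m[3]
    g2 <- m[4]
    if (g2 == "") {
      if (nchar(g1) == 4L) { # fused form, e.g. 0101
        g2 <- substr(g1, 3, 4)
        g1 <- substr(g1, 1, 2)
      } else if (nchar(g1) == 3L) {
        return(NA_character_) # ambiguous split
      } else {
        return(NA_character_) # single field, no protein part
      }
    } else if (nchar(g1) > 2L) {
      return(NA_character_)
    }
    sprintf("%s*%02d:%02d", locus, as.integer(g1), as.integer(g2))
  }, "", USE.NAMES = FALSE)
}

#' Curate raw assay records into labelled peptide datasets
#'
#' Pipeline: species/class filter, length filter, alphabet check (after
#' uppercasing), allele standardisation, merge of identical
#' (peptide, allele) records by summing assay counts, positive-rate
#' labelling with strict thresholds (ambiguous rates discarded), and
#' default-allele assignment. Output is sorted by peptide then allele so
#' it is independent of input record order.
#'
#' @param records data.frame of raw assay records (peptide, allele,
#'   n_positive, n_total, species, mhc_class).
#' @param config a [curation_config()].
#' @return list with `full_dataset` (unknown alleles replaced by the
#'   default), `known_allele_dataset` (unknown-allele peptides excluded),
#'   and `report` (named exclusion counts by reason). Both datasets are
#'   data.frames (peptide, allele, label, positive_rate, n_assays).
#' @export
curate <- function(records, config = curation_config()) {
  empty <- data.frame(peptide = character(), allele = character(),
                      label = character(), positive_rate = numeric(),
                      n_assays = integer(), stringsAsFactors = FALSE)
  report <- c(species = 0L, mhc_class = 0L, length = 0L,
              illegal_residue = 0L, ambiguous_rate = 0L)
  if (is.null(records) || nrow(records) == 0L)
    return(list(full_dataset = empty, known_allele_dataset = empty,
                report = report))
  stopifnot(all(c("peptide", "allele", "n_positive", "n_total") %in%
                  names(records)))
  if (any(records$n_positive > records$n_total) || any(records$n_total < 1L))
    abort_input("invalid assay counts: need n_positive <= n_total, n_total >= 1")
  if (is.null(records$species)) records$species <- config$species_filter
  if (is.null(records$mhc_class)) records$mhc_class <- config$mhc_class_filter

  keep <- records$species == config$species_filter
  report["species"] <- sum(!keep)
  rec <- records[keep, , drop = FALSE]

  keep <- rec$mhc_class == config$mhc_class_filter
  report["mhc_class"] <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]

  len <- nchar(rec$peptide)
  keep <- len >= config$min_len & len <= config$max_len
  report["length"] <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]

  chk <- check_illegal_peptides(rec$peptide)
  report["illegal_residue"] <- sum(!chk$kept)
  rec$peptide <- chk$peptide
  rec <- rec[chk$kept, , drop = FALSE]

  if (nrow(rec) == 0L)
    return(list(full_dataset = empty, known_allele_dataset = empty,
                report = report))

  rec$allele_std <- modify_hla_type(rec$allele)
  key <- paste(rec$peptide, ifelse(is.na(rec$allele_std), "<unknown>",
                                   rec$allele_std), sep = "\r")
  pos <- tapply(rec$n_positive, key, sum)
  tot <- tapply(rec$n_total, key, sum)
  rate <- if (config$aggregate == "pooled") {
    as.numeric(pos / tot)
  } else {
    as.numeric(tapply(rec$n_positive / rec$n_total, key, mean))
  }
  parts <- strsplit(names(pos), "\r", fixed = TRUE)
  merged <- data.frame(
    peptide = vapply(parts, `[`, "", 1L),
    allele = vapply(parts, `[`, "", 2L),
    positive_rate = rate,
    n_assays = as.integer(tot),
    stringsAsFactors = FALSE)

  lab <- ifelse(merged$positive_rate > config$pos_threshold, "positive",
                ifelse(merged$positive_rate < config$neg_threshold,
                       "negative", NA))
  report["ambiguous_rate"] <- sum(is.na(lab))
  merged$label <- lab
  merged <- merged[!is.na(lab), , drop = FALSE]

  unknown <- merged$allele == "<unknown>"
  full <- merged
  full$allele[unknown] <- config$default_allele
  known <- merged[!unknown, , drop = FALSE]

  ord_cols <- c("peptide", "allele", "label", "positive_rate", "n_assays")
  full <- full[order(full$peptide, full$allele), ord_cols]
  known <- known[order(known$peptide, known$allele), ord_cols]
  rownames(full) <- rownames(known) <- NULL
  list(full_dataset = full, known_allele_dataset = known, report = report)
}

#' Write a curated dataset and its exclusion report
#' @param curated result of [curate()].
#' @param path output TSV path for the full dataset; the report is written
#'   next to it with suffix `.report.txt`.
#' @export
write_curated_tsv <- function(curated, path) {
  utils::write.table(curated$full_dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rep_path <- paste0(sub("\\.tsv$", "", path), ".report.txt")
  writeLines(c(sprintf("excluded_%s\t%d", names(curated$report),
                       curated$report),
               sprintf("curated_full\t%d", nrow(curated$full_dataset)),
               sprintf("curated_known_allele\t%d",
                       nrow(curated$known_allele_dataset))), rep_path)
}
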