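# Assembly of the 9-feature vector per peptide: one baseline score plus
# <x, y, z> coordinates from two cell-line structures and the two radial
# positions of the peptide's DNA locus bead.

#' Load a baseline score table
#'
#' Reads a TSV of (peptide, allele, score). A NetMHCIIpan-style
#' multi-column export is also accepted by naming the column to extract
#' via `score_column`. Duplicate (peptide, allele) keys keep the highest
#' score.
#'
#' @param path TSV path with a header row.
#' @param mode score provenance label: "BA", "EL" or "surrogate".
#' @param score_column column holding the score (default "score").
#' @return A `baseline_scores` data.frame (peptide, allele, score) with
#'   attributes `mode` and `score_column`.
#' @export
load_baseline_scores <- function(path, mode = c("surrogate", "BA", "EL"),
                                 score_column = "score") {
  mode <- match.arg(mode)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("peptide", "allele") %in% names(df)))
    abort_input("baseline table needs peptide and allele columns")
  if (!score_column %in% names(df))
    abort_input("baseline table lacks score column '", score_column, "'")
  raw <- df[[score_column]]
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(num))
  if (length(bad))
    abort_input("non-numeric score at row ", bad[1], ": '", raw[bad[1]], "'")
  df$score <- num
  df <- df[order(df$peptide, df$allele, -df$score), c("peptide", "allele",
                                                      "score")]
  dup <- duplicated(df[, c("peptide", "allele")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "mode") <- mode
  attr(df, "score_column") <- score_column
  attr(df, "n_duplicates_dropped") <- sum(dup)
  class(df) <- c("baseline_scores", "data.frame")
  df
}

#' Baseline scores from the surrogate scorer
#'
#' Convenience constructor scoring peptides directly with
#' [surrogate_baseline_score()] instead of reading a file.
#' @param peptides,alleles parallel character vectors.
#' @return A `baseline_scores` data.frame.
#' @export
surrogate_score_table <- function(peptides, alleles) {
  df <- data.frame(peptide = peptides, allele = alleles,
                   score = surrogate_baseline_score(peptides),
                   stringsAsFactors = FALSE)
  df <- unique(df[order(df$peptide, df$allele), , drop = FALSE])
  rownames(df) <- NULL
  attr(df, "mode") <- "surrogate"
  class(df) <- c("baseline_scores", "data.frame")
  df
}

#' Assemble the 9-feature table
#'
#' Inner join of curated peptides with their locus bin, a bead in each of
#' the two structures, and a baseline score. Feature order is fixed:
#' score, then x/y/z of the first structure, x/y/z of the second, then the
#' two radii (Euclidean norms of the coordinate triples). Peptides missing
#' any ingredient are dropped with a reason count.
#'
#' @param mapped data.frame from [map_peptides()] (curated + bin columns).
#' @param structures list of exactly two `genome_structure` objects
#'   sharing a bin size.
#' @param scores a `baseline_scores` table.
#' @return A `feature_table` data.frame: peptide, allele, label, then the 9
#'   feature columns; attributes `feature_names` and `dropped` (named
#'   counts by reason).
#' @export
assemble_features <- function(mapped, structures, scores) {
  stopifnot(length(structures) == 2L)
  if (structures[[1]]$bin_size_bp != structures[[2]]$bin_size_bp)
    abort_input("structures have different bin sizes")
  cl <- vapply(structures, `[[`, "", "cell_line")
  if (cl[1] == cl[2]) cl <- paste0(cl, c(".1", ".2"))
  feat_names <- c("score",
                  paste0(cl[1], "_", c("x", "y", "z")),
                  paste0(cl[2], "_", c("x", "y", "z")),
                  paste0(cl[1], "_r"), paste0(cl[2], "_r"))

  dropped <- c(no_locus = 0L, no_bead = 0L, no_score = 0L)
  n <- nrow(mapped)
  score_key <- paste(scores$peptide, scores$allele, sep = "\r")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(mapped$bin_index[i])) {
      dropped["no_locus"] <- dropped["no_locus"] + 1L
      next
    }
    beads <- lapply(structures, function(st) {
      chain <- st$chains[[mapped$chromosome[i]]]
      if (is.null(chain) || mapped$bin_index[i] >= nrow(chain) ||
          mapped$bin_index[i] < 0L) return(NULL)
      bead_lookup(st, mapped$chromosome[i], mapped$bin_index[i])
    })
    if (any(vapply(beads, is.null, TRUE))) {
      dropped["no_bead"] <- dropped["no_bead"] + 1L
      next
    }
    s <- scores$score[match(paste(mapped$peptide[i], mapped$allele[i],
                                  sep = "\r"), score_key)]
    if (length(s) != 1L || is.na(s)) {
      dropped["no_score"] <- dropped["no_score"] + 1L
      next
    }
    rows[[i]] <- c(s,
                   beads[[1]][c("x", "y", "z")], beads[[2]][c("x", "y", "z")],
                   beads[[1]][["radius"]], beads[[2]][["radius"]])
  }
  keep <- !vapply(rows, is.null, TRUE)
  fm <- do.call(rbind, rows[keep])
  out <- data.frame(peptide = mapped$peptide[keep],
                    allele = mapped$allele[keep],
                    label = mapped$label[keep],
                    stringsAsFactors = FALSE)
  if (is.null(fm)) fm <- matrix(numeric(0), 0, 9)
  colnames(fm) <- feat_names
  out <- cbind(out, as.data.frame(fm))
  rownames(out) <- NULL
  attr(out, "feature_names") <- feat_names
  attr(out, "dropped") <- dropped
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature matrix and label vector from a feature table
#' @param features a `feature_table`.
#' @return list(x = numeric matrix n x 9, y = 0/1 integer labels).
#' @export
feature_matrix <- function(features) {
  fn <- attr(features, "feature_names")
  x <- as.matrix(features[, fn, drop = FALSE])
  y <- as.integer(features$label == "positive")
  list(x = x, y = y)
}

#' Write / read a feature table (TSV round-trip preserves column order)
#' @param features a `feature_table`.
#' @param path output path.
#' @export
write_feature_tsv <- function(features, path) {
  utils::write.table(format(features, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  attr(df, "feature_names") <- setdiff(names(df),
                                       c("peptide", "allele", "label"))
  class(df) <- c("feature_table", "data.frame")
  df
}
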