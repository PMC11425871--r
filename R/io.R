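# Plain-text readers/writers for pipeline inputs and outputs.

#' Write contact matrices as COO TSV
#'
#' One row per nonzero upper-triangle cell: chromosome, bin_i, bin_j, count
#' (0-based bins, i <= j). The first comment line records the bin size and
#' per-chromosome bin counts so the matrix shape round-trips.
#'
#' @param maps a `contact_matrix` or named list of them.
#' @param path output path.
#' @export
write_contacts_coo <- function(maps, path) {
  if (inherits(maps, "contact_matrix")) maps <- list(maps)
  names(maps) <- vapply(maps, function(m) m$chromosome, "")
  hdr <- sprintf("# bin_size_bp=%d %s", maps[[1]]$bin_size_bp,
                 paste(sprintf("%s=%d", names(maps),
                               vapply(maps, function(m) nrow(m$counts), 1L)),
                       collapse = " "))
  rows <- lapply(maps, function(m) {
    idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(chromosome = m$chromosome, bin_i = idx[, 1L] - 1L,
               bin_j = idx[, 2L] - 1L, count = m$counts[idx])
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "chromosome\tbin_i\tbin_j\tcount"), con)
  df <- do.call(rbind, rows)
  if (!is.null(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Read contact matrices from COO TSV
#'
#' Accepts the format written by [write_contacts_coo()]; without the shape
#' comment, matrix dimensions are inferred from the largest bin index.
#'
#' @param path input path.
#' @param bin_size_bp bin size override if no header comment is present.
#' @return Named list of `contact_matrix`.
#' @export
read_contacts_coo <- function(path, bin_size_bp = 500000L) {
  lines <- readLines(path)
  shape <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    kv <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
    kvp <- strsplit(kv, "=")
    vals <- stats::setNames(vapply(kvp, `[`, "", 2L), vapply(kvp, `[`, "", 1L))
    bin_size_bp <- as.integer(vals[["bin_size_bp"]])
    shape <- vals[setdiff(names(vals), "bin_size_bp")]
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  if (any(df$count < 0)) abort_input("negative count in ", path)
  chroms <- if (!is.null(shape)) names(shape) else unique(df$chromosome)
  maps <- lapply(chroms, function(chr) {
    sub <- df[df$chromosome == chr, , drop = FALSE]
    n <- if (!is.null(shape)) as.integer(shape[[chr]])
         else max(sub$bin_i, sub$bin_j) + 1L
    m <- matrix(0, n, n)
    m[cbind(sub$bin_i + 1L, sub$bin_j + 1L)] <- sub$count
    m[cbind(sub$bin_j + 1L, sub$bin_i + 1L)] <- sub$count
    contact_matrix(chr, m, bin_size_bp)
  })
  names(maps) <- chroms
  maps
}

#' Write a genome structure as TSV
#'
#' Columns: cell_line, chromosome, bin_index (0-based), x, y, z, radius.
#' @param structure a `genome_structure`.
#' @param path output path.
#' @export
write_structure_tsv <- function(structure, path) {
  rows <- do.call(rbind, lapply(names(structure$chains), function(chr) {
    m <- structure$chains[[chr]]
    data.frame(cell_line = structure$cell_line, chromosome = chr,
               bin_index = seq_len(nrow(m)) - 1L,
               x = m[, 1], y = m[, 2], z = m[, 3],
               radius = sqrt(rowSums(m^2)), stringsAsFactors = FALSE)
  }))
  hdr <- sprintf("# nucleus_radius=%g bin_size_bp=%d",
                 structure$nucleus_radius, structure$bin_size_bp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(rows, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a genome structure TSV written by [write_structure_tsv()]
#' @param path input path.
#' @return A `genome_structure`.
#' @export
read_structure_tsv <- function(path) {
  lines <- readLines(path)
  R <- 10
  bin_size <- 500000L
  if (startsWith(lines[1], "#")) {
    kv <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
    kvp <- strsplit(kv, "=")
    vals <- stats::setNames(vapply(kvp, `[`, "", 2L), vapply(kvp, `[`, "", 1L))
    R <- as.numeric(vals[["nucleus_radius"]])
    bin_size <- as.integer(vals[["bin_size_bp"]])
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  chains <- lapply(split(df, factor(df$chromosome, levels = unique(df$chromosome))),
                   function(sub) {
    sub <- sub[order(sub$bin_index), , drop = FALSE]
    m <- as.matrix(sub[, c("x", "y", "z")])
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  structure(list(cell_line = df$cell_line[1], chains = chains,
                 nucleus_radius = R, bin_size_bp = bin_size),
            class = "genome_structure")
}

#' Read raw assay records from TSV
#'
#' Expects columns peptide, allele, n_positive, n_total and optionally
#' species and mhc_class (defaulted to human / class II when absent).
#' @param path input path.
#' @return data.frame of raw assay records.
#' @export
read_assay_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = character())
  need <- c("peptide", "allele", "n_positive", "n_total")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_input("assay TSV missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$species)) df$species <- "Homo sapiens"
  if (is.null(df$mhc_class)) df$mhc_class <- "II"
  df
}
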