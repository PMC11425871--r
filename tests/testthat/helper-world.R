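# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small two-cell-line world: 2 chains x 40 beads, 60 genes, 300 peptides.
small_world <- function() {
  if (is.null(.fixtures$world))
    .fixtures$world <- simulate_world(n_chains = 2L, beads_per_chain = 40L,
                                      n_genes = 60L, n_peptides = 300L,
                                      seed = 101L)
  .fixtures$world
}

# Hand-built genome structure with beads at chosen coordinates.
manual_structure <- function(coords_by_chr, R = 10, bin_size = 500000L,
                             cell_line = "manual") {
  chains <- lapply(coords_by_chr, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  structure(list(cell_line = cell_line, chains = chains,
                 nucleus_radius = R, bin_size_bp = as.integer(bin_size)),
            class = "genome_structure")
}

# Random labelled score instances for metric oracles.
random_instance <- function(n, tie_prob = 0.3) {
  scores <- round(stats::runif(n), if (stats::runif(1) < tie_prob) 1 else 6)
  labels <- stats::rbinom(n, 1, 0.4)
  if (sum(labels) == 0) labels[1] <- 1L
  if (sum(labels) == n) labels[1] <- 0L
  list(scores = scores, labels = labels)
}
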