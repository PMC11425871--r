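# Generators: confined walks, power-law contact maps, logistic label model.

test_that("confined walk has exact bond lengths, confinement, seed determinism", {
  st <- gen_structure(1, 2, bond_length = 1.0, nucleus_radius = 5.0, seed = 7)
  expect_equal(sqrt(sum((st$chains$chr1[2, ] - st$chains$chr1[1, ])^2)), 1.0)

  st2 <- gen_structure(2, 50, 0.5, 5.0, seed = 1)
  radii <- bead_radii(st2)$radius
  expect_true(all(radii <= 5.0))
  bonds <- unname(unlist(lapply(st2$chains,
                                function(ch) sqrt(rowSums(diff(ch)^2)))))
  expect_equal(bonds, rep(0.5, length(bonds)), tolerance = 1e-12)

  st3 <- gen_structure(2, 50, 0.5, 5.0, seed = 1)
  expect_identical(st2$chains, st3$chains)
})

test_that("degenerate walk geometries are rejected", {
  expect_error(gen_structure(0, 10, 1, 5, seed = 1), "n_chains")
  expect_error(gen_structure(1, 10, -1, 5, seed = 1), "positive")
  expect_error(gen_structure(1, 10, 12, 5, seed = 1), "confined")
})

test_that("contact map follows the distance power law and is symmetric", {
  # beads on a line: d(1,2) = 1, d(1,3) = 2
  st <- manual_structure(list(chr1 = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))))
  maps <- gen_contact_map(st, alpha = 1, depth = 1e4, seed = 3)
  lam <- attr(maps$chr1, "lambda")
  expect_equal(lam[1, 2] / lam[1, 3], 2)
  m <- maps$chr1$counts
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))

  # Spearman(lambda, distance) is exactly -1 before Poisson sampling
  d <- chain_distances(st, "chr1")
  ut <- upper.tri(d)
  expect_equal(cor(lam[ut], d[ut], method = "spearman"), -1)
})

test_that("total contact count concentrates around the requested depth", {
  st <- gen_structure(1, 100, 1, 10, seed = 9)
  maps <- gen_contact_map(st, alpha = 1, depth = 1e6, seed = 4)
  total <- sum(maps$chr1$counts) / 2 # each pair stored twice
  expect_lt(abs(total - 1e6), 4 * sqrt(1e6))
})

test_that("coincident beads make the contact map ill-defined", {
  st <- manual_structure(list(chr1 = rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))))
  expect_error(gen_contact_map(st, 1, 1e4, seed = 1), "coincident")
})

test_that("peptide lengths are within 11-30 and generation is reproducible", {
  w <- small_world()
  lens <- nchar(w$peptide_table$peptide)
  expect_true(all(lens >= 11 & lens <= 30))

  again <- gen_peptide_dataset(w$structures_truth, w$gene_table, 300L,
                               w$effect_params,
                               seed = derive_seed(101L, "peptides"))
  expect_identical(w$peptide_table, again)
})

test_that("null label model gives positive-assay rate near one half", {
  w <- small_world()
  pep <- gen_peptide_dataset(w$structures_truth, w$gene_table, 2000L,
                             effect_params = list(b0 = 0, b_base = 0,
                                                  b_rad = 0),
                             seed = 5)
  rate <- sum(pep$n_positive) / sum(pep$n_total)
  expect_equal(rate, 0.5, tolerance = 0.03)
})

test_that("strong negative radial effect shows up as negative rank correlation", {
  w <- small_world()
  pep <- gen_peptide_dataset(w$structures_truth, w$gene_table, 500L,
                             effect_params = list(b0 = 0, b_base = 0,
                                                  b_rad = -8),
                             seed = 6)
  per_pep <- aggregate(cbind(n_positive, n_total) ~ peptide + mean_norm_radius,
                       pep, sum)
  rho <- cor(per_pep$mean_norm_radius,
             per_pep$n_positive / per_pep$n_total, method = "spearman")
  expect_lt(rho, 0)
})

test_that("short-protein annotation cannot yield peptides", {
  w <- small_world()
  stub <- data.frame(gene_id = "G1", chromosome = "chr1", start_bp = 0,
                     end_bp = 30, protein = "ACDEFGHIKL") # 10 residues
  expect_error(gen_peptide_dataset(w$structures_truth, stub, 10L, seed = 1),
               "shorter than 11")
})

test_that("logistic fit on assay counts recovers the radial coefficient", {
  w <- small_world()
  ep <- list(b0 = 0, b_base = 0.5, b_rad = -2)
  pep <- gen_peptide_dataset(w$structures_truth, w$gene_table, 5000L,
                             effect_params = ep, seed = 31,
                             split_frac = 0)
  fit <- glm(cbind(n_positive, n_total - n_positive) ~ baseline_score +
               mean_norm_radius, family = binomial(), data = pep)
  est <- coef(fit)[["mean_norm_radius"]]
  se <- summary(fit)$coefficients["mean_norm_radius", "Std. Error"]
  expect_lt(est, 0)
  expect_lt(abs(est - ep$b_rad), 2 * se)
})

test_that("surrogate scorer is deterministic, bounded and length-tolerant", {
  peps <- c("ACDEFGHIKLM", "WWWWWWWWWWWWWWW", "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL")
  s1 <- surrogate_baseline_score(peps)
  s2 <- surrogate_baseline_score(peps)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_error(surrogate_baseline_score("ACDEF"), "shorter")
})

test_that("a written world bundle round-trips through the readers", {
  w <- small_world()
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(unlist(paths))))

  maps <- read_contacts_coo(paths$contacts_ESC)
  expect_equal(maps$chr1$counts, w$contact_maps$ESC$chr1$counts)
  st <- read_structure_tsv(paths$structure_ESC)
  expect_equal(st$chains$chr2, w$structures_truth$ESC$chains$chr2,
               tolerance = 1e-12)
  assays <- read_assay_tsv(paths$assays)
  expect_equal(nrow(assays), nrow(w$peptide_table))
})
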