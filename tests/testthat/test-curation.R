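# Filtering, allele standardisation, merging and positive-rate labelling.

test_that("alphabet screen keeps canonical peptides and reports offenders", {
  res <- check_illegal_peptides(c("SIINFEKLAAYGG", "SIINFEKLAAXGG",
                                  "siinfeklaaygg", "ACDB"))
  expect_equal(res$kept, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$reason[2], "X")
  expect_equal(res$reason[4], "B")
  expect_equal(res$peptide[3], "SIINFEKLAAYGG") # uppercased before the check
})

test_that("allele names are standardised across separator styles", {
  raw <- c("HLA-DRB1*01:01", "DRB1_0101", "DRB1-15-01", "DRB10701",
           "DQB1*03:02", "dpb1_0401", "DRB1*4:1", "", "garbage", NA)
  expect_equal(modify_hla_type(raw),
               c("DRB1*01:01", "DRB1*01:01", "DRB1*15:01", "DRB1*07:01",
                 "DQB1*03:02", "DPB1*04:01", "DRB1*04:01",
                 NA, NA, NA))
})

# Twelve hand-built records exercising every exclusion reason and both labels.
curation_fixture <- function() {
  data.frame(
    peptide = c("ACDEFGHIKLM",                      # wrong species
                "ACDEFGHIKLMN",                     # MHC class I
                "ACDEFGHIKL",                       # too short (10)
                "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLM",  # too long (31)
                "ACDEFGHIKXM",                      # illegal residue X
                "CCDEFGHIKLM", "CCDEFGHIKLM",       # merged -> 8/10 positive
                "DCDEFGHIKLM",                      # 5/10 ambiguous
                "ECDEFGHIKLM",                      # 1/10 negative
                "FCDEFGHIKLM",                      # unknown allele, positive
                "GCDEFGHIKLM",                      # 0/8 negative
                "hcdefghiklm"),                     # lowercase, 2/10 negative
    allele = c("DRB1*01:01", "DRB1*01:01", "DRB1*01:01", "DRB1*01:01",
               "DRB1*01:01", "DRB1*01:01", "DRB1*01:01", "DRB1*01:01",
               "DQB1*03:02", "", "HLA-DRB1_0401", "DRB1*07:01"),
    n_positive = c(1, 1, 1, 1, 1, 3, 5, 5, 1, 9, 0, 2),
    n_total = c(2, 2, 2, 2, 2, 4, 6, 10, 10, 10, 8, 10),
    species = c("Mus musculus", rep("Homo sapiens", 11)),
    mhc_class = c("II", "I", rep("II", 10)),
    stringsAsFactors = FALSE)
}

test_that("hand-built assay table curates to the hand-derived dataset", {
  out <- curate(curation_fixture(), curation_config())
  expected_full <- data.frame(
    peptide = c("CCDEFGHIKLM", "ECDEFGHIKLM", "FCDEFGHIKLM", "GCDEFGHIKLM",
                "HCDEFGHIKLM"),
    allele = c("DRB1*01:01", "DQB1*03:02", "DRB1*01:01", "DRB1*04:01",
               "DRB1*07:01"),
    label = c("positive", "negative", "positive", "negative", "negative"),
    positive_rate = c(0.8, 0.1, 0.9, 0.0, 0.2),
    n_assays = c(10L, 10L, 10L, 8L, 10L),
    stringsAsFactors = FALSE)
  expect_equal(out$full_dataset, expected_full)
  expect_equal(out$known_allele_dataset,
               expected_full[expected_full$peptide != "FCDEFGHIKLM", ],
               ignore_attr = TRUE)
  expect_equal(out$report,
               c(species = 1L, mhc_class = 1L, length = 2L,
                 illegal_residue = 1L, ambiguous_rate = 1L))
})

test_that("boundary rates at the thresholds are discarded", {
  rec <- data.frame(peptide = c("ACDEFGHIKLM", "CCDEFGHIKLM", "DCDEFGHIKLM"),
                    allele = "DRB1*01:01",
                    n_positive = c(7, 3, 5), n_total = 10,
                    species = "Homo sapiens", mhc_class = "II",
                    stringsAsFactors = FALSE)
  out <- curate(rec)
  # 0.70 and 0.30 fail the strict inequalities; 0.50 is in between
  expect_equal(nrow(out$full_dataset), 0L)
  expect_equal(out$report[["ambiguous_rate"]], 3L)
})

test_that("pooled and mean aggregation differ when assay sizes differ", {
  rec <- data.frame(peptide = "ACDEFGHIKLM", allele = "DRB1*01:01",
                    n_positive = c(2, 9), n_total = c(4, 9),
                    species = "Homo sapiens", mhc_class = "II",
                    stringsAsFactors = FALSE)
  pooled <- curate(rec, curation_config(aggregate = "pooled"))
  averaged <- curate(rec, curation_config(aggregate = "mean"))
  expect_equal(pooled$full_dataset$positive_rate, 11 / 13)  # size-weighted
  expect_equal(averaged$full_dataset$positive_rate, 0.75)   # (0.5 + 1)/2
})

test_that("curation is order-independent and idempotent", {
  fx <- curation_fixture()
  out <- curate(fx)
  shuffled <- curate(fx[rev(seq_len(nrow(fx))), ])
  expect_identical(out$full_dataset, shuffled$full_dataset)

  # feed the curated output back through as raw records
  back <- data.frame(peptide = out$full_dataset$peptide,
                     allele = out$full_dataset$allele,
                     n_positive = round(out$full_dataset$positive_rate *
                                          out$full_dataset$n_assays),
                     n_total = out$full_dataset$n_assays,
                     species = "Homo sapiens", mhc_class = "II",
                     stringsAsFactors = FALSE)
  expect_equal(curate(back)$full_dataset, out$full_dataset)
})

test_that("every record lands in a curated peptide or a counted exclusion", {
  w <- small_world()
  out <- curate(w$peptide_table)
  merged_groups <- length(unique(paste(
    toupper(w$peptide_table$peptide),
    ifelse(modify_hla_type(w$peptide_table$allele) %in% NA, "<u>",
           modify_hla_type(w$peptide_table$allele)))))
  expect_equal(nrow(out$full_dataset) + out$report[["ambiguous_rate"]],
               merged_groups)
  # assay-count conservation within kept peptides
  key <- paste(toupper(w$peptide_table$peptide),
               modify_hla_type(w$peptide_table$allele))
  totals <- tapply(w$peptide_table$n_total, key, sum)
  kept_key <- paste(out$known_allele_dataset$peptide,
                    out$known_allele_dataset$allele)
  expect_equal(unname(out$known_allele_dataset$n_assays),
               unname(as.integer(totals[kept_key])))
})

test_that("known-allele dataset is a subset of the full dataset", {
  out <- curate(small_world()$peptide_table)
  full_key <- paste(out$full_dataset$peptide, out$full_dataset$allele)
  known_key <- paste(out$known_allele_dataset$peptide,
                     out$known_allele_dataset$allele)
  expect_true(all(known_key %in% full_key))
})

test_that("empty input produces empty outputs, not an error", {
  out <- curate(data.frame(peptide = character(), allele = character(),
                           n_positive = integer(), n_total = integer()))
  expect_equal(nrow(out$full_dataset), 0L)
  expect_equal(nrow(out$known_allele_dataset), 0L)
})
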