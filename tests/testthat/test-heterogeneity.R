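test_that("heterogeneity score follows the MAF x 2 / purity formula", {
  expect_equal(heterogeneity_score(0.30, 60), 1.0)
  expect_equal(heterogeneity_score(0.20, 80), 0.5)
  expect_equal(heterogeneity_score(0, 70), 0)
  # homogeneity: doubling MAF or halving cellularity doubles the score
  set.seed(3)
  maf <- runif(50, 0.01, 0.49)
  tc <- runif(50, 20, 99)
  expect_equal(heterogeneity_score(2 * maf, tc),
               2 * heterogeneity_score(maf, tc))
  expect_equal(heterogeneity_score(maf, tc / 2),
               2 * heterogeneity_score(maf, tc))
  expect_error(heterogeneity_score(1.4, 60), "\\[0, 1\\]")
  expect_error(heterogeneity_score(0.3, 0), "\\(0, 100\\]")
})

test_that("background classification partitions the score axis", {
  expect_equal(classify_background(c(0, 0.94, 0.95, 1.00, 1.05, 1.06, 1.5)),
               c("WT", "STC", "ATC", "ATC", "ATC", "CNV", "CNV"))
  # exhaustive grid over the (maf, tc) domain: exactly one label each,
  # consistent with the interval definition
  grid <- expand.grid(maf = seq(0, 1, by = 0.05),
                      tc = seq(5, 100, by = 5))
  hs <- heterogeneity_score(grid$maf, grid$tc)
  lab <- classify_background(hs)
  expect_true(all(lab %in% c("WT", "STC", "ATC", "CNV")))
  manual <- ifelse(hs == 0, "WT",
                   ifelse(hs < 0.95, "STC",
                          ifelse(hs <= 1.05, "ATC", "CNV")))
  expect_identical(lab, manual)
  expect_error(classify_background(-0.1), "non-negative")
})

test_that("paired locus comparison distinguishes inter, intra and none", {
  a <- make_assessment("C1", "APC", "c.1A>T", 0.6, 1.3)
  cmp <- compare_pair_locus(a[1, ], a[2, ])
  expect_equal(cmp$change_class, "inter_status")

  b <- make_assessment("C1", "APC", "c.1A>T", 1.2, 1.9)
  cmp <- compare_pair_locus(b[1, ], b[2, ])
  expect_equal(cmp$change_class, "intra_status")
  expect_equal(cmp$delta_hs, 0.7)

  d <- make_assessment("C1", "APC", "c.1A>T", 1.2, 1.4)
  expect_equal(compare_pair_locus(d[1, ], d[2, ])$change_class, "none")

  e2 <- make_assessment("C2", "APC", "c.1A>T", 1.2, 1.4)
  expect_error(compare_pair_locus(b[1, ], e2[2, ]), "mismatched")
})

test_that("discordance summary reproduces the designed 41-of-58 cohort", {
  cmp <- make_comparisons(22, 19, 17)
  ds <- discordance_summary(cmp, rounding = "three_decimals")
  expect_equal(unname(ds$counts), c(22, 19, 17))
  expect_equal(ds$discordant, 41)
  expect_equal(ds$denominator, 58)
  expect_equal(ds$z, 6.927, tolerance = 1e-3)
  expect_equal(ds$test$difference, 0.414, tolerance = 1e-12)
})

test_that("discordance summary boundaries give fractions 0 and 1", {
  all_none <- make_comparisons(0, 0, 10)
  ds0 <- discordance_summary(all_none)
  expect_equal(ds0$proportion, 0)
  expect_equal(ds0$z, -Inf)

  all_disc <- make_comparisons(6, 4, 0)
  ds1 <- discordance_summary(all_disc)
  expect_equal(ds1$proportion, 1)
  expect_equal(ds1$z, Inf)

  half <- discordance_summary(make_comparisons(5, 5, 10))
  expect_equal(half$z, 0)
  expect_error(discordance_summary(make_comparisons(0, 0, 0)), "empty")
})

test_that("denominator policy drops metastasis-private loci by default", {
  cmp <- make_comparisons(4, 0, 6)
  # add two metastasis-private loci (wild-type primary)
  extra <- data.frame(case_id = c("X1", "X2"), gene = "G",
                      hgvs_c = c("c.900A>T", "c.901A>T"),
                      status_primary = "WT", status_metastasis = "STC",
                      hs_primary = 0, hs_metastasis = 0.5,
                      delta_hs = 0.5, change_class = "inter_status",
                      stringsAsFactors = FALSE)
  cmp <- rbind(cmp, extra)
  expect_equal(discordance_summary(cmp)$denominator, 10)
  expect_equal(discordance_summary(cmp, "union_loci")$denominator, 12)
})

test_that("the packaged mutation profile satisfies all four headline counts
          at once", {
  calls <- as_mutation_calls(load_fixture("table1"))
  mc <- mutation_concordance(calls)
  expect_equal(mc$total_loci, 60)
  expect_equal(mc$identical_loci, 54)
  expect_equal(sum(calls$present[calls$role == "primary"]), 58)
  expect_equal(sum(calls$present[calls$role == "metastasis"]), 56)
  expect_equal(mc$private_primary, 4)
  expect_equal(mc$private_metastasis, 2)
})

test_that("single-pair concordance edge cases", {
  one <- data.frame(case_id = "C1", role = c("primary", "metastasis"),
                    gene = "TP53", hgvs_c = "c.1A>T",
                    present = c(TRUE, TRUE), stringsAsFactors = FALSE)
  expect_equal(mutation_concordance(one)$identical_loci, 1)

  one$present <- c(TRUE, FALSE)
  mc <- mutation_concordance(one)
  expect_equal(mc$identical_loci, 0)
  expect_equal(mc$private_primary, 1)

  expect_error(mutation_concordance(one[1, ]), "only one role")
})

test_that("gene frequencies count cases over the full cohort", {
  calls <- as_mutation_calls(load_fixture("table1"))
  gf <- gene_frequencies(calls)
  expect_equal(gf$pct_cases[gf$gene == "TP53"], 86)
  expect_equal(gf$n_cases[gf$gene == "TP53"], 19)
  expect_equal(gf$pct_cases[gf$gene == "PIK3CA"], 9)
  expect_equal(gf$pct_cases[gf$gene == "SMAD4"], 9)
  # per-gene locus counts over the combined groups sum to the 60 total
  expect_equal(sum(gf$n_mutations), 60)
  expect_equal(gf$n_mutations[gf$gene == "APC"], 18)
  expect_equal(gf$n_mutations[gf$gene == "KRAS"], 10)

  solo <- data.frame(case_id = "C1", role = c("primary", "metastasis"),
                     gene = "KRAS", hgvs_c = "c.35G>A",
                     present = c(TRUE, TRUE), stringsAsFactors = FALSE)
  expect_equal(gene_frequencies(solo)$pct_cases, 100)
})

test_that("MAFR is the ratio to the sample's top trunk driver", {
  calls <- data.frame(
    case_id = "C1", role = "primary",
    gene = c("APC", "TP53"), hgvs_c = c("c.1A>T", "c.2A>T"),
    present = TRUE, maf = c(0.40, 0.20), stringsAsFactors = FALSE)
  res <- mafr_table(calls)
  expect_equal(res$mafr[res$gene == "TP53"], 0.5)
  expect_equal(res$mafr[res$gene == "APC"], 1.0)
  expect_equal(unique(res$reference_gene), "APC")

  # exhaustive oracle on a 5-mutation sample
  set.seed(21)
  five <- data.frame(
    case_id = "C2", role = "metastasis",
    gene = c("APC", "KRAS", "TP53", "PIK3CA", "SMAD4"),
    hgvs_c = sprintf("c.%dA>T", 1:5), present = TRUE,
    maf = round(runif(5, 0.05, 0.6), 3), stringsAsFactors = FALSE)
  res <- mafr_table(five)
  ref <- max(five$maf[five$gene %in% c("APC", "KRAS", "NRAS", "BRAF")])
  expect_equal(res$mafr, five$maf / ref)

  # branch-driver fallback and no-driver warning
  tp_only <- five[five$gene %in% c("TP53", "PIK3CA"), ]
  res <- mafr_table(tp_only)
  expect_equal(unique(res$reference_gene), "TP53")
  expect_warning(out <- mafr_table(five[five$gene == "SMAD4", ]),
                 "no driver")
  expect_equal(nrow(out), 0)
})

test_that("paired correlation recovers a designed correlation", {
  expect_equal(correlate_pairs(1:10, 1:10)$r, 1)
  expect_equal(correlate_pairs(1:10, 10:1)$r, -1)
  set.seed(99)
  n <- 200
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  expect_lt(abs(correlate_pairs(x, y)$r - 0.8), 0.1)
})

test_that("the full mutation pipeline runs end to end with scores", {
  d <- simulation_design(n_pairs = 10)
  mut <- generate_mutation_cohort(d, 5)
  res <- run_mutation_analysis(mut$calls, mut$pairs)
  expect_s3_class(res, "mutation_results")
  expect_true(all(c("heterogeneity", "locus_comparisons", "mafr") %in%
                    names(res$tables)))
  expect_true(res$summary$discordant <= res$summary$denominator)
  out <- tempfile()
  paths <- write_reports(res, out)
  expect_true(file.exists(file.path(out, "locus_comparisons.tsv")))
  expect_true(file.exists(file.path(out, "summary.json")))
})
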