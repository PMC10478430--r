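test_that("mutation tables survive a write-read round trip", {
  d <- simulation_design(n_pairs = 4)
  mut <- generate_mutation_cohort(d, 2)
  path <- tempfile(fileext = ".tsv")
  write_mutation_table(mut$calls, path, mut$pairs)
  back <- read_mutation_table(path)
  expect_equal(back$calls[c("case_id", "role", "gene", "hgvs_c",
                            "present")],
               mut$calls[c("case_id", "role", "gene", "hgvs_c",
                           "present")])
  expect_equal(back$calls$maf, mut$calls$maf, tolerance = 1e-9)
  expect_equal(back$pairs$tc_primary,
               mut$pairs$tc_primary[match(back$pairs$case_id,
                                          mut$pairs$case_id)])
})

test_that("mutation reader enforces its schema and value contracts", {
  write_tsv <- function(lines) {
    p <- tempfile(fileext = ".tsv")
    writeLines(lines, p)
    p
  }
  header <- "case_id\trole\tgene\thgvs_c\tpresent\tmaf"

  # empty file with a valid header: empty collections, no error
  res <- read_mutation_table(write_tsv(header))
  expect_equal(nrow(res$calls), 0)
  expect_null(res$pairs)

  # missing required column is named
  expect_error(read_mutation_table(
    write_tsv(c("case_id\trole\tgene", "1\tprimary\tAPC"))), "hgvs_c")

  # out-of-range allele fraction names the row
  expect_error(read_mutation_table(write_tsv(c(
    header, "1\tprimary\tAPC\tc.1A>T\tTRUE\t1.4"))), "row\\(s\\) 1")

  # duplicate locus within a role
  expect_error(read_mutation_table(write_tsv(c(
    header,
    "1\tprimary\tAPC\tc.1A>T\tTRUE\t0.3",
    "1\tprimary\tAPC\tc.1A>T\tTRUE\t0.4"))), "duplicate")

  # presence and allele fraction must agree
  expect_error(read_mutation_table(write_tsv(c(
    header, "1\tprimary\tAPC\tc.1A>T\tFALSE\t0.3"))), "present = FALSE")

  # unknown columns ride along as annotations
  res <- read_mutation_table(write_tsv(c(
    paste0(header, "\tsift"),
    "1\tprimary\tAPC\tc.1A>T\tTRUE\t0.3\tDeleterious (0)")))
  expect_equal(res$calls$sift, "Deleterious (0)")
})

test_that("packaged fixtures load offline with the printed shapes", {
  t1 <- load_fixture("table1")
  expect_equal(nrow(t1), 60)
  expect_equal(length(attr(t1, "case_ids")), 22)
  # the case-4 CDH1 locus: mutant primary, wild-type metastasis
  cdh1 <- t1[t1$gene == "CDH1", ]
  expect_equal(cdh1$primary, "+")
  expect_equal(cdh1$metastasis, "Wild")
  # four primary-private and two metastasis-private loci
  expect_equal(sum(t1$primary == "+" & t1$metastasis == "Wild"), 4)
  expect_equal(sum(t1$primary == "Wild" & t1$metastasis == "+"), 2)

  t2 <- load_fixture("table2")
  expect_equal(nrow(t2), 21 * 6)
  p22 <- t2[t2$pair_id == "P22" & t2$mirna_id == "miRNA20a", ]
  expect_equal(c(p22$primary, p22$metastasis), c("NORMAL", "LOW"))

  t3 <- load_fixture("table3")
  expect_equal(dim(t3), c(21, 6))
  expect_equal(t3["P1", "miRNA31"], 0.016550802)

  expect_error(load_fixture("table9"), "valid names")
})

test_that("wide fixture expands to one call per locus and role", {
  calls <- as_mutation_calls(load_fixture("table1"))
  expect_equal(nrow(calls), 120)
  expect_equal(sort(unique(calls$role)), c("metastasis", "primary"))
  expect_true(all(c("sift", "polyphen", "fathmm") %in% names(calls)))
  expect_equal(length(attr(calls, "case_ids")), 22)
})

test_that("VCF pairs yield allele fractions from AF or AD", {
  pur <- data.frame(case_id = "C1", tc_primary = 80, tc_metastasis = 60)
  vcf <- write_test_vcf(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\tAF=0.5;GENE=TP53\tGT\t0/1",
    "chr2\t200\t.\tG\tC\t.\tPASS\tGENE=KRAS\tGT:AD\t0/1:30,10",
    "chr3\t300\t.\tC\tA,G\t.\tPASS\t.\tGT:AD\t1/2:10,5,5"))
  calls <- read_vcf_pair(vcf, vcf, pur)
  pri <- calls[calls$role == "primary", ]
  expect_equal(pri$maf[pri$gene == "TP53"], 0.5)
  expect_equal(pri$maf[pri$gene == "KRAS"], 0.25)
  # multi-allelic record split, keyed by position
  expect_equal(sort(pri$maf[grepl("^chr3", pri$gene)]), c(0.25, 0.25))
  expect_equal(nrow(pri), 4)
  expect_equal(unique(pri$tc), 80)
  expect_equal(unique(calls$tc[calls$role == "metastasis"]), 60)

  bad <- write_test_vcf("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1")
  expect_error(read_vcf_pair(bad, bad, pur), "neither a usable AF nor AD")
})

test_that("report writer emits tables plus an atomic JSON summary", {
  res <- list(tables = list(things = data.frame(a = 1:2, b = c("x", "y"))),
              summary = list(n = 2, flag = TRUE))
  out <- tempfile()
  write_reports(res, out)
  expect_true(file.exists(file.path(out, "things.tsv")))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(js$n, 2)
  expect_true(js$flag)
  # re-running overwrites cleanly
  write_reports(res, out)
  expect_equal(jsonlite::read_json(file.path(out, "summary.json"))$n, 2)

  # empty results still produce a summary
  empty_dir <- tempfile()
  write_reports(list(), empty_dir)
  expect_true(file.exists(file.path(empty_dir, "summary.json")))

  # an existing file path cannot serve as the output directory
  f <- tempfile(); writeLines("x", f)
  expect_error(write_reports(res, f), "not a directory")
})

test_that("config validates its thresholds", {
  cfg <- analysis_config()
  expect_equal(cfg$rr_high, 2)
  expect_equal(cfg$pm_re_cutoff, 2)
  expect_error(analysis_config(rr_high = -1), "positive")
  expect_error(analysis_config(pathway_fraction = 0), "\\(0, 1\\]")
  expect_error(analysis_config(hs_stc_max = 1.1, hs_atc_max = 1.0),
               "must not exceed")
})

test_that("the command-line wrapper reproduces the packaged analyses", {
  script <- system.file("scripts", "metconcord.R", package = "metconcord")
  expect_true(nzchar(script))
  out <- tempfile()
  res <- system2("Rscript", c(script, "reproduce", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  txt <- paste(res, collapse = "\n")
  expect_match(txt, "60 loci, identical 54")
  expect_match(txt, "z = 6.927")
  expect_true(file.exists(file.path(out, "summary.json")))
})
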