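# small in-code builders shared across test files

# an assessed-locus row pair (primary + metastasis) for comparison tests
make_assessment <- function(case_id, gene, hgvs, hs_p, hs_m) {
  data.frame(case_id = case_id, role = c("primary", "metastasis"),
             gene = gene, hgvs_c = hgvs, hs = c(hs_p, hs_m),
             status = classify_background(c(hs_p, hs_m)),
             stringsAsFactors = FALSE)
}

# a comparison table with designed change-class counts (all primary
# statuses non-wild-type so every locus enters the default denominator)
make_comparisons <- function(n_inter, n_intra, n_none) {
  n <- n_inter + n_intra + n_none
  if (n == 0) {
    return(data.frame(case_id = character(), gene = character(),
                      hgvs_c = character(), status_primary = character(),
                      status_metastasis = character(),
                      hs_primary = numeric(), hs_metastasis = numeric(),
                      delta_hs = numeric(), change_class = character()))
  }
  hs_p <- rep(0.6, n)
  hs_m <- c(rep(1.3, n_inter),   # STC -> CNV
            rep(0.05, n_intra),  # STC -> STC, dHS = 0.55
            rep(0.6, n_none))
  df <- data.frame(
    case_id = sprintf("C%03d", seq_len(n)), gene = "G",
    hgvs_c = sprintf("c.%dA>T", seq_len(n)),
    status_primary = classify_background(hs_p),
    status_metastasis = classify_background(hs_m),
    hs_primary = hs_p, hs_metastasis = hs_m,
    delta_hs = abs(hs_p - hs_m),
    stringsAsFactors = FALSE)
  df$change_class <- ifelse(df$status_primary != df$status_metastasis,
                            "inter_status",
                            ifelse(df$delta_hs >= 0.5, "intra_status",
                                   "none"))
  stopifnot(sum(df$change_class == "inter_status") == n_inter,
            sum(df$change_class == "intra_status") == n_intra,
            sum(df$change_class == "none") == n_none)
  df
}

# a minimal Ct table: one pooled normal plus paired tumours, built from
# designed per-(pair, miRNA) log2 fold changes (vs normal) on each role
make_ct_table <- function(fold_p, fold_m, tc_p, tc_m, ct_ref = 20,
                          baseline = 3, noise_sd = 0) {
  pairs <- rownames(fold_p)
  mir <- colnames(fold_p)
  row_block <- function(sample_id, role, folds, tc) {
    dil <- if (role == "normal") 0 else log2(100 / tc)
    mean_ct <- ct_ref + baseline - folds + dil
    reps <- matrix(rep(mean_ct, 3), ncol = 3)
    if (noise_sd > 0) reps <- reps + rnorm(length(reps), 0, noise_sd)
    data.frame(sample_id = sample_id, role = role, mirna_id = mir,
               ct_rep1 = reps[, 1], ct_rep2 = reps[, 2],
               ct_rep3 = reps[, 3], ct_rnu6b = ct_ref,
               stringsAsFactors = FALSE)
  }
  out <- list(row_block("N1", "normal", rep(0, length(mir)), NA))
  for (i in seq_along(pairs)) {
    out[[length(out) + 1L]] <- row_block(pairs[i], "primary",
                                         fold_p[i, ], tc_p[i])
    out[[length(out) + 1L]] <- row_block(pairs[i], "metastasis",
                                         fold_m[i, ], tc_m[i])
  }
  do.call(rbind, out)
}

# write a tiny VCF to a temp file and return its path
write_test_vcf <- function(body_lines) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(c(header, body_lines), path)
  path
}

# brute-force step-up BH evaluation used as an independent oracle
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) m / j * sorted[j], numeric(1)), 1)
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}
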