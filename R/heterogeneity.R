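#' Heterogeneity score of a somatic mutation
#'
#' HS = MAF x 2 / tumour-cell fraction. A heterozygous mutation carried by
#' every tumour cell in a perfectly pure sample gives HS = 1; stromal
#' dilution is cancelled by dividing by the tumour-cell fraction. Scores
#' above the clonal band indicate a copy-number background and are legal
#' (they are not capped).
#'
#' @param maf mutant allele fraction in \[0, 1\] (vectorised).
#' @param tc tumour cellularity in percent, in (0, 100\].
#' @return numeric vector of non-negative scores; 0 whenever `maf` is 0.
#' @examples
#' heterogeneity_score(0.30, 60)  # 1.0
#' @export
heterogeneity_score <- function(maf, tc) {
  if (any(is.na(maf)) || any(maf < 0 | maf > 1))
    stop("maf must lie in [0, 1]")
  if (any(is.na(tc)) || any(tc <= 0 | tc > 100))
    stop("tumour cellularity must lie in (0, 100]")
  maf * 2 / (tc / 100)
}

#' Classify the clonality background of a heterogeneity score
#'
#' Partitions the score axis into wild type (`WT`, HS = 0), subclonal
#' (`STC`, 0 < HS < 0.95), clonal (`ATC`, 0.95 <= HS <= 1.05) and
#' copy-number-variation background (`CNV`, HS > 1.05). The clonal band is
#' closed on both sides so the three positive ranges form a partition;
#' `WT` takes precedence at exactly 0.
#'
#' @param hs non-negative score(s).
#' @param stc_max,atc_max band bounds (see [analysis_config()]).
#' @return character vector of `"WT"`, `"STC"`, `"ATC"`, `"CNV"`.
#' @export
classify_background <- function(hs, stc_max = 0.95, atc_max = 1.05) {
  if (any(is.na(hs)) || any(hs < 0)) stop("hs must be non-negative")
  out <- rep("CNV", length(hs))
  out[hs <= atc_max] <- "ATC"
  out[hs < stc_max] <- "STC"
  out[hs == 0] <- "WT"
  out
}

#' Score and classify every mutation call
#'
#' Joins per-case tumour cellularities onto the call table, computes the
#' heterogeneity score for each call (0 for absent calls) and classifies
#' its background status.
#'
#' @param calls data.frame of mutation calls with `case_id`, `role`,
#'   `gene`, `hgvs_c`, `present` and `maf`.
#' @param pairs pair table with `case_id`, `tc_primary`, `tc_metastasis`;
#'   may be `NULL` if `calls` already carries a `tc` column.
#' @param config [analysis_config()] supplying the band bounds.
#' @return the call table with `tc`, `hs` and `status` columns appended.
#' @export
assess_heterogeneity <- function(calls, pairs = NULL,
                                 config = analysis_config()) {
  df <- calls
  if (!"tc" %in% names(df)) {
    if (is.null(pairs)) stop("need a 'tc' column or a pair table")
    tc_p <- stats::setNames(pairs$tc_primary, pairs$case_id)
    tc_m <- stats::setNames(pairs$tc_metastasis, pairs$case_id)
    df$tc <- ifelse(df$role == "primary",
                    tc_p[as.character(df$case_id)],
                    tc_m[as.character(df$case_id)])
  }
  if (!"maf" %in% names(df)) stop("calls need a 'maf' column")
  maf <- ifelse(df$present, df$maf, 0)
  df$hs <- heterogeneity_score(maf, df$tc)
  df$status <- classify_background(df$hs, config$hs_stc_max,
                                   config$hs_atc_max)
  df
}

#' Compare one locus between the members of a tumour pair
#'
#' An *inter-status* change is a different background label in primary and
#' metastasis; an *intra-status* change keeps the label but shifts the
#' score by at least `change_threshold` (0.5 by default: the shift seen
#' when the whole tumour-cell population gains or loses one mutant allele
#' copy). Anything else is `none`.
#'
#' @param a,b one-row data.frames (or lists) with `case_id`, `gene`,
#'   `hgvs_c`, `hs`, `status`; `a` the primary, `b` the metastasis.
#' @param change_threshold minimum absolute HS difference for an
#'   intra-status change.
#' @return one-row data.frame: `case_id`, `gene`, `hgvs_c`,
#'   `status_primary`, `status_metastasis`, `hs_primary`,
#'   `hs_metastasis`, `delta_hs`, `change_class`.
#' @export
compare_pair_locus <- function(a, b, change_threshold = 0.5) {
  if (!identical(as.character(a$case_id), as.character(b$case_id)) ||
      !identical(a$gene, b$gene) || !identical(a$hgvs_c, b$hgvs_c))
    stop("mismatched case or locus keys")
  delta <- abs(a$hs - b$hs)
  cls <- if (a$status != b$status) "inter_status"
         else if (delta >= change_threshold) "intra_status"
         else "none"
  data.frame(case_id = as.character(a$case_id), gene = a$gene,
             hgvs_c = a$hgvs_c, status_primary = a$status,
             status_metastasis = b$status, hs_primary = a$hs,
             hs_metastasis = b$hs, delta_hs = delta, change_class = cls,
             stringsAsFactors = FALSE)
}

#' Compare all loci of all tumour pairs
#'
#' Vectorised application of [compare_pair_locus()] to an assessed call
#' table. Every locus must be observed in both roles (the wild-type
#' member is an explicit call with `maf = 0`).
#'
#' @param assessments output of [assess_heterogeneity()].
#' @param change_threshold see [compare_pair_locus()].
#' @return data.frame of locus comparisons.
#' @export
compare_pairs <- function(assessments, change_threshold = 0.5) {
  need <- c("case_id", "role", "gene", "hgvs_c", "hs", "status")
  required_columns(assessments, need, "assessment table")
  p <- assessments[assessments$role == "primary", ]
  m <- assessments[assessments$role == "metastasis", ]
  kp <- paste(p$case_id, p$gene, p$hgvs_c, sep = "\r")
  km <- paste(m$case_id, m$gene, m$hgvs_c, sep = "\r")
  if (!setequal(kp, km) || anyDuplicated(kp) || anyDuplicated(km))
    stop("every locus must appear exactly once per role")
  m <- m[match(kp, km), ]
  delta <- abs(p$hs - m$hs)
  cls <- ifelse(p$status != m$status, "inter_status",
                ifelse(delta >= change_threshold, "intra_status", "none"))
  data.frame(case_id = as.character(p$case_id), gene = p$gene,
             hgvs_c = p$hgvs_c, status_primary = p$status,
             status_metastasis = m$status, hs_primary = p$hs,
             hs_metastasis = m$hs, delta_hs = delta, change_class = cls,
             stringsAsFactors = FALSE)
}

#' Summarise background-status discordance across a cohort
#'
#' Counts inter-status, intra-status and unchanged loci and tests the
#' discordant fraction (inter + intra) against its complement with
#' [one_proportion_z()]. The denominator defaults to loci detected in the
#' primary tumour (matching the study's 41-of-58 headline); `union_loci`
#' instead counts every locus mutant in either member.
#'
#' @param comparisons output of [compare_pairs()].
#' @param denominator_policy `"primary_loci"` or `"union_loci"`.
#' @param rounding handed to [one_proportion_z()].
#' @return list with `counts` (named vector inter/intra/none),
#'   `discordant`, `denominator`, `proportion` and `test` (a
#'   `"prop_test"`; at an all-or-none boundary `test` is `NULL` and `z`
#'   carries the infinite limit).
#' @export
discordance_summary <- function(comparisons,
                                denominator_policy = c("primary_loci",
                                                       "union_loci"),
                                rounding = c("none", "three_decimals")) {
  denominator_policy <- match.arg(denominator_policy)
  rounding <- match.arg(rounding)
  if (!nrow(comparisons)) stop("empty comparison collection")
  sel <- if (denominator_policy == "primary_loci")
    comparisons$status_primary != "WT"
  else comparisons$status_primary != "WT" | comparisons$status_metastasis != "WT"
  cc <- comparisons[sel, ]
  n <- nrow(cc)
  if (!n) stop("no loci left under the chosen denominator policy")
  counts <- c(inter = sum(cc$change_class == "inter_status"),
              intra = sum(cc$change_class == "intra_status"),
              none = sum(cc$change_class == "none"))
  k <- counts[["inter"]] + counts[["intra"]]
  if (k == 0 || k == n) {
    # complement null degenerates at the boundary; report the limit
    return(list(counts = counts, discordant = k, denominator = n,
                proportion = k / n, z = if (k == 0) -Inf else Inf,
                test = NULL))
  }
  test <- one_proportion_z(k, n, rounding = rounding)
  list(counts = counts, discordant = k, denominator = n,
       proportion = k / n, z = test$z, test = test)
}

#' Pairwise identity of mutation status
#'
#' A locus is *identical* between the members of its pair when it is
#' mutant in both or wild type in both. Calls must cover both roles for
#' every locus.
#'
#' @param calls long call table with `case_id`, `role`, `gene`, `hgvs_c`,
#'   `present`.
#' @return list with `identical_loci`, `total_loci`, `private_primary`,
#'   `private_metastasis`.
#' @examples
#' calls <- as_mutation_calls(load_fixture("table1"))
#' mutation_concordance(calls)  # 54 of 60 identical
#' @export
mutation_concordance <- function(calls) {
  p <- calls[calls$role == "primary", ]
  m <- calls[calls$role == "metastasis", ]
  kp <- paste(p$case_id, p$gene, p$hgvs_c, sep = "\r")
  km <- paste(m$case_id, m$gene, m$hgvs_c, sep = "\r")
  if (!setequal(kp, km))
    stop("locus observed for only one role; wild-type members must be ",
         "encoded explicitly")
  m <- m[match(kp, km), ]
  list(identical_loci = sum(p$present == m$present),
       total_loci = length(kp),
       private_primary = sum(p$present & !m$present),
       private_metastasis = sum(!p$present & m$present))
}

#' Per-gene mutation frequencies
#'
#' For each gene, the fraction of cases carrying at least one mutation in
#' either member of the pair (rounded to a whole percent) and the number
#' of distinct mutant loci across the combined tumour groups.
#'
#' @param calls long call table (see [mutation_concordance()]).
#' @param case_ids optional full case list; cases without any mutation
#'   (absent from `calls`) still count in the denominator. Defaults to
#'   the `case_ids` attribute of `calls`, else to the cases observed.
#' @return data.frame with `gene`, `n_cases`, `pct_cases`, `n_mutations`,
#'   sorted by decreasing frequency.
#' @export
gene_frequencies <- function(calls, case_ids = NULL) {
  if (is.null(case_ids)) case_ids <- attr(calls, "case_ids")
  if (is.null(case_ids)) case_ids <- unique(as.character(calls$case_id))
  n_cases_total <- length(unique(case_ids))
  if (n_cases_total < 1) stop("need at least one case")
  mut <- calls[calls$present, ]
  genes <- unique(mut$gene)
  res <- lapply(genes, function(g) {
    sub <- mut[mut$gene == g, ]
    ncase <- length(unique(as.character(sub$case_id)))
    nloci <- length(unique(paste(sub$case_id, sub$gene, sub$hgvs_c,
                                 sep = "\r")))
    data.frame(gene = g, n_cases = ncase,
               pct_cases = round(100 * ncase / n_cases_total),
               n_mutations = nloci, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$n_cases, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Mutant allele frequency ratios relative to a driver mutation
#'
#' Within each sample, every mutation's MAF is expressed as a ratio to the
#' MAF of that sample's reference driver, cancelling cellularity effects.
#' The driver is the highest-MAF present mutation among the trunk-driver
#' genes; when no trunk driver is mutant the branch-driver genes are used
#' as fallback. Samples without any driver are dropped with a warning.
#'
#' @param calls call table with `case_id`, `role`, `gene`, `hgvs_c`,
#'   `present`, `maf`.
#' @param trunk_genes trunk-driver gene set (early clonal drivers).
#' @param branch_genes fallback branch-driver gene set.
#' @return data.frame with `case_id`, `role`, `gene`, `hgvs_c`, `maf`,
#'   `mafr`, `reference_gene`, `reference_hgvs_c`.
#' @export
mafr_table <- function(calls,
                       trunk_genes = c("APC", "KRAS", "NRAS", "BRAF"),
                       branch_genes = "TP53") {
  required_columns(calls, c("case_id", "role", "gene", "hgvs_c",
                            "present", "maf"), "call table")
  mut <- calls[calls$present & !is.na(calls$maf) & calls$maf > 0, ]
  sample_key <- paste(mut$case_id, mut$role, sep = "\r")
  out <- list()
  for (s in unique(sample_key)) {
    sub <- mut[sample_key == s, ]
    drv <- sub[sub$gene %in% trunk_genes, ]
    if (!nrow(drv)) drv <- sub[sub$gene %in% branch_genes, ]
    if (!nrow(drv)) {
      warning("no driver mutation in sample ", sub$case_id[1], "/",
              sub$role[1], "; sample excluded from MAFR")
      next
    }
    ref <- drv[which.max(drv$maf), ]
    sub$mafr <- sub$maf / ref$maf
    sub$reference_gene <- ref$gene
    sub$reference_hgvs_c <- ref$hgvs_c
    out[[length(out) + 1L]] <-
      sub[c("case_id", "role", "gene", "hgvs_c", "maf", "mafr",
            "reference_gene", "reference_hgvs_c")]
  }
  if (!length(out))
    return(data.frame(case_id = character(), role = character(),
                      gene = character(), hgvs_c = character(),
                      maf = numeric(), mafr = numeric(),
                      reference_gene = character(),
                      reference_hgvs_c = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate a paired quantity between primary and metastasis
#'
#' Pearson correlation of matched per-locus values (heterogeneity scores
#' or MAF ratios). Delegates to [pearson_r()].
#'
#' @param values_primary,values_metastasis paired numeric vectors.
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
correlate_pairs <- function(values_primary, values_metastasis) {
  pearson_r(values_primary, values_metastasis)
}

#' Run the full somatic-mutation analysis
#'
#' Chains scoring, background classification, paired comparison,
#' discordance testing, presence/absence concordance, per-gene
#' frequencies, the MAFR table and the primary-metastasis HS correlation.
#' When `calls` carries no usable MAF (presence-only data) the
#' score-dependent stages are skipped.
#'
#' @param calls long call table.
#' @param pairs pair (cellularity) table, or `NULL`.
#' @param config an [analysis_config()].
#' @return object of class `"mutation_results"` with `tables` and
#'   `summary` components suitable for [write_reports()].
#' @export
run_mutation_analysis <- function(calls, pairs = NULL,
                                  config = analysis_config()) {
  concord <- mutation_concordance(calls)
  freqs <- gene_frequencies(calls)
  tables <- list(gene_frequencies = freqs)
  summary <- list(
    total_loci = concord$total_loci,
    identical_loci = concord$identical_loci,
    private_primary = concord$private_primary,
    private_metastasis = concord$private_metastasis,
    primary_mutations = concord$total_loci - concord$private_metastasis,
    metastasis_mutations = concord$total_loci - concord$private_primary
  )
  have_maf <- "maf" %in% names(calls) && any(!is.na(calls$maf))
  have_tc <- "tc" %in% names(calls) || !is.null(pairs)
  if (have_maf && have_tc) {
    assess <- assess_heterogeneity(calls, pairs, config)
    comp <- compare_pairs(assess, config$delta_hs_threshold)
    disc <- discordance_summary(comp, rounding = config$rounding)
    hs_p <- comp$hs_primary
    hs_m <- comp$hs_metastasis
    corr <- tryCatch(correlate_pairs(hs_p, hs_m), error = function(e) NULL)
    mafr <- mafr_table(assess)
    tables$heterogeneity <- assess
    tables$locus_comparisons <- comp
    tables$mafr <- mafr
    summary$discordant <- disc$discordant
    summary$denominator <- disc$denominator
    summary$discordant_fraction <- disc$proportion
    summary$z <- disc$z
    summary$p_value <- if (is.null(disc$test)) NA else disc$test$p_value
    summary$hs_flagged_above_2 <- sum(assess$hs > 2)
    if (!is.null(corr)) {
      summary$hs_r <- corr$r
      summary$hs_r_squared <- corr$r_squared
      summary$hs_p <- corr$p_value
    }
    result_extra <- list(discordance = disc, correlation = corr)
  } else {
    result_extra <- list(discordance = NULL, correlation = NULL)
  }
  structure(c(list(tables = tables, summary = summary,
                   concordance = concord), result_extra),
            class = "mutation_results")
}
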