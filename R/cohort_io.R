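#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline with the study's
#' defaults. Heterogeneity-score (HS) category bounds partition the score
#' axis into wild type (0), subclonal (0 < HS < `hs_stc_max`), clonal
#' (`hs_stc_max` <= HS <= `hs_atc_max`) and copy-number backgrounds
#' (HS > `hs_atc_max`).
#'
#' @param hs_stc_max upper (exclusive) HS bound of the subclonal band.
#' @param hs_atc_max upper (inclusive) HS bound of the clonal band.
#' @param delta_hs_threshold minimum absolute HS difference for an
#'   intra-status change between paired tumours.
#' @param rr_high,rr_low relative-ratio cutoffs for high/low miRNA
#'   expression (inclusive). The `0.5/1.5` pooled-normal preset can be
#'   selected by passing `rr_high = 1.5`.
#' @param pm_re_cutoff fold-change cutoff for an altered
#'   primary-to-metastasis expression ratio (inclusive, both directions).
#' @param pathway_fraction,pair_fraction,population_fraction the three
#'   inclusive >= 50% fractions of the pathway/pair/population cascade.
#' @param tc_direction sign convention for the tumour-cellularity
#'   correction of delta-delta-Ct values: `"scale_up"` multiplies the
#'   measured relative ratio by 100/TC (stromal dilution attenuates the
#'   tumour signal; dividing by the tumour fraction restores it),
#'   `"scale_down"` applies the opposite sign.
#' @param rounding rounding policy handed to [one_proportion_z()].
#' @param replicate_sd_warn warn when Ct replicate standard deviation
#'   exceeds this many cycles.
#' @param seed optional integer seed recorded for downstream generators.
#'
#' @return list of class `"metconcord_config"`.
#' @export
analysis_config <- function(hs_stc_max = 0.95,
                            hs_atc_max = 1.05,
                            delta_hs_threshold = 0.5,
                            rr_high = 2.0,
                            rr_low = 0.5,
                            pm_re_cutoff = 2.0,
                            pathway_fraction = 0.5,
                            pair_fraction = 0.5,
                            population_fraction = 0.5,
                            tc_direction = c("scale_up", "scale_down"),
                            rounding = c("none", "three_decimals"),
                            replicate_sd_warn = 0.5,
                            seed = NULL) {
  tc_direction <- match.arg(tc_direction)
  rounding <- match.arg(rounding)
  thresholds <- c(hs_stc_max = hs_stc_max, hs_atc_max = hs_atc_max,
                  delta_hs_threshold = delta_hs_threshold,
                  rr_high = rr_high, rr_low = rr_low,
                  pm_re_cutoff = pm_re_cutoff)
  if (any(thresholds <= 0))
    stop("all thresholds must be positive")
  fracs <- c(pathway_fraction, pair_fraction, population_fraction)
  if (any(fracs <= 0 | fracs > 1))
    stop("cascade fractions must lie in (0, 1]")
  if (hs_stc_max > hs_atc_max)
    stop("hs_stc_max must not exceed hs_atc_max")
  structure(
    list(hs_stc_max = hs_stc_max, hs_atc_max = hs_atc_max,
         delta_hs_threshold = delta_hs_threshold,
         rr_high = rr_high, rr_low = rr_low, pm_re_cutoff = pm_re_cutoff,
         pathway_fraction = pathway_fraction, pair_fraction = pair_fraction,
         population_fraction = population_fraction,
         tc_direction = tc_direction, rounding = rounding,
         replicate_sd_warn = replicate_sd_warn, seed = seed),
    class = "metconcord_config"
  )
}

required_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")))
  invisible(TRUE)
}

#' Read a paired somatic-mutation table
#'
#' Reads a tab-separated table with one row per mutation locus per tumour
#' role. Required columns: `case_id`, `role` (`primary`/`metastasis`),
#' `gene`, `hgvs_c`. Optional columns: `present` (logical or `+`/`Wild`),
#' `maf` (mutant allele fraction in \[0, 1\]), `tc` (tumour cellularity in
#' percent). Any further columns are preserved untouched as pass-through
#' annotations (e.g. SIFT/PolyPhen/FATHMM predictions).
#'
#' When `present` is absent it is derived from `maf > 0`. Tumour-pair
#' records (one row per case with both cellularities) are assembled from
#' the `tc` column when available.
#'
#' @param path path to a UTF-8, tab-separated file with a header row.
#' @return list with `calls` (data.frame of mutation calls) and `pairs`
#'   (data.frame with `case_id`, `tc_primary`, `tc_metastasis`, or `NULL`
#'   when no cellularity column is present).
#' @seealso [write_mutation_table()], [load_fixture()]
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  required_columns(df, c("case_id", "role", "gene", "hgvs_c"),
                   "mutation table")
  if (nrow(df) == 0) {
    return(list(calls = empty_calls(names(df)), pairs = NULL))
  }
  bad_role <- !df$role %in% c("primary", "metastasis")
  if (any(bad_role))
    stop("invalid role in row(s) ", paste(which(bad_role), collapse = ", "),
         ": must be 'primary' or 'metastasis'")

  if ("maf" %in% names(df)) {
    maf <- suppressWarnings(as.numeric(df$maf))
    bad <- !is.na(df$maf) & df$maf != "" & (is.na(maf) | maf < 0 | maf > 1)
    if (any(bad))
      stop("maf outside [0, 1] in row(s) ",
           paste(which(bad), collapse = ", "))
    df$maf <- maf
  }
  if ("tc" %in% names(df)) df$tc <- as.numeric(df$tc)
  if ("present" %in% names(df)) {
    df$present <- parse_presence(df$present)
  } else if ("maf" %in% names(df)) {
    df$present <- !is.na(df$maf) & df$maf > 0
  } else {
    stop("mutation table needs a 'present' or 'maf' column")
  }
  if ("maf" %in% names(df)) {
    bad <- !df$present & !is.na(df$maf) & df$maf > 0
    if (any(bad))
      stop("present = FALSE with maf > 0 in row(s) ",
           paste(which(bad), collapse = ", "))
  }

  key <- paste(df$case_id, df$role, df$gene, df$hgvs_c, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (case, role, gene, hgvs_c) in row(s) ",
         paste(which(duplicated(key)), collapse = ", "))

  pairs <- NULL
  if ("tc" %in% names(df)) pairs <- pairs_from_tc(df)
  list(calls = df, pairs = pairs)
}

parse_presence <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "+", "mutant", "present", "1")] <- TRUE
  out[x %in% c("false", "wild", "-", "absent", "0", "wt")] <- FALSE
  if (any(is.na(out)))
    stop("unrecognised presence value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

empty_calls <- function(nm) {
  df <- data.frame(case_id = character(), role = character(),
                   gene = character(), hgvs_c = character(),
                   present = logical(), stringsAsFactors = FALSE)
  df
}

pairs_from_tc <- function(df) {
  keep <- !is.na(df$tc)
  if (!any(keep)) return(NULL)
  agg <- unique(df[keep, c("case_id", "role", "tc")])
  chk <- table(paste(agg$case_id, agg$role))
  if (any(chk > 1))
    stop("inconsistent tumour cellularity within a (case, role)")
  wide <- stats::reshape(agg, idvar = "case_id", timevar = "role",
                         direction = "wide")
  names(wide) <- sub("^tc\\.", "tc_", names(wide))
  for (col in c("tc_primary", "tc_metastasis"))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  tc <- c(wide$tc_primary, wide$tc_metastasis)
  if (any(!is.na(tc) & tc <= 0))
    stop("tumour cellularity must be strictly positive")
  rownames(wide) <- NULL
  wide[c("case_id", "tc_primary", "tc_metastasis")]
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()]: writes calls (merging per-case
#' cellularities back into a `tc` column when `pairs` is given) as a
#' tab-separated UTF-8 file. A write-then-read round trip reproduces the
#' call collection field by field.
#'
#' @param calls data.frame of mutation calls.
#' @param path output path.
#' @param pairs optional pair table with `case_id`, `tc_primary`,
#'   `tc_metastasis`.
#' @export
write_mutation_table <- function(calls, path, pairs = NULL) {
  df <- calls
  if (!is.null(pairs)) {
    tc_p <- stats::setNames(pairs$tc_primary, pairs$case_id)
    tc_m <- stats::setNames(pairs$tc_metastasis, pairs$case_id)
    df$tc <- ifelse(df$role == "primary",
                    tc_p[as.character(df$case_id)],
                    tc_m[as.character(df$case_id)])
  }
  write_table_atomic(df, path, sep = "\t")
  invisible(path)
}

#' Read a tumour-pair (cellularity) table
#'
#' Tab-separated with columns `case_id`, `tc_primary`, `tc_metastasis`
#' (percentages in (0, 100\]).
#'
#' @param path input path.
#' @return data.frame of pair records.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required_columns(df, c("case_id", "tc_primary", "tc_metastasis"),
                   "pair table")
  df$case_id <- as.character(df$case_id)
  tc <- c(df$tc_primary, df$tc_metastasis)
  if (any(!is.na(tc) & (tc <= 0 | tc > 100)))
    stop("tumour cellularity must lie in (0, 100]")
  df
}

#' Read a qPCR Ct table
#'
#' Comma-separated with columns `sample_id`, `role`
#' (`normal`/`primary`/`metastasis`), `mirna_id`, replicate Ct columns
#' `ct_rep1`, `ct_rep2`, ... and the reference-gene Ct `ct_rnu6b`.
#'
#' @param path input path.
#' @return data.frame with the replicate columns left as read.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required_columns(df, c("sample_id", "role", "mirna_id", "ct_rnu6b"),
                   "Ct table")
  rep_cols <- grep("^ct_rep", names(df), value = TRUE)
  if (!length(rep_cols))
    stop("Ct table is missing required column(s): ct_rep1, ...")
  bad_role <- !df$role %in% c("normal", "primary", "metastasis")
  if (any(bad_role))
    stop("invalid role in row(s) ", paste(which(bad_role), collapse = ", "))
  ct <- as.matrix(df[rep_cols])
  if (any(!is.na(ct) & ct <= 0) || any(!is.na(df$ct_rnu6b) & df$ct_rnu6b <= 0))
    stop("Ct values must be positive")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read an RPPA intensity table
#'
#' Comma-separated with columns `sample_id`, `role`
#' (`primary`/`metastasis`), `marker`, `raw_signal`,
#' `total_protein_signal`.
#'
#' @param path input path.
#' @return data.frame of spot measurements.
#' @export
read_rppa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required_columns(df, c("sample_id", "role", "marker", "raw_signal",
                         "total_protein_signal"), "RPPA table")
  if (any(!df$role %in% c("primary", "metastasis")))
    stop("RPPA roles must be 'primary' or 'metastasis'")
  if (any(df$raw_signal < 0)) stop("raw_signal must be non-negative")
  if (any(df$total_protein_signal <= 0))
    stop("total_protein_signal must be strictly positive")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read matched VCF files for one tumour pair
#'
#' Loads the primary and metastatic VCFs of a single case and converts
#' each record to a mutation call. Mutant allele fraction is taken from
#' INFO `AF` when present, otherwise computed as alt-depth over total
#' depth from the first sample's FORMAT `AD`. Multi-allelic records are
#' split into one call per alternate allele. Loci are keyed by the INFO
#' `GENE` annotation when available, else by `CHROM:POS:REF:ALT`.
#'
#' @param vcf_primary,vcf_metastasis paths to VCF 4.x files.
#' @param purity one-row pair record (`case_id`, `tc_primary`,
#'   `tc_metastasis`).
#' @return data.frame of mutation calls (`case_id`, `role`, `gene`,
#'   `hgvs_c`, `present`, `maf`, `tc`).
#' @export
read_vcf_pair <- function(vcf_primary, vcf_metastasis, purity) {
  stopifnot(is.data.frame(purity), nrow(purity) == 1)
  p <- vcf_calls_one(vcf_primary, purity$case_id, "primary",
                     purity$tc_primary)
  m <- vcf_calls_one(vcf_metastasis, purity$case_id, "metastasis",
                     purity$tc_metastasis)
  rbind(p, m)
}

vcf_calls_one <- function(path, case_id, role, tc) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm)))  # single-record files come back as a bare vector
    fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(case_id = character(), role = character(),
                      gene = character(), hgvs_c = character(),
                      present = logical(), maf = numeric(), tc = numeric()))
  }
  info_af <- vcfR::extract.info(v, "AF")
  gene <- vcfR::extract.info(v, "GENE")
  ad <- NULL
  if (ncol(v@gt) >= 2) {
    gt_fields <- strsplit(v@gt[, 1], ":")
    smp <- strsplit(v@gt[, 2], ":")
    ad <- vapply(seq_along(gt_fields), function(i) {
      hit <- match("AD", gt_fields[[i]])
      if (is.na(hit) || hit > length(smp[[i]])) NA_character_
      else smp[[i]][hit]
    }, character(1))
  }

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- maf_for_record(info_af[i], if (is.null(ad)) NA else ad[i],
                          length(alts), i)
    for (j in seq_along(alts)) {
      key <- sprintf("%s:%s:%s:%s", fix$CHROM[i], fix$POS[i],
                     fix$REF[i], alts[j])
      g <- if (!is.null(gene) && !is.na(gene[i])) gene[i] else key
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = as.character(case_id), role = role, gene = g,
        hgvs_c = key, present = afs[j] > 0, maf = afs[j], tc = tc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

maf_for_record <- function(af, ad, n_alt, rec) {
  if (!is.na(af) && nzchar(af)) {
    vals <- as.numeric(strsplit(af, ",", fixed = TRUE)[[1]])
    if (length(vals) == n_alt) return(vals)
  }
  if (!is.na(ad) && nzchar(ad)) {
    d <- as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]])
    if (length(d) == n_alt + 1 && sum(d) > 0) return(d[-1] / sum(d))
  }
  stop("record ", rec, " carries neither a usable AF nor AD field")
}

#' Load a packaged study table
#'
#' The three printed data tables of the study ship with the package as
#' plain-text fixtures:
#' \describe{
#'   \item{`table1`}{somatic-mutation presence/absence profile: 60 loci
#'     across 22 paired cases (wide; `primary`/`metastasis` columns hold
#'     `+` or `Wild`). The full 22-case list, including the two
#'     mutation-free cases, is attached as `attr(, "case_ids")`.}
#'   \item{`table2`}{high/normal/low expression category per tumour for 6
#'     miRNAs in 21 pairs (long).}
#'   \item{`table3`}{primary-to-metastasis relative-expression ratios: a
#'     21 x 6 numeric matrix (pairs x miRNAs), values exactly as
#'     printed.}
#' }
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return see above.
#' @examples
#' nrow(load_fixture("table1"))            # 60 loci
#' load_fixture("table3")["P1", "miRNA31"] # 0.016550802
#' @export
load_fixture <- function(name) {
  valid <- c("table1", "table2", "table3")
  if (length(name) != 1 || !name %in% valid)
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  path <- function(f) system.file("extdata", f, package = "metconcord",
                                  mustWork = TRUE)
  switch(name,
    table1 = {
      df <- utils::read.delim(path("table1_mutations.tsv"), sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
      cases <- utils::read.delim(path("table1_cases.tsv"),
                                 colClasses = "character")
      attr(df, "case_ids") <- cases$case_id
      df
    },
    table2 = utils::read.csv(path("table2_mirna_categories.csv"),
                             stringsAsFactors = FALSE),
    table3 = {
      df <- utils::read.csv(path("table3_pm_re.csv"),
                            stringsAsFactors = FALSE)
      mirnas <- unique(df$mirna_id)
      pairs <- unique(df$pair_id)
      m <- matrix(NA_real_, length(pairs), length(mirnas),
                  dimnames = list(pairs, mirnas))
      m[cbind(df$pair_id, df$mirna_id)] <- df$pm_re
      m
    })
}

#' Convert the wide mutation fixture to long calls
#'
#' Expands one row per locus (with `primary` and `metastasis` presence
#' columns) into one mutation call per locus per role, carrying the
#' annotation columns along. The `case_ids` attribute of the input, when
#' present, is propagated.
#'
#' @param table1 wide table as returned by `load_fixture("table1")`.
#' @return data.frame of calls (`case_id`, `role`, `gene`, `hgvs_c`,
#'   `present`, annotations).
#' @export
as_mutation_calls <- function(table1) {
  required_columns(table1, c("case_id", "gene", "hgvs_c", "primary",
                             "metastasis"), "wide mutation table")
  ann <- setdiff(names(table1), c("case_id", "gene", "hgvs_c",
                                  "primary", "metastasis"))
  long <- function(role) {
    out <- table1[c("case_id", "gene", "hgvs_c", ann)]
    out$role <- role
    out$present <- parse_presence(table1[[role]])
    out[c("case_id", "role", "gene", "hgvs_c", "present", ann)]
  }
  res <- rbind(long("primary"), long("metastasis"))
  rownames(res) <- NULL
  attr(res, "case_ids") <- attr(table1, "case_ids")
  res
}

# write a data.frame atomically with a fixed dialect
write_table_atomic <- function(df, path, sep = "\t") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "", eol = "\n",
                     fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

#' Write per-item tables and a machine-readable summary
#'
#' Generic report writer for the three analysis result objects (see
#' [run_mutation_analysis()], [run_mirna_analysis()],
#' [run_rppa_analysis()]). Each tabular component is written as a
#' tab-separated file with a deterministic column order and every headline
#' statistic lands in `summary.json`. Re-running overwrites atomically.
#'
#' @param results a result object with `tables` (named list of
#'   data.frames) and `summary` (named list of scalars) components.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(results, outdir) {
  if (file.exists(outdir) && !dir.exists(outdir))
    stop("output path exists and is not a directory: ", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("could not create output directory: ", outdir)
  tables <- results$tables
  if (is.null(tables)) tables <- list()
  tables <- Filter(Negate(is.null), tables)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    write_table_atomic(tables[[nm]], p)
    paths <- c(paths, p)
  }
  summary <- results$summary
  if (is.null(summary)) summary <- list(n_tables = length(tables))
  sp <- file.path(outdir, "summary.json")
  tmp <- paste0(sp, ".tmp")
  jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  file.rename(tmp, sp)
  invisible(c(paths, sp))
}
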