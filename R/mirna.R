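#' Delta-delta-Ct relative quantification
#'
#' Two-step comparative Ct: per tissue, the target miRNA Ct is referenced
#' to the small-RNA reference gene (RNU6B), then the tumour's delta-Ct is
#' referenced to the normal-tissue delta-Ct. Amplification efficiency is
#' assumed to be 2 per cycle.
#'
#' @param ct_target_tumour,ct_ref_tumour mean replicate Ct of the target
#'   and reference gene in tumour tissue.
#' @param ct_target_normal,ct_ref_normal the same in normal tissue.
#' @return delta-delta-Ct (cycles); the relative ratio is
#'   `2^-delta_delta_ct`.
#' @examples
#' delta_delta_ct(19, 18, 21, 19)  # -1, i.e. twofold up
#' @export
delta_delta_ct <- function(ct_target_tumour, ct_ref_tumour,
                           ct_target_normal, ct_ref_normal) {
  vals <- c(ct_target_tumour, ct_ref_tumour, ct_target_normal,
            ct_ref_normal)
  if (any(is.na(vals))) stop("missing Ct value")
  if (any(vals <= 0)) stop("Ct values must be positive")
  (ct_target_tumour - ct_ref_tumour) - (ct_target_normal - ct_ref_normal)
}

#' Normalise a delta-delta-Ct value to 100% tumour cellularity
#'
#' Stromal admixture dilutes the tumour-derived signal in proportion to
#' the tumour-cell fraction, so the measured fold change is corrected by
#' the factor 100/TC on the linear scale, i.e. by `-log2(100/TC)` cycles
#' (the default `"scale_up"` direction). The correction is the identity at
#' TC = 100. The opposite sign convention is available for sensitivity
#' analysis.
#'
#' @param ddct delta-delta-Ct value(s).
#' @param tc tumour cellularity in percent, in (0, 100\].
#' @param direction `"scale_up"` (default; corrected relative ratio =
#'   measured ratio x 100/TC) or `"scale_down"`.
#' @return corrected delta-delta-Ct.
#' @examples
#' tc_normalise_ddct(0, 50)  # -1: RR doubles at 50% cellularity
#' @export
tc_normalise_ddct <- function(ddct, tc,
                              direction = c("scale_up", "scale_down")) {
  direction <- match.arg(direction)
  if (any(is.na(tc)) || any(tc <= 0 | tc > 100))
    stop("tumour cellularity must lie in (0, 100]")
  shift <- log2(100 / tc)
  if (direction == "scale_up") ddct - shift else ddct + shift
}

#' Categorise a relative expression ratio
#'
#' @param rr positive relative ratio(s), `2^-ddct`.
#' @param high_cutoff ratios `>=` this are `high` (default 2).
#' @param low_cutoff ratios `<=` this are `low` (default 0.5).
#' @return character vector of `"high"`, `"normal"`, `"low"`.
#' @export
categorise_rr <- function(rr, high_cutoff = 2.0, low_cutoff = 0.5) {
  if (any(is.na(rr)) || any(rr <= 0)) stop("relative ratios must be positive")
  ifelse(rr >= high_cutoff, "high", ifelse(rr <= low_cutoff, "low", "normal"))
}

#' Quantify miRNA expression from a Ct table
#'
#' Full per-sample chain: replicate means (warning when the replicate SD
#' exceeds `config$replicate_sd_warn` cycles), delta-Ct against the
#' reference gene, delta-delta-Ct against the normal-tissue baseline
#' (mean across normal samples per miRNA), cellularity correction,
#' relative ratio and high/normal/low category.
#'
#' @param ct Ct table as returned by [read_ct_table()]; tumour rows carry
#'   the case id as `sample_id`.
#' @param pairs pair table with per-case cellularities.
#' @param config an [analysis_config()].
#' @return data.frame of class `"expression_quant"` with one row per
#'   tumour sample x miRNA: `sample_id`, `role`, `mirna_id`, `delta_ct`,
#'   `delta_delta_ct`, `delta_delta_ct_tc`, `rr`, `category`.
#' @export
quantify_expression <- function(ct, pairs, config = analysis_config()) {
  rep_cols <- grep("^ct_rep", names(ct), value = TRUE)
  if (!length(rep_cols)) stop("no ct_rep* replicate columns")
  reps <- as.matrix(ct[rep_cols])
  ct$ct_mean <- rowMeans(reps, na.rm = TRUE)
  ct$ct_sd <- apply(reps, 1, stats::sd, na.rm = TRUE)
  n_noisy <- sum(!is.na(ct$ct_sd) & ct$ct_sd > config$replicate_sd_warn)
  if (n_noisy > 0)
    warning(n_noisy, " assay(s) with replicate Ct SD above ",
            config$replicate_sd_warn, " cycles")
  ct$delta_ct <- ct$ct_mean - ct$ct_rnu6b

  normal <- ct[ct$role == "normal", ]
  if (!nrow(normal)) stop("Ct table contains no normal-tissue rows")
  baseline <- tapply(normal$delta_ct, normal$mirna_id, mean)

  tum <- ct[ct$role != "normal", ]
  if (!nrow(tum)) stop("Ct table contains no tumour rows")
  miss <- setdiff(unique(tum$mirna_id), names(baseline))
  if (length(miss))
    stop("no normal baseline for miRNA(s): ", paste(miss, collapse = ", "))
  tum$delta_delta_ct <- tum$delta_ct -
    as.numeric(baseline[tum$mirna_id])

  tc_p <- stats::setNames(pairs$tc_primary, pairs$case_id)
  tc_m <- stats::setNames(pairs$tc_metastasis, pairs$case_id)
  tc <- unname(ifelse(tum$role == "primary", tc_p[tum$sample_id],
                      tc_m[tum$sample_id]))
  if (any(is.na(tc)))
    stop("missing tumour cellularity for sample(s): ",
         paste(unique(tum$sample_id[is.na(tc)]), collapse = ", "))
  tum$delta_delta_ct_tc <- tc_normalise_ddct(tum$delta_delta_ct, tc,
                                             config$tc_direction)
  tum$rr <- 2^(-tum$delta_delta_ct_tc)
  tum$category <- categorise_rr(tum$rr, config$rr_high, config$rr_low)
  out <- tum[c("sample_id", "role", "mirna_id", "delta_ct",
               "delta_delta_ct", "delta_delta_ct_tc", "rr", "category")]
  rownames(out) <- NULL
  class(out) <- c("expression_quant", "data.frame")
  out
}

#' Paired expression-category concordance per miRNA
#'
#' Builds the 3 x 3 (high/normal/low) contingency table of primary versus
#' metastasis categories for each miRNA and computes Cohen's kappa.
#' Structurally degenerate tables are reported undefined (see
#' [cohens_kappa()]).
#'
#' @param categories data.frame with `mirna_id`, `primary`, `metastasis`
#'   (categories, case-insensitive), one row per pair x miRNA — e.g.
#'   `load_fixture("table2")`.
#' @return data.frame with one row per miRNA (`kappa`, `se`, `ci_lo`,
#'   `ci_hi`, `po`, `pe`, `defined`); the full `"kappa_result"` objects
#'   are attached as `attr(, "kappas")`.
#' @export
concordance_by_mirna <- function(categories) {
  required_columns(categories, c("mirna_id", "primary", "metastasis"),
                   "category table")
  lv <- c("high", "normal", "low")
  pri <- tolower(categories$primary)
  met <- tolower(categories$metastasis)
  bad <- !(pri %in% lv) | !(met %in% lv)
  if (any(bad))
    stop("unknown category label(s): ",
         paste(unique(c(categories$primary, categories$metastasis)
                      [!c(pri, met) %in% lv]), collapse = ", "))
  mirnas <- unique(categories$mirna_id)
  kappas <- list()
  rows <- lapply(mirnas, function(id) {
    sel <- categories$mirna_id == id
    tab <- table(factor(pri[sel], levels = lv),
                 factor(met[sel], levels = lv))
    k <- withCallingHandlers(cohens_kappa(as.matrix(unclass(tab))),
                             warning = function(w) invokeRestart("muffleWarning"))
    kappas[[id]] <<- k
    data.frame(mirna_id = id, kappa = k$kappa, se = k$se,
               ci_lo = k$ci95[1], ci_hi = k$ci95[2], po = k$po, pe = k$pe,
               defined = k$defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "kappas") <- kappas
  out
}

#' Primary-to-metastasis relative-expression calls
#'
#' Forms the ratio PM-RE = RR(primary) / RR(metastasis) per pair and
#' miRNA and flags it *altered* when it reaches the fold-change cutoff in
#' either direction (inclusive: `pm_re >= cutoff` or `<= 1/cutoff`).
#' Supply either two relative-ratio tables or pre-computed ratios (the
#' printed study ratios are consumed as-is via `ratios`).
#'
#' @param rr_primary,rr_metastasis data.frames with `sample_id` (or
#'   `pair_id`), `mirna_id`, `rr`, matched by pair and miRNA.
#' @param ratios alternatively, a data.frame with `pair_id`, `mirna_id`,
#'   `pm_re`, or a pairs x miRNAs numeric matrix such as
#'   `load_fixture("table3")`.
#' @param cutoff fold-change cutoff (default 2).
#' @return list with `calls` (data.frame `pair_id`, `mirna_id`, `pm_re`,
#'   `altered`) and `counts` (data.frame `mirna_id`, `k`, `n`).
#' @examples
#' pm_re_calls(ratios = load_fixture("table3"))$counts
#' @export
pm_re_calls <- function(rr_primary = NULL, rr_metastasis = NULL,
                        ratios = NULL, cutoff = 2.0) {
  if (cutoff <= 1) stop("cutoff must exceed 1")
  if (is.null(ratios)) {
    if (is.null(rr_primary) || is.null(rr_metastasis))
      stop("supply either 'ratios' or both relative-ratio tables")
    idcol <- intersect(c("pair_id", "sample_id"), names(rr_primary))[1]
    kp <- paste(rr_primary[[idcol]], rr_primary$mirna_id, sep = "\r")
    km <- paste(rr_metastasis[[idcol]], rr_metastasis$mirna_id, sep = "\r")
    if (!setequal(kp, km)) stop("unmatched pairs between the RR tables")
    mm <- rr_metastasis[match(kp, km), ]
    ratios <- data.frame(pair_id = as.character(rr_primary[[idcol]]),
                         mirna_id = rr_primary$mirna_id,
                         pm_re = rr_primary$rr / mm$rr,
                         stringsAsFactors = FALSE)
  } else if (is.matrix(ratios)) {
    ratios <- data.frame(pair_id = rep(rownames(ratios), ncol(ratios)),
                         mirna_id = rep(colnames(ratios),
                                        each = nrow(ratios)),
                         pm_re = as.vector(ratios),
                         stringsAsFactors = FALSE)
  }
  required_columns(ratios, c("pair_id", "mirna_id", "pm_re"),
                   "PM-RE table")
  if (any(is.na(ratios$pm_re)) || any(ratios$pm_re <= 0))
    stop("PM-RE ratios must be positive")
  ratios$altered <- ratios$pm_re >= cutoff | ratios$pm_re <= 1 / cutoff
  counts <- stats::aggregate(altered ~ mirna_id, ratios,
                             function(x) sum(x))
  names(counts)[2] <- "k"
  nn <- stats::aggregate(altered ~ mirna_id, ratios, length)
  counts$n <- nn$altered[match(counts$mirna_id, nn$mirna_id)]
  # preserve the input miRNA order
  counts <- counts[match(unique(ratios$mirna_id), counts$mirna_id), ]
  rownames(counts) <- NULL
  list(calls = ratios, counts = counts)
}

#' Proportion tests for altered PM-RE counts
#'
#' One complement-null z-test per miRNA with Benjamini-Hochberg
#' adjustment across the tested family.
#'
#' @param counts data.frame with `mirna_id`, `k` (altered pairs) and
#'   optionally `n`, or a named integer vector of altered counts.
#' @param n number of pairs (used when `counts` lacks an `n` column).
#' @param rounding handed to [one_proportion_z()].
#' @return data.frame with `mirna_id`, `k`, `n`, `p_hat`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
pm_re_tests <- function(counts, n = NULL,
                        rounding = c("none", "three_decimals")) {
  rounding <- match.arg(rounding)
  if (!is.data.frame(counts))
    counts <- data.frame(mirna_id = names(counts), k = as.integer(counts),
                         stringsAsFactors = FALSE)
  if (!"n" %in% names(counts)) {
    if (is.null(n)) stop("supply 'n' when counts carry no n column")
    counts$n <- n
  }
  # at k = 0 or k = n the complement null degenerates; report the limit
  tests <- Map(function(k, n) {
    if (k == 0 || k == n)
      return(list(p_hat = k / n, z = if (k == 0) -Inf else Inf,
                  p_value = 0))
    one_proportion_z(k, n, rounding = rounding)
  }, counts$k, counts$n)
  out <- data.frame(
    mirna_id = counts$mirna_id, k = counts$k, n = counts$n,
    p_hat = vapply(tests, `[[`, numeric(1), "p_hat"),
    z = vapply(tests, `[[`, numeric(1), "z"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  out$p_adjusted <- bh_adjust(out$p_value)$adjusted
  out
}

#' Overall discordance rule across the miRNA panel
#'
#' The two tumour groups are called discordant overall when at least half
#' of the tested miRNAs show an altered PM-RE in at least half of the
#' pairs (both bounds inclusive).
#'
#' @param calls the `calls` component of [pm_re_calls()] (columns
#'   `mirna_id`, `altered`).
#' @return list with `fractions` (named per-miRNA altered fractions),
#'   `range` (min/max), and `discordant` (logical).
#' @export
overall_discordance <- function(calls) {
  if (!nrow(calls)) stop("empty PM-RE call table")
  required_columns(calls, c("mirna_id", "altered"), "PM-RE call table")
  fractions <- c(tapply(calls$altered, calls$mirna_id, mean))
  fractions <- fractions[unique(calls$mirna_id)]
  list(fractions = fractions, range = range(fractions),
       discordant = mean(fractions >= 0.5) >= 0.5)
}

#' Run the full miRNA concordance analysis
#'
#' From a raw Ct table to per-miRNA kappas, PM-RE calls, proportion tests
#' and the overall discordance flag.
#'
#' @param ct Ct table ([read_ct_table()]).
#' @param pairs pair (cellularity) table.
#' @param config an [analysis_config()].
#' @return object of class `"mirna_results"` with `tables` and `summary`
#'   components for [write_reports()].
#' @export
run_mirna_analysis <- function(ct, pairs, config = analysis_config()) {
  quant <- quantify_expression(ct, pairs, config)
  p <- quant[quant$role == "primary", ]
  m <- quant[quant$role == "metastasis", ]
  key <- paste(p$sample_id, p$mirna_id, sep = "\r")
  m <- m[match(key, paste(m$sample_id, m$mirna_id, sep = "\r")), ]
  categories <- data.frame(pair_id = p$sample_id, mirna_id = p$mirna_id,
                           primary = p$category, metastasis = m$category,
                           stringsAsFactors = FALSE)
  kappas <- concordance_by_mirna(categories)
  pm <- pm_re_calls(rr_primary = p[c("sample_id", "mirna_id", "rr")],
                    rr_metastasis = m[c("sample_id", "mirna_id", "rr")],
                    cutoff = config$pm_re_cutoff)
  tests <- pm_re_tests(pm$counts, rounding = config$rounding)
  overall <- overall_discordance(pm$calls)
  structure(
    list(tables = list(expression = as.data.frame(quant),
                       categories = categories,
                       concordance = kappas,
                       pm_re = pm$calls,
                       pm_re_tests = tests),
         summary = list(
           n_pairs = length(unique(categories$pair_id)),
           n_mirnas = length(unique(categories$mirna_id)),
           altered_fraction_min = overall$range[1],
           altered_fraction_max = overall$range[2],
           overall_discordant = overall$discordant),
         overall = overall),
    class = "mirna_results")
}
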