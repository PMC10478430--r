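#' Default isoform/modified-form collapsing map
#'
#' Modified forms and isoforms count only once against their parent
#' biomarker: the regulatory-subunit pair P85/P110 maps to PI3K, the
#' phospho form of PTEN to PTEN and the two phospho-AKT epitopes to AKT.
#' Every other marker maps to itself.
#'
#' @return named list: parent marker -> member markers.
#' @export
default_isoform_map <- function() {
  list(PI3K = c("P85", "P110"),
       PTEN = c("PTEN", "phosphoPTEN"),
       AKT = c("phosphoAKT-serine", "phosphoAKT-threonine"))
}

#' Default biological pathway map (collapsed markers)
#'
#' The six marker groups used for the pathway cascade: cell-adhesion /
#' epithelial-mesenchymal transition, RAS-RAF-MEK, PI3K-AKT-PTEN,
#' TGFB-SMAD4, apoptosis and transcriptional mis-regulation. Members are
#' the *collapsed* parent markers (see [default_isoform_map()]).
#'
#' @return named list: pathway -> collapsed marker members.
#' @export
default_pathway_map <- function() {
  list(
    `CAM-EMT` = c("CD34", "CD31", "D2-40", "BEREP4", "AE1-3",
                  "E-cadherin"),
    `RAS-RAF-MEK` = c("RAS", "RASA1", "pCRAF"),
    `PI3K-AKT-PTEN` = c("PI3K", "PTEN", "AKT", "mtor", "pGSK"),
    `TGFB-SMAD4` = c("TGFBRII", "SMAD4"),
    apoptosis = "BCL2",
    `transcriptional-misregulation` = c("WT1", "KLF4")
  )
}

#' Default isoform/related-marker validation pairs
#'
#' The marker pairs whose alteration-status agreement validates the
#' SD-cutoff differential-expression approach: isoforms/modified forms
#' and functionally related proteins.
#'
#' @return list of length-2 character vectors.
#' @export
default_validation_pairs <- function() {
  list(c("CD34", "CD31"),
       c("P85", "P110"),
       c("PTEN", "phosphoPTEN"),
       c("RAS", "RASA1"),
       c("phosphoAKT-serine", "phosphoAKT-threonine"),
       c("mtor", "phosphoAKT-serine"),
       c("mtor", "phosphoAKT-threonine"),
       c("TGFBRII", "SMAD4"))
}

# the receptor is recorded under one canonical name
normalise_marker <- function(marker) {
  ifelse(marker == "TGFB", "TGFBRII", marker)
}

#' Total-protein-normalised relative expression
#'
#' @param raw spot intensity of the biomarker (non-negative).
#' @param total_protein total-protein intensity of the same lysate
#'   (strictly positive).
#' @return ratio `raw / total_protein` (vectorised).
#' @export
relative_expression <- function(raw, total_protein) {
  if (any(is.na(total_protein)) || any(total_protein <= 0))
    stop("total-protein signal must be strictly positive")
  if (any(is.na(raw)) || any(raw < 0))
    stop("raw signal must be non-negative")
  raw / total_protein
}

#' Cellularity adjustment of metastatic marker expression
#'
#' Corrects the metastatic relative expression for the cellularity
#' difference between the members of a pair:
#' `Em + (dTC/100) x Em` with `dTC = TC(primary) - TC(metastasis)`. The
#' adjustment is linear in the expression, an upward correction when the
#' metastasis is less cellular than its primary, and the identity at
#' equal cellularities.
#'
#' @param e_m metastatic relative expression (vectorised).
#' @param tc_primary,tc_metastasis cellularities in percent, in (0, 100].
#' @return adjusted expression.
#' @export
tc_normalise_met <- function(e_m, tc_primary, tc_metastasis) {
  tc <- c(tc_primary, tc_metastasis)
  if (any(is.na(tc)) || any(tc <= 0 | tc > 100))
    stop("tumour cellularity must lie in (0, 100]")
  e_m * (1 + (tc_primary - tc_metastasis) / 100)
}

#' Per-marker expression dispersion across the tumour population
#'
#' Sample standard deviation (n - 1 denominator) of a marker's relative
#' expression over every sample, primary and metastatic combined.
#'
#' @param expressions numeric vector of >= 2 values.
#' @return the standard deviation.
#' @export
marker_sd <- function(expressions) {
  expressions <- expressions[!is.na(expressions)]
  if (length(expressions) < 2)
    stop("need at least 2 values to estimate a dispersion")
  stats::sd(expressions)
}

#' Differential-expression call for one marker in one pair
#'
#' The metastatic expression is significantly altered when the difference
#' between primary and cellularity-adjusted metastatic expression is
#' strictly greater (in magnitude) than the marker's population SD.
#' Direction is reported relative to the metastasis: `up` when the
#' metastasis is higher.
#'
#' @param e_p primary relative expression.
#' @param e_m_tc cellularity-adjusted metastatic expression.
#' @param sd the marker's population standard deviation.
#' @return list with `differential` (`e_p - e_m_tc`) and `direction`
#'   (`"up"`, `"down"`, `"none"`).
#' @export
alteration_call <- function(e_p, e_m_tc, sd) {
  diff <- e_p - e_m_tc
  direction <- ifelse(diff < -sd, "up", ifelse(diff > sd, "down", "none"))
  list(differential = diff, direction = direction)
}

#' Call alterations for a whole RPPA cohort
#'
#' Normalises every spot to total protein, adjusts metastatic values for
#' the pair's cellularity difference, estimates each marker's population
#' SD (over primary and adjusted metastatic values combined, by default)
#' and calls the per-pair differential direction.
#'
#' @param rppa measurement table ([read_rppa_table()]); tumour rows carry
#'   the case id as `sample_id`.
#' @param pairs pair (cellularity) table.
#' @param sd_scope `"combined"` (default) pools both roles per marker;
#'   `"per_role"` estimates the SD from primary samples only.
#' @param sd_before_adjustment compute the SD cutoff on unadjusted
#'   metastatic values (default `FALSE`: after adjustment).
#' @return list with `calls` (data.frame `case_id`, `marker`, `e_primary`,
#'   `e_metastasis_tc`, `differential`, `direction`, `altered`) and
#'   `dispersions` (data.frame `marker`, `sd`).
#' @export
call_alterations <- function(rppa, pairs, sd_scope = c("combined",
                                                       "per_role"),
                             sd_before_adjustment = FALSE) {
  sd_scope <- match.arg(sd_scope)
  df <- rppa
  df$marker <- normalise_marker(df$marker)
  df$expression <- relative_expression(df$raw_signal,
                                       df$total_protein_signal)
  tc_p <- stats::setNames(pairs$tc_primary, pairs$case_id)
  tc_m <- stats::setNames(pairs$tc_metastasis, pairs$case_id)

  p <- df[df$role == "primary", ]
  m <- df[df$role == "metastasis", ]
  key <- paste(p$sample_id, p$marker, sep = "\r")
  mkey <- paste(m$sample_id, m$marker, sep = "\r")
  if (!setequal(key, mkey))
    stop("unmatched (case, marker) between primary and metastasis")
  m <- m[match(key, mkey), ]
  tcp <- tc_p[p$sample_id]
  tcm <- tc_m[p$sample_id]
  if (any(is.na(tcp)) || any(is.na(tcm)))
    stop("missing cellularity for case(s): ",
         paste(unique(p$sample_id[is.na(tcp) | is.na(tcm)]),
               collapse = ", "))
  e_m_tc <- tc_normalise_met(m$expression, tcp, tcm)

  met_for_sd <- if (sd_before_adjustment) m$expression else e_m_tc
  pool <- if (sd_scope == "combined")
    data.frame(marker = c(p$marker, m$marker),
               e = c(p$expression, met_for_sd))
  else data.frame(marker = p$marker, e = p$expression)
  sds <- tapply(pool$e, pool$marker, marker_sd)
  disp <- data.frame(marker = names(sds), sd = as.numeric(sds),
                     stringsAsFactors = FALSE)

  ac <- alteration_call(p$expression, e_m_tc, sds[p$marker])
  calls <- data.frame(case_id = p$sample_id, marker = p$marker,
                      e_primary = p$expression, e_metastasis_tc = e_m_tc,
                      differential = as.numeric(ac$differential),
                      direction = as.character(ac$direction),
                      stringsAsFactors = FALSE)
  calls$altered <- calls$direction != "none"
  rownames(calls) <- NULL
  list(calls = calls, dispersions = disp)
}

#' Alteration-status concordance between related markers
#'
#' Cross-tabulates the three-level alteration status (up/none/down) of
#' each marker pair across all tumour pairs and computes Cohen's kappa —
#' the internal validation of the SD-cutoff approach. Pairs with a marker
#' missing from the data are skipped with a warning.
#'
#' @param calls alteration-call table (`case_id`, `marker`, `direction`).
#' @param pair_list list of length-2 marker vectors; defaults to
#'   [default_validation_pairs()].
#' @return data.frame with `marker_a`, `marker_b`, `kappa`, `se`,
#'   `ci_lo`, `ci_hi`, `defined`; full kappa objects in
#'   `attr(, "kappas")`.
#' @export
validate_isoform_concordance <- function(calls,
                                         pair_list =
                                           default_validation_pairs()) {
  lv <- c("up", "none", "down")
  rows <- list()
  kappas <- list()
  for (pr in pair_list) {
    a <- calls[calls$marker == pr[1], ]
    b <- calls[calls$marker == pr[2], ]
    if (!nrow(a) || !nrow(b)) {
      warning("marker missing from data, skipping pair ",
              pr[1], "/", pr[2])
      next
    }
    b <- b[match(a$case_id, b$case_id), ]
    tab <- table(factor(a$direction, levels = lv),
                 factor(b$direction, levels = lv))
    k <- withCallingHandlers(cohens_kappa(as.matrix(unclass(tab))),
                             warning = function(w) invokeRestart("muffleWarning"))
    nm <- paste(pr[1], pr[2], sep = "/")
    kappas[[nm]] <- k
    rows[[nm]] <- data.frame(marker_a = pr[1], marker_b = pr[2],
                             kappa = k$kappa, se = k$se,
                             ci_lo = k$ci95[1], ci_hi = k$ci95[2],
                             defined = k$defined, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(marker_a = character(), marker_b = character(),
                      kappa = numeric(), se = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(),
                      defined = logical())
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "kappas") <- kappas
  out
}

#' Collapse isoform/modified-form calls onto parent biomarkers
#'
#' A parent is altered when any of its members is altered (idempotent,
#' monotone union); markers outside the map pass through unchanged.
#'
#' @param calls alteration-call table (`case_id`, `marker`, `altered`).
#' @param isoform_map named list parent -> members; defaults to
#'   [default_isoform_map()].
#' @return data.frame with `case_id`, `marker` (collapsed), `altered`.
#' @export
collapse_isoforms <- function(calls, isoform_map = default_isoform_map()) {
  parent <- stats::setNames(rep(names(isoform_map),
                                lengths(isoform_map)),
                            unlist(isoform_map))
  mk <- calls$marker
  mapped <- ifelse(mk %in% names(parent), parent[mk], mk)
  agg <- stats::aggregate(altered ~ case_id + marker,
                          data.frame(case_id = calls$case_id,
                                     marker = mapped,
                                     altered = calls$altered,
                                     stringsAsFactors = FALSE),
                          any)
  agg <- agg[order(agg$case_id, agg$marker), ]
  rownames(agg) <- NULL
  agg
}

#' Pathway-level alteration calls
#'
#' A pathway is altered for a tumour pair when at least half of its
#' (collapsed) member markers are altered.
#'
#' @param collapsed collapsed alteration table ([collapse_isoforms()]).
#' @param pathway_map named list pathway -> members; defaults to
#'   [default_pathway_map()].
#' @param fraction inclusive alteration fraction threshold (default 0.5).
#' @return data.frame with `case_id`, `pathway`, `n_markers`,
#'   `n_altered`, `altered_fraction`, `altered`.
#' @export
pathway_calls <- function(collapsed, pathway_map = default_pathway_map(),
                          fraction = 0.5) {
  if (any(lengths(pathway_map) == 0))
    stop("empty pathway in the pathway map")
  cases <- unique(collapsed$case_id)
  rows <- list()
  for (cs in cases) {
    sub <- collapsed[collapsed$case_id == cs, ]
    status <- stats::setNames(sub$altered, sub$marker)
    for (pw in names(pathway_map)) {
      members <- intersect(pathway_map[[pw]], names(status))
      if (!length(members)) next
      frac <- mean(status[members])
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cs, pathway = pw, n_markers = length(members),
        n_altered = sum(status[members]), altered_fraction = frac,
        altered = frac >= fraction, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pair-level profiles and the population verdict
#'
#' A tumour pair has an altered expression profile when at least half of
#' its analysed pathways are altered; the primary and metastatic groups
#' differ at the population level when at least half of the pairs have
#' altered profiles (all bounds inclusive).
#'
#' @param pathways pathway-call table ([pathway_calls()]).
#' @param pair_fraction,population_fraction the two inclusive cutoffs.
#' @return list with `pairs` (data.frame `case_id`, `n_pathways`,
#'   `n_altered`, `fraction`, `profile_altered`), `altered_pairs`,
#'   `n_pairs`, `altered_pair_fraction`, `population_different`.
#' @export
pair_and_population_summary <- function(pathways, pair_fraction = 0.5,
                                        population_fraction = 0.5) {
  if (!nrow(pathways)) stop("empty pathway-call table")
  agg <- stats::aggregate(altered ~ case_id, pathways,
                          function(x) c(n = length(x), k = sum(x)))
  tab <- data.frame(case_id = agg$case_id,
                    n_pathways = agg$altered[, "n"],
                    n_altered = agg$altered[, "k"],
                    stringsAsFactors = FALSE)
  tab$fraction <- tab$n_altered / tab$n_pathways
  tab$profile_altered <- tab$fraction >= pair_fraction
  frac <- mean(tab$profile_altered)
  list(pairs = tab, altered_pairs = sum(tab$profile_altered),
       n_pairs = nrow(tab), altered_pair_fraction = frac,
       population_different = frac >= population_fraction)
}

#' Run the full RPPA pathway analysis
#'
#' Normalisation, cellularity adjustment, SD-cutoff alteration calls,
#' isoform validation kappas, collapsing, and the pathway / pair /
#' population cascade.
#'
#' @param rppa measurement table ([read_rppa_table()]).
#' @param pairs pair (cellularity) table.
#' @param config an [analysis_config()].
#' @param pathway_map,isoform_map,validation_pairs overrides of the
#'   default maps.
#' @return object of class `"rppa_results"` with `tables` and `summary`
#'   components for [write_reports()].
#' @export
run_rppa_analysis <- function(rppa, pairs, config = analysis_config(),
                              pathway_map = default_pathway_map(),
                              isoform_map = default_isoform_map(),
                              validation_pairs =
                                default_validation_pairs()) {
  alt <- call_alterations(rppa, pairs)
  validation <- suppressWarnings(
    validate_isoform_concordance(alt$calls, validation_pairs))
  collapsed <- collapse_isoforms(alt$calls, isoform_map)
  pw <- pathway_calls(collapsed, pathway_map, config$pathway_fraction)
  pop <- pair_and_population_summary(pw, config$pair_fraction,
                                     config$population_fraction)
  pw_pop <- stats::aggregate(altered ~ pathway, pw, sum)
  structure(
    list(tables = list(alterations = alt$calls,
                       marker_sd = alt$dispersions,
                       isoform_validation = validation,
                       collapsed = collapsed,
                       pathway_calls = pw,
                       pair_profiles = pop$pairs),
         summary = list(
           n_pairs = pop$n_pairs,
           altered_pairs = pop$altered_pairs,
           altered_pair_fraction = pop$altered_pair_fraction,
           population_different = pop$population_different),
         population = pop,
         pathway_totals = pw_pop),
    class = "rppa_results")
}
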