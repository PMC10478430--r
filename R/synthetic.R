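#' Simulation design for a synthetic paired-tumour cohort
#'
#' Encodes the statistical structure the analysis itself assumes: mutant
#' allele fractions determined by a target clonality background and the
#' sample's cellularity (the score formula run backwards), Ct values
#' shifted by designed log2 effects and diluted by the stromal fraction,
#' and marker expressions shifted by multiples of the marker SD. The
#' defaults emulate the study conditions: 22 tumour pairs, cellularities
#' between 40 and 90 percent, ~70% locus discordance, per-miRNA altered
#' fractions matching the printed panel, and per-pathway alteration
#' probabilities matching the printed pathway tallies.
#'
#' @param n_pairs number of tumour pairs.
#' @param tc_range cellularity range (percent) sampled uniformly.
#' @param loci_per_pair somatic loci simulated per pair.
#' @param status_probs sampling probabilities of the primary-tumour
#'   background status (`STC`, `ATC`, `CNV`, `WT`).
#' @param discordance_prob probability that a locus changes background
#'   status in the metastasis.
#' @param hs_noise_sd SD of truncated score noise within a status band.
#' @param mirna_ids panel of miRNA identifiers.
#' @param mirna_altered_prob per-miRNA probability that a pair's
#'   primary-to-metastasis ratio is altered (recycled to the panel).
#' @param mirna_effect_log2 absolute log2 primary-vs-metastasis effect
#'   given alteration.
#' @param ct_noise_sd replicate Ct noise SD in cycles.
#' @param ct_baseline_dct normal-tissue delta-Ct of every miRNA.
#' @param ct_reference reference-gene Ct.
#' @param pathway_probs per-pathway alteration probabilities (named by
#'   the pathways of [default_pathway_map()], recycled).
#' @param rppa_shift_sd alteration shift in multiples of the marker SD.
#' @param rppa_noise_sd relative measurement noise of unaltered
#'   metastatic expression (fraction of the marker SD).
#' @param rppa_meanlog,rppa_sdlog log-normal parameters of baseline
#'   marker expression.
#' @return list of class `"simulation_design"`.
#' @export
simulation_design <- function(n_pairs = 22,
                              tc_range = c(40, 90),
                              loci_per_pair = 3,
                              status_probs = c(STC = 0.33, ATC = 0.03,
                                               CNV = 0.60, WT = 0.04),
                              discordance_prob = 0.7,
                              hs_noise_sd = 0,
                              mirna_ids = c("miRNA20a", "miRNA21",
                                            "miRNA29a", "miRNA31",
                                            "miRNA92", "miRNA224"),
                              mirna_altered_prob = c(0.571, 0.571, 0.619,
                                                     0.810, 0.762, 0.714),
                              mirna_effect_log2 = 2,
                              ct_noise_sd = 0.1,
                              ct_baseline_dct = 3,
                              ct_reference = 20,
                              pathway_probs = c(0.70, 0.75, 0.65, 0.55,
                                                0.65, 0.80),
                              rppa_shift_sd = 3,
                              rppa_noise_sd = 0.05,
                              rppa_meanlog = 0,
                              rppa_sdlog = 0.25) {
  if (n_pairs < 1) stop("n_pairs must be at least 1")
  if (length(tc_range) != 2 || tc_range[1] <= 0 || tc_range[2] > 100 ||
      tc_range[1] > tc_range[2])
    stop("tc_range must be an increasing interval within (0, 100]")
  probs <- c(discordance_prob, mirna_altered_prob, pathway_probs)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(c(hs_noise_sd, ct_noise_sd, rppa_noise_sd) < 0))
    stop("noise SDs must be non-negative")
  if (abs(sum(status_probs) - 1) > 1e-8)
    stop("status_probs must sum to 1")
  structure(
    list(n_pairs = n_pairs, tc_range = tc_range,
         loci_per_pair = loci_per_pair, status_probs = status_probs,
         discordance_prob = discordance_prob, hs_noise_sd = hs_noise_sd,
         mirna_ids = mirna_ids,
         mirna_altered_prob = rep_len(mirna_altered_prob,
                                      length(mirna_ids)),
         mirna_effect_log2 = mirna_effect_log2,
         ct_noise_sd = ct_noise_sd, ct_baseline_dct = ct_baseline_dct,
         ct_reference = ct_reference,
         pathway_probs = rep_len(pathway_probs,
                                 length(default_pathway_map())),
         rppa_shift_sd = rppa_shift_sd, rppa_noise_sd = rppa_noise_sd,
         rppa_meanlog = rppa_meanlog, rppa_sdlog = rppa_sdlog),
    class = "simulation_design")
}

# fixed per-generator seed offsets: enabling or disabling one data type
# must not shift another's draws
seed_for <- function(seed, offset) {
  (as.integer(seed) + offset) %% .Machine$integer.max
}

# draw a score inside a status band; bands are kept clear of the 0.5
# intra-status threshold so concordant loci never trip it by noise
draw_hs <- function(status, noise_sd) {
  base <- switch(status,
                 WT = 0,
                 STC = stats::runif(1, 0.20, 0.90),
                 ATC = stats::runif(1, 0.95, 1.05),
                 CNV = stats::runif(1, 1.10, 1.90))
  if (status != "WT" && noise_sd > 0) {
    eps <- max(-0.04, min(0.04, stats::rnorm(1, 0, noise_sd)))
    base <- base + eps
    base <- switch(status,
                   STC = min(max(base, 0.01), 0.949),
                   ATC = min(max(base, 0.95), 1.05),
                   CNV = min(max(base, 1.051), 1.95))
  }
  base
}

#' Generate a synthetic somatic-mutation cohort
#'
#' Inverts the heterogeneity-score formula: for a target background
#' status a score is drawn inside the status band and the mutant allele
#' fraction realised as `MAF = HS x (TC/100) / 2` (truncated to
#' \[0.01, 0.99\] for present mutations). With the designed discordance
#' probability the metastatic member is redrawn in a different status
#' band, producing an inter-status change; otherwise the primary score is
#' kept exactly.
#'
#' @param design a [simulation_design()].
#' @param seed integer master seed.
#' @return list with `calls` (long mutation table including `maf` and
#'   `tc`), `pairs`, and `truth` (per-locus designed statuses and
#'   discordance flags).
#' @export
generate_mutation_cohort <- function(design, seed) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed_for(seed, 101L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  statuses <- names(design$status_probs)
  genes <- c("APC", "KRAS", "TP53", "PIK3CA", "SMAD4")
  calls <- list()
  truth <- list()
  pairs <- data.frame(case_id = sprintf("S%02d", seq_len(design$n_pairs)),
                      tc_primary = round(stats::runif(design$n_pairs,
                                                      design$tc_range[1],
                                                      design$tc_range[2])),
                      tc_metastasis = round(stats::runif(design$n_pairs,
                                                         design$tc_range[1],
                                                         design$tc_range[2])),
                      stringsAsFactors = FALSE)
  for (i in seq_len(design$n_pairs)) {
    for (l in seq_len(design$loci_per_pair)) {
      st_p <- sample(statuses, 1, prob = design$status_probs)
      hs_p <- draw_hs(st_p, design$hs_noise_sd)
      discordant <- stats::runif(1) < design$discordance_prob
      if (discordant) {
        st_m <- sample(setdiff(statuses, st_p), 1)
        hs_m <- draw_hs(st_m, design$hs_noise_sd)
      } else {
        st_m <- st_p
        hs_m <- hs_p
      }
      gene <- genes[(l - 1L) %% length(genes) + 1L]
      hgvs <- sprintf("c.%dA>T", 100L * l + i)
      maf <- function(hs, tc) {
        if (hs == 0) return(0)
        min(max(hs * (tc / 100) / 2, 0.01), 0.99)
      }
      calls[[length(calls) + 1L]] <- data.frame(
        case_id = pairs$case_id[i],
        role = c("primary", "metastasis"),
        gene = gene, hgvs_c = hgvs,
        present = c(st_p != "WT", st_m != "WT"),
        maf = c(maf(hs_p, pairs$tc_primary[i]),
                maf(hs_m, pairs$tc_metastasis[i])),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        case_id = pairs$case_id[i], gene = gene, hgvs_c = hgvs,
        status_primary = st_p, status_metastasis = st_m,
        discordant = discordant, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  truth <- do.call(rbind, truth)
  rownames(calls) <- rownames(truth) <- NULL
  list(calls = calls, pairs = pairs, truth = truth)
}

#' Generate a synthetic qPCR Ct cohort
#'
#' Ct model: `ct_target = ct_ref + baseline_dct - log2(fold) +
#' log2(100/TC) + noise`, where the stromal-dilution term is the exact
#' inverse of the pipeline's cellularity correction. Metastatic tumours
#' express at the normal-tissue level; with the designed per-miRNA
#' probability a pair receives a primary-vs-metastasis log2 effect of
#' +/- `mirna_effect_log2`, otherwise zero. Three replicate wells are
#' emitted per assay plus a pooled-normal sample.
#'
#' @param design a [simulation_design()].
#' @param seed integer master seed.
#' @return list with `ct` (Ct table), `pairs` and `truth` (per pair x
#'   miRNA designed effect and altered flag).
#' @export
generate_ct_cohort <- function(design, seed) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed_for(seed, 202L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  pairs <- data.frame(case_id = sprintf("S%02d", seq_len(design$n_pairs)),
                      tc_primary = round(stats::runif(design$n_pairs,
                                                      design$tc_range[1],
                                                      design$tc_range[2])),
                      tc_metastasis = round(stats::runif(design$n_pairs,
                                                         design$tc_range[1],
                                                         design$tc_range[2])),
                      stringsAsFactors = FALSE)
  mir <- design$mirna_ids
  noise <- function(n) if (design$ct_noise_sd > 0)
    stats::rnorm(n, 0, design$ct_noise_sd) else numeric(n)

  make_rows <- function(sample_id, role, fold_log2, tc) {
    dilution <- if (role == "normal") 0 else log2(100 / tc)
    mean_ct <- design$ct_reference + design$ct_baseline_dct -
      fold_log2 + dilution
    reps <- matrix(rep(mean_ct, each = 3) + noise(3 * length(mir)),
                   nrow = length(mir), byrow = TRUE)
    data.frame(sample_id = sample_id, role = role, mirna_id = mir,
               ct_rep1 = reps[, 1], ct_rep2 = reps[, 2],
               ct_rep3 = reps[, 3], ct_rnu6b = design$ct_reference,
               stringsAsFactors = FALSE)
  }

  rows <- list(make_rows("N-pool", "normal", rep(0, length(mir)), NA))
  truth <- list()
  for (i in seq_len(design$n_pairs)) {
    altered <- stats::runif(length(mir)) < design$mirna_altered_prob
    sign <- sample(c(-1, 1), length(mir), replace = TRUE)
    effect <- ifelse(altered, sign * design$mirna_effect_log2, 0)
    # metastasis at normal-tissue level; effect lands on the primary
    rows[[length(rows) + 1L]] <- make_rows(pairs$case_id[i], "primary",
                                           effect, pairs$tc_primary[i])
    rows[[length(rows) + 1L]] <- make_rows(pairs$case_id[i], "metastasis",
                                           rep(0, length(mir)),
                                           pairs$tc_metastasis[i])
    truth[[i]] <- data.frame(case_id = pairs$case_id[i], mirna_id = mir,
                             effect_log2 = effect, altered = altered,
                             stringsAsFactors = FALSE)
  }
  ct <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  rownames(ct) <- rownames(truth) <- NULL
  list(ct = ct, pairs = pairs, truth = truth)
}

#' Generate a synthetic RPPA cohort
#'
#' Baseline marker expressions are log-normal; with the designed
#' per-pathway probability, every marker of a pathway is shifted in the
#' metastasis by `rppa_shift_sd` theoretical marker SDs (direction random,
#' flipped upward when a downward shift would go non-positive), so the
#' pathway's 50% rule fires exactly when the pathway was drawn altered.
#' The raw metastatic value is pre-divided by the pair's cellularity
#' correction so the pipeline's adjustment recovers the designed target.
#'
#' @param design a [simulation_design()].
#' @param seed integer master seed.
#' @return list with `rppa` (measurement table), `pairs` and `truth`
#'   (per pair x pathway altered flags).
#' @export
generate_rppa_cohort <- function(design, seed) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed_for(seed, 303L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  pw_map <- default_pathway_map()
  markers <- unlist(pw_map, use.names = FALSE)
  pw_of <- rep(names(pw_map), lengths(pw_map))
  sdlog <- design$rppa_sdlog
  tau <- sqrt((exp(sdlog^2) - 1) * exp(2 * design$rppa_meanlog + sdlog^2))
  pairs <- data.frame(case_id = sprintf("S%02d", seq_len(design$n_pairs)),
                      tc_primary = round(stats::runif(design$n_pairs,
                                                      design$tc_range[1],
                                                      design$tc_range[2])),
                      tc_metastasis = round(stats::runif(design$n_pairs,
                                                         design$tc_range[1],
                                                         design$tc_range[2])),
                      stringsAsFactors = FALSE)
  rows <- list()
  truth <- list()
  for (i in seq_len(design$n_pairs)) {
    pw_altered <- stats::runif(length(pw_map)) < design$pathway_probs
    names(pw_altered) <- names(pw_map)
    adj <- 1 + (pairs$tc_primary[i] - pairs$tc_metastasis[i]) / 100
    for (j in seq_along(markers)) {
      e_p <- stats::rlnorm(1, design$rppa_meanlog, sdlog)
      target <- e_p
      if (pw_altered[[pw_of[j]]]) {
        shift <- design$rppa_shift_sd * tau * sample(c(-1, 1), 1)
        if (e_p + shift <= 0.01) shift <- abs(shift)
        target <- e_p + shift
      }
      if (design$rppa_noise_sd > 0)
        target <- max(target + stats::rnorm(1, 0,
                                            design$rppa_noise_sd * tau),
                      0.01)
      e_m_raw <- target / adj
      tp <- stats::runif(2, 10000, 20000)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = pairs$case_id[i],
        role = c("primary", "metastasis"),
        marker = markers[j],
        raw_signal = c(e_p, e_m_raw) * tp,
        total_protein_signal = tp,
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(case_id = pairs$case_id[i],
                             pathway = names(pw_map),
                             altered = unname(pw_altered),
                             stringsAsFactors = FALSE)
  }
  rppa <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  rownames(rppa) <- rownames(truth) <- NULL
  list(rppa = rppa, pairs = pairs, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Emits the three input files of the pipeline (mutation TSV, Ct CSV,
#' RPPA CSV), a shared pair TSV and a manifest of the true design
#' parameters for recovery tests. Identical (design, seed) input yields
#' byte-identical files.
#'
#' @param design a [simulation_design()].
#' @param seed integer master seed.
#' @param outdir output directory.
#' @return invisibly, the named vector of paths written.
#' @export
write_synthetic_cohort <- function(design, seed, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mut <- generate_mutation_cohort(design, seed)
  ctc <- generate_ct_cohort(design, seed)
  rpp <- generate_rppa_cohort(design, seed)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.9g", x))
    df
  }
  paths <- c(
    mutations = file.path(outdir, "mutations.tsv"),
    pairs = file.path(outdir, "pairs.tsv"),
    ct = file.path(outdir, "ct.csv"),
    rppa = file.path(outdir, "rppa.csv"),
    manifest = file.path(outdir, "manifest.json"))
  write_table_atomic(fmt(cbind(mut$calls,
                               tc = ifelse(mut$calls$role == "primary",
                                           mut$pairs$tc_primary[
                                             match(mut$calls$case_id,
                                                   mut$pairs$case_id)],
                                           mut$pairs$tc_metastasis[
                                             match(mut$calls$case_id,
                                                   mut$pairs$case_id)]))),
                     paths["mutations"])
  write_table_atomic(fmt(mut$pairs), paths["pairs"])
  write_table_atomic(fmt(ctc$ct), paths["ct"], sep = ",")
  write_table_atomic(fmt(rpp$rppa), paths["rppa"], sep = ",")
  manifest <- list(seed = seed,
                   design = unclass(design),
                   truth = list(mutation = mut$truth, mirna = ctc$truth,
                                rppa = rpp$truth))
  tmp <- paste0(paths["manifest"], ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, paths["manifest"])
  invisible(paths)
}
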