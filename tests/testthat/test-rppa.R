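test_that("total-protein normalisation and cellularity adjustment", {
  expect_equal(relative_expression(10, 5), 2)
  expect_equal(relative_expression(0, 5), 0)
  expect_error(relative_expression(3, 0), "strictly positive")

  expect_equal(tc_normalise_met(1.0, 80, 60), 1.2)
  expect_equal(tc_normalise_met(2.0, 50, 70), 1.6)
  expect_equal(tc_normalise_met(c(0.5, 3), 65, 65), c(0.5, 3))
  # linear in the expression
  expect_equal(tc_normalise_met(5 * 1.3, 80, 40),
               5 * tc_normalise_met(1.3, 80, 40))
  expect_error(tc_normalise_met(1, 0, 50), "\\(0, 100\\]")
})

test_that("marker dispersion matches a two-pass oracle", {
  expect_equal(marker_sd(c(1, 1, 1)), 0)
  expect_equal(marker_sd(c(0, 2)), sqrt(2))
  set.seed(31)
  x <- rlnorm(40)
  oracle <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(marker_sd(x), oracle, tolerance = 1e-12)
  expect_error(marker_sd(5), "at least 2")
})

test_that("alteration calls use a strict SD exceedance and flip under
          role swap", {
  sd <- 0.4
  expect_equal(alteration_call(1.0, 1.0 + 1.5 * sd, sd)$direction, "up")
  expect_equal(alteration_call(1.0 + 1.5 * sd, 1.0, sd)$direction, "down")
  expect_equal(alteration_call(1.0, 1.0 + sd, sd)$direction, "none")
  expect_equal(alteration_call(1.0, 1.0, sd)$direction, "none")
  # antisymmetry: swapping roles flips direction, keeps magnitude
  set.seed(2)
  a <- runif(20); b <- runif(20)
  fwd <- alteration_call(a, b, 0.1)
  rev <- alteration_call(b, a, 0.1)
  expect_equal(fwd$differential, -rev$differential)
  flip <- c(up = "down", none = "none", down = "up")
  expect_equal(unname(flip[fwd$direction]), rev$direction)
})

test_that("isoform collapsing is an idempotent, monotone union", {
  calls <- data.frame(
    case_id = "C1",
    marker = c("P85", "P110", "phosphoAKT-serine",
               "phosphoAKT-threonine", "PTEN", "phosphoPTEN", "BCL2"),
    altered = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  col <- collapse_isoforms(calls)
  get <- function(m) col$altered[col$marker == m]
  expect_true(get("PI3K"))           # one member altered suffices
  expect_true(get("AKT"))            # two members counted once
  expect_false(get("PTEN"))          # no member altered
  expect_true(get("BCL2"))           # unmapped marker passes through
  expect_equal(sum(col$marker == "AKT"), 1)
  # idempotent: collapsing a collapsed table changes nothing
  expect_equal(collapse_isoforms(col), col)
  # monotone: altering a member never un-alters a parent
  calls2 <- calls
  calls2$altered[calls2$marker == "P110"] <- TRUE
  col2 <- collapse_isoforms(calls2)
  expect_true(all(col2$altered >= col$altered[match(col2$marker,
                                                    col$marker)]))
})

test_that("pathway calls apply the inclusive 50% rule after collapsing", {
  mk <- function(markers, altered) data.frame(
    case_id = "C1", marker = markers, altered = altered,
    stringsAsFactors = FALSE)
  ras <- pathway_calls(mk(c("RAS", "RASA1", "pCRAF"),
                          c(TRUE, TRUE, FALSE)))
  expect_true(ras$altered[ras$pathway == "RAS-RAF-MEK"])
  expect_equal(ras$altered_fraction[ras$pathway == "RAS-RAF-MEK"], 2 / 3)

  # only PTEN and AKT altered among the five collapsed members: 2/5
  pi3k <- collapse_isoforms(mk(
    c("P85", "P110", "PTEN", "phosphoPTEN", "phosphoAKT-serine",
      "phosphoAKT-threonine", "mtor", "pGSK"),
    c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)))
  res <- pathway_calls(pi3k)
  expect_equal(res$altered_fraction[res$pathway == "PI3K-AKT-PTEN"], 0.4)
  expect_false(res$altered[res$pathway == "PI3K-AKT-PTEN"])

  solo <- pathway_calls(mk("BCL2", TRUE))
  expect_true(solo$altered[solo$pathway == "apoptosis"])
  expect_error(pathway_calls(mk("BCL2", TRUE),
                             pathway_map = list(empty = character())),
               "empty pathway")
})

test_that("pair and population cascade is inclusive at every level", {
  mk <- function(n_pairs, altered_per_pair) {
    do.call(rbind, lapply(seq_len(n_pairs), function(i) data.frame(
      case_id = sprintf("C%02d", i), pathway = paste0("pw", 1:6),
      altered = rep(c(TRUE, FALSE),
                    c(altered_per_pair[i], 6 - altered_per_pair[i])),
      stringsAsFactors = FALSE)))
  }
  # 16 of 20 pairs with >= 3 of 6 pathways altered
  res <- pair_and_population_summary(mk(20, c(rep(3, 16), rep(2, 4))))
  expect_equal(res$altered_pairs, 16)
  expect_equal(res$altered_pair_fraction, 0.8)
  expect_true(res$population_different)

  # exactly 3/6 pathways in exactly half the pairs: both flags true
  res <- pair_and_population_summary(mk(4, c(3, 3, 2, 2)))
  expect_true(res$population_different)
  expect_equal(res$altered_pair_fraction, 0.5)

  res <- pair_and_population_summary(mk(4, c(0, 0, 0, 0)))
  expect_false(res$population_different)
})

test_that("isoform validation kappa behaves on designed call sets", {
  ids <- sprintf("C%04d", 1:1000)
  mk <- function(m, dir) data.frame(case_id = ids, marker = m,
                                    direction = dir,
                                    stringsAsFactors = FALSE)
  set.seed(13)
  dirs <- c("up", "none", "down")
  # identical vectors agree perfectly
  v <- sample(dirs, 1000, replace = TRUE)
  res <- validate_isoform_concordance(rbind(mk("CD34", v), mk("CD31", v)),
                                      list(c("CD34", "CD31")))
  expect_equal(res$kappa, 1)
  # independent vectors hover at zero
  res <- validate_isoform_concordance(
    rbind(mk("CD34", sample(dirs, 1000, replace = TRUE)),
          mk("CD31", sample(dirs, 1000, replace = TRUE))),
    list(c("CD34", "CD31")))
  expect_lt(abs(res$kappa), 0.05)
  # full discordance is non-positive
  a <- rep(c("up", "down"), 500)
  b <- rep(c("down", "up"), 500)
  res <- suppressWarnings(validate_isoform_concordance(
    rbind(mk("RAS", a), mk("RASA1", b)), list(c("RAS", "RASA1"))))
  expect_lte(res$kappa, 0)
  # missing marker skipped with a warning
  expect_warning(validate_isoform_concordance(mk("RAS", a),
                                              list(c("RAS", "GONE"))),
                 "missing")
})

test_that("synthetic RPPA cohorts recover designed alteration rates", {
  for (pi in c(0.1, 0.5, 0.9)) {
    d <- simulation_design(n_pairs = 200, pathway_probs = pi)
    cohort <- generate_rppa_cohort(d, 1000 + round(100 * pi))
    res <- run_rppa_analysis(cohort$rppa, cohort$pairs)
    pw <- res$tables$pathway_calls
    # every pathway call agrees with the generator's truth: a 3-SD shift
    # is always detected against the population SD cutoff
    tr <- cohort$truth
    idx <- match(paste(pw$case_id, pw$pathway),
                 paste(tr$case_id, tr$pathway))
    expect_true(all(pw$altered == tr$altered[idx]))
    # per-pathway recovered fractions within exact binomial intervals,
    # widened for the 18 simultaneous checks across this loop
    for (p in unique(pw$pathway)) {
      k <- sum(pw$altered[pw$pathway == p])
      ci <- binom.test(k, 200, conf.level = 0.999)$conf.int
      expect_true(pi >= ci[1] && pi <= ci[2],
                  label = sprintf("pathway %s at pi=%.1f (k=%d)", p, pi, k))
    }
    # population altered-pair fraction within the 95% interval of the
    # value the designed cascade induces (>= 3 of 6 pathways altered)
    induced <- sum(dbinom(3:6, 6, pi))
    ci <- binom.test(res$summary$altered_pairs, 200)$conf.int
    expect_true(induced >= ci[1] && induced <= ci[2])
  }
})
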