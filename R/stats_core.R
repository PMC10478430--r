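#' One-proportion z-test with a complement-null convention
#'
#' Tests an observed proportion `k/n` against a null proportion. When `p0`
#' is `NULL` (the default) the null is taken as the *complement* of the
#' observed proportion, `p0 = 1 - k/n`, i.e. the altered fraction is tested
#' against the unaltered fraction. This is the convention under which all
#' of the study's printed z-scores reproduce. A conventional fixed null can
#' be supplied through `p0`.
#'
#' With `rounding = "three_decimals"` both proportions are rounded to three
#' decimal places *before* the z-statistic is formed, which mimics feeding
#' pre-rounded percentages into a desk calculator. The somatic-mutation
#' discordance z-score (41/58) is only reproduced in this mode.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n total number of trials (n >= 1).
#' @param p0 null proportion in (0, 1), or `NULL` for the complement null.
#' @param rounding `"none"` (default) or `"three_decimals"`.
#'
#' @return An object of class `"prop_test"`: a list with elements `k`, `n`,
#'   `p_hat`, `p0`, `z`, `p_value` (two-sided, standard normal) and
#'   `difference` (`p_hat - p0`).
#'
#' @examples
#' one_proportion_z(17, 21)            # z = 7.224
#' one_proportion_z(41, 58, rounding = "three_decimals")  # z = 6.927
#' @export
one_proportion_z <- function(k, n, p0 = NULL,
                             rounding = c("none", "three_decimals")) {
  rounding <- match.arg(rounding)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n))
    stop("'k' and 'n' must be single non-missing counts")
  if (n < 1) stop("'n' must be at least 1")
  if (k < 0 || k > n) stop("'k' must lie in [0, n]")

  p_hat <- k / n
  if (is.null(p0)) p0 <- 1 - p_hat
  if (rounding == "three_decimals") {
    p_hat <- round(p_hat, 3)
    p0 <- round(p0, 3)
  }
  if (p0 <= 0 || p0 >= 1)
    stop("degenerate null proportion: p0 must lie strictly inside (0, 1)")

  z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / n)
  structure(
    list(k = k, n = n, p_hat = p_hat, p0 = p0, z = z,
         p_value = 2 * stats::pnorm(-abs(z)), difference = p_hat - p0),
    class = "prop_test"
  )
}

#' @export
print.prop_test <- function(x, ...) {
  cat(sprintf("One-proportion z-test: %d / %d\n", x$k, x$n))
  cat(sprintf("  p_hat = %.4f  p0 = %.4f  difference = %.4f\n",
              x$p_hat, x$p0, x$difference))
  cat(sprintf("  z = %.3f  two-sided p = %.4g\n", x$z, x$p_value))
  invisible(x)
}

#' Cohen's kappa for a square contingency table
#'
#' Computes unweighted Cohen's kappa with the Fleiss-Cohen-Everitt
#' large-sample standard error and a 95% Wald confidence interval. The
#' table is padded with zero rows/columns so that both margins cover the
#' same category set.
#'
#' Kappa is reported as undefined (`defined = FALSE`, with a warning) when
#' chance agreement is 1 or when fewer than two categories carry counts on
#' either margin: with all of one rater's calls in a single category the
#' statistic carries no information (observed and chance agreement
#' coincide), which is why agreement could not be computed for the
#' all-but-one-low miRNA21 column of the study data.
#'
#' @param table a matrix of non-negative counts; rows one rater (e.g.
#'   primary tumour), columns the other (e.g. metastasis). Dimnames, when
#'   present, identify the categories.
#'
#' @return An object of class `"kappa_result"`: list with `kappa`, `po`
#'   (observed agreement), `pe` (chance agreement), `se`, `ci95`
#'   (length-2 vector), `n`, `defined` and the padded `table`.
#'
#' @examples
#' tab <- matrix(c(16, 1, 3, 1), 2, 2,
#'               dimnames = list(c("low", "high"), c("low", "high")))
#' cohens_kappa(tab)
#' @export
cohens_kappa <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (inherits(table, "table")) table <- unclass(table)
  if (!is.matrix(table) || !is.numeric(table))
    stop("'table' must be a numeric matrix of counts")
  if (any(is.na(table)) || any(table < 0))
    stop("counts must be non-negative and non-missing")
  table <- pad_square(table)
  n <- sum(table)
  if (n < 1) stop("empty table: total count must be at least 1")

  p <- table / n
  po <- sum(diag(p))
  pr <- rowSums(p)
  pc <- colSums(p)
  pe <- sum(pr * pc)

  defined <- pe < 1 && sum(pr > 0) >= 2L && sum(pc > 0) >= 2L
  if (!defined) {
    warning("kappa undefined: degenerate table (chance agreement 1 or a ",
            "single occupied category on a margin)")
    return(structure(
      list(kappa = NA_real_, po = po, pe = pe, se = NA_real_,
           ci95 = c(NA_real_, NA_real_), n = n, defined = FALSE,
           table = table),
      class = "kappa_result"
    ))
  }

  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance
  a <- sum(diag(p) * ((1 - pe) - (pr + pc) * (1 - po))^2)
  b <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (i != j) b <- b + p[i, j] * (pc[i] + pr[j])^2
    }
  }
  b <- (1 - po)^2 * b
  cc <- (po * pe - 2 * pe + po)^2
  se <- sqrt(max(0, a + b - cc)) / ((1 - pe)^2 * sqrt(n))

  structure(
    list(kappa = kappa, po = po, pe = pe, se = se,
         ci95 = kappa + c(-1, 1) * 1.96 * se, n = n, defined = TRUE,
         table = table),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  if (!x$defined) {
    cat("Cohen's kappa: undefined (degenerate table)\n")
  } else {
    cat(sprintf("Cohen's kappa = %.3f (SE %.3f, 95%% CI %.3f to %.3f)\n",
                x$kappa, x$se, x$ci95[1], x$ci95[2]))
    cat(sprintf("  observed agreement %.3f, chance agreement %.3f, n = %d\n",
                x$po, x$pe, as.integer(x$n)))
  }
  invisible(x)
}

# pad a counts matrix to a square with a common category set
pad_square <- function(m) {
  rn <- rownames(m)
  cn <- colnames(m)
  if (is.null(rn) || is.null(cn)) {
    if (nrow(m) != ncol(m))
      stop("unnamed table must already be square")
    return(m)
  }
  cats <- union(rn, cn)
  out <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  out[rn, cn] <- m
  out
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor.test()] returning the correlation, its
#' square and the two-sided p-value from the t-distribution with n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values,
#' returned in the input order. Delegates to
#' [stats::p.adjust()]`(method = "BH")` after validating the input range.
#'
#' @param p_values numeric vector of probabilities in \[0, 1\].
#' @return list with `raw` and `adjusted` vectors (same order as input).
#' @examples
#' bh_adjust(c(0.1859, 0.1859, 0.0247, 0.0001, 0.0001, 0.0001))$adjusted
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || length(p_values) == 0)
    stop("'p_values' must be a non-empty numeric vector")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("all p-values must lie in [0, 1]")
  list(raw = p_values, adjusted = stats::p.adjust(p_values, method = "BH"))
}
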