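CHISQ1_MEDIAN <- 0.4549364

#' Paired TDT statistic on transmitted / pseudo-control dosages
#'
#' The paired test at one site compares, for every case haplotype, the
#' transmitted dose `rho` with its pseudo-control dose `pi` via the
#' discordance sums
#' `NUM = sum(rho * (1 - pi))` and `DEN = NUM + sum(pi * (1 - rho))`.
#' Then `beta = logit(NUM/DEN)`, `var(beta) = DEN / (NUM * (DEN - NUM))`, and
#' `X = beta^2 / var(beta)` follows chi-squared with 1 df under transmission
#' equilibrium — the exact-form conditional-likelihood statistic; with hard
#' 0/1 doses it reduces to the classical discordant-count TDT. Boundary cases
#' (`NUM` equal to 0 or `DEN`, or `DEN = 0`) are flagged degenerate and carry
#' no statistic; with `haldane = TRUE` a 0.5 continuity correction is added
#' to both discordant sums instead (off by default).
#'
#' @param rho,pi Equal-length numeric vectors of transmitted and
#'   pseudo-control doses over all case haplotypes, entries in `[0, 1]`.
#' @param haldane Add 0.5 to both discordant sums (Haldane-Anscombe style)
#'   instead of flagging boundary sites degenerate.
#' @return One-row tibble: `num`, `den`, `beta`, `var_beta`, `x`, `p`,
#'   `degenerate`.
#' @export
paired_tdt <- function(rho, pi, haldane = FALSE) {
  check_doses(rho, pi)
  num <- sum(rho * (1 - pi))
  den <- num + sum(pi * (1 - rho))
  if (haldane) {
    num <- num + 0.5
    den <- den + 1
  }
  degenerate <- den == 0 || num == 0 || num == den
  if (degenerate) {
    return(tibble::tibble(num = num, den = den, beta = NA_real_,
                          var_beta = NA_real_, x = NA_real_, p = NA_real_,
                          degenerate = TRUE))
  }
  beta <- log(num / (den - num))
  var_beta <- den / (num * (den - num))
  x <- beta^2 / var_beta
  tibble::tibble(num = num, den = den, beta = beta, var_beta = var_beta,
                 x = x, p = pchisq(x, 1, lower.tail = FALSE),
                 degenerate = FALSE)
}

#' Unpaired marginal-homogeneity test on dosages
#'
#' Builds the expected 2x2 table of (transmitted, pseudo-control) allele
#' configurations, `A = sum((1-rho)(1-pi))`, `B = sum((1-rho) pi)`,
#' `C = sum(rho (1-pi))`, `D = sum(rho pi)`, with margins `n1. = A + C`,
#' `n2. = B + D`, `n.1 = A + B`, `n.2 = C + D`, and tests marginal
#' homogeneity with `X = sum_m (n_m. - n._m)^2 / (n_m. + n._m)`, chi-squared
#' with 1 df under the null.
#'
#' @inheritParams paired_tdt
#' @return One-row tibble: `a`, `b`, `c`, `d`, `x`, `p`, `degenerate`.
#' @export
unpaired_test <- function(rho, pi) {
  check_doses(rho, pi)
  a <- sum((1 - rho) * (1 - pi))
  b <- sum((1 - rho) * pi)
  cc <- sum(rho * (1 - pi))
  d <- sum(rho * pi)
  n1_ <- a + cc; n2_ <- b + d; n_1 <- a + b; n_2 <- cc + d
  s1 <- n1_ + n_1; s2 <- n2_ + n_2
  degenerate <- s1 == 0 && s2 == 0
  if (degenerate) {
    return(tibble::tibble(a = a, b = b, c = cc, d = d, x = NA_real_,
                          p = NA_real_, degenerate = TRUE))
  }
  t1 <- if (s1 > 0) (n1_ - n_1)^2 / s1 else 0
  t2 <- if (s2 > 0) (n2_ - n_2)^2 / s2 else 0
  x <- t1 + t2
  tibble::tibble(a = a, b = b, c = cc, d = d, x = x,
                 p = pchisq(x, 1, lower.tail = FALSE), degenerate = FALSE)
}

check_doses <- function(rho, pi) {
  if (length(rho) != length(pi)) stop("rho and pi differ in length", call. = FALSE)
  if (length(rho) < 1) stop("need at least one haplotype pair", call. = FALSE)
  if (any(rho < 0 | rho > 1 | pi < 0 | pi > 1)) {
    stop("doses must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Genomic inflation factor
#'
#' `lambda = median(X) / 0.4549364`, the observed over expected median of a
#' chi-squared(1 df) statistic; computed on finite statistics only.
#'
#' @param x_stats Numeric vector of 1-df chi-squared statistics.
#' @return The inflation factor.
#' @export
inflation_lambda <- function(x_stats) {
  x_stats <- x_stats[is.finite(x_stats)]
  if (length(x_stats) == 0) stop("no finite statistics", call. = FALSE)
  median(x_stats) / CHISQ1_MEDIAN
}

#' Apply genomic control to a scan
#'
#' Divides the chosen chi-squared statistics by `lambda` and recomputes
#' p-values. By convention only inflation is corrected: `lambda < 1` is a
#' no-op.
#'
#' @param results Scan results tibble (see [run_surfbat()]).
#' @param lambda Inflation factor to divide by.
#' @param which Which statistic to correct: `"paired"`, `"unpaired"` or both.
#' @return The results tibble with corrected `x_*` and `p_*` columns.
#' @export
genomic_control <- function(results, lambda,
                            which = c("paired", "unpaired")) {
  if (lambda < 1) return(results)
  which <- match.arg(which, several.ok = TRUE)
  if ("paired" %in% which && "x_paired" %in% names(results)) {
    results$x_paired <- results$x_paired / lambda
    results$p_paired <- pchisq(results$x_paired, 1, lower.tail = FALSE)
  }
  if ("unpaired" %in% which && "x_unpaired" %in% names(results)) {
    results$x_unpaired <- results$x_unpaired / lambda
    results$p_unpaired <- pchisq(results$x_unpaired, 1, lower.tail = FALSE)
  }
  results
}
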