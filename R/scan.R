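#' Run the full association scan
#'
#' End-to-end engine: builds the dosage table (copying HMM on typed sites,
#' interpolation at untyped sites), computes per-site case MAF and INFO,
#' filters sites below the MAF or INFO thresholds, and computes the paired
#' (conditional-likelihood TDT) and/or unpaired (marginal-homogeneity)
#' chi-squared statistics on the surviving sites. Filtered sites carry no
#' p-values. The genomic inflation factor is computed over the finite,
#' non-degenerate statistics of the configured test (paired by default).
#'
#' @param panel A [haplotype_panel()] with `cm` attached.
#' @param targets [target_haplotypes()] at a subset of panel sites, `cm`
#'   attached.
#' @param params [hmm_params()].
#' @param maf_min Case minor-allele-frequency threshold (default 0.01).
#' @param info_min INFO-score threshold (default 0.3).
#' @param test Which statistics to compute: `"both"`, `"paired"`,
#'   `"unpaired"`.
#' @param lambda_on Statistic used for the inflation factor (`"paired"`
#'   default).
#' @param gc Apply genomic control (divide statistics by lambda and recompute
#'   p-values) when lambda exceeds 1.
#' @param haldane Continuity-correct boundary sites in the paired test
#'   instead of flagging them degenerate.
#' @param dosages Optionally a precomputed [build_dosage_table()] result for
#'   these inputs, to avoid recomputation.
#' @return A `surfbat_scan` object: list with `results` (tibble, one row per
#'   panel site), `lambda_gc`, `n_tested`, `n_filtered`, `config`. Columns of
#'   `results`: `chrom, pos, id, ref, alt, typed, maf_case, info, num, den,
#'   beta, se_beta, x_paired, p_paired, a, b, c, d, x_unpaired, p_unpaired,
#'   filtered, filter_reason`.
#' @export
run_surfbat <- function(panel, targets, params = hmm_params(),
                        maf_min = 0.01, info_min = 0.3,
                        test = c("both", "paired", "unpaired"),
                        lambda_on = c("paired", "unpaired"),
                        gc = FALSE, haldane = FALSE, dosages = NULL) {
  test <- match.arg(test)
  lambda_on <- match.arg(lambda_on)
  if (test == "unpaired" && lambda_on == "paired") lambda_on <- "unpaired"
  if (is.null(dosages)) dosages <- build_dosage_table(panel, targets, params)
  rho <- dosages$rho
  pi <- dosages$pi
  H_t <- ncol(rho)
  theta <- rowMeans(rho)
  maf <- pmin(theta, 1 - theta)
  bern <- rowSums(rho * (1 - rho))
  info <- ifelse(theta %in% c(0, 1), 1, 1 - bern / (H_t * theta * (1 - theta)))

  filter_reason <- rep(NA_character_, nrow(rho))
  filter_reason[maf < maf_min] <- "maf"
  filter_reason[is.na(filter_reason) & info < info_min] <- "info"
  filtered <- !is.na(filter_reason)
  if (all(filtered)) warning("no sites survive the MAF/INFO filters", call. = FALSE)

  res <- dosages$sites[, c("chrom", "pos", "id", "ref", "alt")]
  res$typed <- dosages$typed
  res$maf_case <- maf
  res$info <- info

  na <- rep(NA_real_, nrow(rho))
  res$num <- na; res$den <- na; res$beta <- na; res$se_beta <- na
  res$x_paired <- na; res$p_paired <- na
  res$a <- na; res$b <- na; res$c <- na; res$d <- na
  res$x_unpaired <- na; res$p_unpaired <- na

  keep <- which(!filtered)
  if (length(keep) > 0 && test %in% c("both", "paired")) {
    num <- rowSums(rho[keep, , drop = FALSE] * (1 - pi[keep, , drop = FALSE]))
    den <- num + rowSums(pi[keep, , drop = FALSE] * (1 - rho[keep, , drop = FALSE]))
    if (haldane) { num <- num + 0.5; den <- den + 1 }
    degen <- den == 0 | num == 0 | num == den
    beta <- ifelse(degen, NA_real_, log(num / (den - num)))
    var_beta <- ifelse(degen, NA_real_, den / (num * (den - num)))
    x <- beta^2 / var_beta
    res$num[keep] <- num; res$den[keep] <- den
    res$beta[keep] <- beta; res$se_beta[keep] <- sqrt(var_beta)
    res$x_paired[keep] <- x
    res$p_paired[keep] <- pchisq(x, 1, lower.tail = FALSE)
  }
  if (length(keep) > 0 && test %in% c("both", "unpaired")) {
    rk <- rho[keep, , drop = FALSE]; pk <- pi[keep, , drop = FALSE]
    a <- rowSums((1 - rk) * (1 - pk)); b <- rowSums((1 - rk) * pk)
    cc <- rowSums(rk * (1 - pk)); d <- rowSums(rk * pk)
    s1 <- 2 * a + b + cc; s2 <- b + cc + 2 * d
    x <- ifelse(s1 > 0, (cc - b)^2 / s1, 0) + ifelse(s2 > 0, (b - cc)^2 / s2, 0)
    x[s1 == 0 & s2 == 0] <- NA_real_
    res$a[keep] <- a; res$b[keep] <- b; res$c[keep] <- cc; res$d[keep] <- d
    res$x_unpaired[keep] <- x
    res$p_unpaired[keep] <- pchisq(x, 1, lower.tail = FALSE)
  }
  res$filtered <- filtered
  res$filter_reason <- filter_reason

  xcol <- if (lambda_on == "paired") res$x_paired else res$x_unpaired
  lam <- if (any(is.finite(xcol))) inflation_lambda(xcol) else NA_real_
  if (isTRUE(gc) && is.finite(lam) && lam > 1) {
    res <- genomic_control(res, lam)
  }
  structure(
    list(results = res, lambda_gc = lam,
         n_tested = sum(!filtered), n_filtered = sum(filtered),
         config = list(maf_min = maf_min, info_min = info_min, test = test,
                       lambda_on = lambda_on, gc = gc, haldane = haldane,
                       ne = params$ne, eps = params$eps,
                       genomewide = 5e-8, suggestive = 1e-5)),
    class = "surfbat_scan"
  )
}

#' @exportS3Method base::print
print.surfbat_scan <- function(x, ...) {
  cat("<surfbat_scan> ", nrow(x$results), " sites: ", x$n_tested, " tested, ",
      x$n_filtered, " filtered; lambda = ",
      formatC(x$lambda_gc, digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Per-site scan results as a tibble
#' @param x A `surfbat_scan`.
#' @param ... Unused.
#' @export
tidy.surfbat_scan <- function(x, ...) x$results

#' One-row scan summary
#' @param x A `surfbat_scan`.
#' @param ... Unused.
#' @return Tibble with `lambda_gc`, `n_sites`, `n_tested`, `n_filtered`,
#'   `n_degenerate`.
#' @export
glance.surfbat_scan <- function(x, ...) {
  tibble::tibble(
    lambda_gc = x$lambda_gc,
    n_sites = nrow(x$results),
    n_tested = x$n_tested,
    n_filtered = x$n_filtered,
    n_degenerate = sum(!x$results$filtered & is.na(x$results$x_paired) &
                         is.na(x$results$x_unpaired))
  )
}

scan_pvals <- function(x, which) {
  p <- if (which == "paired") x$results$p_paired else x$results$p_unpaired
  p[!is.na(p)]
}

#' QQ plot of scan p-values
#'
#' @param object A `surfbat_scan`.
#' @param which `"paired"` (default) or `"unpaired"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surfbat_scan <- function(object, which = c("paired", "unpaired"),
                                  ...) {
  which <- match.arg(which)
  p <- sort(scan_pvals(object, which))
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = sprintf("QQ plot (%s test), lambda = %.3f",
                      which, object$lambda_gc)
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of scan p-values
#'
#' Horizontal reference lines mark the conventional genome-wide (5e-8) and
#' suggestive (1e-5) thresholds; they annotate, never filter.
#'
#' @inheritParams autoplot.surfbat_scan
#' @param scan A `surfbat_scan`.
#' @return A ggplot.
#' @export
plot_manhattan <- function(scan, which = c("paired", "unpaired")) {
  which <- match.arg(which)
  res <- scan$results
  p <- if (which == "paired") res$p_paired else res$p_unpaired
  df <- tibble::tibble(chrom = res$chrom, pos = res$pos, p = p)
  df <- df[!is.na(df$p), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = -log10(.data$p),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.5, show.legend = length(unique(df$chrom)) > 1) +
    ggplot2::geom_hline(yintercept = -log10(5e-8), linetype = 1,
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(1e-5), linetype = 2,
                        colour = "blue") +
    ggplot2::labs(x = "Position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
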