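#' Partner haplotype index
#'
#' Reference haplotypes are stored in pairs per individual; with 0-based
#' columns, individual `i` owns columns `2i` and `2i + 1`. The partner of an
#' even column is the next one, of an odd column the previous one — an
#' involution. (In 1-based counting this is the familiar r(k) = k + 1 for odd
#' k, k - 1 for even k.)
#'
#' @param k 0-based haplotype index (vectorised).
#' @return 0-based index of the partner haplotype.
#' @export
partner_index <- function(k) {
  stopifnot(all(k >= 0))
  ifelse(k %% 2 == 0, k + 1, k - 1)
}

#' Transmitted and pseudo-control dosage at one site
#'
#' Given one target haplotype's posterior copying distribution at a site and
#' the panel alleles there, the transmitted dosage is the posterior
#' probability of copying an ALT-carrying haplotype,
#' `rho = sum_k p_k [H_k = 1]`, and the pseudo-control dosage substitutes each
#' copied haplotype's partner, `pi = sum_k p_k [H_partner(k) = 1]`.
#'
#' @param posterior_row Numeric vector over the 2N reference haplotypes,
#'   summing to 1.
#' @param panel_alleles Binary ALT indicators for the same haplotypes at the
#'   site of interest.
#' @return Named numeric vector `c(rho =, pi =)`.
#' @export
site_dosage <- function(posterior_row, panel_alleles) {
  if (length(posterior_row) != length(panel_alleles)) {
    stop("posterior and allele vectors differ in length", call. = FALSE)
  }
  idx0 <- seq_along(panel_alleles) - 1L
  c(rho = sum(posterior_row[panel_alleles == 1]),
    pi = sum(posterior_row[partner_index(idx0)[panel_alleles == 1] + 1L]))
}

#' Interpolate dosages at an untyped site
#'
#' Dosages at sites absent from the array are linear interpolations, on the
#' genetic-map scale, of the dosages obtained by applying the flanking typed
#' sites' posteriors to the untyped site's panel alleles:
#' `(1 - w) * left + w * right` with `w = (cm - cm_left)/(cm_right - cm_left)`.
#' Outside the typed range the nearest typed posterior is used as-is; a zero
#' cM span falls back to `w = 0.5`.
#'
#' @param left,right Dosage values (scalars or equal-length vectors) from the
#'   left and right flanking typed-site posteriors.
#' @param w Weight on the right flank, in `[0, 1]`.
#' @return Interpolated dosage(s).
#' @export
interpolate_untyped <- function(left, right, w) {
  stopifnot(all(w >= 0 & w <= 1))
  (1 - w) * left + w * right
}

#' IMPUTE-style INFO score on haplotype dosages
#'
#' Ratio-of-variances imputation quality on the haploid doses at one site:
#' with estimated ALT frequency `theta = mean(rho)`,
#' `INFO = 1 - sum(rho*(1-rho)) / (H * theta * (1-theta))`. Equals 1 when all
#' doses are certain (binary), 0 when all doses sit at a common value in
#' (0, 1), and is defined as 1 when `theta` is 0 or 1 (no uncertainty is
#' possible).
#'
#' @param rhos Haplotype doses at one site, in `[0, 1]` (>= 2 values).
#' @return INFO score in `(-Inf, 1]`.
#' @export
info_score <- function(rhos) {
  stopifnot(length(rhos) >= 2)
  theta <- mean(rhos)
  if (theta == 0 || theta == 1) return(1)
  1 - sum(rhos * (1 - rhos)) / (length(rhos) * theta * (1 - theta))
}

#' Case minor-allele frequency from imputed doses
#'
#' @param rhos Haplotype doses at one site.
#' @return `min(theta, 1 - theta)` with `theta = mean(rhos)`.
#' @export
case_maf <- function(rhos) {
  stopifnot(length(rhos) >= 1)
  theta <- mean(rhos)
  min(theta, 1 - theta)
}

# Flank bookkeeping for untyped-site interpolation: for every panel site,
# 0-based indices of the left/right typed rows and the weight on the right.
interp_weights <- function(panel_cm, typed_rows_cm, typed_idx_in_panel) {
  n_typed <- length(typed_rows_cm)
  S <- length(panel_cm)
  iv <- findInterval(panel_cm, typed_rows_cm)
  li <- pmax(iv, 1L)
  ri <- pmin(iv + 1L, n_typed)
  li <- pmin(li, n_typed)
  span <- typed_rows_cm[ri] - typed_rows_cm[li]
  w <- ifelse(ri == li, 0,
       ifelse(span == 0, 0.5, (panel_cm - typed_rows_cm[li]) / span))
  # outside the typed range: nearest typed posterior, degenerate weight
  before <- panel_cm < typed_rows_cm[1]
  after <- panel_cm > typed_rows_cm[n_typed]
  li[before] <- 1L; ri[before] <- 1L; w[before] <- 0
  li[after] <- n_typed; ri[after] <- n_typed; w[after] <- 0
  # a panel site that IS a typed site uses its own posterior exactly
  is_typed <- logical(S)
  is_typed[typed_idx_in_panel] <- TRUE
  li[typed_idx_in_panel] <- seq_len(n_typed)
  ri[typed_idx_in_panel] <- seq_len(n_typed)
  w[typed_idx_in_panel] <- 0
  list(li = li - 1L, ri = ri - 1L, w = w, typed = is_typed)
}

match_typed_sites <- function(panel, targets) {
  idx <- match(site_key(targets$sites), site_key(panel$sites))
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " typed site(s) absent from the panel", call. = FALSE)
  }
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("typed sites out of order relative to the panel", call. = FALSE)
  }
  idx
}

#' Dosage table for a case cohort
#'
#' Runs the copying HMM for every case haplotype on the typed sites and
#' produces transmitted (`rho`) and pseudo-control (`pi`) dosages at every
#' panel site: exact posterior dosages at typed sites, genetic-distance
#' interpolation elsewhere. Interpolation is applied to the (rho, pi)
#' functionals rather than to whole posterior rows — identical for these
#' linear functionals and far cheaper.
#'
#' The pseudo-control construction assumes the two haplotypes within a
#' reference individual share similar ancestry; this is documented, not
#' enforced. When per-haplotype group labels are present, a diagnostic
#' warning is emitted if more than 1% of posterior mass sits on haplotypes
#' whose partner carries a different label.
#'
#' @param panel A [haplotype_panel()] with `cm` attached.
#' @param targets A [target_haplotypes()] whose sites are a subset of the
#'   panel's (matched on chrom, pos, ref, alt) with `cm` attached.
#' @param params [hmm_params()].
#' @return A list of class `dosage_table`: `rho` and `pi` (panel site x
#'   target haplotype matrices), `typed` (logical per panel site), `sites`
#'   (the panel's site tibble).
#' @export
build_dosage_table <- function(panel, targets, params = hmm_params()) {
  typed_idx <- match_typed_sites(panel, targets)
  panel_typed <- subset_sites(panel, typed_idx)
  iw <- interp_weights(panel$sites$cm, panel_typed$sites$cm, typed_idx)
  H_t <- ncol(targets$haplotypes)
  S <- nrow(panel$sites)
  rho <- matrix(NA_real_, S, H_t)
  pi <- matrix(NA_real_, S, H_t)
  groups <- haplotype_groups(panel)
  cross_mass <- 0; total_mass <- 0
  cross_partner <- if (!is.null(groups)) {
    idx0 <- seq_along(groups) - 1L
    groups[partner_index(idx0) + 1L] != groups
  } else NULL
  alleles_t <- t(panel$haplotypes)
  for (h in seq_len(H_t)) {
    post <- forward_backward(targets$haplotypes[, h], panel_typed, params)
    d <- dosages_cpp(t(post), alleles_t, iw$li, iw$ri, iw$w)
    rho[, h] <- d$rho
    pi[, h] <- d$pi
    if (!is.null(cross_partner) && any(cross_partner)) {
      cross_mass <- cross_mass + sum(post[, cross_partner])
      total_mass <- total_mass + nrow(post)
    }
  }
  if (!is.null(cross_partner) && any(cross_partner) &&
      total_mass > 0 && cross_mass / total_mass > 0.01) {
    warning(sprintf(paste0("%.1f%% of posterior copying mass pairs haplotypes ",
                           "across group labels; pseudo-controls may be ",
                           "ancestry-mismatched"), 100 * cross_mass / total_mass),
            call. = FALSE)
  }
  structure(list(rho = rho, pi = pi, typed = iw$typed, sites = panel$sites),
            class = "dosage_table")
}

#' @exportS3Method base::print
print.dosage_table <- function(x, ...) {
  cat("<dosage_table> ", nrow(x$rho), " sites x ", ncol(x$rho),
      " case haplotypes (", sum(x$typed), " typed sites)\n", sep = "")
  invisible(x)
}

#' Export a dosage table as a tidy tibble
#'
#' @param x A `dosage_table`.
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `pos`, `hap`, `rho`, `pi`, `typed`,
#'   one row per (site, case haplotype).
#' @export
tidy.dosage_table <- function(x, ...) {
  S <- nrow(x$rho); H <- ncol(x$rho)
  tibble::tibble(
    chrom = rep(x$sites$chrom, H),
    pos = rep(x$sites$pos, H),
    hap = rep(seq_len(H), each = S),
    rho = as.vector(x$rho),
    pi = as.vector(x$pi),
    typed = rep(x$typed, H)
  )
}

#' Mean posterior copying mass per reference group
#'
#' Runs the copying HMM for every case haplotype on the typed sites and
#' averages, over haplotypes and sites, the posterior mass assigned to each
#' reference group. A calibration diagnostic: for cases simulated as mosaics
#' with known group weights, the recovered masses should match the weights.
#'
#' @inheritParams build_dosage_table
#' @return A tibble with columns `group` and `mass` (masses sum to 1).
#' @export
copying_group_mass <- function(panel, targets, params = hmm_params()) {
  groups <- haplotype_groups(panel)
  if (is.null(groups)) stop("panel carries no group labels", call. = FALSE)
  typed_idx <- match_typed_sites(panel, targets)
  panel_typed <- subset_sites(panel, typed_idx)
  lev <- sort(unique(groups))
  gidx <- match(groups, lev) - 1L
  acc <- numeric(length(lev))
  H_t <- ncol(targets$haplotypes)
  for (h in seq_len(H_t)) {
    post <- forward_backward(targets$haplotypes[, h], panel_typed, params)
    acc <- acc + group_mass_cpp(post, gidx, length(lev))
  }
  tibble::tibble(group = lev, mass = acc / H_t)
}
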