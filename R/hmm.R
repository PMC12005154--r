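#' Li-Stephens copying-model parameters
#'
#' @param ne Effective population size (dimensionless scale factor in the
#'   switch rate). Default 20000, the common imputation-engine default.
#' @param eps Per-site allele mismatch probability: the copying mosaic is
#'   allowed to be imperfect, absorbing recent mutation and genotyping error.
#'   Default 1e-4.
#' @param min_switch Floor on the per-interval switch probability when the
#'   genetic distance is positive. Default 1e-12.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(ne = 20000, eps = 1e-4, min_switch = 1e-12) {
  stopifnot(ne > 0, eps > 0, eps < 0.5, min_switch >= 0)
  structure(list(ne = ne, eps = eps, min_switch = min_switch),
            class = "hmm_params")
}

#' Per-interval switch probability of the copying HMM
#'
#' The classic Li-Stephens parameterization: over a genetic distance `d_cm`
#' (cM) with `H` reference haplotypes, the probability of leaving the current
#' copying state is \eqn{r = 1 - \exp(-0.04 \cdot ne \cdot d / H)} (the
#' `0.04` converts cM to Morgans inside `4 Ne g / H`). The full transition
#' kernel from state k to l is `r/H + (1-r)*[k == l]`: switches land uniformly
#' on the panel. `r` is floored at `min_switch` for positive distances; a zero
#' distance gives the identity kernel.
#'
#' @param d_cm Genetic distance in centiMorgans (vectorised, >= 0).
#' @param H Number of reference haplotypes (>= 2).
#' @param params [hmm_params()].
#' @return Switch probabilities in `[0, 1)`.
#' @export
switch_prob <- function(d_cm, H, params = hmm_params()) {
  if (H < 2) stop("need at least 2 reference haplotypes", call. = FALSE)
  if (any(d_cm < 0)) stop("genetic distances must be >= 0", call. = FALSE)
  r <- 1 - exp(-0.04 * params$ne * d_cm / H)
  pmax(r, ifelse(d_cm > 0, params$min_switch, 0))
}

#' Emission probability of the copying HMM
#'
#' Symmetric allele-mismatch model: `1 - eps` when target and copied panel
#' alleles agree, `eps` otherwise.
#'
#' @param target_allele,panel_allele Binary alleles (vectorised).
#' @param params [hmm_params()].
#' @export
emission_prob <- function(target_allele, panel_allele, params = hmm_params()) {
  stopifnot(all(target_allele %in% 0:1), all(panel_allele %in% 0:1))
  ifelse(target_allele == panel_allele, 1 - params$eps, params$eps)
}

check_typed_inputs <- function(target_hap, panel) {
  alleles <- panel$haplotypes
  if (length(target_hap) != nrow(alleles)) {
    stop("target haplotype length must match number of typed sites",
         call. = FALSE)
  }
  if (ncol(alleles) < 2) stop("panel needs >= 2 haplotypes", call. = FALSE)
  cm <- panel$sites$cm
  if (anyNA(cm)) {
    stop("typed sites carry no genetic positions; run attach_genetic_map()",
         call. = FALSE)
  }
  if (is.unsorted(cm)) stop("cM must be non-decreasing", call. = FALSE)
  list(alleles = alleles, cm = cm)
}

#' Forward-backward posteriors of the copying state
#'
#' Exact posteriors `P(s_j = k | o)` of the Li-Stephens HMM for one target
#' haplotype against a reference panel restricted to the typed sites: uniform
#' `1/H` initial distribution, [switch_prob()] transitions over the inter-site
#' genetic distances, and [emission_prob()] emissions. Computed with per-site
#' rescaling, so long chromosomes do not underflow. Adjacent typed sites at
#' identical cM get an identity transition.
#'
#' @param target_hap Integer vector of observed alleles at the typed sites.
#' @param panel A [haplotype_panel()] restricted to the typed sites, with
#'   `cm` attached.
#' @param params [hmm_params()].
#' @return Matrix (typed site x reference haplotype) of posteriors; each row
#'   sums to 1.
#' @export
forward_backward <- function(target_hap, panel, params = hmm_params()) {
  inp <- check_typed_inputs(target_hap, panel)
  H <- ncol(inp$alleles)
  r <- switch_prob(pmax(diff(inp$cm), 0), H, params)
  fb_posteriors_cpp(as.integer(target_hap), inp$alleles, r, params$eps)
}

#' Brute-force copying posteriors by path enumeration
#'
#' Independent oracle for [forward_backward()]: enumerates every hidden-state
#' path, weights it by its product of initial, transition and emission terms,
#' and marginalises. Only feasible for tiny instances
#' (`H^sites <= 1e6`).
#'
#' @inheritParams forward_backward
#' @return Posterior matrix as in [forward_backward()].
#' @export
brute_force_posteriors <- function(target_hap, panel, params = hmm_params()) {
  inp <- check_typed_inputs(target_hap, panel)
  alleles <- inp$alleles
  T_ <- nrow(alleles); H <- ncol(alleles)
  if (H^T_ > 1e6) stop("instance too large for path enumeration", call. = FALSE)
  r <- switch_prob(pmax(diff(inp$cm), 0), H, params)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), T_)))
  w <- rep(1 / H, nrow(paths))
  for (t in seq_len(T_)) {
    k <- paths[, t]
    e <- ifelse(alleles[cbind(t, k)] == target_hap[t], 1 - params$eps, params$eps)
    w <- w * e
    if (t < T_) {
      stay <- paths[, t + 1] == k
      w <- w * (r[t] / H + (1 - r[t]) * stay)
    }
  }
  post <- matrix(0, T_, H)
  for (t in seq_len(T_)) {
    post[t, ] <- vapply(seq_len(H),
                        function(k) sum(w[paths[, t] == k]), numeric(1))
  }
  post / rowSums(post)
}
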