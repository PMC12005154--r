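scale_n <- function(n, scale, floor_at = 4L) {
  max(as.integer(round(n * scale)), floor_at)
}

#' Build a named simulation scenario
#'
#' Fully reproducible scenario bundles for calibration and power studies,
#' each a deterministic function of `(name, scale, seed)`:
#'
#' * `null` — cases are unbiased 10 cM mosaics of a two-group (AFR/FGR-like)
#'   panel with 50/50 tile-source weights; the transmission-equilibrium null
#'   holds everywhere.
#' * `ancestry_signal` — cases drawn from a pre-simulated mosaic pool so
#'   that, at a focal mid-chromosome position, tiles come from the FGR-like
#'   group versus the AFR-like group in a 650:250 ratio (scaled): a purely
#'   local-ancestry signal with no allele constraint.
#' * `allelic_signal` — cases drawn from the pool so that a signal variant
#'   (chosen mid-chromosome among variants with MAF >= 0.2 in both groups)
#'   has 500 carrier and 400 non-carrier haplotypes (scaled); carriers come
#'   from any group, so the allelic signal is ancestry-confounded.
#' * `admixed_null` — three-way admixed cases with tile-source weights
#'   1/6, 1/3, 1/2 (AFR/EUR/ASIA) and mean tile length 100/12 cM, the
#'   expected segment length 12 generations after admixture; no signal.
#' * `small_panel_inflation` — cases are 5 cM mosaics of a well-matched
#'   (EUR-like) group; the bundle carries two reference panels over the same
#'   sites: `panel` (all well-matched haplotypes) and `panel_mixed` (a small
#'   well-matched subset plus many mismatched haplotypes), to contrast
#'   inflation factors.
#'
#' Array-like typed sites are designed per bundle (MAF > 0.1, r-squared 0.8
#' LD thinning, random selection).
#'
#' @param name Scenario name (see above).
#' @param scale Scale factor applied to case counts, pool size and site
#'   counts; 1 reproduces the bundle's reference conditions.
#' @param seed Integer seed; the bundle is a pure function of
#'   `(name, scale, seed)`.
#' @return A list of class `surfbat_scenario`: `name`, `config`, `panel`
#'   (and `panel_mixed` where applicable), `cases` (a
#'   [target_haplotypes()] at all panel sites), `typed_idx`, `targets`
#'   (cases restricted to typed sites), `truth` (list: `tracks` tibble and
#'   optional `signal` tibble).
#' @export
scenario <- function(name = c("null", "ancestry_signal", "allelic_signal",
                              "admixed_null", "small_panel_inflation"),
                     scale = 1, seed = 1) {
  name <- match.arg(name)
  stopifnot(scale > 0)
  set.seed(seed)
  out <- switch(name,
    null = scenario_null(scale),
    ancestry_signal = scenario_ancestry(scale),
    allelic_signal = scenario_allelic(scale),
    admixed_null = scenario_admixed(scale),
    small_panel_inflation = scenario_small_panel(scale)
  )
  out$name <- name
  out$config$scale <- scale
  out$config$seed <- seed
  class(out) <- "surfbat_scenario"
  out
}

finish_scenario <- function(panel, cases, tracks, config, signal = NULL,
                            force_typed = integer(0)) {
  typed_idx <- design_array_sites(panel, maf_min = 0.1, r2_max = 0.8,
                                  n_sites = config$n_typed)
  typed_idx <- sort(union(typed_idx, force_typed))
  list(
    config = config,
    panel = panel,
    cases = cases,
    typed_idx = typed_idx,
    targets = subset_sites(cases, typed_idx),
    truth = list(tracks = tracks, signal = signal)
  )
}

scenario_null <- function(scale) {
  cfg <- list(
    groups = c(AFR = 250, FGR = 250), n_sites = 5000, n_typed = 1000,
    n_cases = 200, tile_cm = 10, weights = c(AFR = 0.5, FGR = 0.5),
    chrom_cm = 25
  )
  cfg$groups[] <- vapply(cfg$groups, scale_n, integer(1), scale = scale)
  cfg$n_sites <- scale_n(cfg$n_sites, scale, 200L)
  cfg$n_typed <- scale_n(cfg$n_typed, scale, 50L)
  cfg$n_cases <- scale_n(cfg$n_cases, scale)
  panel <- generate_panel(cfg$groups, n_sites = cfg$n_sites,
                          chrom_cm = cfg$chrom_cm)
  sim <- simulate_case_cohort(panel, cfg$n_cases,
                              mosaic_spec(cfg$tile_cm, cfg$weights))
  finish_scenario(panel, sim$targets, sim$tracks, cfg)
}

scenario_ancestry <- function(scale) {
  cfg <- list(
    groups = c(AFR = 250, FGR = 250), n_sites = 3000, n_typed = 1000,
    tile_cm = 10, weights = c(AFR = 0.5, FGR = 0.5), chrom_cm = 25,
    pool_size = 4000, n_focal_fgr = 650, n_focal_afr = 250,
    focal_cm = 12.5
  )
  cfg$groups[] <- vapply(cfg$groups, scale_n, integer(1), scale = scale)
  cfg$n_sites <- scale_n(cfg$n_sites, scale, 200L)
  cfg$n_typed <- scale_n(cfg$n_typed, scale, 50L)
  cfg$pool_size <- scale_n(cfg$pool_size, scale, 40L)
  cfg$n_focal_fgr <- scale_n(cfg$n_focal_fgr, scale)
  cfg$n_focal_afr <- scale_n(cfg$n_focal_afr, scale)
  if ((cfg$n_focal_fgr + cfg$n_focal_afr) %% 2 == 1) {
    cfg$n_focal_fgr <- cfg$n_focal_fgr + 1L
  }
  panel <- generate_panel(cfg$groups, n_sites = cfg$n_sites,
                          chrom_cm = cfg$chrom_cm)
  pool <- simulate_haplotype_pool(panel, cfg$pool_size,
                                  mosaic_spec(cfg$tile_cm, cfg$weights))
  idx <- inject_local_ancestry_signal(pool, cfg$focal_cm, "FGR",
                                      cfg$n_focal_fgr, "AFR",
                                      cfg$n_focal_afr)
  cases <- pool_to_targets(pool, idx)
  tracks <- pool$tracks[pool$tracks$hap %in% idx, ]
  signal <- tibble::tibble(
    type = "local_ancestry", focal_cm = cfg$focal_cm,
    focal_pos = as.integer(cfg$focal_cm * 1e6),
    n_group_a = cfg$n_focal_fgr, n_group_b = cfg$n_focal_afr,
    group_a = "FGR", group_b = "AFR"
  )
  finish_scenario(panel, cases, tracks, cfg, signal)
}

# candidate signal variants: MAF >= 0.2 within every group; pick the one
# closest to mid-chromosome (deterministic given the panel)
pick_signal_site <- function(panel, maf_min = 0.2) {
  cols <- group_columns(panel)
  ok <- rep(TRUE, nrow(panel$sites))
  for (cl in cols) {
    p <- rowMeans(panel$haplotypes[, cl, drop = FALSE])
    ok <- ok & pmin(p, 1 - p) >= maf_min
  }
  if (!any(ok)) stop("no candidate signal variant with MAF >= 0.2 in all groups",
                     call. = FALSE)
  mid <- (panel$sites$cm[1] + panel$sites$cm[nrow(panel$sites)]) / 2
  which(ok)[which.min(abs(panel$sites$cm[ok] - mid))]
}

scenario_allelic <- function(scale) {
  cfg <- list(
    groups = c(AFR = 250, FGR = 250), n_sites = 3000, n_typed = 1000,
    tile_cm = 10, weights = c(AFR = 0.5, FGR = 0.5), chrom_cm = 25,
    pool_size = 4000, n_carriers = 500, n_noncarriers = 400
  )
  cfg$groups[] <- vapply(cfg$groups, scale_n, integer(1), scale = scale)
  cfg$n_sites <- scale_n(cfg$n_sites, scale, 200L)
  cfg$n_typed <- scale_n(cfg$n_typed, scale, 50L)
  cfg$pool_size <- scale_n(cfg$pool_size, scale, 40L)
  cfg$n_carriers <- scale_n(cfg$n_carriers, scale)
  cfg$n_noncarriers <- scale_n(cfg$n_noncarriers, scale)
  if ((cfg$n_carriers + cfg$n_noncarriers) %% 2 == 1) {
    cfg$n_carriers <- cfg$n_carriers + 1L
  }
  panel <- generate_panel(cfg$groups, n_sites = cfg$n_sites,
                          chrom_cm = cfg$chrom_cm)
  signal_site <- pick_signal_site(panel)
  pool <- simulate_haplotype_pool(panel, cfg$pool_size,
                                  mosaic_spec(cfg$tile_cm, cfg$weights))
  idx <- inject_allelic_signal(pool, signal_site, cfg$n_carriers,
                               cfg$n_noncarriers)
  cases <- pool_to_targets(pool, idx)
  tracks <- pool$tracks[pool$tracks$hap %in% idx, ]
  signal <- tibble::tibble(
    type = "allelic", signal_site = signal_site,
    signal_pos = panel$sites$pos[signal_site],
    signal_id = panel$sites$id[signal_site],
    n_carriers = cfg$n_carriers, n_noncarriers = cfg$n_noncarriers
  )
  finish_scenario(panel, cases, tracks, cfg, signal)
}

scenario_admixed <- function(scale) {
  cfg <- list(
    groups = c(AFR = 167, EUR = 167, ASIA = 166), n_sites = 3000,
    n_typed = 1000, n_cases = 200,
    tile_cm = 100 / 12,  # expected segment length 12 generations post-admixture
    weights = c(AFR = 1 / 6, EUR = 1 / 3, ASIA = 1 / 2), chrom_cm = 25
  )
  cfg$groups[] <- vapply(cfg$groups, scale_n, integer(1), scale = scale)
  cfg$n_sites <- scale_n(cfg$n_sites, scale, 200L)
  cfg$n_typed <- scale_n(cfg$n_typed, scale, 50L)
  cfg$n_cases <- scale_n(cfg$n_cases, scale)
  panel <- generate_panel(cfg$groups, n_sites = cfg$n_sites,
                          chrom_cm = cfg$chrom_cm)
  keep <- frequency_window_filter(panel, 0.05, 0.95)
  panel <- subset_sites(panel, which(keep))
  sim <- simulate_case_cohort(panel, cfg$n_cases,
                              mosaic_spec(cfg$tile_cm, cfg$weights))
  finish_scenario(panel, sim$targets, sim$tracks, cfg)
}

scenario_small_panel <- function(scale) {
  cfg <- list(
    n_matched = 1000, n_matched_small = 50, n_mismatched = 950,
    n_sites = 2000, n_typed = 800, n_cases = 100, tile_cm = 5,
    chrom_cm = 25
  )
  cfg$n_matched <- scale_n(cfg$n_matched, scale, 20L)
  cfg$n_matched_small <- scale_n(cfg$n_matched_small, scale)
  cfg$n_mismatched <- scale_n(cfg$n_mismatched, scale, 16L)
  cfg$n_sites <- scale_n(cfg$n_sites, scale, 200L)
  cfg$n_typed <- scale_n(cfg$n_typed, scale, 50L)
  cfg$n_cases <- scale_n(cfg$n_cases, scale)
  world <- generate_panel(c(EUR = cfg$n_matched, AFR = cfg$n_mismatched),
                          n_sites = cfg$n_sites, chrom_cm = cfg$chrom_cm)
  panel_matched <- subset_individuals(world, seq_len(cfg$n_matched))
  sim <- simulate_case_cohort(panel_matched, cfg$n_cases,
                              mosaic_spec(cfg$tile_cm, c(EUR = 1)))
  panel_mixed <- subset_individuals(
    world, c(seq_len(cfg$n_matched_small),
             cfg$n_matched + seq_len(cfg$n_mismatched)))
  out <- finish_scenario(panel_matched, sim$targets, sim$tracks, cfg)
  out$panel_mixed <- panel_mixed
  out
}

#' @exportS3Method base::print
print.surfbat_scenario <- function(x, ...) {
  cat("<surfbat_scenario> ", x$name, ": panel ", n_haplotypes(x$panel),
      " haplotypes x ", nrow(x$panel$sites), " sites; ",
      ncol(x$cases$haplotypes), " case haplotypes; ",
      length(x$typed_idx), " typed sites\n", sep = "")
  invisible(x)
}

#' Write a scenario bundle to disk
#'
#' Emits the reference panel and typed case haplotypes as phased VCFs, the
#' tile truth track as TSV, and the configuration (including any signal
#' metadata) as JSON.
#'
#' @param bundle A [scenario()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reference = file.path(dir, "reference.vcf"),
    targets = file.path(dir, "targets.vcf"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  write_phased_vcf(bundle$panel, paths[["reference"]])
  write_phased_vcf(bundle$targets, paths[["targets"]])
  utils::write.table(bundle$truth$tracks, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  cfg$name <- bundle$name
  if (!is.null(bundle$truth$signal)) cfg$signal <- as.list(bundle$truth$signal)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
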