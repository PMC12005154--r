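#' Mosaic simulation settings
#'
#' @param tile_cm Mean tile length in centiMorgans; tile breakpoints are a
#'   Poisson process on the cM axis with rate `1/tile_cm`, so tile lengths
#'   are Exponential(`tile_cm`). Default 10, the tile length of the primary
#'   simulation design.
#' @param group_weights Named numeric vector of tile-source group
#'   probabilities; must be non-negative and sum to 1.
#' @param pool_size Optional number of haplotypes to pre-simulate when
#'   building a pool to sample signal carriers from.
#' @return A list of class `mosaic_spec`.
#' @export
mosaic_spec <- function(tile_cm = 10, group_weights, pool_size = NULL) {
  stopifnot(tile_cm > 0, all(group_weights >= 0),
            abs(sum(group_weights) - 1) < 1e-8,
            !is.null(names(group_weights)))
  structure(list(tile_cm = tile_cm, group_weights = group_weights,
                 pool_size = pool_size),
            class = "mosaic_spec")
}

# columns of the panel belonging to each group, per haplotype
group_columns <- function(panel) {
  g <- haplotype_groups(panel)
  if (is.null(g)) stop("panel carries no group labels", call. = FALSE)
  split(seq_along(g), g)
}

#' Simulate one mosaic haplotype
#'
#' Draws tile breakpoints as a Poisson process on the genetic-map axis with
#' rate `1/tile_cm`, assigns each tile a source group from `group_weights`
#' and a source haplotype uniformly within that group, and copies the source
#' alleles verbatim within each tile (no mutation; imperfect copying is the
#' HMM's emission model, not the simulator's). Consumes the current R RNG
#' stream; seed at the caller for reproducibility.
#'
#' @param panel A [haplotype_panel()] with group labels and `cm` attached.
#' @param spec A [mosaic_spec()]; every group in its weights must exist in
#'   the panel with at least one haplotype.
#' @return List with `alleles` (integer vector over panel sites) and `tiles`
#'   (tibble: `start_cm`, `end_cm`, `group`, `source` — 1-based panel
#'   column).
#' @export
simulate_mosaic_haplotype <- function(panel, spec) {
  cols <- group_columns(panel)
  gw <- spec$group_weights
  missing_g <- setdiff(names(gw)[gw > 0], names(cols))
  if (length(missing_g) > 0) {
    stop("group(s) absent from panel: ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  }
  cm <- panel$sites$cm
  if (anyNA(cm)) stop("panel needs genetic positions (cm)", call. = FALSE)
  cm0 <- cm[1]; cm1 <- cm[length(cm)]
  L <- cm1 - cm0
  n_bp <- rpois(1, L / spec$tile_cm)
  bp <- sort(runif(n_bp, cm0, cm1))
  bounds <- c(cm0, bp, cm1)
  n_tiles <- length(bounds) - 1L
  groups <- sample(names(gw), n_tiles, replace = TRUE, prob = gw)
  sources <- vapply(groups, function(g) {
    cl <- cols[[g]]
    cl[sample.int(length(cl), 1L)]
  }, integer(1))
  tile_of_site <- findInterval(cm, bounds, all.inside = TRUE)
  alleles <- panel$haplotypes[cbind(seq_along(cm), sources[tile_of_site])]
  list(
    alleles = as.integer(alleles),
    tiles = tibble::tibble(start_cm = bounds[-length(bounds)],
                           end_cm = bounds[-1],
                           group = unname(groups),
                           source = unname(sources))
  )
}

#' Simulate a pool of mosaic haplotypes
#'
#' @inheritParams simulate_mosaic_haplotype
#' @param n Number of haplotypes to simulate.
#' @param seed Optional seed applied before simulation.
#' @return A `haplotype_pool`: list with `alleles` (site x haplotype integer
#'   matrix), `tracks` (tibble with a `hap` column plus the tile fields) and
#'   `sites` (the panel's site tibble).
#' @export
simulate_haplotype_pool <- function(panel, n, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(panel$sites)
  alleles <- matrix(0L, S, n)
  tracks <- vector("list", n)
  for (h in seq_len(n)) {
    m <- simulate_mosaic_haplotype(panel, spec)
    alleles[, h] <- m$alleles
    tracks[[h]] <- tibble::add_column(m$tiles, hap = h, .before = 1)
  }
  structure(list(alleles = alleles, tracks = dplyr::bind_rows(tracks),
                 sites = panel$sites),
            class = "haplotype_pool")
}

#' Simulate a case cohort as panel mosaics
#'
#' Builds `2 * n_cases` mosaic haplotypes of the reference panel — the null
#' model of the association test, under which cases are exchangeable mosaics
#' of the panel and transmission is balanced at every site.
#'
#' @inheritParams simulate_haplotype_pool
#' @param n_cases Number of (diploid) case individuals.
#' @return List with `targets` (a [target_haplotypes()] at all panel sites)
#'   and `tracks` (tile truth tibble).
#' @export
simulate_case_cohort <- function(panel, n_cases, spec, seed = NULL) {
  stopifnot(n_cases >= 1)
  pool <- simulate_haplotype_pool(panel, 2L * n_cases, spec, seed = seed)
  list(
    targets = target_haplotypes(panel$sites, pool$alleles,
                                sample_ids = sprintf("CASE%04d", seq_len(n_cases))),
    tracks = pool$tracks
  )
}

# group of the tile overlapping a focal cM position, per pool haplotype
tile_group_at <- function(pool, focal_cm) {
  tr <- pool$tracks
  hit <- tr$start_cm <= focal_cm & tr$end_cm >= focal_cm
  # a breakpoint exactly at focal_cm can match two tiles; keep the first
  tr <- tr[hit, ]
  tr <- tr[!duplicated(tr$hap), ]
  out <- rep(NA_character_, ncol(pool$alleles))
  out[tr$hap] <- tr$group
  out
}

#' Select pool haplotypes carrying a local-ancestry excess
#'
#' Chooses, without replacement, exactly `n_a` pool haplotypes whose tile
#' overlapping `focal_cm` was copied from `group_a` and `n_b` from
#' `group_b` — an association between local ancestry and case status with no
#' allele constraint imposed.
#'
#' @param pool A `haplotype_pool` (see [simulate_haplotype_pool()]).
#' @param focal_cm Focal genetic position (cM).
#' @param group_a,group_b Group labels to enrich.
#' @param n_a,n_b Haplotype counts for the two groups.
#' @param seed Optional seed.
#' @return Integer vector of selected pool haplotype indices (length
#'   `n_a + n_b`, distinct).
#' @export
inject_local_ancestry_signal <- function(pool, focal_cm, group_a, n_a,
                                         group_b, n_b, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- tile_group_at(pool, focal_cm)
  ia <- which(g == group_a); ib <- which(g == group_b)
  if (length(ia) < n_a || length(ib) < n_b) {
    stop(sprintf("pool too small at focal position: have %d/%d of group %s, %d/%d of group %s",
                 length(ia), n_a, group_a, length(ib), n_b, group_b),
         call. = FALSE)
  }
  sort(c(sample(ia, n_a), sample(ib, n_b)))
}

#' Select pool haplotypes with an allelic excess
#'
#' Chooses, without replacement, `n_carriers` pool haplotypes carrying the
#' ALT allele at `signal_site` and `n_noncarriers` without it. Carriers come
#' from any source group, so an allele-frequency difference between groups
#' makes the allelic signal ancestry-confounded — the design the paired test
#' is meant to survive.
#'
#' @inheritParams inject_local_ancestry_signal
#' @param signal_site Row index of the signal variant in the pool's site
#'   table.
#' @param n_carriers,n_noncarriers Haplotype counts.
#' @return Integer vector of selected pool haplotype indices.
#' @export
inject_allelic_signal <- function(pool, signal_site, n_carriers,
                                  n_noncarriers, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  carrier <- pool$alleles[signal_site, ] == 1L
  ic <- which(carrier); inc <- which(!carrier)
  if (length(ic) < n_carriers || length(inc) < n_noncarriers) {
    stop(sprintf("pool too small at signal site: have %d/%d carriers, %d/%d noncarriers",
                 length(ic), n_carriers, length(inc), n_noncarriers),
         call. = FALSE)
  }
  sort(c(sample(ic, n_carriers), sample(inc, n_noncarriers)))
}

#' Assemble selected pool haplotypes into a case cohort
#'
#' @param pool A `haplotype_pool`.
#' @param idx Haplotype indices (even count; consecutive pairs become
#'   individuals).
#' @return A [target_haplotypes()] at all pool sites.
#' @export
pool_to_targets <- function(pool, idx) {
  stopifnot(length(idx) %% 2 == 0)
  target_haplotypes(pool$sites, pool$alleles[, idx, drop = FALSE],
                    sample_ids = sprintf("CASE%04d", seq_len(length(idx) / 2)))
}

#' Design an array-like typed-site subset
#'
#' Mimics a genotyping-array site list: restrict to minor-allele frequency
#' above `maf_min`, thin for linkage disequilibrium left-to-right (drop any
#' site whose haplotype correlation r-squared with the last retained site
#' within `window_cm` exceeds `r2_max`), then draw `n_sites` uniformly at
#' random. If fewer candidates survive, all are returned with a warning.
#'
#' @param panel A [haplotype_panel()] with `cm` attached.
#' @param maf_min MAF threshold (default 0.1).
#' @param r2_max LD-thinning threshold (default 0.8).
#' @param n_sites Number of sites to select (default 5000).
#' @param window_cm Thinning window in cM (default 1).
#' @param seed Optional seed for the random draw.
#' @return Sorted integer vector of panel site indices.
#' @export
design_array_sites <- function(panel, maf_min = 0.1, r2_max = 0.8,
                               n_sites = 5000, window_cm = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- alt_freq(panel)
  cand <- which(pmin(p, 1 - p) > maf_min)
  keep <- integer(0)
  last <- NA_integer_
  for (i in cand) {
    if (is.na(last) ||
        panel$sites$cm[i] - panel$sites$cm[last] > window_cm) {
      keep <- c(keep, i); last <- i
      next
    }
    r2 <- suppressWarnings(cor(panel$haplotypes[i, ],
                               panel$haplotypes[last, ]))^2
    if (is.na(r2) || r2 <= r2_max) {
      keep <- c(keep, i); last <- i
    }
  }
  if (length(keep) < n_sites) {
    warning(sprintf("only %d candidate sites after filters (requested %d)",
                    length(keep), n_sites), call. = FALSE)
    return(keep)
  }
  sort(sample(keep, n_sites))
}

#' Derived-allele-frequency window filter
#'
#' @param panel A [haplotype_panel()].
#' @param lo,hi Frequency bounds; sites with ALT frequency in `[lo, hi]` are
#'   kept.
#' @return Logical mask over panel sites.
#' @export
frequency_window_filter <- function(panel, lo = 0.05, hi = 0.95) {
  p <- alt_freq(panel)
  p >= lo & p <= hi
}

#' Every-kth site decimation
#'
#' @param n Number of sites.
#' @param k Decimation stride.
#' @return Indices `1, 1 + k, 1 + 2k, ...`.
#' @export
decimate_sites <- function(n, k) seq(1L, n, by = k)

#' Generate a synthetic structured reference panel
#'
#' Builds a phased multi-group panel with realistic allele-frequency
#' differentiation and local linkage disequilibrium, so simulations never
#' require external data. Per site, an ancestral frequency is drawn from a
#' symmetric Beta (clipped to `[0.05, 0.95]`); group frequencies follow the
#' Balding-Nichols model at divergence `fst`; per group, `n_founders`
#' founder haplotypes are drawn site-wise Bernoulli, and each panel
#' haplotype is a fine-grained mosaic (tile mean `founder_tile_cm`) of its
#' group's founders, which creates LD that decays on the cM scale. Panel
#' haplotypes are paired into individuals within group, so partner
#' haplotypes are ancestry-matched by construction. The genetic map is a
#' constant 1 cM/Mb.
#'
#' @param n_per_group Named integer vector: individuals per group.
#' @param n_sites Number of biallelic sites.
#' @param chrom Chromosome label.
#' @param chrom_cm Chromosome length in cM (positions span `chrom_cm` Mb).
#' @param fst Balding-Nichols divergence of each group from the ancestral
#'   pool (default 0.15).
#' @param n_founders Founder haplotypes per group (default 100).
#' @param founder_tile_cm Mean founder-mosaic tile length in cM (default 1).
#' @param beta_shape Shape of the symmetric ancestral-frequency Beta
#'   (default 0.8).
#' @param seed Optional seed.
#' @return A [haplotype_panel()] with group labels and `cm` attached.
#' @export
generate_panel <- function(n_per_group, n_sites = 5000, chrom = "1",
                           chrom_cm = 300, fst = 0.15, n_founders = 100,
                           founder_tile_cm = 1, beta_shape = 0.8,
                           seed = NULL) {
  stopifnot(!is.null(names(n_per_group)), all(n_per_group >= 1))
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(sample.int(as.integer(chrom_cm * 1e6), n_sites))
  cm <- pos / 1e6
  p_anc <- pmin(pmax(rbeta(n_sites, beta_shape, beta_shape), 0.05), 0.95)
  shape_scale <- (1 - fst) / fst
  groups <- names(n_per_group)
  hap_blocks <- list()
  for (g in groups) {
    p_g <- rbeta(n_sites, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    founders <- matrix(rbinom(n_sites * n_founders, 1L, p_g),
                       n_sites, n_founders)
    founder_panel <- haplotype_panel(
      sites = tibble::tibble(chrom = chrom, pos = pos, id = ".",
                             ref = "A", alt = "G", cm = cm),
      haplotypes = founders[, seq_len(2L * (n_founders %/% 2L)), drop = FALSE],
      group_labels = rep(g, n_founders %/% 2L)
    )
    fspec <- mosaic_spec(tile_cm = founder_tile_cm,
                         group_weights = stats::setNames(1, g))
    block <- matrix(0L, n_sites, 2L * n_per_group[[g]])
    for (h in seq_len(ncol(block))) {
      block[, h] <- simulate_mosaic_haplotype(founder_panel, fspec)$alleles
    }
    hap_blocks[[g]] <- block
  }
  haplotypes <- do.call(cbind, hap_blocks)
  haplotype_panel(
    sites = tibble::tibble(
      chrom = chrom, pos = pos,
      id = sprintf("%s:%d", chrom, pos),
      ref = "A", alt = "G", cm = cm
    ),
    haplotypes = haplotypes,
    sample_ids = sprintf("%s%04d", rep(groups, n_per_group),
                         unlist(lapply(n_per_group, seq_len))),
    group_labels = rep(groups, n_per_group)
  )
}

#' Subset a panel to selected individuals
#'
#' @param panel A [haplotype_panel()].
#' @param ind Integer indices of individuals to keep.
#' @return The restricted panel (column pairs kept together).
#' @export
subset_individuals <- function(panel, ind) {
  cols <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  haplotype_panel(
    sites = panel$sites,
    haplotypes = panel$haplotypes[, cols, drop = FALSE],
    sample_ids = panel$sample_ids[ind],
    group_labels = if (is.null(panel$group_labels)) NULL else {
      g <- panel$group_labels
      if (length(g) == panel$n_ind) g[ind] else g[cols]
    }
  )
}
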