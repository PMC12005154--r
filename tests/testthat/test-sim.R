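make_sim_panel <- function(seed = 123, n_sites = 400, chrom_cm = 50) {
  generate_panel(c(A = 30, B = 30), n_sites = n_sites, chrom_cm = chrom_cm,
                 n_founders = 20, seed = seed)
}

test_that("mosaic haplotypes copy their recorded sources verbatim", {
  panel <- make_sim_panel()
  set.seed(1)
  for (i in 1:5) {
    m <- simulate_mosaic_haplotype(panel, mosaic_spec(10, c(A = 0.5, B = 0.5)))
    cm <- panel$sites$cm
    for (j in seq_len(nrow(m$tiles))) {
      in_tile <- cm >= m$tiles$start_cm[j] & cm <= m$tiles$end_cm[j]
      expect_equal(m$alleles[in_tile],
                   panel$haplotypes[in_tile, m$tiles$source[j]])
    }
    # tiles are contiguous and cover the chromosome
    expect_equal(m$tiles$start_cm[1], cm[1])
    expect_equal(m$tiles$end_cm[nrow(m$tiles)], cm[length(cm)])
    if (nrow(m$tiles) > 1) {
      expect_equal(m$tiles$start_cm[-1], m$tiles$end_cm[-nrow(m$tiles)])
    }
  }
})

test_that("single-group weights always copy from that group", {
  panel <- make_sim_panel()
  set.seed(2)
  m <- simulate_mosaic_haplotype(panel, mosaic_spec(5, c(A = 1)))
  expect_true(all(m$tiles$group == "A"))
  groups <- haplotype_groups(panel)
  expect_true(all(groups[m$tiles$source] == "A"))
})

test_that("tile process is Poisson on the cM axis", {
  panel <- make_sim_panel(n_sites = 20, chrom_cm = 100)
  L <- diff(range(panel$sites$cm))
  spec <- mosaic_spec(10, c(A = 0.5, B = 0.5))
  set.seed(31)
  counts <- integer(4000)
  gaps <- numeric(0)
  for (i in seq_along(counts)) {
    tl <- simulate_mosaic_haplotype(panel, spec)$tiles
    counts[i] <- nrow(tl)
    if (nrow(tl) > 2) {
      # one complete gap per haplotype: pooling all interior gaps would
      # length-bias the sample toward haplotypes with many breakpoints
      gaps <- c(gaps, tl$end_cm[2] - tl$start_cm[2])
    }
  }
  # mean tile count = 1 + L / tile_cm
  expect_equal(mean(counts), 1 + L / 10, tolerance = 0.03)
  # complete tile lengths are Exponential(rate 1/tile_cm)
  expect_gt(suppressWarnings(ks.test(gaps, "pexp", 1 / 10))$p.value, 0.01)
})

test_that("tile-source groups follow the mosaic weights", {
  panel <- make_sim_panel(n_sites = 300, chrom_cm = 100)
  pool <- simulate_haplotype_pool(panel, 200,
                                  mosaic_spec(10, c(A = 0.3, B = 0.7)),
                                  seed = 7)
  frac <- mean(pool$tracks$group == "B")
  se <- sqrt(0.3 * 0.7 / nrow(pool$tracks))
  expect_lt(abs(frac - 0.7), 4 * se)
})

test_that("case cohorts are deterministic given the seed", {
  panel <- make_sim_panel()
  a <- simulate_case_cohort(panel, 10, mosaic_spec(10, c(A = 0.5, B = 0.5)),
                            seed = 99)
  b <- simulate_case_cohort(panel, 10, mosaic_spec(10, c(A = 0.5, B = 0.5)),
                            seed = 99)
  expect_identical(a, b)
  expect_equal(ncol(a$targets$haplotypes), 20L)
})

test_that("local-ancestry injection hits the exact composition", {
  panel <- make_sim_panel(n_sites = 300, chrom_cm = 60)
  pool <- simulate_haplotype_pool(panel, 300,
                                  mosaic_spec(10, c(A = 0.5, B = 0.5)),
                                  seed = 17)
  focal <- 30
  idx <- inject_local_ancestry_signal(pool, focal, "A", 60, "B", 20, seed = 3)
  expect_length(idx, 80)
  expect_length(unique(idx), 80)  # without replacement
  tr <- pool$tracks[pool$tracks$hap %in% idx, ]
  at_focal <- tr[tr$start_cm <= focal & tr$end_cm >= focal, ]
  at_focal <- at_focal[!duplicated(at_focal$hap), ]
  expect_equal(sum(at_focal$group == "A"), 60)
  expect_equal(sum(at_focal$group == "B"), 20)
  expect_error(
    inject_local_ancestry_signal(pool, focal, "A", 10000, "B", 0),
    "pool too small")
  # one-sided selection: every selected haplotype overlaps with that group
  idx_a <- inject_local_ancestry_signal(pool, focal, "A", 15, "B", 0, seed = 4)
  tr_a <- pool$tracks[pool$tracks$hap %in% idx_a, ]
  tr_a <- tr_a[tr_a$start_cm <= focal & tr_a$end_cm >= focal, ]
  expect_true(all(tr_a[!duplicated(tr_a$hap), ]$group == "A"))
})

test_that("allelic injection hits the exact carrier count", {
  panel <- make_sim_panel(n_sites = 300, chrom_cm = 60)
  pool <- simulate_haplotype_pool(panel, 300,
                                  mosaic_spec(10, c(A = 0.5, B = 0.5)),
                                  seed = 19)
  freqs <- rowMeans(pool$alleles)
  site <- which.min(abs(freqs - 0.5))
  idx <- inject_allelic_signal(pool, site, 50, 40, seed = 5)
  expect_length(idx, 90)
  expect_equal(sum(pool$alleles[site, idx]), 50)
  # zero carriers leaves the site monomorphic REF in the selection
  idx0 <- inject_allelic_signal(pool, site, 0, 30, seed = 6)
  expect_equal(sum(pool$alleles[site, idx0]), 0)
  expect_error(inject_allelic_signal(pool, site, 10000, 0), "pool too small")
})

test_that("array design thins by MAF and LD", {
  # two identical columns: the second is dropped at any r2 threshold < 1
  hap <- cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 0L))
  panel <- tiny_panel(t(hap), pos = c(1000L, 1100L, 1200L))
  keep <- suppressWarnings(design_array_sites(panel, maf_min = 0.05,
                                              r2_max = 0.8, n_sites = 10))
  expect_false(2L %in% keep)
  expect_true(all(c(1L, 3L) %in% keep))
  # r2 = 1/3 example survives thinning at 0.8
  hap2 <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L))
  panel2 <- tiny_panel(t(hap2), pos = c(1000L, 1100L))
  expect_equal(suppressWarnings(cor(hap2[, 1], hap2[, 2]))^2, 1 / 3,
               tolerance = 1e-12)
  keep2 <- suppressWarnings(design_array_sites(panel2, maf_min = 0.05,
                                               r2_max = 0.8, n_sites = 10))
  expect_equal(keep2, c(1L, 2L))
  # shortfall returns everything with a warning
  expect_warning(design_array_sites(panel2, maf_min = 0.05, n_sites = 10),
                 "candidate")
})

test_that("frequency window filter and decimation count correctly", {
  freqs <- c(0.04, 0.5, 0.96, 0.05, 0.95)
  hap <- sapply(freqs, function(p) {
    c(rep(1L, round(p * 100)), rep(0L, 100 - round(p * 100)))
  })
  panel <- tiny_panel(t(hap), pos = (1:5) * 1000L)
  expect_equal(frequency_window_filter(panel), c(FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_length(decimate_sites(100, 5), 20)
  expect_equal(decimate_sites(100, 5)[1:3], c(1L, 6L, 11L))
})

test_that("generated panels are group-structured and ancestry-paired", {
  panel <- make_sim_panel(seed = 55)
  expect_equal(n_haplotypes(panel), 120L)
  g <- haplotype_groups(panel)
  # partner haplotypes always share a group label
  expect_true(all(g == g[partner_index(seq_along(g) - 1L) + 1L]))
  # groups are differentiated: mean per-site Fst is positive
  pa <- rowMeans(panel$haplotypes[, g == "A"])
  pb <- rowMeans(panel$haplotypes[, g == "B"])
  fst <- hudson_fst(pa, 60, pb, 60)
  expect_gt(mean(fst, na.rm = TRUE), 0.05)
})

test_that("scenario bundles are deterministic and carry their truth", {
  b1 <- scenario("null", scale = 0.05, seed = 7)
  b2 <- scenario("null", scale = 0.05, seed = 7)
  expect_identical(b1, b2)
  d1 <- file.path(tempdir(), "scn1"); d2 <- file.path(tempdir(), "scn2")
  write_scenario(b1, d1); write_scenario(b2, d2)
  for (f in c("reference.vcf", "targets.vcf", "truth.tsv", "config.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  anc <- scenario("ancestry_signal", scale = 0.05, seed = 7)
  expect_equal(anc$truth$signal$type, "local_ancestry")
  expect_equal(ncol(anc$cases$haplotypes),
               anc$truth$signal$n_group_a + anc$truth$signal$n_group_b)
  alle <- scenario("allelic_signal", scale = 0.05, seed = 7)
  sig <- alle$truth$signal
  expect_equal(sum(alle$cases$haplotypes[sig$signal_site, ]), sig$n_carriers)
  expect_error(scenario("nope"), "arg")
})
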