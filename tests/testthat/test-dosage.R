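test_that("partner index is the within-individual mirror", {
  # the 1-based rule r(1)=2, r(2)=1 maps to 0-based partner(0)=1, partner(1)=0
  expect_equal(partner_index(0), 1)
  expect_equal(partner_index(1), 0)
  k <- 0:9
  expect_equal(partner_index(partner_index(k)), k)  # involution
})

test_that("site dosage sums posterior mass over ALT carriers and partners", {
  # point mass on a haplotype carrying ALT whose partner carries REF
  post <- c(1, 0, 0, 0)
  expect_equal(site_dosage(post, c(1L, 0L, 0L, 1L)),
               c(rho = 1, pi = 0))
  # split posterior: 0.6 on hap0 (ALT, partner REF), 0.4 on hap2 (REF, partner ALT)
  post <- c(0.6, 0, 0.4, 0)
  expect_equal(site_dosage(post, c(1L, 0L, 0L, 1L)),
               c(rho = 0.6, pi = 0.4))
  # monomorphic ALT site: both doses 1 regardless of the posterior
  expect_equal(site_dosage(c(0.3, 0.2, 0.1, 0.4), rep(1L, 4)),
               c(rho = 1, pi = 1))
  expect_error(site_dosage(c(0.5, 0.5), c(1L, 0L, 0L)), "length")
})

test_that("untyped-site interpolation is linear on the cM scale", {
  expect_equal(interpolate_untyped(0.2, 0.8, 0.5), 0.5)
  expect_equal(interpolate_untyped(0.2, 0.8, 0), 0.2)
  expect_equal(interpolate_untyped(0.2, 0.8, 1), 0.8)
  # left 0.2 at 1.0 cM, right 0.8 at 2.0 cM, site at 1.25 cM
  expect_equal(interpolate_untyped(0.2, 0.8, (1.25 - 1) / (2 - 1)), 0.35)
})

test_that("INFO is the dosage-variance ratio", {
  expect_equal(info_score(c(1, 1, 0, 0)), 1)         # certain doses
  expect_equal(info_score(rep(0.37, 8)), 0)           # pure uncertainty
  expect_equal(info_score(c(1, 1, 0.5, 0.5)), 1 / 3)
  expect_equal(info_score(rep(0, 5)), 1)              # theta at boundary
  set.seed(3)
  for (i in 1:20) expect_lte(info_score(runif(6)), 1)
})

test_that("case MAF folds the mean dose", {
  expect_equal(case_maf(rep(0, 4)), 0)
  expect_equal(case_maf(rep(0.7, 4)), 0.3)
  expect_equal(case_maf(c(1, 0, 0, 0.2)), 0.3)
})

test_that("a target equal to a panel haplotype copies it everywhere", {
  set.seed(21)
  S <- 60
  hap <- matrix(rbinom(S * 8, 1, 0.5), S, 8)
  panel <- tiny_panel(hap, pos = seq_len(S) * 50000L)
  # point-mass regime: vanishing mismatch AND switch probabilities, so the
  # posterior sits on the exact copy and its partner supplies pi
  targets_all <- target_haplotypes(panel$sites, hap[, 3, drop = FALSE])
  dt <- build_dosage_table(panel, targets_all,
                           hmm_params(ne = 1e-3, eps = 1e-10))
  expect_equal(as.vector(dt$rho), hap[, 3], tolerance = 1e-6)
  expect_equal(as.vector(dt$pi), hap[, 4], tolerance = 1e-6)
  # with a typed subset the alleles are still recovered after rounding
  typed <- seq(1, S, by = 3)
  targets <- target_haplotypes(panel$sites[typed, ],
                               hap[typed, 3, drop = FALSE])
  dt2 <- build_dosage_table(panel, targets,
                            hmm_params(ne = 10, eps = 1e-10))
  expect_equal(round(as.vector(dt2$rho)), hap[, 3])
  expect_equal(round(as.vector(dt2$pi)), hap[, 4])
  expect_equal(sum(dt2$typed), length(typed))
})

test_that("dosage table equals composing oracle posteriors by hand", {
  set.seed(31)
  S <- 8
  hap <- matrix(rbinom(S * 4, 1, 0.5), S, 4)
  cm <- cumsum(c(0, runif(S - 1, 0.1, 1)))
  panel <- tiny_panel(hap, pos = seq_len(S) * 1000L, cm = cm)
  typed <- c(2L, 5L, 7L)
  params <- hmm_params(ne = 200, eps = 0.01)
  target <- rbinom(length(typed), 1, 0.5)
  targets <- target_haplotypes(panel$sites[typed, ],
                               matrix(target, ncol = 1))
  dt <- build_dosage_table(panel, targets, params)

  post <- brute_force_posteriors(target, subset_sites(panel, typed), params)
  expected <- sapply(seq_len(S), function(s) {
    at <- function(row) site_dosage(post[row, ], hap[s, ])
    if (s %in% typed) return(at(match(s, typed)))
    iv <- findInterval(cm[s], cm[typed])
    if (iv == 0) return(at(1))
    if (iv >= length(typed)) return(at(length(typed)))
    w <- (cm[s] - cm[typed][iv]) / (cm[typed][iv + 1] - cm[typed][iv])
    interpolate_untyped(at(iv), at(iv + 1), w)
  })
  expect_equal(as.vector(dt$rho), unname(expected["rho", ]), tolerance = 1e-10)
  expect_equal(as.vector(dt$pi), unname(expected["pi", ]), tolerance = 1e-10)
})

test_that("doses stay in [0,1] and respect the within-individual swap", {
  set.seed(41)
  S <- 30
  hap <- matrix(rbinom(S * 10, 1, 0.4), S, 10)
  panel <- tiny_panel(hap, pos = seq_len(S) * 20000L)
  typed <- seq(1, S, by = 2)
  tgt <- matrix(rbinom(length(typed) * 4, 1, 0.5), ncol = 4)
  targets <- target_haplotypes(panel$sites[typed, ], tgt)
  dt <- build_dosage_table(panel, targets, hmm_params(ne = 1000, eps = 0.01))
  expect_true(all(dt$rho >= 0 & dt$rho <= 1))
  expect_true(all(dt$pi >= 0 & dt$pi <= 1))
  # with a FIXED posterior, swapping each individual's two allele columns
  # exchanges transmitted and un-transmitted dosages
  swap <- as.vector(rbind(seq(2, 10, 2), seq(1, 9, 2)))
  post <- runif(10); post <- post / sum(post)
  for (s in c(1L, 7L, 20L)) {
    d <- site_dosage(post, hap[s, ])
    d_sw <- site_dosage(post, hap[s, swap])
    expect_equal(unname(d_sw["rho"]), unname(d["pi"]))
    expect_equal(unname(d_sw["pi"]), unname(d["rho"]))
  }
  # the full pipeline is invariant under the same swap: posteriors follow
  # the permutation, so both dosages are unchanged
  panel_sw <- tiny_panel(hap[, swap], pos = seq_len(S) * 20000L)
  dt_sw <- build_dosage_table(panel_sw, targets,
                              hmm_params(ne = 1000, eps = 0.01))
  expect_equal(dt_sw$rho, dt$rho, tolerance = 1e-9)
  expect_equal(dt_sw$pi, dt$pi, tolerance = 1e-9)
})

test_that("uniform posteriors recover the panel allele frequency", {
  # with identical panel haplotype likelihoods the posterior is uniform and
  # rho equals the panel ALT frequency at every site
  S <- 5
  hap <- cbind(c(1L,0L,1L,0L,1L), c(1L,0L,1L,0L,1L),
               c(1L,0L,0L,1L,1L), c(1L,0L,0L,1L,1L))
  panel <- tiny_panel(hap, pos = seq_len(S) * 1000L)
  # target matches all haplotypes at typed sites 1,2 (monomorphic there)
  targets <- target_haplotypes(panel$sites[1:2, ], matrix(c(1L, 0L), ncol = 1))
  dt <- build_dosage_table(panel, targets, hmm_params())
  expect_equal(as.vector(dt$rho), rowMeans(hap), tolerance = 1e-3)
})

test_that("tidy() flattens the dosage table", {
  hap <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  panel <- tiny_panel(hap)
  targets <- target_haplotypes(panel$sites, hap)
  td <- tidy(build_dosage_table(panel, targets))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 2)
  expect_named(td, c("chrom", "pos", "hap", "rho", "pi", "typed"))
})

test_that("copying mass concentrates on the source group", {
  set.seed(51)
  S <- 40
  hap <- cbind(matrix(rbinom(S * 4, 1, 0.9), S, 4),
               matrix(rbinom(S * 4, 1, 0.1), S, 4))
  panel <- tiny_panel(hap, pos = seq_len(S) * 25000L,
                      groups = c("HI", "HI", "LO", "LO"))
  targets <- target_haplotypes(panel$sites, hap[, 1, drop = FALSE])
  gm <- copying_group_mass(panel, targets, hmm_params(ne = 100, eps = 0.01))
  expect_equal(sum(gm$mass), 1, tolerance = 1e-9)
  expect_gt(gm$mass[gm$group == "HI"], 0.9)
})
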