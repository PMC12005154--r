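#' Phased haplotype panel
#'
#' A `haplotype_panel` holds a phased, biallelic haplotype matrix together with
#' its site metadata. Haplotype columns come in pairs: columns `2i - 1` and
#' `2i` (1-based) belong to individual `i`, the layout the pseudo-control
#' construction relies on. The allele matrix is coded 0 = REF, 1 = ALT.
#'
#' @param sites A data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   and optionally `cm` (cumulative genetic position in centiMorgans). Sites
#'   must be sorted by strictly increasing `pos` within a chromosome.
#' @param haplotypes Integer matrix, sites in rows, haplotypes in columns,
#'   entries in `{0, 1}`. Must have an even number of columns.
#' @param sample_ids Character vector of individual labels, one per column
#'   pair. Generated when missing.
#' @param group_labels Optional per-individual ancestry/region tags (length
#'   `N` individuals, or length `2N` for per-haplotype tags). Used by the
#'   simulator and by copying-mass diagnostics only; the test itself never
#'   consumes ancestry labels.
#'
#' @return An object of class `haplotype_panel` with elements `sites`
#'   (a tibble), `haplotypes`, `sample_ids`, `group_labels` and `n_ind`.
#' @export
haplotype_panel <- function(sites, haplotypes, sample_ids = NULL,
                            group_labels = NULL) {
  sites <- tibble::as_tibble(sites)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    stop("`sites` needs columns chrom, pos, ref, alt", call. = FALSE)
  }
  if (!"id" %in% names(sites)) sites$id <- "."
  if (!"cm" %in% names(sites)) sites$cm <- NA_real_
  sites <- sites[, c("chrom", "pos", "id", "ref", "alt", "cm")]
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != nrow(sites)) {
    stop("haplotype matrix rows must match number of sites", call. = FALSE)
  }
  if (ncol(haplotypes) %% 2L != 0L) {
    stop("haplotype columns must pair into individuals (even count)",
         call. = FALSE)
  }
  if (nrow(haplotypes) > 0 && !all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype entries must be 0/1", call. = FALSE)
  }
  if (any(sites$pos < 1)) stop("positions must be >= 1", call. = FALSE)
  if (any(sites$ref == sites$alt)) stop("ref must differ from alt", call. = FALSE)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("sites must be strictly sorted by position within chromosome ", ch,
           call. = FALSE)
    }
  }
  n_ind <- ncol(haplotypes) %/% 2L
  if (is.null(sample_ids)) sample_ids <- sprintf("IND%04d", seq_len(n_ind))
  if (length(sample_ids) != n_ind) {
    stop("sample_ids must have one entry per individual", call. = FALSE)
  }
  if (!is.null(group_labels) &&
      !length(group_labels) %in% c(n_ind, 2L * n_ind)) {
    stop("group_labels must have length N or 2N", call. = FALSE)
  }
  structure(
    list(sites = sites, haplotypes = haplotypes, sample_ids = sample_ids,
         group_labels = group_labels, n_ind = n_ind),
    class = "haplotype_panel"
  )
}

#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$sites), " sites x ", 2L * x$n_ind,
      " haplotypes (", x$n_ind, " individuals)\n", sep = "")
  if (!is.null(x$group_labels)) {
    cat("  groups:", paste(names(table(x$group_labels)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$haplotypes)

#' Number of haplotypes in a panel
#' @param panel A `haplotype_panel`.
#' @return Integer count of haplotype columns (2N).
#' @export
n_haplotypes <- function(panel) ncol(panel$haplotypes)

#' Per-haplotype group labels
#'
#' Expands per-individual group labels to one label per haplotype column.
#' Returns `NULL` when the panel carries no labels.
#' @param panel A `haplotype_panel`.
#' @export
haplotype_groups <- function(panel) {
  g <- panel$group_labels
  if (is.null(g)) return(NULL)
  if (length(g) == panel$n_ind) rep(g, each = 2L) else g
}

site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Typed case haplotypes
#'
#' Case (target) haplotypes observed at a subset of panel sites, in the same
#' matrix layout as [haplotype_panel()]. Columns `2i - 1`, `2i` are the two
#' phased haplotypes of case `i`. Unlike a reference panel, an odd number of
#' haplotype columns is allowed (each target haplotype is imputed
#' independently; pairing matters only for the reference panel's
#' pseudo-controls).
#'
#' @inheritParams haplotype_panel
#' @return An object of class `target_haplotypes`.
#' @export
target_haplotypes <- function(sites, haplotypes, sample_ids = NULL) {
  haplotypes <- as.matrix(haplotypes)
  odd <- ncol(haplotypes) %% 2L == 1L
  if (odd) haplotypes <- cbind(haplotypes, 0L)
  obj <- haplotype_panel(sites, haplotypes, sample_ids)
  if (odd) {
    obj$haplotypes <- obj$haplotypes[, -ncol(obj$haplotypes), drop = FALSE]
    obj$n_ind <- NA_integer_
    obj$sample_ids <- sprintf("HAP%04d", seq_len(ncol(obj$haplotypes)))
  }
  class(obj) <- c("target_haplotypes", "haplotype_panel")
  obj
}

#' Restrict targets (or a panel) to a subset of sites
#' @param x A `haplotype_panel` or `target_haplotypes`.
#' @param idx Integer row indices of sites to keep.
#' @return Object of the same class restricted to `idx`.
#' @export
subset_sites <- function(x, idx) {
  x$sites <- x$sites[idx, , drop = FALSE]
  x$haplotypes <- x$haplotypes[idx, , drop = FALSE]
  x
}

#' Alternate-allele frequencies per site
#' @param panel A `haplotype_panel`.
#' @return Numeric vector of ALT frequencies over haplotypes.
#' @export
alt_freq <- function(panel) rowMeans(panel$haplotypes)

#' Hudson's Fst for one or more biallelic sites
#'
#' Per-site Hudson estimator in the ratio form
#' \deqn{\hat F_{st} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'       {p_1(1-p_2) + p_2(1-p_1)}}
#' computed per variant (not as a ratio of averages), since it feeds a
#' per-variant exclusion filter. `NA` is returned where the denominator is
#' zero, i.e. both samples are monomorphic for the same allele.
#'
#' @param p1,p2 ALT-allele frequencies in the two samples (vectorised).
#' @param n1,n2 Haplotype counts in the two samples; must be >= 2.
#' @return Numeric vector of Fst estimates (can be negative; `NA` when
#'   undefined).
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("n1 and n2 must be >= 2", call. = FALSE)
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Flag Fst outlier sites between two panels
#'
#' Computes per-site Hudson's Fst on the sites shared by two panels and flags
#' sites whose Fst exceeds the mean plus six standard deviations of the
#' observed (defined) Fst values — the screen used to drop batch-effect
#' variants when merging sequencing panels.
#'
#' @param panel_a,panel_b `haplotype_panel` objects sharing sites (matched on
#'   chrom, pos, ref, alt).
#' @return A list with `keep` (logical mask over the shared, ordered site
#'   set), `threshold`, and `report`, a tibble with one row per shared site
#'   (`chrom`, `pos`, `id`, `ref`, `alt`, `fst`, `excluded`).
#' @export
fst_outlier_filter <- function(panel_a, panel_b) {
  ka <- site_key(panel_a$sites); kb <- site_key(panel_b$sites)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) stop("panels share no sites", call. = FALSE)
  ia <- match(shared, ka); ib <- match(shared, kb)
  pa <- rowMeans(panel_a$haplotypes[ia, , drop = FALSE])
  pb <- rowMeans(panel_b$haplotypes[ib, , drop = FALSE])
  fst <- hudson_fst(pa, n_haplotypes(panel_a), pb, n_haplotypes(panel_b))
  ok <- !is.na(fst)
  thr <- mean(fst[ok]) + 6 * stats::sd(fst[ok])
  if (is.na(thr)) thr <- Inf  # a single defined value: sd undefined, keep all
  excluded <- ok & fst > thr
  report <- panel_a$sites[ia, c("chrom", "pos", "id", "ref", "alt")]
  report$fst <- fst
  report$excluded <- excluded
  list(keep = !excluded, threshold = thr, report = tibble::as_tibble(report))
}

#' Merge two phased panels on their shared sites
#'
#' Intersects sites on (chrom, pos, ref, alt) and concatenates haplotype
#' columns, panel A first. Sites present at the same position but with
#' mismatching alleles are dropped (and counted), never flipped or swapped:
#' the panels are assumed allele-harmonized upstream, and a silent strand or
#' allele flip is a worse failure mode than a dropped site.
#'
#' @param panel_a,panel_b `haplotype_panel` objects on the same chromosome.
#' @return A merged `haplotype_panel`; attribute `n_allele_mismatch` counts
#'   same-position sites dropped for allele disagreement.
#' @export
merge_panels <- function(panel_a, panel_b) {
  ca <- unique(panel_a$sites$chrom); cb <- unique(panel_b$sites$chrom)
  if (!identical(sort(ca), sort(cb))) {
    stop("panels must cover the same chromosome(s)", call. = FALSE)
  }
  ka <- site_key(panel_a$sites); kb <- site_key(panel_b$sites)
  shared <- ka[ka %in% kb]
  ia <- match(shared, ka); ib <- match(shared, kb)
  pos_a <- paste(panel_a$sites$chrom, panel_a$sites$pos)
  pos_b <- paste(panel_b$sites$chrom, panel_b$sites$pos)
  n_mismatch <- sum(pos_a %in% pos_b) - length(shared)
  ga <- panel_a$group_labels; gb <- panel_b$group_labels
  groups <- NULL
  if (!is.null(ga) || !is.null(gb)) {
    if (is.null(ga)) ga <- rep(NA_character_, panel_a$n_ind)
    if (is.null(gb)) gb <- rep(NA_character_, panel_b$n_ind)
    if (length(ga) == 2L * panel_a$n_ind || length(gb) == 2L * panel_b$n_ind) {
      if (length(ga) == panel_a$n_ind) ga <- rep(ga, each = 2L)
      if (length(gb) == panel_b$n_ind) gb <- rep(gb, each = 2L)
    }
    groups <- c(ga, gb)
  }
  out <- haplotype_panel(
    sites = panel_a$sites[ia, , drop = FALSE],
    haplotypes = cbind(panel_a$haplotypes[ia, , drop = FALSE],
                       panel_b$haplotypes[ib, , drop = FALSE]),
    sample_ids = make.unique(c(panel_a$sample_ids, panel_b$sample_ids)),
    group_labels = groups
  )
  attr(out, "n_allele_mismatch") <- n_mismatch
  out
}
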