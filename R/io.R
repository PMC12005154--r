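#' Read a phased VCF into a haplotype panel
#'
#' Reads a VCF (plain or bgzipped) via vcfR, keeping phased biallelic SNVs
#' only. Records that are multiallelic, non-SNV, carry missing alleles, or are
#' unphased are skipped with a count (or, for unphased genotypes in strict
#' mode, raise an error naming the record).
#'
#' @param path Path to a VCF file with GT for all samples.
#' @param region Optional `"chrom"` or `"chrom:start-end"` restriction.
#' @param strict If `TRUE` (default), an unphased genotype is an error; if
#'   `FALSE` the record is skipped and counted.
#' @return A [haplotype_panel()]. Attribute `n_skipped` holds the number of
#'   records dropped by the filters.
#' @export
read_phased_vcf <- function(path, region = NULL, strict = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (nrow(fix) == 0) {
    return(haplotype_panel(
      sites = tibble::tibble(chrom = character(), pos = integer(),
                             id = character(), ref = character(),
                             alt = character()),
      haplotypes = matrix(integer(), 0, if (is.null(gt)) 0 else 2L * (ncol(gt) - 1L)),
      sample_ids = if (is.null(gt)) character() else colnames(gt)[-1]
    ))
  }
  fix$POS <- as.integer(fix$POS)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:(\\d+)-(\\d+))?$", region))[[1]]
    keep <- fix$CHROM == m[2]
    if (m[3] != "") keep <- keep & fix$POS >= as.integer(m[4]) & fix$POS <= as.integer(m[5])
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
  }
  samples <- colnames(gt)[-1]
  gtm <- gt[, -1, drop = FALSE]
  # strip any FORMAT payload beyond GT
  gtm[] <- sub(":.*$", "", gtm)
  biallelic_snv <- !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  unphased <- apply(gtm, 1L, function(x) any(grepl("/", x, fixed = TRUE)))
  missing_gt <- apply(gtm, 1L, function(x) any(!grepl("^[01][|/][01]$", x)))
  if (strict && any(unphased & biallelic_snv & !missing_gt)) {
    bad <- which(unphased & biallelic_snv & !missing_gt)[1]
    stop(sprintf("unphased genotype at %s:%s in strict mode",
                 fix$CHROM[bad], fix$POS[bad]), call. = FALSE)
  }
  keep <- biallelic_snv & !unphased & !missing_gt
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " record(s) skipped (multiallelic/non-SNV/unphased/missing)")
  }
  fix <- fix[keep, , drop = FALSE]
  gtm <- gtm[keep, , drop = FALSE]
  n_sites <- nrow(fix)
  hap <- matrix(0L, n_sites, 2L * length(samples))
  if (n_sites > 0) {
    a1 <- substr(gtm, 1L, 1L) == "1"
    a2 <- substr(gtm, 3L, 3L) == "1"
    hap[, seq(1L, ncol(hap), by = 2L)] <- a1 * 1L
    hap[, seq(2L, ncol(hap), by = 2L)] <- a2 * 1L
  }
  out <- haplotype_panel(
    sites = tibble::tibble(chrom = fix$CHROM, pos = fix$POS,
                           id = ifelse(is.na(fix$ID), ".", fix$ID),
                           ref = fix$REF, alt = fix$ALT),
    haplotypes = hap, sample_ids = samples
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased GT (`a|b`); a round trip through
#' [read_phased_vcf()] reproduces the allele matrix exactly.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=surfbat",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  ), con)
  n_sites <- nrow(panel$sites)
  if (n_sites > 0) {
    h <- panel$haplotypes
    odd <- seq(1L, ncol(h), by = 2L)
    gt <- matrix(paste0(h[, odd, drop = FALSE], "|", h[, odd + 1L, drop = FALSE]),
                 nrow = n_sites)
    lines <- paste(panel$sites$chrom, panel$sites$pos, panel$sites$id,
                   panel$sites$ref, panel$sites$alt, ".", ".", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a recombination map
#'
#' Accepts the two common tab/space-separated dialects, auto-detected by
#' column count: 3-column HapMap style (`position`, `rate(cM/Mb)`, `cM`) and
#' 4-column PLINK style (`chrom`, `id`, `cM`, `position`). A header line is
#' detected and dropped.
#'
#' @param path Map file path.
#' @param chrom Chromosome label to assign for the 3-column dialect (which
#'   carries none); ignored for the PLINK dialect.
#' @return A `genetic_map`: a tibble with columns `chrom`, `pos`, `cm`,
#'   strictly increasing in `pos` and non-decreasing in `cm` per chromosome.
#' @export
read_genetic_map <- function(path, chrom = NULL) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", skip = 0, fill = TRUE)
  # drop a header row if the numeric columns fail to parse
  num_try <- suppressWarnings(as.numeric(raw[1, ncol(raw)]))
  if (is.na(num_try)) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) == 3) {
    if (is.null(chrom)) stop("3-column map carries no chromosome; supply `chrom`",
                             call. = FALSE)
    map <- tibble::tibble(chrom = chrom,
                          pos = as.integer(raw[[1]]),
                          cm = as.numeric(raw[[3]]))
  } else if (ncol(raw) == 4) {
    map <- tibble::tibble(chrom = as.character(raw[[1]]),
                          pos = as.integer(raw[[4]]),
                          cm = as.numeric(raw[[3]]))
  } else {
    stop("unrecognized genetic map layout (need 3 or 4 columns)", call. = FALSE)
  }
  genetic_map(map)
}

#' Construct a genetic map from anchors
#'
#' @param anchors Data frame with columns `chrom`, `pos`, `cm`; at least two
#'   anchors per chromosome, strictly increasing `pos` and non-decreasing `cm`.
#' @return A `genetic_map` tibble.
#' @export
genetic_map <- function(anchors) {
  map <- tibble::as_tibble(anchors)[, c("chrom", "pos", "cm")]
  map <- dplyr::arrange(map, .data$chrom, .data$pos)
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) < 2) stop("need >= 2 anchors per chromosome", call. = FALSE)
    if (is.unsorted(sub$pos, strictly = TRUE)) {
      stop("anchor positions must be strictly increasing", call. = FALSE)
    }
    if (is.unsorted(sub$cm)) stop("cM must be non-decreasing", call. = FALSE)
  }
  class(map) <- c("genetic_map", class(map))
  map
}

#' Interpolate genetic positions onto panel sites
#'
#' Sets the `cm` column of the panel's sites by piecewise-linear interpolation
#' between map anchors. Positions outside the anchor range are extrapolated at
#' the local recombination rate of the nearest flanking interval, floored at
#' 0 cM/Mb (and at 0 cM absolute).
#'
#' @param panel A [haplotype_panel()] (or `target_haplotypes`).
#' @param map A [genetic_map()].
#' @return The panel with `sites$cm` filled in.
#' @export
attach_genetic_map <- function(panel, map) {
  cm <- numeric(nrow(panel$sites))
  for (ch in unique(panel$sites$chrom)) {
    anchors <- map[map$chrom == ch, ]
    if (nrow(anchors) == 0) {
      stop("chromosome ", ch, " absent from genetic map", call. = FALSE)
    }
    idx <- which(panel$sites$chrom == ch)
    cm[idx] <- interpolate_cm(panel$sites$pos[idx], anchors$pos, anchors$cm)
  }
  panel$sites$cm <- cm
  panel
}

interpolate_cm <- function(pos, anchor_pos, anchor_cm) {
  out <- stats::approx(anchor_pos, anchor_cm, xout = pos, rule = 1)$y
  n <- length(anchor_pos)
  left_rate <- max(0, (anchor_cm[2] - anchor_cm[1]) / (anchor_pos[2] - anchor_pos[1]))
  right_rate <- max(0, (anchor_cm[n] - anchor_cm[n - 1]) /
                       (anchor_pos[n] - anchor_pos[n - 1]))
  lo <- pos < anchor_pos[1]
  hi <- pos > anchor_pos[n]
  out[lo] <- pmax(0, anchor_cm[1] - (anchor_pos[1] - pos[lo]) * left_rate)
  out[hi] <- anchor_cm[n] + (pos[hi] - anchor_pos[n]) * right_rate
  out
}
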