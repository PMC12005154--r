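# Shared fixtures: all built in code, no files on disk.

make_sites <- function(pos, chrom = "1", cm = pos / 1e6,
                       ref = "A", alt = "G") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), id = ".",
                 ref = ref, alt = alt, cm = cm)
}

# small deterministic panel: `hap` is a site x haplotype 0/1 matrix
tiny_panel <- function(hap, pos = NULL, cm = NULL, groups = NULL) {
  hap <- as.matrix(hap)
  if (is.null(pos)) pos <- seq_len(nrow(hap)) * 1000L
  if (is.null(cm)) cm <- pos / 1e6
  haplotype_panel(make_sites(pos, cm = cm), hap, group_labels = groups)
}

random_tiny_instance <- function(n_sites = NULL, n_haps = NULL) {
  if (is.null(n_sites)) n_sites <- sample(1:5, 1)
  if (is.null(n_haps)) n_haps <- sample(c(2L, 4L), 1)
  hap <- matrix(rbinom(n_sites * n_haps, 1, 0.5), n_sites, n_haps)
  cm <- cumsum(c(0, runif(n_sites - 1, 0, 2)))
  list(
    panel = tiny_panel(hap, pos = seq_len(n_sites) * 1000L, cm = cm),
    target = rbinom(n_sites, 1, 0.5),
    params = hmm_params(ne = sample(c(50, 500, 5000), 1),
                        eps = sample(c(1e-2, 1e-3), 1))
  )
}

# Naive case-vs-panel allele-frequency chi-squared contrast. Deliberately a
# test fixture, not package code: it is the stratification-blind comparator
# the pseudo-control test is designed to improve on.
naive_freq_chisq <- function(case_alleles, panel_alleles) {
  n1 <- length(case_alleles); n2 <- length(panel_alleles)
  p <- (sum(case_alleles) + sum(panel_alleles)) / (n1 + n2)
  if (p == 0 || p == 1) return(1)
  z2 <- (mean(case_alleles) - mean(panel_alleles))^2 /
    (p * (1 - p) * (1 / n1 + 1 / n2))
  stats::pchisq(z2, 1, lower.tail = FALSE)
}

write_tmp_vcf <- function(lines, ext = ".vcf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_record <- function(chrom, pos, ref, alt, gts, id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", ".", ".", "GT", gts),
        collapse = "\t")
}
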