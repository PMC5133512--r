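#' Construct a genotype panel
#'
#' Bundles an additive dosage matrix (individuals x SNPs, values 0/1/2
#' counting a designated allele) with per-SNP metadata. `maf` and `mac` are
#' recomputed from the realized sample: `mac` is the minor allele count
#' `min(s, 2n - s)` where `s` is the summed dosage, and `maf = mac / (2n)`.
#' Fractional dosages (e.g. externally imputed) are rounded to the nearest
#' integer before allele counting.
#'
#' @param dosages numeric matrix, rows = individuals (rownames = ids),
#'   columns = SNPs (colnames = SNP ids), values in \[0, 2\].
#' @param chrom,pos per-SNP chromosome labels and 1-based positions.
#' @return A list of class `genotype_panel` with elements `dosages` and
#'   `snp_meta` (`snp`, `chrom`, `pos`, `maf`, `mac`).
#' @export
genotype_panel <- function(dosages, chrom, pos) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)),
            !is.null(colnames(dosages)),
            length(chrom) == ncol(dosages), length(pos) == ncol(dosages))
  if (any(dosages < 0 | dosages > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  if (any(pos < 1))
    stop("positions must be strictly positive", call. = FALSE)
  meta <- data.frame(snp = colnames(dosages), chrom = as.character(chrom),
                     pos = as.integer(pos), stringsAsFactors = FALSE)
  cnt <- colSums(round(dosages))
  n2 <- 2 * nrow(dosages)
  meta$mac <- as.integer(pmin(cnt, n2 - cnt))
  meta$maf <- meta$mac / n2
  structure(list(dosages = dosages, snp_meta = meta), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d SNPs, MAF %.4f-%.4f\n",
              nrow(x$dosages), ncol(x$dosages),
              min(x$snp_meta$maf), max(x$snp_meta$maf)))
  invisible(x)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder dosages are drawn binomial(2, MAF) under Hardy-Weinberg; each
#' non-founder receives one allele from each parent by Mendelian transmission
#' (a parent with dosage d transmits the counted allele with probability
#' d/2). SNPs are dropped independently (no linkage).
#'
#' @param pedigree a `fam_pedigree`.
#' @param maf_list per-SNP minor allele frequencies in (0, 0.5].
#' @param seed integer seed.
#' @param chrom,pos optional per-SNP chromosome/position metadata; defaults
#'   spread SNPs 1 Mb apart on chromosome "1".
#' @param snp_names optional SNP identifiers.
#' @return A [genotype_panel()] with realized `maf`/`mac`.
#' @export
drop_genotypes <- function(pedigree, maf_list, seed,
                           chrom = NULL, pos = NULL, snp_names = NULL) {
  if (any(maf_list <= 0 | maf_list > 0.5))
    stop("configuration error: MAFs must lie in (0, 0.5]", call. = FALSE)
  m <- length(maf_list)
  n <- nrow(pedigree)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000000L
  if (is.null(snp_names)) snp_names <- sprintf("snp_%s_%d", chrom, pos)
  set.seed(seed)
  ord <- pedigree_order(pedigree)
  fi <- match(pedigree$father, pedigree$id)
  mi <- match(pedigree$mother, pedigree$id)
  dos <- matrix(0L, n, m, dimnames = list(pedigree$id, snp_names))
  for (i in ord) {
    if (pedigree$founder[i]) {
      dos[i, ] <- rbinom(m, 2L, maf_list)
    } else {
      dos[i, ] <- rbinom(m, 1L, dos[fi[i], ] / 2) +
                  rbinom(m, 1L, dos[mi[i], ] / 2)
    }
  }
  genotype_panel(dos, chrom = chrom, pos = pos)
}

#' Minor-allele-count filter
#'
#' A SNP passes when its minor allele count, recomputed within the analyzed
#' subset of individuals, is at least `threshold`. Stratified analyses
#' re-apply the filter within each stratum.
#'
#' @param panel a `genotype_panel`.
#' @param rows individual ids (or indices) defining the analysis subset;
#'   `NULL` means all.
#' @param threshold minimum minor allele count (default 2).
#' @return A named logical vector over SNPs.
#' @export
#' @examples
#' # a single heterozygote (MAC 1) fails, MAC 2 passes
mac_filter <- function(panel, rows = NULL, threshold = 2L) {
  stopifnot(threshold >= 0)
  d <- panel$dosages
  if (!is.null(rows)) d <- d[rows, , drop = FALSE]
  cnt <- colSums(round(d))
  mac <- pmin(cnt, 2 * nrow(d) - cnt)
  setNames(mac >= threshold, colnames(d))
}

#' Add high-LD proxy SNPs to a panel
#'
#' Copies selected SNPs to adjacent positions with a small per-genotype
#' flip probability, creating pairs in strong linkage disequilibrium. The
#' generator simulates SNPs without LD by default; this mechanism exists to
#' exercise LD pruning.
#'
#' @param panel a `genotype_panel`.
#' @param snps SNP ids to copy.
#' @param flip_prob probability that a copied dosage is resampled from the
#'   SNP's marginal distribution (0 gives perfect copies, r^2 = 1).
#' @param seed integer seed.
#' @param offset_bp position offset of each proxy from its source.
#' @return A `genotype_panel` with one `<snp>_proxy` column appended per
#'   requested SNP.
#' @export
add_ld_proxies <- function(panel, snps, flip_prob = 0.05, seed = 1L,
                           offset_bp = 1L) {
  stopifnot(all(snps %in% colnames(panel$dosages)),
            flip_prob >= 0, flip_prob <= 1)
  set.seed(seed)
  d <- panel$dosages
  mi <- match(snps, panel$snp_meta$snp)
  prox <- vapply(seq_along(snps), function(k) {
    g <- d[, snps[k]]
    swap <- runif(nrow(d)) < flip_prob
    g[swap] <- sample(g, sum(swap), replace = TRUE)
    g
  }, numeric(nrow(d)))
  colnames(prox) <- paste0(snps, "_proxy")
  genotype_panel(cbind(d, prox),
                 chrom = c(panel$snp_meta$chrom, panel$snp_meta$chrom[mi]),
                 pos = c(panel$snp_meta$pos, panel$snp_meta$pos[mi] + offset_bp))
}
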