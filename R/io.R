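#' Write pedigree and genotypes as PLINK-style PED/MAP text
#'
#' PED columns: family, individual id, father (0 for founders), mother, sex
#' (1 = male, 2 = female), phenotype placeholder (-9), then one allele pair
#' per SNP. The counted (dosage) allele is written as `2` and the other as
#' `1`, so dosage equals the number of `2` alleles. MAP columns: chromosome,
#' SNP id, genetic distance (0), 1-based position.
#'
#' @param pedigree a `fam_pedigree`.
#' @param panel a `genotype_panel` aligned with the pedigree.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_ped_map <- function(pedigree, panel, prefix) {
  stopifnot(all(pedigree$id %in% rownames(panel$dosages)))
  d <- round(panel$dosages[pedigree$id, , drop = FALSE])
  n <- nrow(d); m <- ncol(d)
  a1 <- ifelse(d >= 1, "2", "1")
  a2 <- ifelse(d == 2, "2", "1")
  geno <- matrix("", n, 2L * m)
  geno[, seq(1L, 2L * m, by = 2L)] <- a1
  geno[, seq(2L, 2L * m, by = 2L)] <- a2
  ped <- cbind(pedigree$family, pedigree$id,
               ifelse(is.na(pedigree$father), "0", pedigree$father),
               ifelse(is.na(pedigree$mother), "0", pedigree$mother),
               ifelse(pedigree$sex == "male", "1", "2"),
               "-9", geno)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  write.table(ped, ped_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  map <- cbind(panel$snp_meta$chrom, panel$snp_meta$snp, "0",
               panel$snp_meta$pos)
  write.table(map, map_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a PLINK-style PED/MAP pair
#'
#' Round-trips files produced by [write_ped_map()] bit-exactly: dosage is
#' the count of allele `2`. Parent id `0` marks a founder. Mendelian
#' inconsistencies between rounded parental and offspring dosages are
#' counted and reported as a warning.
#'
#' @param ped_path,map_path file paths.
#' @return List with `pedigree` (a `fam_pedigree`) and `genotypes` (a
#'   `genotype_panel`).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp", "cm", "pos"))
  lines <- readLines(ped_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  want <- 6L + 2L * m
  for (i in seq_along(fields))
    if (length(fields[[i]]) != want)
      stop(sprintf("parse error at PED line %d: %d fields, expected %d",
                   i, length(fields[[i]]), want), call. = FALSE)
  ped_mat <- do.call(rbind, fields)
  ped <- data.frame(family = ped_mat[, 1L], id = ped_mat[, 2L],
                    father = ifelse(ped_mat[, 3L] == "0", NA, ped_mat[, 3L]),
                    mother = ifelse(ped_mat[, 4L] == "0", NA, ped_mat[, 4L]),
                    sex = ifelse(ped_mat[, 5L] == "1", "male", "female"),
                    stringsAsFactors = FALSE)
  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  gen <- rep(1L, nrow(ped))  # recovered below from parent depth
  fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
  ord <- pedigree_order(ped)
  for (i in ord)
    if (!ped$founder[i]) gen[i] <- max(gen[fi[i]], gen[mi[i]]) + 1L
  ped$generation <- gen
  class(ped) <- c("fam_pedigree", "data.frame")
  validate_pedigree(ped)

  al <- ped_mat[, -(1:6), drop = FALSE]
  dos <- (al[, seq(1L, 2L * m, by = 2L), drop = FALSE] == "2") +
         (al[, seq(2L, 2L * m, by = 2L), drop = FALSE] == "2")
  storage.mode(dos) <- "integer"
  dimnames(dos) <- list(ped$id, map$snp)
  n_bad <- count_mendel_errors(ped, dos)
  if (n_bad > 0)
    warning(n_bad, " Mendelian inconsistencies detected", call. = FALSE)
  list(pedigree = ped,
       genotypes = genotype_panel(dos, chrom = as.character(map$chrom),
                                  pos = map$pos))
}

# dosage-level Mendelian check: offspring dosage must be attainable from
# one allele per parent (parent d transmits 1 iff d=2, 0 iff d=0, else either)
count_mendel_errors <- function(ped, dos) {
  fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
  kids <- which(!ped$founder)
  if (!length(kids)) return(0L)
  fd <- dos[fi[kids], , drop = FALSE]
  md <- dos[mi[kids], , drop = FALSE]
  kd <- dos[kids, , drop = FALSE]
  lo <- (fd == 2) + (md == 2)
  hi <- 2L - ((fd == 0) + (md == 0))
  sum(kd < lo | kd > hi)
}

#' Write / read a phenotype table as TSV
#'
#' Tab-separated with header (`id`, `sbp_t3`, `age`, `sex`, `med`,
#' `pc1..pck`), `.` decimal separator.
#'
#' @param phenotypes phenotype data frame.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(id = "character"))
}

#' Write scan results as TSV
#'
#' Numeric columns use `.` decimals; p-values below 1e-4 are printed in
#' scientific notation (`1.3E-06` style), larger ones in fixed notation.
#'
#' @param results scan-result data frame from [run_scan()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results
  for (cn in intersect(c("p_1df", "p_2df"), names(out))) {
    p <- out[[cn]]
    out[[cn]] <- ifelse(is.na(p), NA,
                        ifelse(p < 1e-4, sprintf("%.1E", p),
                               sprintf("%.4f", p)))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export genotypes as VCF v4.2
#'
#' Interoperability export (GT field only, one sample column per
#' individual); the counted allele is written as the ALT allele so the
#' genotype dosage equals the ALT allele count.
#'
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  d <- round(panel$dosages)
  meta <- panel$snp_meta
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  ord <- order(meta$chrom, meta$pos)
  for (j in ord) {
    writeLines(paste(c(meta$chrom[j], meta$pos[j], meta$snp[j], "A", "B",
                       ".", "PASS", ".", "GT", gt[, j]), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Write evaluation summaries as TSV
#'
#' @param summary data frame from [tpp()], [fpp()] or
#'   [convergence_summary()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
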