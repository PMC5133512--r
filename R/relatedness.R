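#' Numerator relationship matrix of a pedigree
#'
#' Expected additive genetic relationships (twice the kinship coefficients)
#' by the recursive tabular method: founders have `A_ii = 1` and `A_ij = 0`
#' among themselves; a non-founder `i` with parents `f`, `m` has
#' `A_ij = (A_fj + A_mj)/2` for earlier `j` and `A_ii = 1 + A_fm/2`
#' (inbreeding handled by the recursion). Families are disjoint blocks, so
#' the result is sparse block-diagonal; between-family entries are exactly
#' zero.
#'
#' @param pedigree a `fam_pedigree` (or any pedigree data frame with
#'   `family`, `id`, `father`, `mother`, `founder`).
#' @return A symmetric sparse `Matrix::dsCMatrix` with `dimnames` set to
#'   pedigree ids, rows/columns in pedigree row order.
#' @export
#' @examples
#' set.seed(1)
#' ped <- generate_pedigree(sim_config(n_families = 1))
#' A <- numerator_relationship_matrix(ped)
numerator_relationship_matrix <- function(pedigree) {
  ord <- pedigree_order(pedigree)  # errors on cycles
  fams <- unique(pedigree$family)
  blocks <- vector("list", length(fams))
  perm <- integer(0)
  for (b in seq_along(fams)) {
    rows <- which(pedigree$family == fams[b])
    perm <- c(perm, rows)
    sub <- pedigree[rows, , drop = FALSE]
    sord <- pedigree_order(sub)
    nf <- length(rows)
    fa <- match(sub$father, sub$id)
    mo <- match(sub$mother, sub$id)
    if (any(!is.na(sub$father) & is.na(fa)) ||
        any(!is.na(sub$mother) & is.na(mo)))
      stop("parents must belong to the same family block", call. = FALSE)
    A <- matrix(0, nf, nf)
    pos <- integer(nf)  # processing rank of each local index
    for (r in seq_along(sord)) pos[sord[r]] <- r
    for (r in seq_along(sord)) {
      i <- sord[r]
      if (sub$founder[i]) {
        A[i, i] <- 1
      } else {
        f <- fa[i]; m <- mo[i]
        earlier <- sord[seq_len(r - 1L)]
        if (length(earlier)) {
          v <- (A[f, earlier] + A[m, earlier]) / 2
          A[i, earlier] <- v
          A[earlier, i] <- v
        }
        A[i, i] <- 1 + A[f, m] / 2
      }
    }
    dimnames(A) <- list(sub$id, sub$id)
    blocks[[b]] <- A
  }
  out <- if (length(blocks) == 1L) Matrix::Matrix(blocks[[1L]], sparse = TRUE)
         else Matrix::bdiag(blocks)
  out <- methods::as(Matrix::forceSymmetric(out), "CsparseMatrix")
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  dimnames(out) <- list(ids, ids)
  # restore original pedigree row order
  out[pedigree$id, pedigree$id]
}

#' Greedy LD pruning by position order
#'
#' Scans SNPs within each chromosome in position order; a SNP is retained
#' unless its squared Pearson correlation of dosages (within `subset`) with
#' any previously retained SNP on the same chromosome exceeds `r2_threshold`.
#' SNPs monomorphic within the subset are dropped first.
#'
#' @param panel a `genotype_panel`.
#' @param r2_threshold retain threshold on r^2, in (0, 1\].
#' @param subset individual ids (default: all) within which correlations are
#'   computed, e.g. founders.
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(panel, r2_threshold = 0.2, subset = NULL) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  d <- panel$dosages
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  if (nrow(d) == 0L) stop("subset is empty", call. = FALSE)
  meta <- panel$snp_meta
  poly <- apply(d, 2L, function(x) var(x) > 0)
  keep <- character(0)
  for (ch in unique(meta$chrom)) {
    idx <- which(meta$chrom == ch & poly)
    idx <- idx[order(meta$pos[idx])]
    kept_cols <- integer(0)
    for (j in idx) {
      ok <- TRUE
      if (length(kept_cols)) {
        r2 <- cor(d[, j], d[, kept_cols, drop = FALSE])^2
        ok <- all(r2 <= r2_threshold)
      }
      if (ok) kept_cols <- c(kept_cols, j)
    }
    keep <- c(keep, meta$snp[kept_cols])
  }
  keep
}

#' Principal components from pedigree founders
#'
#' Computes ancestry principal components in unrelated founders only:
#' founder dosages are centred by per-SNP founder means (and scaled to unit
#' founder variance when `scale. = TRUE`, the default), and the top `k` right
#' singular directions define the loadings. Relatives are assigned scores by
#' projection with [project_pcs()] using the frozen founder means/loadings.
#'
#' @param panel a `genotype_panel`.
#' @param founders founder individual ids.
#' @param snp_subset SNP ids to use; all must be polymorphic among founders.
#' @param k number of components (default 5).
#' @param scale. scale SNPs to unit founder variance.
#' @return A list of class `pc_model`: `snp_subset`, `founder_means`,
#'   `founder_sds`, `loadings` (m x k, orthonormal columns), `scores`
#'   (founder scores), `k`.
#' @export
founder_pca <- function(panel, founders, snp_subset = NULL, k = 5L,
                        scale. = TRUE) {
  stopifnot(k >= 1L)
  if (is.null(snp_subset)) snp_subset <- colnames(panel$dosages)
  d <- panel$dosages[founders, snp_subset, drop = FALSE]
  mu <- colMeans(d)
  sdv <- apply(d, 2L, sd)
  if (any(sdv == 0))
    stop("snp_subset must be polymorphic among founders; monomorphic: ",
         paste(head(snp_subset[sdv == 0], 5L), collapse = ", "), call. = FALSE)
  if (!scale.) sdv <- rep(1, length(sdv))
  z <- sweep(sweep(d, 2L, mu), 2L, sdv, "/")
  if (k > min(nrow(z) - 1L, ncol(z)))
    stop("k exceeds the rank of the centred founder matrix", call. = FALSE)
  sv <- svd(z, nu = 0, nv = k)
  loadings <- sv$v
  dimnames(loadings) <- list(snp_subset, paste0("pc", seq_len(k)))
  scores <- z %*% loadings
  structure(list(snp_subset = snp_subset, founder_means = mu,
                 founder_sds = sdv, loadings = loadings, scores = scores,
                 k = as.integer(k), scaled = scale.),
            class = "pc_model")
}

#' Project individuals onto founder principal components
#'
#' Linear map using the model's frozen founder means, scales and loadings:
#' `score = ((dosage - founder_mean) / founder_sd) %*% loadings`. Founder
#' rows reproduce their [founder_pca()] scores exactly.
#'
#' @param model a `pc_model`.
#' @param panel a `genotype_panel` containing every model SNP.
#' @return An n x k score matrix (rownames = individual ids).
#' @export
project_pcs <- function(model, panel) {
  missing <- setdiff(model$snp_subset, colnames(panel$dosages))
  if (length(missing))
    stop("panel is missing model SNPs: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  d <- panel$dosages[, model$snp_subset, drop = FALSE]
  z <- sweep(sweep(d, 2L, model$founder_means), 2L, model$founder_sds, "/")
  z %*% model$loadings
}

#' Write nonzero relationship-matrix entries as TSV
#'
#' Three columns `id1`, `id2`, `value`; upper triangle including the
#' diagonal.
#'
#' @param R relationship matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_relationship_tsv <- function(R, path) {
  tr <- Matrix::drop0(Matrix::forceSymmetric(R))
  sm <- methods::as(methods::as(tr, "generalMatrix"), "TsparseMatrix")
  ids <- rownames(R)
  keep <- sm@i <= sm@j
  df <- data.frame(id1 = ids[sm@i[keep] + 1L], id2 = ids[sm@j[keep] + 1L],
                   value = sm@x[keep])
  df <- df[order(df$id1, df$id2), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
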