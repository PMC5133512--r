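test_that("relationship matrix reproduces path-counting coefficients", {
  A <- as.matrix(numerator_relationship_matrix(hand_pedigree()))
  expect_equal(A["f1", "s1"], 0.5)   # parent-offspring
  expect_equal(A["s1", "s2"], 0.5)   # full sibs
  expect_equal(A["g1", "g2"], 0.125) # first cousins
  expect_equal(A["f1", "g1"], 0.25)  # grandparent
  expect_equal(unname(diag(A)), rep(1, 10))  # non-inbred
  expect_equal(A["f1", "f3"], 0)     # marry-in founder unrelated
  expect_equal(A["f1", "u1"], 0)     # between families exactly zero
})

test_that("inbreeding: child of full sibs has diagonal 1.25", {
  ped <- data.frame(
    family = 1, id = c("p1", "p2", "b", "s", "k"),
    father = c(NA, NA, "p1", "p1", "b"),
    mother = c(NA, NA, "p2", "p2", "s"),
    sex = c("male", "female", "male", "female", "male"),
    founder = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    generation = c(1, 1, 2, 2, 3), stringsAsFactors = FALSE)
  class(ped) <- c("fam_pedigree", "data.frame")
  A <- as.matrix(numerator_relationship_matrix(ped))
  expect_equal(A["k", "k"], 1.25)  # 1 + A(b,s)/2
})

test_that("founders-only pedigree gives the identity matrix", {
  A <- numerator_relationship_matrix(founder_pedigree(7))
  expect_equal(as.matrix(A), diag(7), ignore_attr = TRUE)
})

test_that("A is positive semidefinite with zero between-family blocks", {
  for (seed in 1:3) {
    set.seed(seed)
    ped <- generate_pedigree(tiny_config())
    A <- numerator_relationship_matrix(ped)
    expect_gte(min(eigen(as.matrix(A), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
    f1 <- ped$id[ped$family == 1]
    f2 <- ped$id[ped$family == 2]
    expect_equal(max(abs(A[f1, f2])), 0)
  }
})

test_that("greedy LD pruning matches a brute-force pairwise-r2 oracle", {
  set.seed(8)
  n <- 60
  base <- rbinom(n, 2, 0.4)
  d <- cbind(s1 = base,
             s2 = rbinom(n, 2, 0.3),
             s3 = base,                       # duplicate of s1 (r2 = 1)
             s4 = pmin(2, base + rbinom(n, 1, 0.2)),  # correlated with s1
             s5 = rbinom(n, 2, 0.5))
  rownames(d) <- paste0("i", 1:n)
  panel <- genotype_panel(d, chrom = rep("1", 5), pos = 1:5 * 10)
  kept <- ld_prune(panel, r2_threshold = 0.2)
  # independent greedy check written out longhand
  oracle <- character(0)
  for (s in colnames(d)) {
    ok <- TRUE
    for (k in oracle) if (cor(d[, s], d[, k])^2 > 0.2) ok <- FALSE
    if (ok) oracle <- c(oracle, s)
  }
  expect_identical(kept, oracle)
  expect_false("s3" %in% kept)  # perfect-LD copy removed
})

test_that("mutually uncorrelated SNPs are all retained", {
  set.seed(9)
  d <- matrix(rbinom(400 * 6, 2, 0.5), 400, 6,
              dimnames = list(paste0("i", 1:400), paste0("s", 1:6)))
  panel <- genotype_panel(d, chrom = rep("2", 6), pos = 1:6)
  expect_length(ld_prune(panel, 0.2), 6L)
})

test_that("founder PCA separates two founder populations on PC1", {
  set.seed(10)
  n1 <- 60; n2 <- 60; m <- 80
  f1 <- runif(m, 0.1, 0.4); f2 <- pmin(0.5, f1 + 0.35)
  d <- rbind(
    matrix(rbinom(n1 * m, 2, rep(f1, each = n1)), n1, m),
    matrix(rbinom(n2 * m, 2, rep(f2, each = n2)), n2, m))
  dimnames(d) <- list(paste0("i", 1:(n1 + n2)), paste0("s", 1:m))
  panel <- genotype_panel(d, chrom = rep("1", m), pos = 1:m)
  ids <- rownames(d)
  pcm <- founder_pca(panel, founders = ids, k = 5)
  pc1 <- pcm$scores[, 1]
  pops <- rep(c("a", "b"), c(n1, n2))
  expect_true(min(pc1[pops == "b"]) > max(pc1[pops == "a"]) ||
              min(pc1[pops == "a"]) > max(pc1[pops == "b"]))
  # founder scores are centred per PC
  expect_lt(max(abs(colMeans(pcm$scores))), 1e-8)
  # loadings are orthonormal
  expect_equal(crossprod(pcm$loadings), diag(5), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("projection reproduces founder scores and is an exact linear map", {
  set.seed(11)
  m <- 40
  d <- matrix(rbinom(50 * m, 2, 0.4), 50, m,
              dimnames = list(paste0("i", 1:50), paste0("s", 1:m)))
  panel <- genotype_panel(d, chrom = rep("1", m), pos = 1:m)
  pcm <- founder_pca(panel, founders = rownames(d), k = 3)
  proj <- project_pcs(pcm, panel)
  expect_equal(proj, pcm$scores, tolerance = 1e-10)
  # all-heterozygote row maps to ((1 - mean)/sd) %*% loadings exactly
  het <- matrix(1, 1, m, dimnames = list("h", colnames(d)))
  ph <- genotype_panel(rbind(d, het), chrom = rep("1", m), pos = 1:m)
  sc <- project_pcs(pcm, ph)["h", ]
  expect_equal(sc,
               drop(((1 - pcm$founder_means) / pcm$founder_sds) %*%
                    pcm$loadings),
               tolerance = 1e-10)
  # linearity over convex combinations of dosage rows
  w <- 0.3
  combo <- w * d[1, ] + (1 - w) * d[2, ]
  pc_combo <- drop(((combo - pcm$founder_means) / pcm$founder_sds) %*%
                   pcm$loadings)
  expect_equal(pc_combo, w * proj[1, ] + (1 - w) * proj[2, ],
               tolerance = 1e-10)
})

test_that("PCA guards: monomorphic subset and excessive k error", {
  d <- cbind(a = rep(1, 10), b = rbinom(10, 2, 0.5))
  rownames(d) <- paste0("i", 1:10)
  panel <- genotype_panel(d, chrom = c("1", "1"), pos = 1:2)
  expect_error(founder_pca(panel, rownames(d), k = 1), "polymorphic")
  expect_error(founder_pca(panel, rownames(d), snp_subset = "b", k = 5),
               "rank")
  pcm <- founder_pca(panel, rownames(d), snp_subset = "b", k = 1)
  expect_error(project_pcs(pcm, genotype_panel(
    matrix(1, 2, 1, dimnames = list(c("x", "y"), "zzz")),
    chrom = "1", pos = 1)), "missing")
})

test_that("LD proxies are in high LD with their source and get pruned", {
  set.seed(12)
  d <- matrix(rbinom(200 * 3, 2, 0.4), 200, 3,
              dimnames = list(paste0("i", 1:200), c("a", "b", "c")))
  panel <- genotype_panel(d, chrom = rep("1", 3), pos = c(100, 200, 300))
  aug <- add_ld_proxies(panel, "a", flip_prob = 0.02, seed = 4)
  expect_true("a_proxy" %in% colnames(aug$dosages))
  expect_gt(cor(aug$dosages[, "a"], aug$dosages[, "a_proxy"])^2, 0.8)
  kept <- ld_prune(aug, r2_threshold = 0.2)
  expect_true("a" %in% kept)
  expect_false("a_proxy" %in% kept)
})
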