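# Small fixtures shared across tests; all built in code.

# compact 3-generation config: 3 families x 12 = 36 individuals, 12 founders
tiny_config <- function(...) {
  defaults <- list(n_families = 3L,
                   family_template = list(n_generations = 3L,
                                          gen2_children = 2L,
                                          gen3_children = 3L),
                   n_null_snps = 20L, null_maf_range = c(0.1, 0.5),
                   n_replicates = 2L, seed = 123L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-built two-family pedigree with known relationships:
#   fam 1: founders f1 x f2 -> sibs s1, s2; s1 x f3 -> g1; s2 x f4 -> g2
#   (g1, g2 are first cousins); fam 2: a lone founder couple
hand_pedigree <- function() {
  ped <- data.frame(
    family = c(1, 1, 1, 1, 1, 1, 1, 1, 2, 2),
    id = c("f1", "f2", "s1", "s2", "f3", "f4", "g1", "g2", "u1", "u2"),
    father = c(NA, NA, "f1", "f1", NA, NA, "s1", "f4", NA, NA),
    mother = c(NA, NA, "f2", "f2", NA, NA, "f3", "s2", NA, NA),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female", "male", "female"),
    founder = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                TRUE, TRUE),
    generation = c(1, 1, 2, 2, 2, 2, 3, 3, 1, 1),
    stringsAsFactors = FALSE)
  class(ped) <- c("fam_pedigree", "data.frame")
  ped
}

# founder-only pedigree of n unrelated individuals
founder_pedigree <- function(n, prefix = "i") {
  ped <- data.frame(family = seq_len(n), id = paste0(prefix, seq_len(n)),
                    father = NA_character_, mother = NA_character_,
                    sex = rep(c("male", "female"), length.out = n),
                    founder = TRUE, generation = 1L,
                    stringsAsFactors = FALSE)
  class(ped) <- c("fam_pedigree", "data.frame")
  ped
}

# minimal replicate-dataset list around explicit pieces
make_dataset <- function(pedigree, panel, phenotypes, R, replicate_index = 1L) {
  structure(list(pedigree = pedigree, genotypes = panel,
                 phenotypes = phenotypes, R = R, truth = NULL,
                 replicate_index = replicate_index),
            class = "replicate_dataset")
}

# a converged lmm_fit stub with given coefficients and covariance
fake_fit <- function(beta, covariance) {
  dimnames(covariance) <- list(names(beta), names(beta))
  structure(list(beta = beta, covariance = covariance,
                 vc = list(sigma2_additive = 0,
                           sigma2_resid = c(resid = 1)),
                 loglik_reml = NA_real_, loglik_ml = NA_real_,
                 converged = TRUE, reason = NA_character_,
                 n_used = 100L, iterations = 1L, residual_groups = "resid",
                 vc_mode = "exact"),
            class = "lmm_fit")
}

# dense reference REML log-likelihood, written independently of fit_lmm
dense_reml_loglik <- function(y, X, R, sigma2_a, sigma2_e_vec) {
  n <- length(y); p <- ncol(X)
  V <- sigma2_a * as.matrix(R) + diag(sigma2_e_vec, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                     t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}
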