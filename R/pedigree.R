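#' Generate a multi-family extended pedigree
#'
#' Builds `n_families` disjoint families from the configured template. The
#' default template is a three-generation extended family: a founder couple,
#' `gen2_children` of theirs who each marry a founder spouse, and
#' `gen3_children` per second-generation couple (54 members, 6 founders). Sex
#' is structurally fixed for coupled individuals (couples are male/female);
#' terminal-generation children are assigned female with a probability
#' adjusted so the expected cohort proportion of females equals
#' `prop_female`. Uses the current RNG state; [generate_replicates()] seeds it
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A data frame of class `fam_pedigree`, topologically ordered
#'   (parents precede children), with columns `family`, `id`, `father`,
#'   `mother` (`NA` for founders), `sex` (`"male"`/`"female"`), `founder`,
#'   `generation`.
#' @export
#' @examples
#' set.seed(1)
#' ped <- generate_pedigree(sim_config(n_families = 2))
#' table(ped$founder)
generate_pedigree <- function(config) {
  config <- validate_sim_config(config)
  tpl <- config$family_template
  ngen <- as.integer(tpl$n_generations)
  fams <- vector("list", config$n_families)

  # per-family counts used to balance child sex towards prop_female
  tmp <- build_family(1L, tpl, p_child_female = 0.5)
  n_total <- nrow(tmp) * config$n_families
  n_coupled <- sum(!is.na(tmp$spouse_slot)) * config$n_families
  n_free <- n_total - n_coupled
  p_child <- if (n_free > 0)
    min(1, max(0, (config$prop_female * n_total - 0.5 * n_coupled) / n_free))
  else 0.5

  for (f in seq_len(config$n_families))
    fams[[f]] <- build_family(f, tpl, p_child_female = p_child)
  ped <- do.call(rbind, fams)
  ped$spouse_slot <- NULL
  rownames(ped) <- NULL
  class(ped) <- c("fam_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

# One family from the template. Individuals whose sex is structurally fixed
# by a couple carry spouse_slot; free (terminal) children are sexed at random.
build_family <- function(fam, tpl, p_child_female) {
  ngen <- as.integer(tpl$n_generations)
  idc <- function(k) sprintf("%d_%d", fam, k)
  rows <- list()
  k <- 0L
  add <- function(father, mother, sex, founder, gen, spouse_slot = NA) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(family = fam, id = idc(k),
                             father = father, mother = mother,
                             sex = sex, founder = founder, generation = gen,
                             spouse_slot = spouse_slot,
                             stringsAsFactors = FALSE)
    idc(k)
  }
  pa <- add(NA_character_, NA_character_, "male", TRUE, 1L, spouse_slot = 1)
  ma <- add(NA_character_, NA_character_, "female", TRUE, 1L, spouse_slot = 1)
  if (ngen >= 2L) {
    for (j in seq_len(tpl$gen2_children)) {
      if (ngen >= 3L) {
        # gen-2 children marry in a founder spouse: couples alternate sex
        csex <- if (j %% 2L == 1L) "male" else "female"
        child <- add(pa, ma, csex, FALSE, 2L, spouse_slot = 1 + j)
        ssex <- if (csex == "male") "female" else "male"
        spouse <- add(NA_character_, NA_character_, ssex, TRUE, 2L,
                      spouse_slot = 1 + j)
        fa3 <- if (csex == "male") child else spouse
        mo3 <- if (csex == "male") spouse else child
        for (m in seq_len(tpl$gen3_children)) {
          gsex <- if (runif(1) < p_child_female) "female" else "male"
          add(fa3, mo3, gsex, FALSE, 3L)
        }
      } else {
        gsex <- if (runif(1) < p_child_female) "female" else "male"
        add(pa, ma, gsex, FALSE, 2L)
      }
    }
  }
  do.call(rbind, rows)
}

#' Validate pedigree structure
#'
#' Checks the structural invariants: founders have no parent links and
#' non-founders have both; all parent identifiers resolve; fathers are male
#' and mothers female; parent links are acyclic with parents preceding
#' children in row order.
#'
#' @param ped a `fam_pedigree` data frame.
#' @return `ped` invisibly; errors describe the violated invariant.
#' @export
validate_pedigree <- function(ped) {
  req <- c("family", "id", "father", "mother", "sex", "founder", "generation")
  if (!all(req %in% names(ped)))
    stop("pedigree is missing columns: ",
         paste(setdiff(req, names(ped)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(ped$id))
    stop("pedigree ids are not unique", call. = FALSE)
  both_na <- is.na(ped$father) & is.na(ped$mother)
  both_ok <- !is.na(ped$father) & !is.na(ped$mother)
  if (any(ped$founder & !both_na))
    stop("founders must have no parent links", call. = FALSE)
  if (any(!ped$founder & !both_ok))
    stop("non-founders must have both parent links", call. = FALSE)
  idx <- match(ped$id, ped$id)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  if (any(!is.na(ped$father) & is.na(fi)) || any(!is.na(ped$mother) & is.na(mi)))
    stop("unresolved parent identifier in pedigree", call. = FALSE)
  if (any(ped$sex[fi[!is.na(fi)]] != "male") ||
      any(ped$sex[mi[!is.na(mi)]] != "female"))
    stop("fathers must be male and mothers female", call. = FALSE)
  ord <- pedigree_order(ped)  # errors on cycles
  invisible(ped)
}

#' Topological order of a pedigree
#'
#' Kahn's algorithm over the parent-child graph; errors on cycles.
#'
#' @param ped a pedigree data frame.
#' @return An integer permutation of rows with parents before children.
#' @export
pedigree_order <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  indeg <- (!is.na(fi)) + (!is.na(mi))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i]))
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n)
    stop("pedigree parent links contain a cycle", call. = FALSE)
  ord
}
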