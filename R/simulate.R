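#' Simulation configuration
#'
#' Bundles everything the gene-drop simulator needs: the pedigree template,
#' the marker table (with population MAFs and liability-scale effect sizes),
#' the disease prevalence, the number of phenotype replicates and the seed.
#'
#' @param pedigree_template Either [three_generation()] or a `fam_pedigree`
#'   to use as-is.
#' @param n_families Number of families (ignored for a custom pedigree).
#' @param markers A tibble with columns `marker_id`, `gene`,
#'   `functional_class`, `population_maf` (in \[0, 0.5\]; 0 gives a fixed
#'   all-zero marker) and `effect_beta`
#'   (liability-scale effect per minor-allele copy; 0 for neutral variants).
#'   An optional `chromosome` column is carried through to the annotation.
#' @param prevalence_k Disease prevalence in (0, 1).
#' @param n_replicates Number of phenotype replicates (>= 1).
#' @param seed Integer seed; one seed deterministically drives pedigree
#'   construction, founder alleles, transmissions and every replicate via an
#'   internal sub-seed scheme, so each piece is independently reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(pedigree_template = three_generation(4),
                       n_families = 8, markers, prevalence_k = 0.3,
                       n_replicates = 200, seed = 1) {
  check_prevalence(prevalence_k)
  if (n_replicates < 1 || n_families < 1) {
    abort_famqls("n_replicates and n_families must be >= 1.",
                 "famqls_config_error")
  }
  markers <- tibble::as_tibble(markers)
  needed <- c("marker_id", "gene", "functional_class", "population_maf",
              "effect_beta")
  if (!all(needed %in% names(markers))) {
    abort_famqls(sprintf("markers needs columns %s.",
                         paste(needed, collapse = ", ")),
                 "famqls_config_error")
  }
  if (!"chromosome" %in% names(markers)) {
    markers$chromosome <- as.character(as.integer(factor(markers$gene)) %% 22 + 1)
  }
  if (any(markers$population_maf < 0 | markers$population_maf > 0.5)) {
    abort_famqls("population_maf must lie in [0, 0.5].", "famqls_config_error")
  }
  if (anyDuplicated(markers$marker_id)) {
    abort_famqls("marker_id values must be unique.", "famqls_config_error")
  }
  structure(list(pedigree_template = pedigree_template,
                 n_families = as.integer(n_families), markers = markers,
                 prevalence_k = prevalence_k,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Three-generation pedigree template
#'
#' Each family: a founder couple; their `n_children` children, each married
#' to an unrelated founder spouse; and `n_children` grandchildren per
#' second-generation couple. Family size is `2 + 2 n + n^2` (17 members for
#' `n = 3`, 82 for `n = 8`).
#'
#' @param n_children Children per couple; a scalar, or a vector recycled
#'   across families so family sizes can vary.
#' @return A template object consumed by [gene_drop()].
#' @export
three_generation <- function(n_children = 4) {
  structure(list(type = "three_generation", n_children = n_children),
            class = "ped_template")
}

build_pedigree <- function(cfg) {
  tpl <- cfg$pedigree_template
  if (inherits(tpl, "fam_pedigree")) return(tpl)
  nch <- rep_len(tpl$n_children, cfg$n_families)
  fams <- lapply(seq_len(cfg$n_families), function(f) {
    n <- nch[[f]]
    rows <- list(tibble::tibble(person_id = c("G1_1", "G1_2"),
                                father_id = NA_character_,
                                mother_id = NA_character_,
                                sex = c("male", "female")))
    for (c_ in seq_len(n)) {
      child <- sprintf("G2_%d", c_)
      spouse <- sprintf("G2S_%d", c_)
      child_sex <- if (c_ %% 2 == 1) "male" else "female"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        person_id = c(child, spouse),
        father_id = c("G1_1", NA_character_),
        mother_id = c("G1_2", NA_character_),
        sex = c(child_sex, if (child_sex == "male") "female" else "male"))
      gc_ids <- sprintf("G3_%d_%d", c_, seq_len(n))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        person_id = gc_ids,
        father_id = if (child_sex == "male") child else spouse,
        mother_id = if (child_sex == "male") spouse else child,
        sex = rep_len(c("female", "male"), n))
    }
    fam <- dplyr::bind_rows(rows)
    fam$family_id <- sprintf("F%d", f)
    fam
  })
  as_pedigree(dplyr::bind_rows(fams)[, c("family_id", "person_id",
                                         "father_id", "mother_id", "sex")])
}

#' Gene-drop simulation of rare-variant genotypes
#'
#' Draws each founder haplotype allele independently as
#' Bernoulli(`population_maf`) per marker, then transmits one allele from
#' each parent to each child, chosen uniformly and independently per marker
#' (Mendelian segregation, markers dropped independently — rare variants are
#' taken to lie on distinct haplotypes, so no within-gene LD or recombination
#' model). This transmission is precisely what concentrates a founder's rare
#' variant inside that founder's family.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `pedigree` (`fam_pedigree`), `genotypes`
#'   (`famqls_geno` of half-count dosages, no missingness) and `annotation`
#'   (tibble in the [read_annotation()] schema).
#' @export
gene_drop <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- build_pedigree(cfg)
  mk <- cfg$markers
  n <- nrow(ped); J <- nrow(mk)
  fa <- match(ifelse(is.na(ped$father_id), NA,
                     ped_key(ped$family_id, ped$father_id)), key_of(ped))
  mo <- match(ifelse(is.na(ped$mother_id), NA,
                     ped_key(ped$family_id, ped$mother_id)), key_of(ped))

  A1 <- matrix(0L, n, J)    # allele inherited from father (founder: draw 1)
  A2 <- matrix(0L, n, J)
  is_f <- is.na(fa)
  set.seed(child_seed(cfg$seed, 2L))
  A1[is_f, ] <- matrix(stats::rbinom(sum(is_f) * J, 1L,
                                     rep(mk$population_maf, each = sum(is_f))),
                       sum(is_f), J)
  A2[is_f, ] <- matrix(stats::rbinom(sum(is_f) * J, 1L,
                                     rep(mk$population_maf, each = sum(is_f))),
                       sum(is_f), J)
  set.seed(child_seed(cfg$seed, 3L))
  for (i in topo_order(ped)) {
    if (is_f[i]) next
    pick_f <- stats::runif(J) < 0.5
    A1[i, ] <- ifelse(pick_f, A1[fa[i], ], A2[fa[i], ])
    pick_m <- stats::runif(J) < 0.5
    A2[i, ] <- ifelse(pick_m, A1[mo[i], ], A2[mo[i], ])
  }
  g <- tibble::as_tibble(as.data.frame((A1 + A2) / 2))
  names(g) <- mk$marker_id
  g <- dplyr::bind_cols(tibble::tibble(family_id = ped$family_id,
                                       person_id = ped$person_id), g)
  class(g) <- c("famqls_geno", class(tibble::tibble()))
  ann <- mk[, c("marker_id", "gene", "chromosome", "functional_class",
                "population_maf")]
  list(pedigree = ped, genotypes = g, annotation = ann)
}

#' Simulate replicate phenotypes under a liability threshold model
#'
#' For replicate \eqn{r}, individual \eqn{i}'s liability is
#' \deqn{L_{ir} = \sum_j \beta_j \cdot (2\,\mathrm{dosage}_{ij}) +
#'       \epsilon_{ir}, \qquad \epsilon_{ir} \sim N(0,1)}
#' with the noise redrawn each replicate and genotypes held fixed across
#' replicates (replicate phenotype sets over one genotype draw). The
#' affection threshold is the empirical \eqn{(1-k)} quantile of that
#' replicate's liabilities, so every replicate has exactly `round(k * n)`
#' cases; this stabilises power estimates relative to a fixed theoretical
#' threshold.
#'
#' @param geno `famqls_geno` from [gene_drop()].
#' @param cfg The same [sim_config()].
#' @return A `famqls_pheno` tibble (`rep_001`, ... columns of 0/1), with the
#'   prevalence stored in attribute `"prevalence"`.
#' @export
simulate_phenotypes <- function(geno, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(geno)
  m <- round(cfg$prevalence_k * n)
  if (m < 1) {
    abort_famqls("prevalence_k * n must be at least 1 case.",
                 "famqls_config_error")
  }
  mk <- cfg$markers
  causal <- mk$effect_beta != 0
  base <- if (any(causal)) {
    D <- as_unit_matrix(geno[, c("family_id", "person_id",
                                 mk$marker_id[causal])])
    drop(D %*% (2 * mk$effect_beta[causal]))
  } else {
    rep(0, n)
  }
  out <- tibble::tibble(family_id = geno$family_id,
                        person_id = geno$person_id)
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(child_seed(cfg$seed, 100L + r))
    L <- base + stats::rnorm(n)
    z <- numeric(n)
    z[order(L, decreasing = TRUE)[seq_len(m)]] <- 1
    out[[sprintf("rep_%03d", r)]] <- z
  }
  attr(out, "prevalence") <- cfg$prevalence_k
  class(out) <- c("famqls_pheno", class(tibble::tibble()))
  out
}
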