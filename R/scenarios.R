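# Canned simulation scenarios. Each scenario defines its study conditions
# (family structure, marker table, effect sizes, prevalence, replicate count)
# once; the seed only moves the random draws. Scenarios whose definition
# includes realized features of the genotype draw (e.g. "a gene carried by
# several families through distinct variants") use bounded seed-deterministic
# rejection sampling over gene-drop draws until those features hold.

scenario_draw <- function(cfg, predicate, max_attempts = 100L) {
  for (attempt in seq_len(max_attempts)) {
    cfg$seed <- child_seed(cfg$seed_base, 1000L + attempt)
    sim <- gene_drop(cfg)
    if (predicate(sim)) {
      sim$config <- cfg
      sim$attempts <- attempt
      return(sim)
    }
  }
  abort_famqls(sprintf(
    "scenario features not realized in %d gene-drop draws; widen MAFs or change seed.",
    max_attempts), "famqls_config_error")
}

carrier_families <- function(geno, marker) {
  unique(geno$family_id[!is.na(geno[[marker]]) & geno[[marker]] > 0])
}

#' Mini-exome family scenario
#'
#' A desk-scale analogue of an 8-extended-family mini-exome study: 8
#' three-generation families of varying size (17 to 82 members, ~340 total),
#' ~40 genes of 1-6 rare SNPs each (population MAF 0.001-0.01, a mix of
#' synonymous and nonsynonymous), 200 phenotype replicates at prevalence 0.3.
#' Causal structure (all causal variants nonsynonymous, effects on the
#' liability scale):
#' * `GENE01` — a CFTR-like gene: 6 distinct causal variants
#'   (`beta = 1.2`), so different families can carry different mutations of
#'   the same gene;
#' * `GENE02` — a single causal variant (`beta = 1.5`) that the scenario
#'   guarantees is private to one family;
#' * `GENE03` — 3 causal variants (`beta = 1.2`);
#' * all remaining genes neutral.
#'
#' The returned draw is guaranteed (by bounded rejection over gene-drop
#' draws, deterministic in `seed`) to contain: a gene carried by at least two
#' families via distinct member variants; at least one causal variant
#' segregating in exactly one family with two or more carriers; and at least
#' one founder-carried variant never transmitted to a non-founder.
#'
#' @param seed Integer seed.
#' @param n_replicates Number of phenotype replicates.
#' @return A list: `pedigree`, `genotypes`, `annotation`, `phenotypes`,
#'   `config` (the accepted [sim_config()]), `markers` (marker table with
#'   effects), `private_causal` (marker id of a realized one-family causal
#'   variant).
#' @export
gaw17_like_scenario <- function(seed = 1, n_replicates = 200) {
  set.seed(child_seed(seed, 11L))
  n_genes <- 40
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  snps_per_gene <- pmax(1L, pmin(6L, stats::rpois(n_genes, 2.2) + 1L))
  snps_per_gene[1L] <- 6L   # the CFTR-like gene
  snps_per_gene[2L] <- 1L
  snps_per_gene[3L] <- 3L
  mk <- dplyr::bind_rows(lapply(seq_len(n_genes), function(i) {
    nj <- snps_per_gene[[i]]
    tibble::tibble(
      marker_id = sprintf("%s_V%d", genes[[i]], seq_len(nj)),
      gene = genes[[i]],
      chromosome = as.character((i - 1L) %% 22L + 1L),
      functional_class = sample(c("nonsynonymous", "synonymous"), nj,
                                replace = TRUE, prob = c(0.55, 0.45)),
      population_maf = stats::runif(nj, 0.001, 0.01),
      effect_beta = 0)
  }))
  causal <- c(sprintf("GENE01_V%d", 1:6), "GENE02_V1",
              sprintf("GENE03_V%d", 1:3))
  mk$functional_class[mk$marker_id %in% causal] <- "nonsynonymous"
  mk$population_maf[mk$gene == "GENE01"] <- 0.006
  mk$population_maf[mk$marker_id == "GENE02_V1"] <- 0.006
  mk$effect_beta[mk$gene %in% c("GENE01", "GENE03")] <- 1.2
  mk$effect_beta[mk$marker_id == "GENE02_V1"] <- 1.5

  cfg <- sim_config(pedigree_template = three_generation(c(3, 4, 4, 5, 5, 6, 7, 8)),
                    n_families = 8, markers = mk, prevalence_k = 0.3,
                    n_replicates = n_replicates, seed = seed)
  cfg$seed_base <- seed

  predicate <- function(sim) {
    g <- sim$genotypes
    g01 <- sprintf("GENE01_V%d", 1:6)
    fams_by_variant <- lapply(g01, carrier_families, geno = g)
    multi_family_gene <-
      length(unique(unlist(fams_by_variant))) >= 2L &&
      sum(lengths(fams_by_variant) > 0L) >= 2L
    private_ok <- any(vapply(causal, function(mkid) {
      f <- carrier_families(g, mkid)
      length(f) == 1L && sum(g[[mkid]] > 0) >= 2L
    }, logical(1)))
    fk <- key_of(founders(sim$pedigree))
    is_f <- key_of(g) %in% fk
    D <- as_unit_matrix(g)
    untransmitted <- any(colSums(D[is_f, , drop = FALSE] > 0) > 0 &
                           colSums(D[!is_f, , drop = FALSE] > 0) == 0)
    multi_family_gene && private_ok && untransmitted
  }

  sim <- scenario_draw(cfg, predicate)
  sim$phenotypes <- simulate_phenotypes(sim$genotypes, sim$config)
  sim$markers <- mk
  priv <- causal[vapply(causal, function(mkid) {
    f <- carrier_families(sim$genotypes, mkid)
    length(f) == 1L && sum(sim$genotypes[[mkid]] > 0) >= 2L
  }, logical(1))]
  sim$private_causal <- priv[[1L]]
  sim
}

#' Null scenario for test calibration
#'
#' The same family structure and marker table as [gaw17_like_scenario()] but
#' with every effect set to zero, so case status is independent of genotype.
#' No rejection sampling: any draw is a valid null.
#'
#' @param seed Integer seed.
#' @param n_replicates Number of phenotype replicates (default 5000, sized
#'   for type-I-error estimation).
#' @return A list: `pedigree`, `genotypes`, `annotation`, `phenotypes`,
#'   `config`.
#' @export
null_scenario <- function(seed = 1, n_replicates = 5000) {
  set.seed(child_seed(seed, 11L))
  n_genes <- 40
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  snps_per_gene <- pmax(1L, pmin(6L, stats::rpois(n_genes, 2.2) + 1L))
  mk <- dplyr::bind_rows(lapply(seq_len(n_genes), function(i) {
    nj <- snps_per_gene[[i]]
    tibble::tibble(
      marker_id = sprintf("%s_V%d", genes[[i]], seq_len(nj)),
      gene = genes[[i]],
      chromosome = as.character((i - 1L) %% 22L + 1L),
      functional_class = sample(c("nonsynonymous", "synonymous"), nj,
                                replace = TRUE, prob = c(0.55, 0.45)),
      population_maf = stats::runif(nj, 0.002, 0.01),
      effect_beta = 0)
  }))
  cfg <- sim_config(pedigree_template = three_generation(c(3, 4, 4, 5, 5, 6, 7, 8)),
                    n_families = 8, markers = mk, prevalence_k = 0.3,
                    n_replicates = n_replicates, seed = child_seed(seed, 21L))
  sim <- gene_drop(cfg)
  sim$phenotypes <- simulate_phenotypes(sim$genotypes, cfg)
  sim$config <- cfg
  sim
}

#' Collapsing-contrast scenario
#'
#' A two-gene scenario built to show when gene-level collapsing helps and
#' when it hurts, at prevalence 0.3 with 200 phenotype replicates over 8
#' three-generation families:
#' * `PRIV` — 3 causal rare variants (`beta = 1.2`, MAF 0.006) guaranteed by
#'   rejection sampling to segregate in three *different* single families
#'   with 4-10 carriers each (rare in the data but numerous enough that each
#'   family contributes real, comparable signal; pooling one dominant
#'   variant with two negligible ones would be the dilution case instead):
#'   the collapsed indicator can pool the three families' signals while each
#'   single-SNP test sees only one family.
#' * `DILUT` — 1 strong causal variant (`beta = 2.2`, MAF 0.008, guaranteed
#'   to segregate with 5-10 carriers so its single-SNP test has substantial
#'   power) plus 20 neutral rare members (MAF 0.005): the collapsed
#'   indicator buries the causal carriers among neutral carriers.
#'
#' Because gene-drop markers are independent, each conditioned variant is
#' rejection-sampled on its own column (statistically identical to
#' conditioning the joint draw, and far cheaper).
#' A block of 10 neutral background genes is included so the marker table is
#' not degenerate.
#'
#' @param seed Integer seed.
#' @param n_replicates Number of phenotype replicates.
#' @return As [gaw17_like_scenario()], without `private_causal`.
#' @export
collapsing_contrast_scenario <- function(seed = 1, n_replicates = 200) {
  set.seed(child_seed(seed, 31L))
  priv <- tibble::tibble(
    marker_id = sprintf("PRIV_V%d", 1:3), gene = "PRIV", chromosome = "1",
    functional_class = "nonsynonymous", population_maf = 0.006,
    effect_beta = 1.2)
  dilut <- tibble::tibble(
    marker_id = c("DILUT_V1", sprintf("DILUT_N%02d", 1:20)), gene = "DILUT",
    chromosome = "2", functional_class = "nonsynonymous",
    population_maf = c(0.008, rep(0.005, 20)),
    effect_beta = c(2.2, rep(0, 20)))
  bg <- dplyr::bind_rows(lapply(1:10, function(i) {
    tibble::tibble(marker_id = sprintf("BG%02d_V%d", i, 1:2),
                   gene = sprintf("BG%02d", i),
                   chromosome = as.character(i + 2L),
                   functional_class = sample(c("nonsynonymous", "synonymous"),
                                             2, replace = TRUE),
                   population_maf = stats::runif(2, 0.002, 0.01),
                   effect_beta = 0)
  }))
  mk <- dplyr::bind_rows(priv, dilut, bg)
  tpl <- three_generation(c(3, 4, 4, 5, 5, 6, 7, 8))
  cfg <- sim_config(pedigree_template = tpl, n_families = 8, markers = mk,
                    prevalence_k = 0.3, n_replicates = n_replicates,
                    seed = seed)
  ped <- build_pedigree(cfg)

  # Markers are dropped independently, so each conditioned variant can be
  # rejection-sampled on its own (identical to conditioning the joint draw,
  # at per-marker cost). Deterministic sub-seed stream per marker.
  draw_conditioned <- function(mrow, pred, stream, max_attempts = 2000L) {
    for (a in seq_len(max_attempts)) {
      cfg1 <- sim_config(tpl, 8, mrow, 0.3, 1,
                         child_seed(child_seed(seed, stream), a))
      g1 <- gene_drop(cfg1)$genotypes
      if (pred(g1[[mrow$marker_id]], g1$family_id)) return(g1[[mrow$marker_id]])
    }
    abort_famqls(sprintf(
      "carrier pattern for %s not realized in %d gene-drop draws.",
      mrow$marker_id, max_attempts), "famqls_config_error")
  }

  used_fams <- character(0)
  cols <- list()
  for (v in 1:3) {
    id <- sprintf("PRIV_V%d", v)
    y <- draw_conditioned(priv[v, ], function(y, fid) {
      carr <- unique(fid[y > 0])
      length(carr) == 1L && !carr %in% used_fams &&
        sum(y > 0) >= 4L && sum(y > 0) <= 10L
    }, stream = 50L + v)
    used_fams <- c(used_fams, unique(ped$family_id[y > 0]))
    cols[[id]] <- y
  }
  cols[["DILUT_V1"]] <- draw_conditioned(dilut[1, ], function(y, fid) {
    sum(y > 0) >= 5L && sum(y > 0) <= 10L
  }, stream = 60L)

  rest <- mk[!mk$marker_id %in% names(cols), ]
  cfg_rest <- sim_config(tpl, 8, rest, 0.3, 1, child_seed(seed, 70L))
  g_rest <- gene_drop(cfg_rest)$genotypes
  g <- tibble::tibble(family_id = ped$family_id, person_id = ped$person_id)
  for (id in mk$marker_id) {
    g[[id]] <- if (id %in% names(cols)) cols[[id]] else g_rest[[id]]
  }
  class(g) <- c("famqls_geno", class(tibble::tibble()))

  sim <- list(pedigree = ped, genotypes = g,
              annotation = mk[, c("marker_id", "gene", "chromosome",
                                  "functional_class", "population_maf")],
              config = cfg)
  sim$phenotypes <- simulate_phenotypes(sim$genotypes, sim$config)
  sim$markers <- mk
  sim
}

#' Write a simulated scenario to disk
#'
#' Emits exactly the text formats the package's readers consume: `.fam`
#' pedigree, `tsv_dosage` genotypes, annotation TSV, replicate phenotype TSV
#' and a flat key-value config file.
#'
#' @param sim A scenario list (from [gene_drop()] plus phenotypes, or any
#'   `*_scenario()` function).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.fam"))
  write_dosages(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(sim$phenotypes)) {
    write_phenotypes(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  }
  if (!is.null(sim$config)) {
    cfg <- sim$config
    lines <- c(sprintf("seed=%d", cfg$seed),
               sprintf("prevalence_k=%g", cfg$prevalence_k),
               sprintf("n_replicates=%d", cfg$n_replicates),
               sprintf("n_families=%d", cfg$n_families))
    writeLines(lines, file.path(dir, "config.txt"))
  }
  invisible(dir)
}
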