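mk1 <- function(maf = 0.5, beta = 0) {
  tibble::tibble(marker_id = "M1", gene = "G1",
                 functional_class = "nonsynonymous",
                 population_maf = maf, effect_beta = beta)
}

test_that("gene drop is seed-deterministic and respects founder allele frequencies", {
  cfg <- sim_config(three_generation(4), 4, mk1(0.5), 0.3, 2, seed = 99)
  a <- gene_drop(cfg)
  b <- gene_drop(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(simulate_phenotypes(a$genotypes, cfg),
                   simulate_phenotypes(b$genotypes, cfg))

  # founder mean dosage ~ Binomial(2 * n_founders, maf) / (2 n)
  big <- gene_drop(sim_config(unrelated_ped(600), markers = mk1(0.5),
                              prevalence_k = 0.3, n_replicates = 1,
                              seed = 4))
  m <- mean(big$genotypes$M1)
  se <- sqrt(0.5 * 0.5 / (2 * 600))
  expect_lt(abs(m - 0.5), 3 * se)

  # monomorphic limit: zero MAF gives all-zero dosages
  zero <- gene_drop(sim_config(three_generation(4), 4, mk1(0), 0.3, 1, 1))
  expect_true(all(zero$genotypes$M1 == 0))
})

test_that("transmission is Mendelian: no allele appears without a carrier parent", {
  cfg <- sim_config(three_generation(c(4, 6)), 2,
                    dplyr::bind_rows(mk1(0.3), within(mk1(0.3),
                                                      marker_id <- "M2")),
                    0.3, 1, seed = 13)
  sim <- gene_drop(cfg)
  ped <- sim$pedigree
  keys <- paste(ped$family_id, ped$person_id, sep = ":")
  for (mid in c("M1", "M2")) {
    y <- sim$genotypes[[mid]]
    for (i in which(!is.na(ped$father_id))) {
      fa <- match(paste(ped$family_id[i], ped$father_id[i], sep = ":"), keys)
      mo <- match(paste(ped$family_id[i], ped$mother_id[i], sep = ":"), keys)
      if (y[i] > 0) expect_true(y[fa] > 0 || y[mo] > 0)
      if (y[i] == 1) expect_true(y[fa] > 0 && y[mo] > 0)
    }
  }
})

test_that("a heterozygous founder transmits the rare allele to half the children", {
  # one couple, many children; condition on father het, mother non-carrier
  n_kids <- 4000
  ped <- as_pedigree(data.frame(
    family_id = "F1",
    person_id = c("P1", "P2", sprintf("K%04d", seq_len(n_kids))),
    father_id = c(NA, NA, rep("P1", n_kids)),
    mother_id = c(NA, NA, rep("P2", n_kids)),
    sex = "unknown", stringsAsFactors = FALSE))
  sim <- NULL
  for (s in 1:200) {
    cand <- gene_drop(sim_config(ped, markers = mk1(0.5),
                                 prevalence_k = 0.3, n_replicates = 1,
                                 seed = s))
    y <- cand$genotypes$M1
    if (y[1] == 0.5 && y[2] == 0) { sim <- cand; break }
  }
  kid_carrier <- sim$genotypes$M1[-(1:2)] > 0
  phat <- mean(kid_carrier)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n_kids))
})

test_that("liability phenotypes have exact case counts and genotype-independent nulls", {
  ped <- unrelated_ped(100)
  cfg <- sim_config(ped, markers = mk1(0.2, beta = 0), prevalence_k = 0.3,
                    n_replicates = 20, seed = 77)
  sim <- gene_drop(cfg)
  ph <- simulate_phenotypes(sim$genotypes, cfg)
  counts <- colSums(as.data.frame(ph)[, -(1:2)])
  expect_true(all(counts == 30))
  # null: carrier case rate matches non-carrier case rate on average
  carrier <- sim$genotypes$M1 > 0
  rates <- sapply(famqls:::value_cols(ph),
                  function(r) mean(ph[[r]][carrier]) - mean(ph[[r]][!carrier]))
  expect_lt(abs(mean(rates)), 0.15)

  expect_error(simulate_phenotypes(sim$genotypes,
                                   sim_config(ped, markers = mk1(),
                                              prevalence_k = 0.001,
                                              n_replicates = 1, seed = 1)),
               class = "famqls_config_error")
})

test_that("strong liability effects overrepresent carriers among cases", {
  ped <- unrelated_ped(200)
  cfg <- sim_config(ped, markers = mk1(0.2, beta = 2), prevalence_k = 0.3,
                    n_replicates = 200, seed = 55)
  sim <- gene_drop(cfg)
  ph <- simulate_phenotypes(sim$genotypes, cfg)
  carrier <- sim$genotypes$M1 > 0
  over <- sapply(famqls:::value_cols(ph),
                 function(r) mean(ph[[r]][carrier]) > mean(ph[[r]][!carrier]))
  expect_gt(mean(over), 0.95)
})

test_that("any single replicate can be regenerated in isolation", {
  ped <- unrelated_ped(50)
  cfg5 <- sim_config(ped, markers = mk1(0.2), prevalence_k = 0.3,
                     n_replicates = 5, seed = 21)
  cfg3 <- sim_config(ped, markers = mk1(0.2), prevalence_k = 0.3,
                     n_replicates = 3, seed = 21)
  g <- gene_drop(cfg5)$genotypes
  ph5 <- simulate_phenotypes(g, cfg5)
  ph3 <- simulate_phenotypes(g, cfg3)
  expect_identical(ph5$rep_003, ph3$rep_003)
})

test_that("the mini-exome scenario realizes its defining features", {
  sim <- gaw17_like_scenario(seed = 3, n_replicates = 5)
  expect_s3_class(as_pedigree(sim$pedigree), "fam_pedigree")
  expect_equal(nrow(sim$pedigree), 340)
  expect_equal(length(unique(sim$pedigree$family_id)), 8)
  expect_silent(famqls:::validate_annotation(sim$annotation))
  D <- as.matrix(as.data.frame(sim$genotypes)[, -(1:2)])
  expect_true(all(D %in% c(0, 0.5, 1)))

  # a CFTR-like gene: >= 2 carrier families through distinct member variants
  g01 <- sprintf("GENE01_V%d", 1:6)
  fams <- lapply(g01, function(m) unique(sim$genotypes$family_id[
    sim$genotypes[[m]] > 0]))
  expect_gte(length(unique(unlist(fams))), 2)
  expect_gte(sum(lengths(fams) > 0), 2)

  # a causal variant private to one family
  pv <- sim$private_causal
  expect_equal(length(unique(sim$genotypes$family_id[sim$genotypes[[pv]] > 0])), 1)

  # some founder-carried variant was never transmitted
  ft <- founder_transmission(sim$genotypes, sim$pedigree)
  expect_gt(sum(ft$present_in_founders & !ft$transmitted), 0)

  # most segregating rare variants are carried by at most two families
  om <- observed_maf(sim$genotypes)
  seg <- om$marker_id[om$maf > 0]
  fd <- family_distribution(sim$genotypes, sim$pedigree, seg)
  expect_gt(mean(fd$n_carrier_families <= 2), 0.5)
})

test_that("scenario writers emit files the readers round-trip", {
  sim <- gaw17_like_scenario(seed = 3, n_replicates = 3)
  dir <- withr::local_tempdir()
  write_scenario(sim, dir)
  ped <- read_pedigree(file.path(dir, "pedigree.fam"))
  expect_equal(as.data.frame(ped)[, 1:4],
               as.data.frame(sim$pedigree)[, 1:4])
  g <- read_genotypes(file.path(dir, "genotypes.tsv"), "tsv_dosage",
                      ped = ped)
  expect_equal(as.data.frame(g), as.data.frame(sim$genotypes))
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(as.data.frame(ph), as.data.frame(sim$phenotypes),
               ignore_attr = TRUE)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$marker_id, sim$annotation$marker_id)
})
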