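# Independent oracles, implemented without touching the package's own code
# paths for the quantities they check.

# Classical allelic chi-square on the 2x2 allele-count table (no continuity
# correction), via stats::chisq.test.
allelic_chisq <- function(Y, Z) {
  tab <- rbind(cases = c(2 * sum(Y[Z == 1]), 2 * sum(1 - Y[Z == 1])),
               controls = c(2 * sum(Y[Z == 0]), 2 * sum(1 - Y[Z == 0])))
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic))
}

# Monte-Carlo kinship estimate by explicit gene-dropping of labelled founder
# alleles: phi_ij = P(one random allele of i IBD to one random allele of j),
# averaged over the four allele pairs. Rows of `ped` must list parents before
# children (all fixtures do).
mc_kinship <- function(ped, person_i, person_j, ndrops = 1e5, seed = 42) {
  set.seed(seed)
  keys <- ped$person_id
  fa <- match(ped$father_id, keys)
  mo <- match(ped$mother_id, keys)
  n <- nrow(ped)
  A1 <- matrix(0L, ndrops, n)
  A2 <- matrix(0L, ndrops, n)
  lab <- 0L
  for (x in seq_len(n)) {
    if (is.na(fa[x])) {
      A1[, x] <- lab + 1L
      A2[, x] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::runif(ndrops) < 0.5
      A1[, x] <- ifelse(pick, A1[, fa[x]], A2[, fa[x]])
      pick <- stats::runif(ndrops) < 0.5
      A2[, x] <- ifelse(pick, A1[, mo[x]], A2[, mo[x]])
    }
  }
  i <- match(person_i, keys)
  j <- match(person_j, keys)
  share <- ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
              (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])) / 4
  list(estimate = mean(share), se = stats::sd(share) / sqrt(ndrops))
}
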