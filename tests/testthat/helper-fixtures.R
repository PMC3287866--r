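ped_key <- famqls:::ped_key

# Pedigree fixtures, built in code. Columns follow as_pedigree()'s contract.

ped_rows <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(family_id = r[[1]], person_id = r[[2]],
               father_id = ifelse(r[[3]] == "0", NA, r[[3]]),
               mother_id = ifelse(r[[4]] == "0", NA, r[[4]]),
               sex = r[[5]], stringsAsFactors = FALSE)
  }))
  as_pedigree(df)
}

trio_ped <- function() {
  ped_rows(c("F1", "A", "0", "0", "male"),
           c("F1", "B", "0", "0", "female"),
           c("F1", "C", "A", "B", "male"))
}

sibs_ped <- function() {
  ped_rows(c("F1", "A", "0", "0", "male"),
           c("F1", "B", "0", "0", "female"),
           c("F1", "C", "A", "B", "male"),
           c("F1", "D", "A", "B", "female"))
}

halfsib_ped <- function() {
  ped_rows(c("F1", "A", "0", "0", "male"),
           c("F1", "B", "0", "0", "female"),
           c("F1", "C", "0", "0", "female"),
           c("F1", "D", "A", "B", "male"),
           c("F1", "E", "A", "C", "female"))
}

cousins_ped <- function() {
  ped_rows(c("F1", "GP1", "0", "0", "male"),
           c("F1", "GP2", "0", "0", "female"),
           c("F1", "P1", "GP1", "GP2", "male"),
           c("F1", "P2", "GP1", "GP2", "female"),
           c("F1", "S1", "0", "0", "female"),
           c("F1", "S2", "0", "0", "male"),
           c("F1", "C1", "P1", "S1", "male"),
           c("F1", "C2", "S2", "P2", "female"))
}

# offspring of a full-sib mating: inbreeding 0.25, kinship diagonal 0.625
inbred_ped <- function() {
  ped_rows(c("F1", "A", "0", "0", "male"),
           c("F1", "B", "0", "0", "female"),
           c("F1", "C", "A", "B", "male"),
           c("F1", "D", "A", "B", "female"),
           c("F1", "E", "C", "D", "male"))
}

unrelated_ped <- function(n, family_id = "F1") {
  as_pedigree(data.frame(
    family_id = family_id, person_id = sprintf("U%03d", seq_len(n)),
    father_id = NA_character_, mother_id = NA_character_,
    sex = rep_len(c("male", "female"), n), stringsAsFactors = FALSE))
}

# wide genotype tibble from a pedigree and a named list of dosage vectors
make_geno <- function(ped, markers) {
  g <- tibble::tibble(family_id = ped$family_id, person_id = ped$person_id)
  for (nm in names(markers)) g[[nm]] <- markers[[nm]]
  class(g) <- c("famqls_geno", class(tibble::tibble()))
  g
}

make_pheno <- function(ped, ...) {
  reps <- list(...)
  ph <- tibble::tibble(family_id = ped$family_id, person_id = ped$person_id)
  for (i in seq_along(reps)) ph[[sprintf("rep_%03d", i)]] <- reps[[i]]
  class(ph) <- c("famqls_pheno", class(tibble::tibble()))
  ph
}

make_annotation <- function(marker_id, gene,
                            functional_class = "nonsynonymous",
                            population_maf = 0.005) {
  tibble::tibble(marker_id = marker_id, gene = gene,
                 chromosome = "1",
                 functional_class = rep_len(functional_class,
                                            length(marker_id)),
                 population_maf = rep_len(population_maf, length(marker_id)))
}
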