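# Internal helpers shared across modules.

# (family_id, person_id) is the unique key everywhere; the combined string key
# indexes kinship matrices and aligns genotype/phenotype tables to pedigrees.
ped_key <- function(family_id, person_id) paste(family_id, person_id, sep = ":")

key_of <- function(df) ped_key(df$family_id, df$person_id)

# Columns of a wide genotype-like tibble that are data, not keys.
value_cols <- function(df) setdiff(names(df), c("family_id", "person_id"))

abort_famqls <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "famqls_error"), ...)
}

check_prevalence <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0 || k >= 1) {
    abort_famqls("`k` (disease prevalence) must be a single number in (0, 1).",
                 "famqls_argument_error")
  }
  invisible(k)
}

# Deterministic sub-seed derivation: one user seed fans out into independent
# streams (pedigree, founder alleles, transmission, each phenotype replicate,
# scenario rejection attempts) so any piece can be regenerated in isolation.
# Kept strictly below 2^31 - 1.
child_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(stream) * 7919) %% 2147483629)
}

# Align a wide keyed table (genotypes, phenotypes, collapsed indicators) to a
# vector of keys, erroring on absences.
align_to_keys <- function(df, keys, what = "table") {
  dk <- key_of(df)
  idx <- match(keys, dk)
  if (anyNA(idx)) {
    missing <- keys[is.na(idx)]
    abort_famqls(
      sprintf("%s is missing %d pedigree individual(s), e.g. %s.",
              what, length(missing), missing[[1L]]),
      "famqls_alignment_error"
    )
  }
  df[idx, , drop = FALSE]
}

as_unit_matrix <- function(df) {
  cols <- value_cols(df)
  m <- as.matrix(df[, cols, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- key_of(df)
  m
}
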