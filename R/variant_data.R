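#' Read a genotype matrix
#'
#' Loads per-individual minor-allele dosages coded as half-counts
#' (0, 0.5, 1 for 0, 1, 2 copies of the minor allele; `NA` for missing), the
#' coding the quasi-likelihood score tests operate on.
#'
#' Two dialects are supported:
#' * `"tsv_dosage"`: a TSV with header `family_id person_id <marker ids...>`
#'   and integer minor-allele counts 0/1/2 (or half-counts 0/0.5/1, e.g. a
#'   collapsed-indicator table written by [write_dosages()]); counts are
#'   converted to half-counts.
#' * `"ped_map"`: a LINKAGE/PLINK `.ped` with allele pairs per marker
#'   (`0 0` = missing) plus a `.map` file giving marker ids. The minor allele
#'   is determined per marker from observed frequency, ties broken
#'   lexicographically by allele symbol.
#'
#' @param path Path to the dosage TSV or `.ped` file.
#' @param dialect `"tsv_dosage"` or `"ped_map"`.
#' @param map For `"ped_map"`: path to the `.map` file (columns: chromosome,
#'   marker id, \[genetic position,\] base-pair position).
#' @param ped Optional `fam_pedigree`; if supplied, rows are checked and
#'   reordered to match the pedigree.
#' @return A tibble of class `famqls_geno`: columns `family_id`, `person_id`,
#'   then one numeric column per marker.
#' @export
read_genotypes <- function(path, dialect = c("tsv_dosage", "ped_map"),
                           map = NULL, ped = NULL) {
  dialect <- match.arg(dialect)
  g <- switch(dialect,
              tsv_dosage = read_tsv_dosage(path),
              ped_map = read_ped_map(path, map))
  if (!is.null(ped)) {
    if (nrow(g) != nrow(ped)) {
      abort_famqls(sprintf(
        "genotype rows (%d) do not match pedigree individuals (%d).",
        nrow(g), nrow(ped)), "famqls_alignment_error")
    }
    g <- align_to_keys(g, key_of(ped), "genotype table")
  }
  class(g) <- c("famqls_geno", class(tibble::tibble()))
  g
}

read_tsv_dosage <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA)
  if (!all(c("family_id", "person_id") %in% names(raw))) {
    abort_famqls("dosage TSV needs 'family_id' and 'person_id' columns.",
                 "famqls_parse_error")
  }
  g <- tibble::as_tibble(raw)
  g$family_id <- as.character(g$family_id)
  g$person_id <- as.character(g$person_id)
  for (col in value_cols(g)) {
    v <- as.numeric(g[[col]])
    ok <- is.na(v) | v %in% c(0, 0.5, 1, 2)
    if (!all(ok)) {
      abort_famqls(sprintf("marker %s has dosage values outside {0, 1, 2} / {0, 0.5, 1}.",
                           col), "famqls_parse_error")
    }
    # integer allele counts -> half-counts; half-count input passes through
    if (any(v > 1, na.rm = TRUE) || all(v %in% c(0, 1, 2, NA))) v <- v / 2
    g[[col]] <- v
  }
  g
}

read_ped_map <- function(path, map) {
  if (is.null(map)) {
    abort_famqls("dialect 'ped_map' requires the `map` file path.",
                 "famqls_argument_error")
  }
  mp <- utils::read.table(map, header = FALSE, colClasses = "character")
  marker_ids <- mp[[2L]]
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  n_allele_cols <- ncol(raw) - 6L
  if (n_allele_cols != 2L * length(marker_ids)) {
    abort_famqls(sprintf(
      ".ped has %d genotype columns but .map lists %d markers (need %d).",
      n_allele_cols, length(marker_ids), 2L * length(marker_ids)),
      "famqls_parse_error")
  }
  out <- tibble::tibble(family_id = raw[[1L]], person_id = raw[[2L]])
  for (j in seq_along(marker_ids)) {
    a1 <- raw[[6L + 2L * j - 1L]]
    a2 <- raw[[6L + 2L * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) > 2L) {
      abort_famqls(sprintf("marker %s has more than two alleles (%s).",
                           marker_ids[[j]], paste(alleles, collapse = ", ")),
                   "famqls_parse_error")
    }
    if (length(alleles) == 0L) {
      out[[marker_ids[[j]]]] <- rep(NA_real_, nrow(raw))
      next
    }
    counts <- vapply(alleles, function(a) sum(a1[!miss] == a) + sum(a2[!miss] == a),
                     numeric(1))
    # minor = least frequent observed allele; on an exact tie the
    # lexicographically later symbol is declared minor (deterministic)
    cand <- alleles[counts == min(counts)]
    minor <- cand[length(cand)]
    dosage <- ((a1 == minor) + (a2 == minor)) / 2
    dosage[miss] <- NA_real_
    out[[marker_ids[[j]]]] <- dosage
  }
  out
}

#' Write a dosage TSV
#'
#' Writes the wide half-count dosage table (genotypes or collapsed gene
#' indicators) in the `tsv_dosage` dialect that [read_genotypes()] consumes.
#'
#' @param g A `famqls_geno` (or collapsed-indicator) tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(g, path) {
  utils::write.table(as.data.frame(g), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a variant annotation table
#'
#' TSV with columns `marker_id`, `gene`, `chromosome`, `functional_class`
#' (`synonymous`, `nonsynonymous` or `unknown`) and `population_maf` in
#' \[0, 0.5\].
#'
#' @param path File path.
#' @return A tibble with the columns above.
#' @export
read_annotation <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  needed <- c("marker_id", "gene", "chromosome", "functional_class",
              "population_maf")
  if (!all(needed %in% names(raw))) {
    abort_famqls(sprintf("annotation TSV needs columns %s.",
                         paste(needed, collapse = ", ")),
                 "famqls_parse_error")
  }
  ann <- tibble::as_tibble(raw[, needed])
  ann$population_maf <- as.numeric(ann$population_maf)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  if (anyDuplicated(ann$marker_id)) {
    abort_famqls("annotation marker_id values must be unique.",
                 "famqls_validation_error")
  }
  bad <- !is.na(ann$population_maf) &
    (ann$population_maf < 0 | ann$population_maf > 0.5)
  if (any(bad)) {
    abort_famqls(sprintf("population_maf outside [0, 0.5] for marker %s.",
                         ann$marker_id[bad][[1L]]),
                 "famqls_validation_error")
  }
  ok_class <- c("synonymous", "nonsynonymous", "unknown")
  ann$functional_class[!ann$functional_class %in% ok_class] <- "unknown"
  ann
}

#' @rdname read_annotation
#' @param ann Annotation tibble.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write replicate affection-status tables
#'
#' Wide TSV: key columns `family_id`, `person_id`, then one 0/1 column per
#' phenotype replicate (1 = case). Replicate phenotype sets over fixed
#' genotypes are the package's unit of power estimation.
#'
#' @param path File path.
#' @return A tibble of class `famqls_pheno`.
#' @export
read_phenotypes <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!all(c("family_id", "person_id") %in% names(raw))) {
    abort_famqls("phenotype TSV needs 'family_id' and 'person_id' columns.",
                 "famqls_parse_error")
  }
  ph <- tibble::as_tibble(raw)
  ph$family_id <- as.character(ph$family_id)
  ph$person_id <- as.character(ph$person_id)
  for (col in value_cols(ph)) {
    v <- as.numeric(ph[[col]])
    if (!all(is.na(v) | v %in% c(0, 1))) {
      abort_famqls(sprintf("replicate column %s has non-binary entries.", col),
                   "famqls_parse_error")
    }
    ph[[col]] <- v
  }
  class(ph) <- c("famqls_pheno", class(tibble::tibble()))
  ph
}

#' @rdname read_phenotypes
#' @param pheno Phenotype replicate tibble.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Observed minor-allele frequency per marker
#'
#' Mean dosage (half-count) over the non-missing entries of the chosen subset
#' of individuals. Because dosage is (minor-allele count)/2, the mean dosage
#' *is* the sample allele frequency.
#'
#' @param g A `famqls_geno` tibble.
#' @param subset `"all"`, `"founders"` (requires `ped`), or a character vector
#'   of `"family:person"` keys.
#' @param ped A `fam_pedigree`, required for `subset = "founders"`.
#' @return A tibble `marker_id`, `maf`, `n_obs`. Markers with every entry
#'   missing in the subset get `maf = NA` and `n_obs = 0`.
#' @export
observed_maf <- function(g, subset = "all", ped = NULL) {
  keys <- key_of(g)
  idx <- if (identical(subset, "all")) {
    seq_len(nrow(g))
  } else if (identical(subset, "founders")) {
    if (is.null(ped)) {
      abort_famqls("subset = \"founders\" requires `ped`.", "famqls_argument_error")
    }
    which(keys %in% key_of(founders(ped)))
  } else {
    which(keys %in% subset)
  }
  if (length(idx) == 0L) {
    abort_famqls("empty individual subset.", "famqls_argument_error")
  }
  m <- as_unit_matrix(g)[idx, , drop = FALSE]
  n_obs <- colSums(!is.na(m))
  maf <- ifelse(n_obs > 0, colMeans(m, na.rm = TRUE), NA_real_)
  tibble::tibble(marker_id = colnames(m), maf = unname(maf),
                 n_obs = unname(n_obs))
}

#' Select rare markers
#'
#' Markers whose minor allele frequency is strictly below `threshold`
#' ("rare" defaults to MAF < 0.01 in the population). With
#' `source = "observed"` the frequency is estimated from pedigree founders
#' only: founders approximate a population sample, while offspring would
#' inflate the allele correlation.
#'
#' @param ann Annotation tibble (for `source = "population_maf"`).
#' @param threshold Strict upper bound, in (0, 0.5].
#' @param source `"population_maf"` or `"observed"`.
#' @param g,ped Genotypes and pedigree, required for `source = "observed"`.
#' @return Character vector of rare marker ids.
#' @export
rare_filter <- function(ann, threshold = 0.01,
                        source = c("population_maf", "observed"),
                        g = NULL, ped = NULL) {
  source <- match.arg(source)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 0.5) {
    abort_famqls("`threshold` must be in (0, 0.5].", "famqls_argument_error")
  }
  if (source == "population_maf") {
    if (nrow(ann) == 0L) return(character(0))
    ann$marker_id[!is.na(ann$population_maf) & ann$population_maf < threshold]
  } else {
    if (is.null(g) || is.null(ped)) {
      abort_famqls("source = \"observed\" requires `g` and `ped`.",
                   "famqls_argument_error")
    }
    om <- observed_maf(g, subset = "founders", ped = ped)
    om$marker_id[!is.na(om$maf) & om$maf < threshold]
  }
}
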