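#' Read a pedigree from a LINKAGE/PLINK text file
#'
#' Parses the whitespace-delimited pedigree portion shared by PLINK `.fam`
#' files and the leading six columns of LINKAGE/PLINK `.ped` files:
#' `FID IID PAT MAT SEX [PHENO ...]`. The phenotype column, if present, is
#' ignored here; affection status is loaded separately (see
#' [read_phenotypes()]) because the package works with replicate phenotype
#' sets over a fixed pedigree.
#'
#' @param path Path to the pedigree file.
#' @param dialect `"fam"` or `"ped"`. Both share the first five columns; for
#'   `"ped"` any genotype columns beyond the sixth are ignored.
#' @param missing_parent Code marking an absent parent (LINKAGE convention
#'   `"0"`).
#' @return A validated pedigree tibble of class `fam_pedigree` with columns
#'   `family_id`, `person_id`, `father_id`, `mother_id` (`NA` for founders)
#'   and `sex` (`"male"`, `"female"` or `"unknown"`), in file order.
#' @seealso [kinship_matrix()], [founders()]
#' @export
read_pedigree <- function(path, dialect = c("fam", "ped"), missing_parent = "0") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_famqls(sprintf("pedigree file not found: %s", path), "famqls_io_error")
  }
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           fill = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) < 5L) {
    abort_famqls("pedigree file needs at least 5 columns (FID IID PAT MAT SEX).",
                 "famqls_parse_error")
  }
  ped <- tibble::tibble(
    family_id = raw[[1L]],
    person_id = raw[[2L]],
    father_id = ifelse(raw[[3L]] == missing_parent, NA_character_, raw[[3L]]),
    mother_id = ifelse(raw[[4L]] == missing_parent, NA_character_, raw[[4L]]),
    sex = dplyr::case_match(raw[[5L]], "1" ~ "male", "2" ~ "female",
                            .default = "unknown")
  )
  as_pedigree(ped)
}

#' Construct / validate a pedigree tibble
#'
#' Validates pedigree structure and attaches the `fam_pedigree` class.
#' Rows may appear in any order (children before parents is fine): validation
#' and all downstream computations use an internally computed topological
#' order. Checks performed:
#' * `(family_id, person_id)` unique;
#' * both parents present or both absent (founder);
#' * every named parent exists in the same family;
#' * the parent graph is acyclic.
#'
#' @param ped A data frame with columns `family_id`, `person_id`, `father_id`,
#'   `mother_id` (use `NA` for missing parents) and optionally `sex`.
#' @return The pedigree as a `fam_pedigree` tibble, row order preserved.
#' @export
as_pedigree <- function(ped) {
  needed <- c("family_id", "person_id", "father_id", "mother_id")
  if (!all(needed %in% names(ped))) {
    abort_famqls(sprintf("pedigree must have columns %s.",
                         paste(needed, collapse = ", ")),
                 "famqls_parse_error")
  }
  ped <- tibble::as_tibble(ped)
  if (!"sex" %in% names(ped)) ped$sex <- "unknown"
  ped <- ped[, c(needed, "sex")]
  for (col in names(ped)) ped[[col]] <- as.character(ped[[col]])

  keys <- key_of(ped)
  dup <- duplicated(keys)
  if (any(dup)) {
    abort_famqls(sprintf("duplicate individual %s at line %d.",
                         keys[dup][[1L]], which(dup)[[1L]]),
                 "famqls_parse_error")
  }

  half <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(half)) {
    abort_famqls(sprintf(
      "individual %s has exactly one recorded parent; both or neither required.",
      keys[half][[1L]]), "famqls_validation_error")
  }

  nonf <- !is.na(ped$father_id)
  for (parent in c("father_id", "mother_id")) {
    pk <- ped_key(ped$family_id[nonf], ped[[parent]][nonf])
    bad <- !(pk %in% keys)
    if (any(bad)) {
      abort_famqls(sprintf("unknown parent %s for individual %s.",
                           ped[[parent]][nonf][bad][[1L]],
                           keys[nonf][bad][[1L]]),
                   "famqls_validation_error")
    }
  }

  topo_order(ped)  # errors on cycles
  class(ped) <- c("fam_pedigree", class(tibble::tibble()))
  ped
}

# Topological order of pedigree rows (parents before children), Kahn's
# algorithm on the parent graph. Errors if a cycle exists (someone their own
# ancestor).
topo_order <- function(ped) {
  keys <- key_of(ped)
  fa <- match(ifelse(is.na(ped$father_id), NA,
                     ped_key(ped$family_id, ped$father_id)), keys)
  mo <- match(ifelse(is.na(ped$mother_id), NA,
                     ped_key(ped$family_id, ped$mother_id)), keys)
  n <- nrow(ped)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    cyc <- keys[setdiff(seq_len(n), ord)]
    abort_famqls(sprintf("pedigree contains a cycle involving %s.", cyc[[1L]]),
                 "famqls_validation_error")
  }
  ord
}

#' Founders of a pedigree
#'
#' Individuals with no recorded parents, in pedigree order. Founders are
#' assumed drawn from the population: mutually unrelated and non-inbred.
#'
#' @param ped A `fam_pedigree` tibble.
#' @return The founder rows of `ped`.
#' @export
founders <- function(ped) {
  ped[is.na(ped$father_id) & is.na(ped$mother_id), , drop = FALSE]
}

#' Kinship matrix of a pedigree
#'
#' Computes the kinship matrix \eqn{\Phi} by the standard recursion, processed
#' in an order where parents precede children:
#' \deqn{\phi_{ij} = \tfrac12(\phi_{fj} + \phi_{mj}),\qquad
#'       \phi_{ii} = \tfrac12(1 + \phi_{fm})}
#' for an individual \eqn{i} with parents \eqn{f,m}; founders have
#' \eqn{\phi_{ii} = 1/2} and are mutually unrelated. The diagonal follows the
#' convention \eqn{\Phi_{ii} = (1 + h_i)/2} with \eqn{h_i} the inbreeding
#' coefficient (the kinship of \eqn{i}'s parents). Individuals in different
#' families have kinship exactly 0, so the matrix is block diagonal by family.
#'
#' Under this covariance convention, a dosage vector \eqn{Y} of minor-allele
#' half-counts has \eqn{\mathrm{Var}(Y) = p(1-p)\,\Phi} under the null, which
#' is the structure the score tests in [mqls_statistic()] rely on.
#'
#' @param ped A `fam_pedigree` tibble.
#' @return A dense symmetric matrix with rows/columns named
#'   `"<family_id>:<person_id>"` in pedigree order.
#' @export
kinship_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  keys <- key_of(ped)
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(keys, keys))
  if (n == 0L) return(K)
  for (fid in unique(ped$family_id)) {
    rows <- which(ped$family_id == fid)
    K[rows, rows] <- kinship_block(ped[rows, , drop = FALSE])
  }
  K
}

kinship_block <- function(fam) {
  m <- nrow(fam)
  ids <- fam$person_id
  fa <- match(fam$father_id, ids)
  mo <- match(fam$mother_id, ids)
  K <- matrix(0, m, m)
  done <- logical(m)
  for (i in topo_order(fam)) {
    if (is.na(fa[i])) {
      K[i, i] <- 0.5                       # founder: unrelated, non-inbred
    } else {
      f <- fa[i]; mm <- mo[i]
      prev <- which(done)
      if (length(prev)) {
        v <- 0.5 * (K[f, prev] + K[mm, prev])
        K[i, prev] <- v
        K[prev, i] <- v
      }
      K[i, i] <- 0.5 * (1 + K[f, mm])
    }
    done[i] <- TRUE
  }
  K
}

#' Inbreeding coefficients
#'
#' `h_i = 2 * Phi_ii - 1`, the kinship of the individual's parents.
#'
#' @param ped A `fam_pedigree` tibble.
#' @return A tibble with `family_id`, `person_id`, `inbreeding`.
#' @export
inbreeding <- function(ped) {
  K <- kinship_matrix(ped)
  tibble::tibble(family_id = ped$family_id, person_id = ped$person_id,
                 inbreeding = unname(2 * diag(K) - 1))
}

#' Write a pedigree as a PLINK .fam file
#'
#' @param ped A `fam_pedigree` tibble.
#' @param path Output path.
#' @param phenotype Optional numeric/character vector for the sixth column;
#'   defaults to `-9` (missing).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, phenotype = NULL) {
  sex_code <- dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2",
                                .default = "0")
  out <- data.frame(
    ped$family_id, ped$person_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex_code,
    if (is.null(phenotype)) rep("-9", nrow(ped)) else as.character(phenotype)
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}
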