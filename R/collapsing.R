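#' Gene indicator: collapse a gene's rare variants into one carrier variable
#'
#' Builds the dichotomous gene indicator \eqn{G}: for each individual,
#' \eqn{G = 1} if any rare variant in the gene is present (genotype AB or BB
#' at any member SNP), \eqn{G = 0} if every member SNP is homozygous for the
#' common allele. A homozygous-rare genotype does not count beyond presence —
#' with genuinely rare alleles it is vanishingly unlikely, and the indicator
#' is deliberately presence/absence only (no MAF or functional weighting).
#'
#' The indicator is also returned as `pseudo_dosage = indicator / 2`, i.e.
#' coded like a SNP with no homozygous-rare carriers, so collapsed genes flow
#' through [mqls_statistic()]/[wqls_statistic()] unchanged.
#'
#' Missing rule: an individual missing a genotype at any member marker is
#' `NA` unless a non-missing member genotype already forces carrier status.
#'
#' @param g A `famqls_geno` tibble.
#' @param ann Annotation tibble (see [read_annotation()]).
#' @param gene Gene name.
#' @param class_filter `"all"` or `"nonsynonymous_only"`.
#' @param rare_set Character vector of rare marker ids (from [rare_filter()]).
#' @return A tibble `family_id`, `person_id`, `indicator`, `pseudo_dosage`
#'   with attributes `gene` and `markers` (the member markers used).
#' @export
gene_indicator <- function(g, ann, gene,
                           class_filter = c("all", "nonsynonymous_only"),
                           rare_set) {
  class_filter <- match.arg(class_filter)
  members <- gene_members(ann, gene, class_filter, rare_set)
  if (length(members) == 0L) {
    abort_famqls(sprintf("gene %s has no qualifying rare marker.", gene),
                 "famqls_empty_gene")
  }
  missing_markers <- setdiff(members, value_cols(g))
  if (length(missing_markers)) {
    abort_famqls(sprintf("marker %s of gene %s absent from genotype table.",
                         missing_markers[[1L]], gene),
                 "famqls_alignment_error")
  }
  m <- as_unit_matrix(g[, c("family_id", "person_id", members)])
  carrier <- rowSums(m > 0, na.rm = TRUE) > 0
  any_na <- rowSums(is.na(m)) > 0
  ind <- unname(ifelse(carrier, 1, ifelse(any_na, NA_real_, 0)))
  out <- tibble::tibble(family_id = g$family_id, person_id = g$person_id,
                        indicator = ind, pseudo_dosage = ind / 2)
  attr(out, "gene") <- gene
  attr(out, "markers") <- members
  out
}

gene_members <- function(ann, gene, class_filter, rare_set) {
  keep <- ann$gene == gene & ann$marker_id %in% rare_set
  if (class_filter == "nonsynonymous_only") {
    keep <- keep & ann$functional_class == "nonsynonymous"
  }
  ann$marker_id[keep]
}

#' Collapse every gene with at least one qualifying rare variant
#'
#' Applies [gene_indicator()] across the annotation's genes and returns the
#' collapsed pseudo-dosages as a wide genotype-like tibble (one column per
#' gene, values 0 / 0.5 / `NA`), directly usable by [test_markers()] and
#' writable with [write_dosages()]. Genes whose indicator is monomorphic
#' among non-missing individuals are retained but flagged untestable.
#'
#' @inheritParams gene_indicator
#' @return A tibble of class `famqls_collapsed`: key columns plus one
#'   pseudo-dosage column per gene. The attribute `"genes"` holds a tibble
#'   `gene`, `n_markers`, `markers` (list-column), `testable`.
#' @export
collapse_all <- function(g, ann, class_filter = c("all", "nonsynonymous_only"),
                         rare_set) {
  class_filter <- match.arg(class_filter)
  genes <- unique(ann$gene)
  out <- tibble::tibble(family_id = g$family_id, person_id = g$person_id)
  info <- list()
  for (gn in genes) {
    members <- gene_members(ann, gn, class_filter, rare_set)
    if (length(members) == 0L) next
    gi <- gene_indicator(g, ann, gn, class_filter, rare_set)
    vals <- gi$pseudo_dosage[!is.na(gi$pseudo_dosage)]
    out[[gn]] <- gi$pseudo_dosage
    info[[length(info) + 1L]] <- tibble::tibble(
      gene = gn, n_markers = length(members), markers = list(members),
      testable = length(unique(vals)) > 1L)
  }
  attr(out, "genes") <- if (length(info)) dplyr::bind_rows(info) else
    tibble::tibble(gene = character(0), n_markers = integer(0),
                   markers = list(), testable = logical(0))
  class(out) <- c("famqls_collapsed", "famqls_geno", class(tibble::tibble()))
  out
}

#' Gene membership table of a collapsed set
#'
#' @param collapsed A `famqls_collapsed` tibble.
#' @return Tibble `gene`, `marker_id` (one row per member marker), as needed
#'   by [compare_collapsed_vs_single()].
#' @export
collapsed_members <- function(collapsed) {
  info <- attr(collapsed, "genes")
  tidyr::unnest(dplyr::select(info, "gene", marker_id = "markers"),
                "marker_id")
}
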