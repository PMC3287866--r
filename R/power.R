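#' Estimate power from replicate association results
#'
#' Power of a test for a unit (marker or collapsed gene) is the proportion of
#' phenotype replicates in which its p-value falls strictly below the
#' significance threshold. Replicates where the unit was untestable count as
#' non-hits (power is deflated, not inflated) and are reported in
#' `untestable_n` so they can be audited.
#'
#' @param results A `famqls_assoc` tibble with a `replicate` column (from
#'   [test_replicates()], or per-replicate results bound by hand).
#' @param threshold Significance level; hits are `p_value < threshold`.
#' @return A tibble of class `famqls_power`: `marker_id`, `test`,
#'   `threshold`, `n_replicates`, `n_hits`, `untestable_n`, `power`.
#' @export
estimate_power <- function(results, threshold = 0.05) {
  if (!"replicate" %in% names(results)) {
    abort_famqls("results need a `replicate` column; see test_replicates().",
                 "famqls_argument_error")
  }
  units_per_rep <- dplyr::summarise(
    dplyr::group_by(results, .data$replicate),
    key = paste(sort(.data$marker_id), collapse = "\r"), .groups = "drop")
  if (length(unique(units_per_rep$key)) > 1L) {
    abort_famqls("replicates tested different unit sets; cannot pool.",
                 "famqls_alignment_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(results, .data$marker_id, .data$test),
    n_replicates = dplyr::n(),
    n_hits = sum(!is.na(.data$p_value) & .data$p_value < threshold),
    untestable_n = sum(.data$status != "ok"),
    .groups = "drop")
  out$threshold <- threshold
  out$power <- out$n_hits / out$n_replicates
  out <- out[order(match(out$marker_id, unique(results$marker_id)), out$test),
             c("marker_id", "test", "threshold", "n_replicates", "n_hits",
               "untestable_n", "power")]
  class(out) <- c("famqls_power", class(tibble::tibble()))
  out
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`. The conventional stringent threshold for a mini-exome
#' of 3,205 genes at family-wise level 0.05 is `0.05 / 3205 = 1.56e-5`.
#'
#' @param alpha Family-wise significance level.
#' @param n_tests Number of tests (>= 1); the gene count is the usual
#'   denominator for gene-level collapsing.
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    abort_famqls("n_tests must be a count >= 1.", "famqls_argument_error")
  }
  alpha / n_tests
}

#' How many families carry each variant
#'
#' A family "carries" a marker iff any member has dosage > 0. The
#' accompanying histogram bins (0, 1, 2, 3+ carrier families) summarise how
#' concentrated rare variants are within families; with genuinely rare
#' variants most segregating markers sit in the 1-2 family bins, which is why
#' one or two families end up driving a combined association result.
#'
#' @param g `famqls_geno` tibble.
#' @param ped `fam_pedigree` (defines the family universe).
#' @param markers Marker ids to summarise (default: all columns of `g`).
#' @return A tibble of class `famqls_famdist`: `marker_id`,
#'   `n_carrier_families`, `carrier_family_ids` (list-column). The binned
#'   histogram is available via [carrier_family_bins()].
#' @export
family_distribution <- function(g, ped, markers = NULL) {
  markers <- markers %||% value_cols(g)
  fams <- lapply(markers, carrier_families, geno = g)
  out <- tibble::tibble(marker_id = markers,
                        n_carrier_families = lengths(fams),
                        carrier_family_ids = fams)
  class(out) <- c("famqls_famdist", class(tibble::tibble()))
  out
}

#' @rdname family_distribution
#' @param fd A `famqls_famdist` tibble.
#' @return For `carrier_family_bins()`: tibble `bin` (`"0"`, `"1"`, `"2"`,
#'   `"3+"`), `n_markers`.
#' @export
carrier_family_bins <- function(fd) {
  binned <- cut(fd$n_carrier_families, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
                labels = c("0", "1", "2", "3+"))
  counts <- as.integer(table(binned))
  tibble::tibble(bin = factor(c("0", "1", "2", "3+"),
                              levels = c("0", "1", "2", "3+")),
                 n_markers = counts)
}

#' Founder presence and transmission of each variant
#'
#' For each marker: is any founder a carrier, and, if so, did the variant
#' reach any non-founder? Many founder-carried rare variants are simply never
#' transmitted, which is a key reason family data sample fewer rare variants
#' than their founders own. A marker carried only by non-founders is flagged
#' `inconsistent` (impossible under gene-drop; in real data it signals a
#' Mendelian error or de novo variant) with a warning.
#'
#' @inheritParams family_distribution
#' @return A tibble: `marker_id`, `present_in_founders`, `transmitted`,
#'   `inconsistent`.
#' @export
founder_transmission <- function(g, ped, markers = NULL) {
  markers <- markers %||% value_cols(g)
  fk <- key_of(founders(ped))
  is_f <- key_of(g) %in% fk
  D <- as_unit_matrix(g[, c("family_id", "person_id", markers)])
  in_found <- colSums(D[is_f, , drop = FALSE] > 0, na.rm = TRUE) > 0
  in_nonf <- colSums(D[!is_f, , drop = FALSE] > 0, na.rm = TRUE) > 0
  inconsistent <- in_nonf & !in_found
  if (any(inconsistent)) {
    rlang::warn(sprintf(
      "%d marker(s) carried only by non-founders (Mendelian inconsistency or de novo), e.g. %s.",
      sum(inconsistent), markers[inconsistent][[1L]]))
  }
  tibble::tibble(marker_id = markers,
                 present_in_founders = unname(in_found),
                 transmitted = unname(in_found & in_nonf),
                 inconsistent = unname(inconsistent))
}

#' Collapsed vs best single-marker power per gene
#'
#' For each gene, compares the power of the collapsed gene indicator with the
#' best power attained by any of its member SNPs on the same replicates and
#' threshold. A positive `delta` means collapsing pooled signal (typically
#' different families carrying different causal variants of one gene); a
#' negative `delta` means collapsing buried a strong causal SNP among neutral
#' members.
#'
#' @param collapsed_power `famqls_power` table for collapsed genes.
#' @param single_power `famqls_power` table for single markers.
#' @param membership Tibble `gene`, `marker_id` mapping genes to member
#'   markers (see [collapsed_members()]).
#' @return A tibble: `gene`, `collapsed_power`, `best_single_marker_power`,
#'   `best_marker`, `delta`.
#' @export
compare_collapsed_vs_single <- function(collapsed_power, single_power,
                                        membership) {
  if (!isTRUE(all.equal(unique(collapsed_power$threshold),
                        unique(single_power$threshold)))) {
    abort_famqls("power tables were computed at different thresholds.",
                 "famqls_alignment_error")
  }
  genes <- collapsed_power$marker_id
  rows <- lapply(genes, function(gn) {
    members <- membership$marker_id[membership$gene == gn]
    sp <- single_power[single_power$marker_id %in% members, ]
    if (nrow(sp) == 0L) {
      abort_famqls(sprintf("gene %s has no member marker in the single-marker power table.",
                           gn), "famqls_alignment_error")
    }
    best <- which.max(sp$power)
    cp <- collapsed_power$power[collapsed_power$marker_id == gn]
    tibble::tibble(gene = gn, collapsed_power = cp,
                   best_single_marker_power = sp$power[[best]],
                   best_marker = sp$marker_id[[best]],
                   delta = cp - sp$power[[best]])
  })
  dplyr::bind_rows(rows)
}

#' Write a power table as TSV
#'
#' @param x A `famqls_power` (or comparison) tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_power <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
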