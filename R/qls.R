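#' Precomputed kinship factorization
#'
#' Cholesky-factors a kinship matrix once so that repeated score tests reuse
#' the factor (all solves go through `backsolve`; no explicit inverse is ever
#' formed). Positive definiteness of any valid pedigree's kinship matrix is
#' asserted by the factorization itself.
#'
#' @param phi Kinship matrix (see [kinship_matrix()]), or an object already
#'   returned by this function (returned unchanged).
#' @return An object of class `kinship_decomp`.
#' @export
kinship_decomp <- function(phi) {
  if (inherits(phi, "kinship_decomp")) return(phi)
  phi <- as.matrix(phi)
  R <- tryCatch(chol(phi), error = function(e) {
    abort_famqls(paste0("kinship matrix is not positive definite",
                        if (!is.null(rownames(phi)))
                          sprintf(" (block containing %s)", rownames(phi)[[1L]])
                        else "", "."),
                 "famqls_linalg_error")
  })
  a <- phi_solve_R(R, rep(1, nrow(phi)))          # Phi^{-1} 1
  structure(list(phi = phi, R = R, a = drop(a), s = sum(a),
                 keys = rownames(phi)),
            class = "kinship_decomp")
}

# Solve Phi x = b given the upper Cholesky factor R (Phi = R'R); b may be a
# matrix.
phi_solve_R <- function(R, b) {
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

phi_solve <- function(decomp, b) phi_solve_R(decomp$R, b)

# Subset a decomposition's kinship matrix and refactor.
decomp_subset <- function(decomp, idx) {
  kinship_decomp(decomp$phi[idx, idx, drop = FALSE])
}

#' Quasi-likelihood allele frequency estimate
#'
#' Best linear unbiased estimate of the allele frequency under the null given
#' the kinship covariance: \eqn{\hat p = (1'\Phi^{-1}Y)/(1'\Phi^{-1}1)},
#' computed via Cholesky solves. With unrelated individuals
#' (\eqn{\Phi \propto I}) this is the sample mean dosage. The estimate is
#' clamped to \[0, 1\] against floating-point drift.
#'
#' @param Y Complete numeric dosage vector (half-counts).
#' @param phi Kinship matrix or [kinship_decomp()] aligned to `Y`.
#' @return The scalar estimate.
#' @export
ql_allele_freq <- function(Y, phi) {
  d <- kinship_decomp(phi)
  if (length(Y) != nrow(d$phi)) {
    abort_famqls("length(Y) does not match the kinship matrix.",
                 "famqls_alignment_error")
  }
  min(1, max(0, sum(d$a * Y) / d$s))
}

# Tolerance below which var_U is treated as degenerate, relative to the
# binomial scale p(1-p).
VAR_TOL <- 1e-12

new_qls_fit <- function(test, n_used, ql_freq = NA_real_, score_U = NA_real_,
                        var_U = NA_real_, statistic = NA_real_,
                        p_value = NA_real_, status = "ok",
                        marker_id = NA_character_,
                        scope = "all_families") {
  structure(list(marker_id = marker_id, test = test, scope = scope,
                 n_used = n_used, ql_freq = ql_freq, score_U = score_U,
                 var_U = var_U, statistic = statistic, p_value = p_value,
                 status = status),
            class = "qls_fit")
}

#' @export
print.qls_fit <- function(x, ...) {
  cat(sprintf("%s score test (%s)\n", x$test, x$scope))
  cat(sprintf("  n = %d, p-hat = %s, status = %s\n", x$n_used,
              format(x$ql_freq, digits = 4), x$status))
  if (identical(x$status, "ok")) {
    cat(sprintf("  U = %.6g, Var(U) = %.6g, X1^2 = %.4f, p = %.4g\n",
                x$score_U, x$var_U, x$statistic, x$p_value))
  }
  invisible(x)
}

qls_core <- function(Y, Z, k, decomp, test) {
  n <- length(Y)
  phat <- min(1, max(0, sum(decomp$a * Y) / decomp$s))
  sig2 <- phat * (1 - phat)
  if (length(unique(Y)) < 2L || sig2 <= 0) {
    return(new_qls_fit(test, n, ql_freq = phat, status = "monomorphic"))
  }
  if (length(unique(Z)) < 2L) {
    return(new_qls_fit(test, n, ql_freq = phat,
                       status = "no_phenotype_contrast"))
  }
  if (test == "MQLS") {
    V <- Z - k
    U <- sum(V * (Y - phat))
    q <- sum(V * (decomp$phi %*% V)) - sum(V)^2 / decomp$s
  } else {
    b <- phi_solve(decomp, Z)
    U <- sum(b * Y) - sum(b) * phat          # Z' Phi^{-1} (Y - phat 1)
    q <- sum(Z * b) - sum(b)^2 / decomp$s
  }
  var_U <- sig2 * q
  if (!is.finite(var_U) || var_U < VAR_TOL * sig2) {
    return(new_qls_fit(test, n, ql_freq = phat, score_U = U, var_U = var_U,
                       status = "degenerate_variance"))
  }
  stat <- U^2 / var_U
  new_qls_fit(test, n, ql_freq = phat, score_U = U, var_U = var_U,
              statistic = stat,
              p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

check_YZ <- function(Y, Z, phi_n) {
  if (anyNA(Y) || anyNA(Z)) {
    abort_famqls("Y and Z must be complete; drop missing entries (and the matching kinship rows) upstream.",
                 "famqls_argument_error")
  }
  if (length(Y) != length(Z) || length(Y) != phi_n) {
    abort_famqls("Y, Z and the kinship matrix must be aligned.",
                 "famqls_alignment_error")
  }
  if (!all(Z %in% c(0, 1))) {
    abort_famqls("Z must be a 0/1 case indicator.", "famqls_argument_error")
  }
}

#' MQLS: prevalence-weighted quasi-likelihood score test
#'
#' Score test of association between a dosage vector and case status in
#' related individuals. With phenotype contrast \eqn{V = Z - k\,1} (cases
#' up-weighted by \eqn{1-k}, controls by \eqn{-k}, \eqn{k} the population
#' prevalence) and \eqn{\hat p} the quasi-likelihood allele frequency:
#' \deqn{U = V'(Y - \hat p 1), \quad
#'   \mathrm{Var}(U) = \hat p(1-\hat p)\left[V'\Phi V -
#'   (V'1)^2 / (1'\Phi^{-1}1)\right]}
#' and \eqn{U^2/\mathrm{Var}(U)} is referred to the upper tail of
#' \eqn{\chi^2_1}. For unrelated individuals with `k` equal to the sample
#' case fraction this is exactly the classical allelic chi-square test.
#'
#' @param Y Complete dosage vector (half-counts, or a collapsed gene's
#'   pseudo-dosage).
#' @param Z 0/1 case indicator, aligned to `Y`.
#' @param k Disease prevalence in (0, 1).
#' @param phi Kinship matrix or [kinship_decomp()] on the same individuals.
#' @return A `qls_fit` object; see [tidy.qls_fit()]. Monomorphic input, a
#'   constant phenotype, or a degenerate variance yield an untestable fit
#'   (status flag set, no p-value) rather than an error.
#' @seealso [wqls_statistic()], [test_markers()]
#' @export
mqls_statistic <- function(Y, Z, k, phi) {
  check_prevalence(k)
  d <- kinship_decomp(phi)
  check_YZ(Y, Z, nrow(d$phi))
  qls_core(Y, Z, k, d, "MQLS")
}

#' WQLS: quasi-likelihood score test of the mean model E\[Y\] = p1 + rZ
#'
#' The earlier quasi-likelihood score test: tests \eqn{r = 0} in the
#' generalized-least-squares mean model, reducing to
#' \deqn{U = Z'\Phi^{-1}(Y - \hat p 1), \quad
#'   \mathrm{Var}(U) = \hat p(1-\hat p)\left[Z'\Phi^{-1}Z -
#'   (Z'\Phi^{-1}1)^2/(1'\Phi^{-1}1)\right].}
#' Needs no prevalence. For unrelated samples it equals the classical allelic
#' chi-square.
#'
#' @inheritParams mqls_statistic
#' @return A `qls_fit` object.
#' @export
wqls_statistic <- function(Y, Z, phi) {
  d <- kinship_decomp(phi)
  check_YZ(Y, Z, nrow(d$phi))
  qls_core(Y, Z, k = NA_real_, d, "WQLS")
}

fit_to_row <- function(f) {
  tibble::tibble(marker_id = f$marker_id, test = f$test, scope = f$scope,
                 n_used = f$n_used, ql_freq = f$ql_freq, score_U = f$score_U,
                 var_U = f$var_U, statistic = f$statistic,
                 p_value = f$p_value, status = f$status)
}

resolve_Z <- function(pheno, replicate) {
  cols <- value_cols(pheno)
  if (is.numeric(replicate)) {
    if (replicate < 1 || replicate > length(cols)) {
      abort_famqls(sprintf("replicate index %s out of range (1..%d).",
                           replicate, length(cols)),
                   "famqls_argument_error")
    }
    cols[[replicate]]
  } else {
    if (!replicate %in% cols) {
      abort_famqls(sprintf("replicate column %s not found.", replicate),
                   "famqls_argument_error")
    }
    replicate
  }
}

#' Test every marker (or collapsed gene) in one phenotype replicate
#'
#' Runs [mqls_statistic()] or [wqls_statistic()] marker by marker. Individuals
#' with a missing phenotype in the chosen replicate are excluded from that
#' replicate's tests (their kinship rows dropped); individuals missing the
#' tested marker's genotype are dropped listwise for that marker, with a
#' warning naming how many. Untestable markers are flagged in `status`, never
#' silently dropped. An advisory is logged when fewer than 30 individuals
#' remain (the chi-square reference is asymptotic).
#'
#' @param g `famqls_geno` (or `famqls_collapsed`) tibble.
#' @param pheno `famqls_pheno` replicate table aligned to the same
#'   individuals.
#' @param replicate Replicate column index or name.
#' @param test `"MQLS"` or `"WQLS"`.
#' @param k Prevalence, required for MQLS.
#' @param phi Kinship matrix or decomposition whose rows are the keys of `g`.
#' @param scope Scope label stored on the results.
#' @return A tibble of class `famqls_assoc`, one row per marker: `marker_id`,
#'   `test`, `scope`, `n_used`, `ql_freq`, `score_U`, `var_U`, `statistic`,
#'   `p_value`, `status`.
#' @export
test_markers <- function(g, pheno, replicate = 1, test = c("MQLS", "WQLS"),
                         k = NULL, phi, scope = "all_families") {
  test <- match.arg(test)
  if (test == "MQLS") check_prevalence(k)
  d <- kinship_decomp(phi)
  keys <- key_of(g)
  if (!is.null(d$keys) && !identical(d$keys, keys)) {
    if (!all(keys %in% d$keys) || length(keys) != nrow(d$phi)) {
      abort_famqls("genotype rows and kinship matrix keys do not match.",
                   "famqls_alignment_error")
    }
    d <- decomp_subset(d, match(keys, d$keys))
  }
  ph <- align_to_keys(pheno, keys, "phenotype table")
  Z_full <- ph[[resolve_Z(ph, replicate)]]

  keep0 <- !is.na(Z_full)
  Ymat <- as_unit_matrix(g)
  results <- vector("list", ncol(Ymat))
  cache <- new.env(parent = emptyenv())
  n_listwise <- 0L
  for (j in seq_len(ncol(Ymat))) {
    y <- Ymat[, j]
    keep <- keep0 & !is.na(y)
    if (sum(keep) == 0L) {
      f <- new_qls_fit(test, 0L, status = "no_data")
    } else {
      if (any(keep0 & is.na(y))) n_listwise <- n_listwise + 1L
      key <- paste(which(keep), collapse = ",")
      dj <- if (all(keep)) d else {
        if (is.null(cache[[key]])) cache[[key]] <- decomp_subset(d, which(keep))
        cache[[key]]
      }
      f <- qls_core(y[keep], Z_full[keep], k %||% NA_real_, dj, test)
    }
    f$marker_id <- colnames(Ymat)[[j]]
    f$scope <- scope
    results[[j]] <- fit_to_row(f)
  }
  if (n_listwise > 0L) {
    rlang::warn(sprintf(
      "%d marker(s) had missing genotypes; affected individuals dropped listwise per marker.",
      n_listwise))
  }
  n_used <- sum(keep0)
  if (n_used > 0L && n_used < 30L) {
    rlang::inform(sprintf(
      "only %d individuals analysed; the chi-square reference is asymptotic.",
      n_used))
  }
  out <- dplyr::bind_rows(results)
  class(out) <- c("famqls_assoc", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-family association tests
#'
#' Restricts [test_markers()] to each family's members in turn (using that
#' family's kinship block) so single-family signals can be compared with the
#' all-family analysis. Families lacking case-control contrast, or markers
#' monomorphic within a family, come back flagged untestable.
#'
#' @inheritParams test_markers
#' @param ped The `fam_pedigree` defining family membership.
#' @param phi Optional precomputed kinship matrix for the whole pedigree.
#' @return A `famqls_assoc` tibble with `scope` set to the family id, rows in
#'   family order.
#' @export
per_family_tests <- function(g, pheno, replicate = 1, test = c("MQLS", "WQLS"),
                             k = NULL, ped, phi = NULL) {
  test <- match.arg(test)
  if (is.null(phi)) phi <- kinship_matrix(ped)
  d <- kinship_decomp(phi)
  keys <- key_of(g)
  out <- list()
  for (fid in unique(ped$family_id)) {
    fam_keys <- key_of(ped[ped$family_id == fid, ])
    idx <- which(keys %in% fam_keys)
    sub_g <- g[idx, , drop = FALSE]
    sub_d <- decomp_subset(d, match(key_of(sub_g), d$keys))
    out[[fid]] <- test_markers(sub_g, pheno, replicate, test, k, sub_d,
                               scope = fid)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("famqls_assoc", class(tibble::tibble()))
  res
}

#' Test all markers across all phenotype replicates
#'
#' The power-estimation workhorse: applies the chosen score test to every
#' marker in every replicate. When genotypes and phenotypes are complete the
#' computation is fully vectorised (one kinship factorization, BLAS-level
#' cross-products over the replicate and marker matrices); otherwise it falls
#' back to per-replicate [test_markers()] calls.
#'
#' @inheritParams test_markers
#' @param replicates Integer indices of replicate columns (default: all).
#' @return A `famqls_assoc` tibble with an extra leading `replicate` column.
#' @seealso [estimate_power()]
#' @export
test_replicates <- function(g, pheno, test = c("MQLS", "WQLS"), k = NULL,
                            phi, replicates = NULL) {
  test <- match.arg(test)
  if (test == "MQLS") check_prevalence(k)
  d <- kinship_decomp(phi)
  keys <- key_of(g)
  ph <- align_to_keys(pheno, keys, "phenotype table")
  rep_cols <- value_cols(ph)
  if (!is.null(replicates)) rep_cols <- rep_cols[replicates]
  Ymat <- as_unit_matrix(g)
  Zmat <- as_unit_matrix(ph[, c("family_id", "person_id", rep_cols)])

  if (anyNA(Ymat) || anyNA(Zmat)) {
    out <- lapply(seq_along(rep_cols), function(r) {
      res <- suppressWarnings(
        test_markers(g, ph, rep_cols[[r]], test, k, d))
      res$replicate <- r
      res
    })
    res <- dplyr::bind_rows(out)[, c("replicate", "marker_id", "test", "scope",
                                     "n_used", "ql_freq", "score_U", "var_U",
                                     "statistic", "p_value", "status")]
    class(res) <- c("famqls_assoc", class(tibble::tibble()))
    return(res)
  }

  n <- nrow(Ymat); J <- ncol(Ymat); R <- ncol(Zmat)
  phat <- pmin(1, pmax(0, drop(crossprod(d$a, Ymat)) / d$s))
  sig2 <- phat * (1 - phat)
  mono <- apply(Ymat, 2, function(y) length(unique(y)) < 2L) | sig2 <= 0
  z_const <- apply(Zmat, 2, function(z) length(unique(z)) < 2L)

  if (test == "MQLS") {
    Vmat <- Zmat - k
    Umat <- crossprod(Vmat, Ymat) - outer(colSums(Vmat), phat)   # R x J
    qr_ <- colSums(Vmat * (d$phi %*% Vmat)) - colSums(Vmat)^2 / d$s
  } else {
    B <- phi_solve(d, Zmat)
    Umat <- crossprod(B, Ymat) - outer(colSums(B), phat)
    qr_ <- colSums(Zmat * B) - colSums(B)^2 / d$s
  }
  var_mat <- outer(qr_, sig2)                                    # R x J
  stat <- Umat^2 / var_mat
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  status <- matrix("ok", R, J)
  status[, mono] <- "monomorphic"
  status[z_const, ] <- "no_phenotype_contrast"
  degen <- sweep(var_mat, 2, VAR_TOL * sig2, `<`) & status == "ok"
  status[degen] <- "degenerate_variance"
  bad <- status != "ok"
  stat[bad] <- NA_real_; pval[bad] <- NA_real_

  res <- tibble::tibble(
    replicate = rep(seq_len(R), times = J),
    marker_id = rep(colnames(Ymat), each = R),
    test = test, scope = "all_families", n_used = n,
    ql_freq = rep(phat, each = R),
    score_U = as.vector(Umat), var_U = as.vector(var_mat),
    statistic = as.vector(stat), p_value = as.vector(pval),
    status = as.vector(status))
  class(res) <- c("famqls_assoc", class(tibble::tibble()))
  res
}

#' Write association results as TSV
#'
#' @param res A `famqls_assoc` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(res, path) {
  utils::write.table(as.data.frame(res), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
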