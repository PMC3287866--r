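#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single score-test fit
#'
#' @param x A `qls_fit` from [mqls_statistic()] or [wqls_statistic()].
#' @param ... Unused.
#' @return A one-row tibble: `term`, `estimate` (the score U), `statistic`,
#'   `p.value`, `status`.
#' @method tidy qls_fit
#' @export
tidy.qls_fit <- function(x, ...) {
  tibble::tibble(term = x$marker_id %||% NA_character_,
                 estimate = x$score_U, statistic = x$statistic,
                 p.value = x$p_value, status = x$status)
}

#' Model-level summary of a score-test fit
#'
#' @param x A `qls_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `test`, `scope`, `n_used`, `ql_freq`, `var_U`.
#' @method glance qls_fit
#' @export
glance.qls_fit <- function(x, ...) {
  tibble::tibble(test = x$test, scope = x$scope, n_used = x$n_used,
                 ql_freq = x$ql_freq, var_U = x$var_U)
}
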