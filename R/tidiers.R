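#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ANOVA fit
#'
#' @param x An `anova_fit`.
#' @param ... Unused.
#' @return The effect table as a tibble: `term, sumsq, df, meansq,
#'   statistic, p.value`.
#' @method tidy anova_fit
#' @export
tidy.anova_fit <- function(x, ...) {
  tibble::as_tibble(x$table)
}

#' One-row summary of an ANOVA fit
#'
#' @param x An `anova_fit`.
#' @param ... Unused.
#' @return A tibble: `n`, `ss_total`, `type`, `degenerate`,
#'   `n_comparisons`, `n_rejected`.
#' @method glance anova_fit
#' @export
glance.anova_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    ss_total = sum(x$table$sumsq),
    type = x$type,
    degenerate = x$degenerate,
    n_comparisons = if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
    n_rejected = if (is.null(x$comparisons)) 0L else sum(x$comparisons$reject))
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("<anova_fit> %s sums of squares, n = %d%s\n", x$type, x$n,
              if (x$degenerate) " [degenerate: zero error variance]" else ""))
  print(tibble::as_tibble(x$table))
  if (!is.null(x$comparisons)) {
    cat(sprintf("Holm-Sidak pairwise comparisons (alpha = %g):\n", x$alpha))
    print(x$comparisons)
  }
  invisible(x)
}

#' Tidy a ddCt result
#'
#' @param x A `ddct_result`.
#' @param ... Unused.
#' @return The per-sample table as a plain tibble.
#' @method tidy ddct_result
#' @export
tidy.ddct_result <- function(x, ...) {
  tibble::as_tibble(x)
}
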