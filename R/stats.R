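#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak procedure: sort the m raw p-values ascending; the i-th
#' sorted value is adjusted to `1 - (1 - p_(i))^(m - i + 1)`; monotone
#' nondecrease is enforced by a running maximum; results are returned in
#' input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise error rate for the rejection flags.
#' @return A tibble `p, p_adj, reject` in the input order.
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    abort("all p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  tibble::tibble(p = p, p_adj = out, reject = out <= alpha)
}

# classical (balanced) two-way fixed-effects SS partition
classical_two_way <- function(y, a, b) {
  grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  na <- tapply(y, a, length); nb <- tapply(y, b, length)
  nab <- tapply(y, list(a, b), length)
  ss_a <- sum(na * (ma - grand)^2)
  ss_b <- sum(nb * (mb - grand)^2)
  cell_of <- mab[cbind(as.character(a), as.character(b))]
  ss_err <- sum((y - cell_of)^2)
  ss_tot <- sum((y - grand)^2)
  ss_ab <- ss_tot - ss_a - ss_b - ss_err
  df_a <- length(ma) - 1; df_b <- length(mb) - 1
  df_ab <- df_a * df_b
  df_err <- length(y) - length(ma) * length(mb)
  tibble::tibble(term = c("A", "B", "A:B", "Residuals"),
                 sumsq = c(ss_a, ss_b, ss_ab, ss_err),
                 df = c(df_a, df_b, df_ab, df_err))
}

anova_f_p <- function(tab) {
  res <- tab[tab$term == "Residuals", ]
  eff <- tab[tab$term != "Residuals", ]
  ms_err <- res$sumsq / res$df
  tab$meansq <- tab$sumsq / tab$df
  if (ms_err <= 1e-12 * max(sum(tab$sumsq), 1)) {
    # zero-variance cells: F undefined, p = 1, flagged
    tab$statistic <- NA_real_
    tab$p.value <- ifelse(tab$term == "Residuals", NA_real_, 1)
    attr(tab, "degenerate") <- TRUE
    return(tab)
  }
  tab$statistic <- ifelse(tab$term == "Residuals", NA_real_,
                          tab$meansq / ms_err)
  tab$p.value <- ifelse(tab$term == "Residuals", NA_real_,
                        pf(tab$meansq / ms_err, tab$df, res$df,
                           lower.tail = FALSE))
  attr(tab, "degenerate") <- FALSE
  tab
}

posthoc_pairwise <- function(y, g, ms_err, df_err, alpha, pooled = TRUE) {
  lv <- levels(g)
  means <- tapply(y, g, mean); ns <- tapply(y, g, length)
  vars <- tapply(y, g, var)
  prs <- utils::combn(lv, 2, simplify = FALSE)
  cmp <- purrr::map_dfr(prs, function(pr) {
    m1 <- means[[pr[1]]]; m2 <- means[[pr[2]]]
    n1 <- ns[[pr[1]]]; n2 <- ns[[pr[2]]]
    if (pooled) {
      se <- sqrt(ms_err * (1 / n1 + 1 / n2))
      df <- df_err
    } else {
      v1 <- vars[[pr[1]]] / n1; v2 <- vars[[pr[2]]] / n2
      se <- sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    }
    stat <- if (se > 0) (m1 - m2) / se else NA_real_
    pv <- if (is.na(stat)) 1 else 2 * pt(abs(stat), df, lower.tail = FALSE)
    tibble::tibble(group1 = pr[1], group2 = pr[2], estimate = m1 - m2,
                   statistic = stat, df = df, p.value = pv)
  })
  hs <- holm_sidak(cmp$p.value, alpha = alpha)
  cmp$p.adj <- hs$p_adj
  cmp$reject <- hs$reject
  cmp
}

#' Two-way fixed-effects ANOVA with Holm-Sidak post hoc comparisons
#'
#' Balanced designs use the classical sum-of-squares partition; unbalanced
#' designs use Type-II sums of squares (via [car::Anova()]). Post hoc
#' comparisons are all pairwise cell-mean contrasts using the pooled error
#' mean square (or Welch-unpooled), with Holm-Sidak step-down adjustment.
#' Cells with zero error variance yield an undefined F reported with
#' `p = 1` and a `degenerate` flag rather than an error.
#'
#' @param data A data frame in long format.
#' @param value,factor_a,factor_b Column names (strings or bare names via
#'   tidy evaluation) of the response and the two crossed factors.
#' @param comparisons Compute the Holm-Sidak pairwise family (default TRUE).
#' @param pooled Use the pooled error MS for post hoc SEs; `FALSE` gives
#'   Welch-unpooled comparisons.
#' @param alpha Family-wise error rate.
#' @return An `anova_fit` object: list with `table` (term, sumsq, df,
#'   meansq, statistic, p.value), `comparisons`, `means` (per-cell mean,
#'   SEM, n), `type` ("classical" or "II") and `degenerate`.
#' @export
two_way_anova <- function(data, value = "value", factor_a = "factor_a",
                          factor_b = "factor_b", comparisons = TRUE,
                          pooled = TRUE, alpha = 0.05) {
  value <- rlang::as_name(rlang::ensym(value))
  factor_a <- rlang::as_name(rlang::ensym(factor_a))
  factor_b <- rlang::as_name(rlang::ensym(factor_b))
  y <- data[[value]]
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  if (any(!is.finite(y))) abort("response values must be finite")
  counts <- table(a, b)
  if (any(counts == 0)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    abort(paste("empty factor combinations:",
                paste(rownames(counts)[miss[, 1]], colnames(counts)[miss[, 2]],
                      sep = ":", collapse = ", ")))
  }
  if (any(counts < 2)) abort("each factor combination needs >= 2 units")
  balanced <- length(unique(as.vector(counts))) == 1
  if (balanced) {
    tab <- classical_two_way(y, a, b)
    type <- "classical"
  } else {
    fit <- lm(y ~ a * b)
    ca <- car::Anova(fit, type = 2)
    tab <- tibble::tibble(
      term = c("A", "B", "A:B", "Residuals"),
      sumsq = ca[c("a", "b", "a:b", "Residuals"), "Sum Sq"],
      df = ca[c("a", "b", "a:b", "Residuals"), "Df"])
    type <- "II"
  }
  tab <- anova_f_p(tab)
  tab$term <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b),
                "Residuals")
  res <- tab[tab$df > 0 & seq_len(nrow(tab)) == nrow(tab), ]
  ms_err <- tab$sumsq[nrow(tab)] / tab$df[nrow(tab)]
  g <- factor(paste(a, b, sep = ":"))
  cmp <- if (comparisons)
    posthoc_pairwise(y, g, ms_err, tab$df[nrow(tab)], alpha, pooled = pooled)
  else NULL
  means <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(g = g, y = y), .data$g),
    mean = mean(.data$y), n = dplyr::n(),
    sem = if (dplyr::n() > 1) sd(.data$y) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop")
  structure(list(table = tab, comparisons = cmp, means = means,
                 type = type, degenerate = isTRUE(attr(tab, "degenerate")),
                 n = length(y), alpha = alpha,
                 factors = c(factor_a, factor_b)),
            class = "anova_fit")
}

#' One-way fixed-effects ANOVA with Holm-Sidak post hoc comparisons
#'
#' @param data A data frame in long format.
#' @param value,group Column names of the response and the grouping factor.
#' @inheritParams two_way_anova
#' @return An `anova_fit` (terms: group, Residuals).
#' @export
one_way_anova <- function(data, value = "value", group = "group",
                          comparisons = TRUE, pooled = TRUE, alpha = 0.05) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  y <- data[[value]]
  g <- factor(data[[group]])
  if (any(!is.finite(y))) abort("response values must be finite")
  if (any(table(g) < 2)) abort("each group needs >= 2 units")
  grand <- mean(y)
  mg <- tapply(y, g, mean); ng <- tapply(y, g, length)
  ss_g <- sum(ng * (mg - grand)^2)
  ss_err <- sum((y - mg[as.character(g)])^2)
  tab <- tibble::tibble(term = c(group, "Residuals"),
                        sumsq = c(ss_g, ss_err),
                        df = c(length(mg) - 1, length(y) - length(mg)))
  tab <- anova_f_p(tab)
  ms_err <- tab$sumsq[2] / tab$df[2]
  cmp <- if (comparisons)
    posthoc_pairwise(y, g, ms_err, tab$df[2], alpha, pooled = pooled)
  else NULL
  means <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(g = g, y = y), .data$g),
    mean = mean(.data$y), n = dplyr::n(),
    sem = if (dplyr::n() > 1) sd(.data$y) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop")
  structure(list(table = tab, comparisons = cmp, means = means,
                 type = "classical",
                 degenerate = isTRUE(attr(tab, "degenerate")),
                 n = length(y), alpha = alpha, factors = group),
            class = "anova_fit")
}

#' Unpaired two-tailed Student's t-test between two groups
#'
#' Thin wrapper over [stats::t.test()] with pooled variance (classical
#' Student's test) returning a tidy one-row tibble.
#'
#' @param data A data frame.
#' @param value,group Column names; `group` must have exactly two levels.
#' @param var_equal Pooled-variance Student's test (default) or Welch.
#' @return A tibble `estimate, statistic, df, p.value, group1, group2`.
#' @export
t_test_groups <- function(data, value = "value", group = "group",
                          var_equal = TRUE) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("group must have exactly two levels")
  y <- data[[value]]
  ht <- stats::t.test(y[g == levels(g)[1]], y[g == levels(g)[2]],
                      var.equal = var_equal)
  tibble::tibble(estimate = unname(ht$estimate[1] - ht$estimate[2]),
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value,
                 group1 = levels(g)[1], group2 = levels(g)[2])
}

#' Per-group mean, SEM and n
#'
#' @param data A data frame.
#' @param value Response column name.
#' @param ... Grouping columns (tidy evaluation).
#' @return A tibble with one row per group: `mean`, `sem` (`NA` for a
#'   single observation), `n`.
#' @export
summarize_groups <- function(data, value = "value", ...) {
  value <- rlang::as_name(rlang::ensym(value))
  dplyr::summarise(
    dplyr::group_by(data, ...),
    mean = mean(.data[[value]]),
    sem = if (dplyr::n() > 1) sd(.data[[value]]) / sqrt(dplyr::n()) else NA_real_,
    n = dplyr::n(),
    .groups = "drop")
}

#' Relative gene expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per sample and gene; each sample's dCt
#' is `Ct(target) - Ct(reference)`; ddCt subtracts the calibrator group's
#' mean dCt; fold change is `2^-ddCt`. The calibrator group's geometric
#' mean fold change is 1 by construction.
#'
#' @param ct_table Tibble `sample, group, gene, ct`.
#' @param target_gene,reference_gene Gene labels in `ct_table`.
#' @param calibrator_group Group whose mean dCt anchors the fold change.
#' @return A `ddct_result` tibble: `sample, group, dct, ddct, fold`.
#' @export
ddct <- function(ct_table, target_gene, reference_gene, calibrator_group) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct_table)))
  avg <- dplyr::summarise(
    dplyr::group_by(ct_table, .data$sample, .data$group, .data$gene),
    ct = mean(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(avg, names_from = "gene", values_from = "ct")
  for (gn in c(target_gene, reference_gene)) {
    if (!gn %in% names(wide) || any(is.na(wide[[gn]]))) {
      miss <- if (gn %in% names(wide))
        wide$sample[is.na(wide[[gn]])] else unique(wide$sample)
      abort(paste0("missing Ct for gene '", gn, "' in sample(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  if (!calibrator_group %in% wide$group)
    abort(paste0("calibrator group '", calibrator_group, "' not present"))
  wide$dct <- wide[[target_gene]] - wide[[reference_gene]]
  cal_mean <- mean(wide$dct[wide$group == calibrator_group])
  wide$ddct <- wide$dct - cal_mean
  wide$fold <- 2^(-wide$ddct)
  out <- wide[c("sample", "group", "dct", "ddct", "fold")]
  tibble::new_tibble(out, class = "ddct_result")
}
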