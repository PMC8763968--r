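#' Group comparison tests
#'
#' The between-genotype tests used on the vesicle panels: Pearson chi-square
#' on a 2x2 detectable-vesicles table, the two-sample Kolmogorov-Smirnov
#' test on per-cell densities, and Student's t test. Each returns a uniform
#' one-row `group_comparison` data.frame.
#'
#' @name group_tests
NULL

group_comparison <- function(test_name, statistic, p_value, n_per_group,
                             effect_summary) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(data.frame(test_name = test_name, statistic = statistic,
                       p_value = p_value,
                       n1 = n_per_group[1], n2 = n_per_group[2],
                       effect_summary = effect_summary,
                       stringsAsFactors = FALSE),
            class = c("group_comparison", "data.frame"))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Chi-square test of homogeneity of two proportions, without continuity
#' correction by default (df = 1, upper-tail p).
#'
#' @param table 2x2 matrix of counts, groups in rows.
#' @param correct apply the Yates continuity correction.
#' @return A `group_comparison` row; proportions of the second column per
#'   group in `effect_summary`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi_square_2x2: both margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  props <- table[, 2] / rowSums(table)
  group_comparison("chi_square", unname(ht$statistic), ht$p.value,
                   rowSums(table),
                   sprintf("proportions %.3f vs %.3f", props[1], props[2]))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum ECDF difference. The p-value is exact (enumeration) for
#' small samples (nx * ny below `exact_limit`, no ties), otherwise from the
#' asymptotic Kolmogorov distribution with effective n = nx*ny/(nx+ny).
#'
#' @param x,y numeric samples.
#' @param exact_limit use the exact distribution when `nx * ny <
#'   exact_limit` (default 1e4).
#' @return A `group_comparison` row; means +/- SEM in `effect_summary`.
#' @export
ks_two_sample <- function(x, y, exact_limit = 1e4) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- length(x) * length(y) < exact_limit
  ht <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  group_comparison("ks_two_sample", unname(ht$statistic), ht$p.value,
                   c(length(x), length(y)),
                   sprintf("mean %.3f +/- %.3f vs %.3f +/- %.3f",
                           mean(x), stats::sd(x) / sqrt(length(x)),
                           mean(y), stats::sd(y) / sqrt(length(y))))
}

#' Student's t test between two groups
#'
#' @param x,y numeric samples.
#' @param paired paired or unpaired test.
#' @param var.equal assume equal variances (classical Student test).
#' @return A `group_comparison` row.
#' @export
t_test_groups <- function(x, y, paired = FALSE, var.equal = TRUE) {
  ht <- stats::t.test(x, y, paired = paired, var.equal = var.equal)
  group_comparison(if (paired) "t_test_paired" else "t_test",
                   unname(ht$statistic), ht$p.value,
                   c(length(x), length(y)),
                   sprintf("mean %.3f +/- %.3f vs %.3f +/- %.3f",
                           mean(x), stats::sd(x) / sqrt(length(x)),
                           mean(y), stats::sd(y) / sqrt(length(y))))
}
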