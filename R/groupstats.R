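# Group statistics used for the assay readouts: Kruskal-Wallis with tie
# correction, Dunn's multiple-comparison post hoc, Welch's one-way ANOVA, and
# mean +/- s.e.m. The omnibus tests delegate to the base-R implementations
# (kruskal.test, oneway.test); Dunn's z statistics are computed from pooled
# midranks here, since base R has no Dunn test.

.as_groups <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (!is.list(groups) || length(groups) < 2)
    stop_gd("need a list of at least 2 groups", class = "groovedock_value_error")
  if (any(vapply(groups, length, 0L) == 0))
    stop_gd("empty group", class = "groovedock_value_error")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

.test_result <- function(statistic, df, p, method, pairwise = NULL) {
  p <- max(p, .Machine$double.xmin)   # never report p = 0
  structure(list(statistic = statistic, df = df, p = p, method = method,
                 pairwise = pairwise), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4f, df %s, p %.4g\n",
              x$method, x$statistic, paste(signif(x$df, 4), collapse = "/"), x$p))
  if (!is.null(x$pairwise)) { cat("pairwise:\n"); print(x$pairwise) }
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Midrank-based H with tie correction
#' `H' = H / (1 - sum(t^3 - t) / (N^3 - N))`, with p from the chi-square
#' distribution on k - 1 degrees of freedom (as computed by
#' [stats::kruskal.test()]). When all observations are identical the statistic
#' is 0 and p is 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3), or a
#'   data.frame with `value` and `group` columns.
#' @return a `test_result`.
#' @export
kruskal_wallis <- function(groups) {
  g <- .as_groups(groups)
  x <- unlist(g, use.names = FALSE)
  if (length(x) < 3)
    stop_gd("need total n >= 3", class = "groovedock_value_error")
  if (length(unique(x)) == 1)
    return(.test_result(0, length(g) - 1, 1, "Kruskal-Wallis"))
  kt <- stats::kruskal.test(g)
  .test_result(unname(kt$statistic), unname(kt$parameter), kt$p.value,
               "Kruskal-Wallis")
}

#' Dunn's multiple-comparison post hoc test
#'
#' For each pair of groups, the Dunn z statistic from pooled midranks with tie
#' correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t)` over tie groups; two-sided p from the normal
#' distribution, adjusted across all k(k-1)/2 pairs.
#'
#' @param groups list of numeric vectors or a data.frame (see
#'   [kruskal_wallis()]).
#' @param adjust multiplicity adjustment: "bonferroni" (default), "holm" or
#'   "none".
#' @return data.frame with columns group_i, group_j, z, p_raw, p_adjusted,
#'   plus the adjustment recorded as an attribute.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  g <- .as_groups(groups)
  x <- unlist(g, use.names = FALSE)
  n <- vapply(g, length, 0L)
  N <- length(x)
  r <- rank(x)                       # midranks
  idx <- rep(seq_along(g), n)
  rbar <- vapply(seq_along(g), function(i) mean(r[idx == i]), 0)
  ties <- table(x)
  Tt <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - Tt / (12 * (N - 1))
  pairs <- utils::combn(seq_along(g), 2)
  z <- apply(pairs, 2, function(ij) {
    (rbar[ij[1]] - rbar[ij[2]]) /
      sqrt(s2 * (1 / n[ij[1]] + 1 / n[ij[2]]))
  })
  z[!is.finite(z)] <- 0              # all-tied data: zero variance => z = 0
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = if (adjust == "none") "none" else adjust)
  out <- data.frame(group_i = names(g)[pairs[1, ]], group_j = names(g)[pairs[2, ]],
                    z = z, p_raw = p_raw, p_adjusted = p_adj,
                    stringsAsFactors = FALSE)
  attr(out, "adjust") <- adjust
  out
}

#' Welch's one-way ANOVA
#'
#' Heteroscedasticity-robust one-way ANOVA (Welch F with Welch-Satterthwaite
#' degrees of freedom), as computed by [stats::oneway.test()] with
#' `var.equal = FALSE`.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2 with
#'   non-zero variance) or a data.frame (see [kruskal_wallis()]).
#' @return a `test_result` with `df = c(df1, df2)`.
#' @export
welch_anova <- function(groups) {
  g <- .as_groups(groups)
  if (any(vapply(g, length, 0L) < 2))
    stop_gd("every group needs n >= 2", class = "groovedock_value_error")
  if (any(vapply(g, stats::var, 0) == 0))
    stop_gd("zero-variance group", class = "groovedock_value_error")
  d <- data.frame(value = unlist(g, use.names = FALSE),
                  group = factor(rep(names(g), vapply(g, length, 0L))))
  ow <- stats::oneway.test(value ~ group, data = d, var.equal = FALSE)
  .test_result(unname(ow$statistic), unname(ow$parameter), ow$p.value,
               "Welch one-way ANOVA")
}

#' Mean and standard error of the mean
#'
#' `sem = sd / sqrt(n)` with the n-1 denominator; by convention `sem = 0` for
#' a single observation (noted via message).
#'
#' @param values numeric vector, n >= 1.
#' @return named vector c(mean, sem, n).
#' @export
mean_sem <- function(values) {
  if (length(values) == 0)
    stop_gd("empty value vector", class = "groovedock_value_error")
  n <- length(values)
  if (n == 1) {
    message("mean_sem: single observation; sem set to 0 by convention")
    return(c(mean = values[[1]], sem = 0, n = 1))
  }
  c(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}
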