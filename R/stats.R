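#' Two-sample Student's t test (pooled variance, two-tailed)
#'
#' The "regular" two-tailed Student's t test with pooled variance and exact
#' degrees of freedom `nA + nB - 2`, as used for unnormalized two-group
#' comparisons.
#'
#' @param group_a,group_b numeric samples (each at least 2 finite values).
#' @param labels group labels for reporting.
#' @return A `test_result`: list with `test`, `statistic`, `df`, `p_value`,
#'   `groups`, `estimate` (difference in means A - B).
#' @export
two_sample_t <- function(group_a, group_b, labels = c("A", "B")) {
  check_sample(group_a, 2L, labels[1])
  check_sample(group_b, 2L, labels[2])
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  new_test_result(
    test = "two-sample Student's t (pooled variance, two-tailed)",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, groups = labels,
    estimate = mean(group_a) - mean(group_b))
}

#' One-sample t test against a reference value
#'
#' Used when data are normalized to the control condition (presented as a
#' fraction or percentage of control): values are tested two-tailed against
#' the reference (default 1). A zero-variance sample whose mean differs from
#' the reference yields an infinite statistic, flagged with the p value
#' reported at the machine floor.
#'
#' @param values numeric sample (at least 2 values).
#' @param reference reference value (default 1, the normalized control).
#' @return A `test_result` with additional field `infinite_statistic`.
#' @export
one_sample_t <- function(values, reference = 1) {
  check_sample(values, 2L, "values")
  if (stats::sd(values) == 0) {
    if (mean(values) == reference) {
      return(new_test_result(test = "one-sample t (two-tailed)",
                             statistic = 0, df = length(values) - 1,
                             p_value = 1, groups = "values",
                             estimate = mean(values) - reference,
                             infinite_statistic = FALSE))
    }
    return(new_test_result(test = "one-sample t (two-tailed)",
                           statistic = sign(mean(values) - reference) * Inf,
                           df = length(values) - 1,
                           p_value = .Machine$double.xmin, groups = "values",
                           estimate = mean(values) - reference,
                           infinite_statistic = TRUE))
  }
  ht <- stats::t.test(values, mu = reference)
  new_test_result(test = "one-sample t (two-tailed)",
                  statistic = unname(ht$statistic),
                  df = unname(ht$parameter), p_value = ht$p.value,
                  groups = "values", estimate = mean(values) - reference,
                  infinite_statistic = FALSE)
}

#' One-way ANOVA with Tukey's multiple comparison test
#'
#' The one-way F test over three or more groups followed by Tukey HSD
#' adjusted pairwise comparisons (studentized-range distribution). With
#' fewer than three groups the caller is directed to [two_sample_t()].
#'
#' @param groups named list of numeric samples (>= 3 groups, each >= 2
#'   values).
#' @return A `test_result` with fields `statistic` (F), `df` (numerator,
#'   denominator), `p_value`, and `tukey` (data frame `pair`, `diff`,
#'   `p_adj`).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 3L) {
    stop("anova_tukey needs at least 3 groups; use two_sample_t() for 2")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  for (nm in names(groups)) check_sample(groups[[nm]], 2L, nm)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  new_test_result(
    test = "one-way ANOVA + Tukey HSD",
    statistic = an[["F value"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    p_value = an[["Pr(>F)"]][1], groups = names(groups),
    estimate = NA_real_,
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL))
}

new_test_result <- function(...) {
  structure(list(...), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}

#' Collect test results into a tidy table
#'
#' @param ... `test_result` objects (optionally named).
#' @return Data frame with `comparison`, `test`, `statistic`, `df`,
#'   `p_value`, `significant` (at the conventional p < 0.05 criterion).
#' @export
tidy_results <- function(...) {
  res <- list(...)
  nms <- names(res)
  if (is.null(nms)) nms <- rep("", length(res))
  rows <- lapply(seq_along(res), function(i) {
    x <- res[[i]]
    data.frame(comparison = if (nzchar(nms[i])) nms[i] else
                 paste(x$groups, collapse = " vs "),
               test = x$test, statistic = x$statistic,
               df = paste(x$df, collapse = ","), p_value = x$p_value,
               significant = x$p_value < 0.05)
  })
  do.call(rbind, rows)
}

check_sample <- function(v, n_min, label) {
  if (length(v) < n_min || any(!is.finite(v))) {
    stop("group '", label, "' needs at least ", n_min, " finite values")
  }
  invisible(TRUE)
}
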