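#' Modified Thompson tau outlier rejection
#'
#' Iteratively removes at most one point per pass: with `n` current values,
#' the rejection threshold is `tau * s` where `s` is the sample standard
#' deviation and
#' `tau = t * (n - 1) / (sqrt(n) * sqrt(n - 2 + t^2))`,
#' with `t` the two-sided Student quantile at `alpha / 2` on `n - 2`
#' degrees of freedom. The point with the largest absolute deviation from
#' the mean is removed if its deviation strictly exceeds `tau * s`;
#' the rule is re-applied to the reduced sample until nothing is removed or
#' fewer than three values remain.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level of the rejection rule (default 0.05).
#' @return An object of class `outlier_report`: list with `kept`,
#'   `removed` (in removal order), and `alpha`.
#' @export
thompson_tau_outliers <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` must not contain NA")
  if (length(values) < 3L)
    stop("modified Thompson tau requires at least 3 values")
  kept <- values
  removed <- numeric(0)
  repeat {
    n <- length(kept)
    if (n < 3L) break
    s <- sd(kept)
    if (s == 0) break
    tq <- qt(1 - alpha / 2, df = n - 2)
    tau <- tq * (n - 1) / (sqrt(n) * sqrt(n - 2 + tq^2))
    dev <- abs(kept - mean(kept))
    i <- which.max(dev)
    if (dev[i] > tau * s) {
      removed <- c(removed, kept[i])
      kept <- kept[-i]
    } else break
  }
  structure(list(kept = kept, removed = removed, alpha = alpha),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> alpha = %g: %d kept, %d removed",
              x$alpha, length(x$kept), length(x$removed)))
  if (length(x$removed) > 0)
    cat(" (", paste(signif(x$removed, 4), collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Two-sample Student t-test (pooled variance)
#'
#' Pooled-variance Student's t, the convention used for the group
#' comparisons throughout this assay family. One-tailed tests require the
#' caller to state the hypothesized direction. Degenerate zero-variance
#' samples are handled as limits: equal means give p = 1, unequal means
#' give p = 0 (with a warning).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param tail `"two"` (default) or `"one"`.
#' @param direction for one-tailed tests: `"greater"` tests the alternative
#'   mean(a) > mean(b); `"less"` the converse.
#' @return An object of class `nmj_ttest`: list with `statistic`,
#'   `df`, `p_value`, `tail`, `direction`, `method`.
#' @export
t_test_groups <- function(a, b, tail = c("two", "one"),
                          direction = c("greater", "less")) {
  tail <- match.arg(tail)
  direction <- match.arg(direction)
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 non-missing values")
  df <- length(a) + length(b) - 2
  res <- if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      list(statistic = 0, p_value = 1)
    } else {
      warning("zero variance with unequal means: p = 0 limit case")
      list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0)
    }
  } else {
    alt <- if (tail == "two") "two.sided" else direction
    tt <- t.test(a, b, var.equal = TRUE, alternative = alt)
    list(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  if (tail == "one" && is.finite(res$statistic) && res$p_value %in% c(0, 1) &&
      res$statistic == 0) res$p_value <- 0.5
  structure(list(statistic = res$statistic, df = df, p_value = res$p_value,
                 tail = tail,
                 direction = if (tail == "one") direction else NA_character_,
                 method = "Student two-sample t-test, pooled variance"),
            class = "nmj_ttest")
}

#' @export
print.nmj_ttest <- function(x, ...) {
  cat(sprintf("<nmj_ttest> %s\n  t = %.4g, df = %d, %s-tailed%s p = %.4g\n",
              x$method, x$statistic, x$df, x$tail,
              if (!is.na(x$direction)) paste0(" (", x$direction, ")") else "",
              x$p_value))
  invisible(x)
}

#' Per-group summary and pairwise t-tests with optional outlier rejection
#'
#' Applies modified Thompson tau rejection independently within each group
#' (the convention for the imaging metrics, where per-group n after
#' rejection is reported), then computes group means, standard errors, and
#' pairwise pooled t-tests.
#'
#' @param values numeric metric values.
#' @param groups group labels, same length as `values`.
#' @param tail,direction passed to [t_test_groups()].
#' @param reject_outliers apply Thompson tau per group first (default TRUE).
#' @param alpha significance level for the rejection rule.
#' @param pairs optional 2-column character matrix of group pairs to test;
#'   default: all unordered pairs.
#' @return A list of class `group_comparison`: `summary` (group, n_before,
#'   n_after, mean, se), `tests` (group_a, group_b, statistic, df, p_value;
#'   `NA` for pairs where a group has fewer than 2 values), `tail`,
#'   `outlier_rejection`, `alpha`.
#' @export
compare_groups <- function(values, groups, tail = "two",
                           direction = "greater", reject_outliers = TRUE,
                           alpha = 0.05, pairs = NULL) {
  keep <- !is.na(values)
  values <- as.numeric(values)[keep]; groups <- as.character(groups)[keep]
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least two groups")
  vals <- lapply(gl, function(g) values[groups == g])
  names(vals) <- gl
  n_before <- vapply(vals, length, integer(1))
  if (reject_outliers)
    vals <- lapply(vals, function(v)
      if (length(v) >= 3) thompson_tau_outliers(v, alpha)$kept else v)
  summ <- do.call(rbind, lapply(gl, function(g) {
    v <- vals[[g]]
    data.frame(group = g, n_before = n_before[[g]], n_after = length(v),
               mean = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }))
  rownames(summ) <- NULL
  if (is.null(pairs)) {
    cmb <- utils::combn(gl, 2)
    pairs <- t(cmb)
  }
  tests <- do.call(rbind, apply(pairs, 1, function(p) {
    if (length(vals[[p[1]]]) < 2 || length(vals[[p[2]]]) < 2)
      return(data.frame(group_a = p[1], group_b = p[2],
                        statistic = NA_real_, df = NA_integer_,
                        p_value = NA_real_))
    tt <- t_test_groups(vals[[p[1]]], vals[[p[2]]], tail = tail,
                        direction = direction)
    data.frame(group_a = p[1], group_b = p[2], statistic = tt$statistic,
               df = tt$df, p_value = tt$p_value)
  }))
  rownames(tests) <- NULL
  structure(list(summary = summ, tests = tests, tail = tail,
                 outlier_rejection = reject_outliers, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("<group_comparison> %s-tailed, outlier rejection %s (alpha = %g)\n",
              x$tail, if (x$outlier_rejection) "on" else "off", x$alpha))
  print.data.frame(x$summary, digits = digits, row.names = FALSE)
  cat("pairwise tests:\n")
  print.data.frame(x$tests, digits = digits, row.names = FALSE)
  invisible(x)
}
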