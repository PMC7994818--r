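# Correlation layer: Pearson/Spearman coefficients, permutation-based
# false-discovery-rate testing, binned scatter summaries, LOESS trends and
# group comparisons.

#' Correlation coefficient
#'
#' Product-moment (Pearson) correlation, or the same applied to average
#' ranks (Spearman). Thin wrapper over [stats::cor()] with the input
#' checking the rest of the package relies on.
#'
#' @param x,y Paired numeric samples of equal length, n >= 3, finite.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  stats::cor(x, y, method = method)
}

check_paired <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  invisible(NULL)
}

#' Permutation false-discovery-rate test of a correlation
#'
#' Significance of a correlation by randomisation: one variable is permuted
#' \code{n_iterations} times and the FDR is the fraction of permutations
#' whose coefficient is at least as good as the observed one (two-sided
#' default: \code{|r_perm| >= |r_obs|}; one-sided option: exceedance in the
#' direction of the observed sign). The observed statistic is included in
#' numerator and denominator (+1/+1), so the FDR is never exactly zero.
#' A correlation is flagged significant when FDR < 0.05.
#'
#' @inheritParams correlation
#' @param n_iterations Number of permutations (>= 100; the canonical run
#'   uses 1e5).
#' @param seed Integer seed; results are reproducible.
#' @param sided \code{"two"} or \code{"one"}.
#' @return List of class \code{"correlation_result"}: \code{coefficient},
#'   \code{method}, \code{n}, \code{fdr}, \code{n_iterations},
#'   \code{sided}, \code{significant}, \code{seed}.
#' @export
permutation_fdr <- function(x, y, method = c("pearson", "spearman"),
                            n_iterations = 100000L, seed = 1L,
                            sided = c("two", "one")) {
  method <- match.arg(method)
  sided <- match.arg(sided)
  check_paired(x, y)
  if (n_iterations < 100)
    stop("n_iterations < 100 gives an unstable FDR estimate", call. = FALSE)
  n_iterations <- as.integer(n_iterations)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  r_obs <- sum(xs * ys) / (n - 1)
  r_perm <- with_rng(seed,
    vapply(seq_len(n_iterations),
           function(i) sum(xs * ys[sample.int(n)]), numeric(1)) / (n - 1))
  better <- if (sided == "two") {
    abs(r_perm) >= abs(r_obs)
  } else if (r_obs >= 0) {
    r_perm >= r_obs
  } else {
    r_perm <= r_obs
  }
  fdr <- (1 + sum(better)) / (1 + n_iterations)
  structure(list(coefficient = r_obs, method = method, n = n, fdr = fdr,
                 n_iterations = n_iterations, sided = sided,
                 significant = fdr < 0.05, seed = as.integer(seed)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s r = %.4f (n = %d), FDR = %.4g (%s-sided, %d perms)%s\n",
              x$method, x$coefficient, x$n, x$fdr, x$sided, x$n_iterations,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Binned scatter summary
#'
#' Bins x into half-open intervals \code{[k w, (k+1) w)} of fixed width
#' \code{w}, anchored at \code{floor(min(x)/w) * w}, and summarises y per
#' bin by its mean and standard error. Empty bins are omitted. This is the
#' construction behind binned scatter plots of deformation indices and
#' strain against Lamin levels (conventional widths: 0.07 for D_cell, 0.06
#' for D_nuc, 0.01 for strain).
#'
#' @inheritParams correlation
#' @param bin_width Bin width on the x axis, > 0.
#' @return Tibble of class \code{"binned_scatter"}: \code{bin_center},
#'   \code{mean_x}, \code{mean_y}, \code{sem_y}, \code{count}; attribute
#'   \code{bin_width}.
#' @export
binned_scatter <- function(x, y, bin_width) {
  check_paired(x, y)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  k <- floor(x / bin_width)
  bins <- sort(unique(k))
  f <- factor(k, levels = bins)
  cnt <- as.integer(table(f))
  mean_x <- as.numeric(tapply(x, f, mean))
  mean_y <- as.numeric(tapply(y, f, mean))
  sd_y <- as.numeric(tapply(y, f, stats::sd))
  sem <- ifelse(cnt > 1, sd_y / sqrt(cnt), 0)
  out <- tibble::tibble(bin_center = (bins + 0.5) * bin_width,
                        mean_x = mean_x, mean_y = mean_y,
                        sem_y = sem, count = cnt)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("binned_scatter", class(out))
  out
}

#' LOESS trend line
#'
#' Locally weighted linear regression (tricube weights, degree 1) evaluated
#' on an even grid across the x range; the trend line drawn through
#' scatter plots.
#'
#' @inheritParams correlation
#' @param span Smoothing span in (0, 1].
#' @param n_grid Number of evaluation points.
#' @return Tibble with columns \code{x} and \code{fit}.
#' @export
loess_trend <- function(x, y, span = 0.75, n_grid = 100L) {
  check_paired(x, y)
  if (length(x) < 10) stop("need n >= 10 for a LOESS trend", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (span * length(x) < 4)
    stop("span too small: local neighbourhoods have fewer than 4 points",
         call. = FALSE)
  fit <- stats::loess(y ~ x, data = data.frame(x = x, y = y),
                      span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = as.integer(n_grid))
  tibble::tibble(x = grid,
                 fit = as.numeric(stats::predict(fit,
                                                 newdata = data.frame(x = grid))))
}

#' Group comparison
#'
#' Two-sided Student's t-test for exactly two groups, or one-way ANOVA for
#' two or more.
#'
#' @param values Numeric response.
#' @param labels Group labels (coerced to factor).
#' @param test \code{"t_test_two_sided"} or \code{"anova_one_way"}.
#' @return List: \code{p_value}, \code{statistic} (t or F), \code{test}.
#' @export
group_compare <- function(values, labels,
                          test = c("t_test_two_sided", "anova_one_way")) {
  test <- match.arg(test)
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  if (test == "t_test_two_sided") {
    if (nlevels(labels) != 2)
      stop("t-test requires exactly 2 groups; use anova_one_way",
           call. = FALSE)
    ht <- stats::t.test(values ~ labels, var.equal = TRUE)
    list(p_value = ht$p.value, statistic = unname(ht$statistic), test = test)
  } else {
    fit <- stats::aov(values ~ labels)
    s <- summary(fit)[[1]]
    list(p_value = s[["Pr(>F)"]][1], statistic = s[["F value"]][1],
         test = test)
  }
}

#' Normalize intensities to a reference group
#'
#' Divides every value by the mean of the reference group, so the reference
#' mean maps to 1. Used to express Lamin levels relative to a reference
#' tissue region.
#'
#' @param values Numeric intensities.
#' @param group_labels Group label per value.
#' @param reference_label Label of the reference group.
#' @return Numeric vector of normalized values.
#' @export
normalize_to_reference <- function(values, group_labels, reference_label) {
  if (length(values) != length(group_labels))
    stop("values and group_labels must have equal length", call. = FALSE)
  ref <- values[group_labels == reference_label]
  if (length(ref) == 0)
    stop(sprintf("reference group '%s' is empty or missing", reference_label),
         call. = FALSE)
  values / mean(ref)
}
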