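#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the data against a normal distribution with the
#' sample's own mean and standard deviation (plug-in parameters; p-values
#' are therefore approximate, as is conventional when the reference
#' parameters are estimated).
#'
#' @param sample numeric vector, n >= 5.
#' @return A `somnirl_test` result: `statistic`, `p_value`, `n1`, `method`.
#' @export
ks_normality <- function(sample) {
  n <- length(sample)
  if (n < 5) stop("KS normality check requires n >= 5")
  if (stats::sd(sample) == 0)
    stop("zero-variance sample: normality test undefined")
  res <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean(sample), stats::sd(sample)))
  test_result(unname(res$statistic), res$p.value, n1 = n, n2 = NA_integer_,
              method = "one-sample Kolmogorov-Smirnov (estimated parameters)")
}

test_result <- function(statistic, p_value, n1, n2, method,
                        effect_size_eta2 = NULL, z = NULL) {
  structure(list(statistic = statistic, p_value = p_value, n1 = n1, n2 = n2,
                 method = method, effect_size_eta2 = effect_size_eta2,
                 z = z),
            class = "somnirl_test")
}

#' @export
print.somnirl_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (!is.null(x$effect_size_eta2))
    cat(sprintf(", eta^2 = %.3f", x$effect_size_eta2))
  cat("\n")
  invisible(x)
}

# Midranks of the pooled sample.
midranks <- function(x) rank(x, ties.method = "average")

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison with midrank tie handling. For small
#' samples (`n1 + n2 <= exact_threshold`) the p-value is computed by exact
#' enumeration of all group assignments of the pooled ranks; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The eta-squared effect size z^2/N is attached (z from the normal
#' approximation).
#'
#' @param a,b numeric samples.
#' @param exact_threshold switch point for exact enumeration (default 20).
#' @return A `somnirl_test` with `statistic` = U (for sample `a`),
#'   `p_value`, `n1`, `n2`, `effect_size_eta2`, `z`.
#' @export
mann_whitney_u <- function(a, b, exact_threshold = 20L) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- midranks(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  # normal approximation pieces (also used for the effect size)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  z <- if (sigma > 0) (u - mu - sign(u - mu) * 0.5) / sigma else 0
  if (sigma > 0 && abs(u - mu) <= 0.5) z <- 0
  if (n <= exact_threshold) {
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(u_all <= u), mean(u_all >= u))
    p <- min(1, p)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    p <- if (sigma > 0) 2 * stats::pnorm(-abs(z)) else 1
    p <- min(1, p)
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  test_result(u, p, n1, n2, method,
              effect_size_eta2 = eta_squared(z, n), z = z)
}

#' Eta-squared effect size from a z statistic
#'
#' The conventional rank-test effect size `z^2 / n_total`, clipped to
#' [0, 1].
#'
#' @param z standardized test statistic.
#' @param n_total total sample size (>= 2).
#' @return Scalar in [0, 1].
#' @export
eta_squared <- function(z, n_total) {
  if (n_total < 2) stop("n_total must be >= 2")
  min(1, z^2 / n_total)
}

#' Significance mask with optional Bonferroni correction
#'
#' @param p_values numeric (possibly named) vector of p-values in [0, 1].
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` or `"bonferroni"` (threshold `alpha / m`).
#' @return Logical vector: `p < threshold`, names preserved.
#' @export
significance_mask <- function(p_values, alpha = 0.05,
                              correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  threshold <- if (correction == "bonferroni")
    alpha / length(p_values) else alpha
  stats::setNames(p_values < threshold, names(p_values))
}
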