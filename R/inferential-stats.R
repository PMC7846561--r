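# Nonparametric test battery: one-sample Wilcoxon signed rank against a
# theoretical median, Mann-Whitney, two-sample Kolmogorov-Smirnov,
# Kruskal-Wallis with Dunn's post hoc, Bonferroni correction, and the
# D'Agostino-Pearson omnibus normality test.

.testResult <- function(statistic, p, n, method, correction = "none",
                        note = NULL) {
  structure(list(statistic = unname(statistic),
                 p_value = min(1, unname(p)),
                 n = n, method = method, correction = correction,
                 note = note),
            class = "SynGoldTest")
}

#' @export
print.SynGoldTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = ", "),
              if (x$correction != "none")
                paste0(", ", x$correction, "-corrected") else ""))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether values are symmetric about `mu0` — the workhorse for
#' asking whether normalized particle locations are biased toward the
#' centre or edge relative to the theoretical median of 0.5 expected
#' under a uniform surface distribution. Values exactly equal to `mu0`
#' are dropped (Wilcoxon's convention). The null distribution is exact
#' for n <= 25 without ties; otherwise a normal approximation with
#' continuity and tie correction is used.
#'
#' @param x numeric sample.
#' @param mu0 hypothesized median (default 0.5).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return a `SynGoldTest` list: `statistic` (V), `p_value`, `n`
#'   (after dropping ties with `mu0`), `method`.
#' @examples
#' wilcoxonOneSample(c(0.6, 0.7, 0.8))   # V = 6, exact p = 0.25
#' @export
wilcoxonOneSample <- function(x, mu0 = 0.5, alternative = "two.sided") {
  x <- x[is.finite(x)]
  nz <- x[x != mu0]
  if (!length(nz))
    return(.testResult(0, 1, 0L, "Wilcoxon signed rank",
                       note = "all values equal mu0; p = 1 by convention"))
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz - mu0))
  ht <- suppressWarnings(stats::wilcox.test(nz, mu = mu0,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  .testResult(ht$statistic, ht$p.value, length(nz),
              "Wilcoxon signed rank")
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test; exact when the smaller sample has at
#' most 8 observations and there are no ties, otherwise a normal
#' approximation with continuity and tie correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return a `SynGoldTest` with the U statistic and p-value.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(x, y, alternative = "two.sided") {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  exact <- min(length(x), length(y)) <= 8L && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  .testResult(ht$statistic, ht$p.value, c(length(x), length(y)),
              "Mann-Whitney U")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF1 - ECDF2|` with the asymptotic Kolmogorov p-value, as
#' used for comparing cumulative distance distributions between
#' conditions.
#'
#' @param x,y numeric samples.
#' @return a `SynGoldTest` with D and the asymptotic p-value.
#' @export
ksTwoSample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  .testResult(ht$statistic, ht$p.value, c(length(x), length(y)),
              "Kolmogorov-Smirnov D")
}

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' Kruskal-Wallis H (tie-corrected) across three or more groups,
#' followed by Dunn's pairwise z-statistics on the pooled ranks with
#' Bonferroni-scaled p-values.
#'
#' @param groups named list of numeric vectors (>= 3 groups).
#' @param adjust `"bonferroni"` (default) or `"none"` for the pairwise
#'   p-values.
#' @return list with `omnibus` (a `SynGoldTest` for H) and `pairwise`
#'   (data.frame: `group1`, `group2`, `z`, `p_value`, `p_adjusted`).
#' @export
kruskalDunn <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 3L)
    stop("need >= 3 groups; use mannWhitney() for two")
  if (any(!lengths(groups))) stop("all groups must be nonempty")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  omnibus <- .testResult(kw$statistic, kw$p.value, lengths(groups),
                         "Kruskal-Wallis H")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = a, group2 = b, z = z, p_value = p,
               p_adjusted = if (adjust == "bonferroni") min(1, m * p)
               else p,
               stringsAsFactors = FALSE)
  }))
  rownames(pw) <- NULL
  list(omnibus = omnibus, pairwise = pw)
}

#' Bonferroni correction
#'
#' @param pvals numeric p-values.
#' @param m number of comparisons; defaults to `length(pvals)` and must
#'   be at least that.
#' @return `pmin(1, m * pvals)`, order preserved.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (m < length(pvals)) stop("m must be >= length(pvals)")
  pmin(1, m * pvals)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the z-transforms of sample skewness (D'Agostino) and
#' kurtosis (Anscombe-Glynn) into `K^2 = z_s^2 + z_k^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom. Requires n >= 20,
#' below which the approximations are invalid.
#'
#' @param x numeric sample (n >= 20, non-constant).
#' @return a `SynGoldTest` with K^2 and the chi-squared p-value.
#' @export
dagostinoPearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20L) stop("dagostinoPearson requires n >= 20")
  if (stats::sd(x) == 0) stop("constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  zk <- ((1 - 2 / (9 * A)) -
         ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- zs^2 + zk^2
  .testResult(K2, stats::pchisq(K2, df = 2, lower.tail = FALSE), n,
              "D'Agostino-Pearson omnibus K^2")
}

#' Results table for a battery of tests
#'
#' @param tests named list of `SynGoldTest` objects (names become the
#'   `comparison` column).
#' @return data.frame mirroring a summary-statistics table: `comparison`,
#'   `n`, `statistic`, `p`, `p_corrected` (Bonferroni over the listed
#'   tests).
#' @export
testBatteryTable <- function(tests) {
  m <- length(tests)
  out <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(comparison = nm, n = paste(t$n, collapse = "/"),
               statistic = t$statistic, p = t$p_value,
               p_corrected = min(1, m * t$p_value),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
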