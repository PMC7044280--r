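# Inferential comparison of fused vs unfused mesh-weighted stress values:
# Shapiro-Wilk normality screening and Welch two-sample t-tests.

#' Shapiro-Wilk normality test (Royston approximation)
#'
#' Computes the W statistic from the Royston (1995) polynomial
#' approximation to the normal order-statistic weights, valid for
#' 3 <= n <= 5000, with the matching normalising transformations for the
#' one-sided p-value (small W indicates departure from normality).
#'
#' @param sample Numeric sample, 3 to 5000 values, non-constant.
#' @return List with `W`, `p`, and `n`.
#' @export
shapiro_wilk <- function(sample) {
  x <- sort(as.numeric(sample))
  n <- length(x)
  if (n < 3 || n > 5000) stop("sample size must be between 3 and 5000")
  if (x[n] - x[1] == 0) stop("W is undefined for a constant sample")

  if (n == 3) {
    a <- c(-sqrt(0.5), 0, sqrt(0.5))
  } else {
    m <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
    ssq <- sum(m^2)
    u <- 1 / sqrt(n)
    an <- m[n] / sqrt(ssq) + 0.221157 * u - 0.147981 * u^2 -
      2.071190 * u^3 + 4.434685 * u^4 - 2.706056 * u^5
    if (n > 5) {
      an1 <- m[n - 1] / sqrt(ssq) + 0.042981 * u - 0.293762 * u^2 -
        1.752461 * u^3 + 5.682633 * u^4 - 3.582633 * u^5
      phi <- (ssq - 2 * m[n]^2 - 2 * m[n - 1]^2) /
        (1 - 2 * an^2 - 2 * an1^2)
      a <- m / sqrt(phi)
      a[n] <- an; a[1] <- -an
      a[n - 1] <- an1; a[2] <- -an1
    } else {
      phi <- (ssq - 2 * m[n]^2) / (1 - 2 * an^2)
      a <- m / sqrt(phi)
      a[n] <- an; a[1] <- -an
    }
  }
  W <- sum(a * x)^2 / sum((x - mean(x))^2)
  W <- min(W, 1)

  if (n == 3) {
    p <- 6 / pi * (asin(sqrt(W)) - asin(sqrt(0.75)))
    p <- min(max(p, 0), 1)
  } else if (n <= 11) {
    gma <- -2.273 + 0.459 * n
    w1 <- -log(gma - log1p(-W))
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    p <- stats::pnorm((w1 - mu) / sig, lower.tail = FALSE)
  } else {
    ln <- log(n)
    w1 <- log1p(-W)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sig <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    p <- stats::pnorm((w1 - mu) / sig, lower.tail = FALSE)
  }
  list(W = W, p = p, n = n)
}

#' Welch's two-sample t-test
#'
#' Location test not assuming equal variances:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value from the t distribution.
#'
#' @param sample1,sample2 Numeric samples with at least 2 values each and
#'   at least one nonzero variance.
#' @return List with `t`, `df`, `p`, group means and sizes.
#' @export
welch_t <- function(sample1, sample2) {
  x <- as.numeric(sample1); y <- as.numeric(sample2)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) stop("both samples are constant; t is undefined")
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean1 = m1, mean2 = m2, n1 = n1, n2 = n2)
}

#' Compare fused and unfused mesh-weighted stress per bone
#'
#' The study's central contrast: for one bone and load angle, pools the
#' per-species MWAM values of both variants for a Shapiro-Wilk normality
#' check, then runs Welch's t-test fused minus unfused. For the fused
#' variant the merged scaphoid-centrale body stands for the scaphoid.
#'
#' @param samples Data frame with columns `species`, `bone`, `variant`
#'   (`fused` / `unfused`), `angle`, `mwam`.
#' @param bone Bone to compare (`"scaphoid"` or `"capitate"`).
#' @param angle Load angle (degrees) to select.
#' @return One-row data frame: sample sizes, group means, pooled
#'   Shapiro-Wilk `W`/`p_W`, Welch `t`/`df`/`p_t`, and effect direction.
#' @export
compare_fused_unfused <- function(samples, bone, angle = 0) {
  s <- samples[samples$bone == bone & samples$angle == angle, , drop = FALSE]
  fu <- s$mwam[s$variant == "fused"]
  un <- s$mwam[s$variant == "unfused"]
  if (length(fu) == 0 || length(un) == 0)
    stop("both variants must be present for bone '", bone, "'")
  if (length(fu) != length(un))
    stop("unequal species coverage across variants for bone '", bone, "'")
  sw <- shapiro_wilk(c(fu, un))
  wt <- welch_t(fu, un)
  data.frame(bone = bone, angle = angle,
             n_fused = wt$n1, n_unfused = wt$n2,
             mean_fused = wt$mean1, mean_unfused = wt$mean2,
             W = sw$W, p_W = sw$p,
             t = wt$t, df = wt$df, p_t = wt$p,
             direction = if (wt$t < 0) "fused_lower" else "fused_higher")
}
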