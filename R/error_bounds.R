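# Berry-Esseen machinery: non-asymptotic bounds on the Kolmogorov-Smirnov
# distance between the law of a standardized arm mean and the standard
# normal, and the p-value uncertainty intervals they imply.

#' Berry-Esseen bound on the normal approximation of a sample mean
#'
#' For iid summands with moment ratio `C = E|X - mu|^3 / sigma^3`, the KS
#' distance between the law of the standardized sample mean and the standard
#' normal is at most `be_constant * C / sqrt(n)`.  The classical constant
#' used throughout is 0.5; the `sqrt(n)` rate cannot be improved.
#'
#' @param n Sample size, `>= 1`.
#' @param C Moment ratio, `>= 1` (see [moment_ratio()]).
#' @param be_constant Berry-Esseen constant, default 0.5.
#' @return The bound `be_constant * C / sqrt(n)`.
#' @examples
#' berry_esseen_epsilon(400, 1)  # 0.025
#' @export
berry_esseen_epsilon <- function(n, C, be_constant = 0.5) {
  n <- check_scalar(n, "n", lower = 1, integerish = TRUE)
  check_scalar(be_constant, "be_constant", lower = 0, open_lower = TRUE)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C < 1) {
    stop_config("the moment ratio satisfies C >= 1 for every distribution; ",
                "got C = ", format(C))
  }
  be_constant * C / sqrt(n)
}

#' Two-arm Berry-Esseen bound
#'
#' Bundles the per-arm bounds and their sum.  Because the p-value is a tail
#' probability of the difference of two independent arm means, its error is
#' bounded by the sum of the per-arm KS bounds (the sup-distance is
#' sub-additive under convolution with an independent summand).
#'
#' @param n1,n0 Per-arm sample sizes.
#' @param C1,C0 Per-arm moment ratios.
#' @param be_constant Berry-Esseen constant, default 0.5.
#' @return An object of class `berry_esseen_bound` with `per_arm` (data frame
#'   of `n`, `C`, `epsilon`) and `combined_epsilon`.
#' @export
berry_esseen_bound <- function(n1, n0, C1 = 1, C0 = 1, be_constant = 0.5) {
  e1 <- berry_esseen_epsilon(n1, C1, be_constant)
  e0 <- berry_esseen_epsilon(n0, C0, be_constant)
  structure(list(
    per_arm = data.frame(arm = c("1", "0"), n = c(n1, n0), C = c(C1, C0),
                         epsilon = c(e1, e0)),
    be_constant = be_constant,
    combined_epsilon = e1 + e0,
    generalized = FALSE
  ), class = "berry_esseen_bound")
}

#' @export
print.berry_esseen_bound <- function(x, ...) {
  cat("Berry-Esseen bound (constant ", x$be_constant, ")\n", sep = "")
  print(x$per_arm, row.names = FALSE)
  cat(sprintf("  combined epsilon = %.6g\n", x$combined_epsilon))
  invisible(x)
}

#' Uncertainty interval for a parametric p-value
#'
#' A parametric p-value is a normal tail probability; its error relative to
#' the true (finite-sample) tail probability is bounded by the combined KS
#' bound of the two arms.  The interval is
#' `[max(0, p - eps), min(1, p + eps)]`.  When the interval contains the
#' configured significance threshold, nominal significance is not guaranteed
#' by the bound, and the report flags it.
#'
#' @param p Nominal parametric p-value in `[0, 1]`.
#' @param bound A [berry_esseen_bound()].
#' @param alpha Significance threshold used for the guarantee flag.
#' @return An object of class `pvalue_interval` with `p_nominal`, `p_lo`,
#'   `p_hi`, `alpha` and `significance_guaranteed`.
#' @examples
#' b <- berry_esseen_bound(400, 400, 1, 1)
#' combined_pvalue_uncertainty(0.03, b)  # [0, 0.08]: not guaranteed at 0.05
#' @export
combined_pvalue_uncertainty <- function(p, bound, alpha = 0.05) {
  check_scalar(p, "p", lower = 0, upper = 1)
  stopifnot(inherits(bound, "berry_esseen_bound"))
  eps <- bound$combined_epsilon
  p_lo <- max(0, p - eps)
  p_hi <- min(1, p + eps)
  structure(list(p_nominal = p, p_lo = p_lo, p_hi = p_hi,
                 combined_epsilon = eps, alpha = alpha,
                 significance_guaranteed = p_hi < alpha,
                 contains_threshold = p_lo <= alpha && alpha <= p_hi),
            class = "pvalue_interval")
}

#' @export
print.pvalue_interval <- function(x, ...) {
  cat(sprintf("p = %.6g, uncertainty interval [%.6g, %.6g] (eps = %.6g)\n",
              x$p_nominal, x$p_lo, x$p_hi, x$combined_epsilon))
  cat(if (x$significance_guaranteed)
        sprintf("significance at alpha = %g is guaranteed\n", x$alpha)
      else
        sprintf("significance at alpha = %g is NOT guaranteed\n", x$alpha))
  invisible(x)
}

#' Minimal equal per-arm sample size for a p-value error tolerance
#'
#' Smallest per-arm `n` such that the combined two-arm Berry-Esseen bound
#' `be_constant * (C1 + C0) / sqrt(n)` does not exceed `tolerance`.  With
#' `tolerance = 0.005` (the error that keeps alpha = 0.05 correct after
#' rounding) and `C = 1` in both arms, this lands in the tens of thousands
#' per arm.
#'
#' @param tolerance Target combined error, in `(0, 1]`.
#' @param C1,C0 Per-arm moment ratios.
#' @param be_constant Berry-Esseen constant, default 0.5.
#' @return The minimal per-arm `n` (integer); satisfies the bound at `n` and
#'   violates it at `n - 1`.
#' @examples
#' min_n_for_tolerance(0.005)  # 40000 per arm
#' @export
min_n_for_tolerance <- function(tolerance, C1 = 1, C0 = 1,
                                be_constant = 0.5) {
  check_scalar(tolerance, "tolerance", lower = 0, upper = 1,
               open_lower = TRUE)
  comb <- function(n) berry_esseen_epsilon(n, C1, be_constant) +
                      berry_esseen_epsilon(n, C0, be_constant)
  if (comb(1) <= tolerance) return(1L)
  n <- ceiling((be_constant * (C1 + C0) / tolerance)^2)
  # guard the closed form against floating-point edge cases
  while (comb(n) > tolerance) n <- n + 1
  while (n > 1 && comb(n - 1) <= tolerance) n <- n - 1
  as.integer(n)
}

#' Guaranteed correct decimal digits of a parametric p-value
#'
#' The largest `k >= 0` such that the combined two-arm error bound does not
#' exceed `0.5 * 10^-k`, i.e. such that rounding the p-value to `k` decimal
#' places is guaranteed correct.  A few hundred to a few thousand subjects
#' per arm guarantee only the first decimal digit.
#'
#' @param n1,n0 Per-arm sample sizes.
#' @param C1,C0 Per-arm moment ratios.
#' @param be_constant Berry-Esseen constant, default 0.5.
#' @return A list with `digits`, the combined `epsilon` and the criterion
#'   string.
#' @examples
#' guaranteed_decimal_digits(500, 500)$digits  # 1
#' @export
guaranteed_decimal_digits <- function(n1, n0, C1 = 1, C0 = 1,
                                      be_constant = 0.5) {
  eps <- berry_esseen_epsilon(n1, C1, be_constant) +
         berry_esseen_epsilon(n0, C0, be_constant)
  k <- 0L
  # tiny multiplicative slack so exact boundary cases (eps == 0.5 * 10^-k)
  # are not lost to floating point
  while (eps <= 0.5 * 10^(-(k + 1L)) * (1 + 1e-12)) k <- k + 1L
  crit <- if (eps <= 0.5 * (1 + 1e-12)) {
    sprintf("combined epsilon %.6g <= 0.5 * 10^-%d (rounding to %d decimal%s)",
            eps, k, k, if (k == 1L) "" else "s")
  } else {
    sprintf("combined epsilon %.6g exceeds 0.5; no decimal digit guaranteed",
            eps)
  }
  list(digits = k, epsilon = eps, criterion = crit)
}

#' Generalized Berry-Esseen bound for independent, non-identical summands
#'
#' For independent summands with variances `sigma2_i` and third absolute
#' central moments `rho3_i`, the KS distance between the standardized sum and
#' the standard normal is at most
#' `constant * sum(rho3) / sum(sigma2)^(3/2)`.  This requires only
#' independence — not distributional homogeneity — so the p-value error can
#' in principle be controlled even for heterogeneous cohorts.  Reduces to the
#' iid formula `constant * C / sqrt(n)` when all summands are identical.
#'
#' @param sigma2 Vector of summand variances, all `> 0`.
#' @param rho3 Vector of third absolute central moments, same length.
#' @param constant Bound constant; default 0.56, configurable (the classical
#'   iid constant 0.5 does not apply verbatim in the non-identical case).
#' @return The bound.
#' @export
generalized_be_epsilon <- function(sigma2, rho3, constant = 0.56) {
  if (!length(sigma2)) stop_config("at least one summand is required")
  if (length(sigma2) != length(rho3)) {
    stop_config("`sigma2` and `rho3` must have the same length")
  }
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop_config("all summand variances must be finite and > 0")
  }
  if (any(!is.finite(rho3)) || any(rho3 < 0)) {
    stop_config("all third absolute central moments must be finite and >= 0")
  }
  check_scalar(constant, "constant", lower = 0, open_lower = TRUE)
  constant * sum(rho3) / sum(sigma2)^1.5
}

#' Monte-Carlo KS distance of a standardized sample mean from normality
#'
#' Estimates the Kolmogorov-Smirnov distance between the empirical law of
#' the standardized `n`-sample mean, `sqrt(n) * (xbar - mu) / sigma`, and the
#' standard normal, by simulating `reps` independent sample means.  Used to
#' verify that the true distance sits below the Berry-Esseen bound.
#'
#' @param dist A [response_distribution()] with positive variance.
#' @param n Sample size of each mean.
#' @param reps Number of Monte-Carlo replicates, `>= 1000`.
#' @param seed Optional seed.
#' @param chunk_reps Replicates generated per memory chunk.
#' @return The estimated KS distance (a single number).
#' @export
empirical_ks_distance <- function(dist, n, reps = 1e5, seed = NULL,
                                  chunk_reps = 20000L) {
  stopifnot(inherits(dist, "response_distribution"))
  n <- as.integer(check_scalar(n, "n", lower = 1, integerish = TRUE))
  reps <- as.integer(check_scalar(reps, "reps", lower = 1000,
                                  integerish = TRUE))
  mu <- dist_mean(dist)
  sg <- dist_sd(dist)
  if (sg <= 0) stop_config("degenerate distribution: KS demo needs variance")
  with_seed(seed, {
    z <- numeric(reps)
    done <- 0L
    while (done < reps) {
      k <- min(chunk_reps, reps - done)
      x <- matrix(dist_sample(dist, k * n), k, n)
      z[done + seq_len(k)] <- (rowMeans(x) - mu) / (sg / sqrt(n))
      done <- done + k
    }
    ks_stat_normal(z)
  })
}
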