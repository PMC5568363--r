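# P-values four ways: parametric normal tail, exact permutation, Monte-Carlo
# permutation, and the permutation-averaged parametric p-value.  All
# permutation methods operate under the sharp (strong) null: each subject's
# observed response is held fixed across re-allocations.

#' Parametric normal-tail p-value
#'
#' Standard-normal tail probability of an observed normalized difference
#' `z`.  The two-sided p-value is twice the smaller tail, capped at 1.
#' When `z` is unavailable (degenerate arm: fewer than two subjects or zero
#' sample variance), the function refuses and directs the caller to the
#' permutation methods, which remain well defined.
#'
#' @param z Observed normalized difference.
#' @param sided `"two-sided"`, `"right"` or `"left"`.
#' @return A p-value in `[0, 1]`.
#' @examples
#' parametric_pvalue(1.959964, "two-sided")  # ~0.05
#' @export
parametric_pvalue <- function(z, sided = c("two-sided", "right", "left")) {
  sided <- match.arg(sided)
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z)) {
    stop_config("`z` is unavailable (degenerate arm?); use a permutation ",
                "method, which needs no variance estimate")
  }
  switch(sided,
    "right"     = stats::pnorm(z, lower.tail = FALSE),
    "left"      = stats::pnorm(z),
    "two-sided" = min(1, 2 * min(stats::pnorm(z),
                                 stats::pnorm(z, lower.tail = FALSE)))
  )
}

# Vectorized per-allocation statistics under the sharp null: y is the fixed
# response vector, A an m x n 0/1 allocation matrix (1 = arm 1).
# Returns delta or z per row; z is NA for degenerate rows.
alloc_statistics <- function(y, A, statistic = c("delta", "z"),
                             pooled = FALSE) {
  statistic <- match.arg(statistic)
  n <- length(y)
  n1 <- rowSums(A)
  n0 <- n - n1
  s1 <- as.vector(A %*% y)
  s0 <- sum(y) - s1
  m1 <- ifelse(n1 > 0, s1 / n1, NaN)
  m0 <- ifelse(n0 > 0, s0 / n0, NaN)
  delta <- m1 - m0
  if (statistic == "delta") return(delta)

  q1 <- as.vector(A %*% (y^2))
  q0 <- sum(y^2) - q1
  v1 <- ifelse(n1 > 1, (q1 - n1 * m1^2) / (n1 - 1), NA_real_)
  v0 <- ifelse(n0 > 1, (q0 - n0 * m0^2) / (n0 - 1), NA_real_)
  # one-pass sums cancel catastrophically for (near-)constant arms; treat
  # variances at round-off scale as zero (degenerate)
  tol <- 1e-12 * (1 + abs(m1)^2 + abs(m0)^2)
  v1[!is.na(v1) & v1 < tol] <- 0
  v0[!is.na(v0) & v0 < tol] <- 0
  # degenerate allocation: either arm with zero sample variance has no z
  deg <- is.na(v1) | is.na(v0) | if (pooled) (v1 <= 0 & v0 <= 0) else
           (v1 <= 0 | v0 <= 0)
  if (pooled) {
    vp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    den <- sqrt(vp * (1 / n1 + 1 / n0))
  } else {
    den <- sqrt(v1 / n1 + v0 / n0)
  }
  z <- delta / den
  z[deg | !is.finite(z)] <- NA_real_
  z
}

# Admissible allocations for a realized trial, expanded to subject columns.
# With cluster-unit randomization the scheme acts on intact clusters in
# enrollment order, and each cluster's arm label is broadcast to its members.
allocation_set_for_trial <- function(trial, design, limit, seed = NULL) {
  if (design$randomization_unit == "cluster") {
    units <- trial$cluster_id
    uu <- unique(units)
    enum <- enumerate_allocations(length(uu), design, limit = limit,
                                  seed = seed)
    enum$allocations <- enum$allocations[, match(units, uu), drop = FALSE]
    enum
  } else {
    enumerate_allocations(length(trial$observed), design, limit = limit,
                          seed = seed)
  }
}

new_pvalue_report <- function(method, statistic_type, statistic, sided, p,
                              n_allocations_used, exact,
                              n_degenerate = 0L, count = NA_real_,
                              note = NULL) {
  if (is.finite(p)) stopifnot(p >= 0, p <= 1)
  structure(list(method = method, statistic_type = statistic_type,
                 statistic = statistic, sided = sided, p = p,
                 n_allocations_used = n_allocations_used, exact = exact,
                 n_degenerate = n_degenerate, count = count,
                 uncertainty = NULL, note = note),
            class = "pvalue_report")
}

#' @export
print.pvalue_report <- function(x, ...) {
  cat("P-value report\n")
  cat(sprintf("  method      %s\n", x$method))
  cat(sprintf("  statistic   %s = %.6g\n", x$statistic_type, x$statistic))
  cat(sprintf("  sidedness   %s\n", x$sided))
  cat(sprintf("  p           %.6g\n", x$p))
  cat(sprintf("  allocations %d (%s)\n", x$n_allocations_used,
              if (isTRUE(x$exact)) "exact enumeration" else "Monte Carlo"))
  if (x$n_degenerate > 0L) {
    cat(sprintf("  degenerate  %d allocations skipped\n", x$n_degenerate))
  }
  if (!is.null(x$uncertainty)) {
    cat(sprintf("  uncertainty [%.6g, %.6g]\n",
                x$uncertainty$p_lo, x$uncertainty$p_hi))
  }
  if (!is.null(x$note)) cat("  note        ", x$note, "\n", sep = "")
  invisible(x)
}

# Count allocations at least as extreme as the observed statistic.  Ties
# count as extreme (conservative, keeps the test exact); comparisons use a
# small relative tolerance so exact ties are not lost to round-off.
count_extreme <- function(stats, obs, sided, two_sided_rule) {
  tol <- 1e-12 * (1 + abs(obs))
  stats <- stats[!is.na(stats)]
  switch(sided,
    "right" = sum(stats >= obs - tol),
    "left"  = sum(stats <= obs + tol),
    "two-sided" = if (two_sided_rule == "absolute") {
      sum(abs(stats) >= abs(obs) - tol)
    } else {
      2L * min(sum(stats >= obs - tol), sum(stats <= obs + tol))
    }
  )
}

#' Permutation (randomization) p-value under the sharp null
#'
#' Recomputes the test statistic for every admissible allocation of the
#' design's randomization scheme — holding each subject's observed response
#' fixed, as the sharp null warrants — and reports the fraction at least as
#' extreme as the observed value.  In `"exact"` mode the full allocation set
#' is enumerated (falling back to Monte Carlo with a note when it exceeds
#' `limit`); in `"mc"` mode `m` allocations are sampled iid from the scheme
#' and the add-one estimator `p = (b + 1) / (m + 1)` is used, so the p-value
#' is never 0 and the test stays valid.
#'
#' @param trial A [realize_trial()] result.
#' @param design The [trial_design()] actually used (its scheme defines the
#'   admissible allocation set).
#' @param statistic `"delta"` (default; always defined) or `"z"`.
#' @param sided `"right"`, `"left"` or `"two-sided"`.
#' @param mode `"exact"` or `"mc"`.
#' @param m Number of Monte-Carlo allocations (`mode = "mc"`), `>= 1`.
#' @param limit Enumeration limit before the exact mode falls back to
#'   Monte Carlo.
#' @param seed Optional seed (Monte-Carlo path).
#' @param two_sided_rule `"absolute"` (default): extremeness is
#'   `|stat| >= |observed|`; `"double-tail"`: twice the smaller tail count.
#' @return A `pvalue_report`.
#' @examples
#' subj <- data.frame(subject_id = 1:4, cluster_id = 1:4, category = "c",
#'                    y_arm0 = c(3, 1, 2, 0), y_arm1 = c(3, 1, 2, 0))
#' des <- trial_design(4, "complete-balanced")
#' tr <- realize_trial(subj, c(1L, 1L, 0L, 0L), des)
#' permutation_pvalue(tr, des, sided = "right")$p  # 2/6
#' @export
permutation_pvalue <- function(trial, design,
                               statistic = c("delta", "z"),
                               sided = c("two-sided", "right", "left"),
                               mode = c("exact", "mc"),
                               m = 999L, limit = 1e6, seed = NULL,
                               two_sided_rule = c("absolute", "double-tail")) {
  stopifnot(inherits(trial, "trial_result"), inherits(design, "trial_design"))
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  mode <- match.arg(mode)
  two_sided_rule <- match.arg(two_sided_rule)

  y <- trial$observed
  n <- length(y)
  obs <- if (statistic == "delta") trial$delta else trial$z
  if (statistic == "z" && !trial$z_ok) {
    stop_config("observed z is unavailable (degenerate arm); use ",
                "statistic = 'delta'")
  }

  note <- NULL
  if (mode == "mc") {
    m <- as.integer(check_scalar(m, "m", lower = 1, integerish = TRUE))
    enum <- allocation_set_for_trial(trial, design, limit = m, seed = seed)
    if (enum$exact) {
      # the admissible set is smaller than m; exact enumeration is free
      mode <- "exact"
    }
  } else {
    enum <- allocation_set_for_trial(trial, design, limit = limit,
                                     seed = seed)
    if (!enum$exact) {
      note <- paste0("allocation count ", format(enum$count),
                     " exceeds limit ", format(limit),
                     "; fell back to Monte Carlo")
      m <- nrow(enum$allocations)
      mode <- "mc"
    }
  }

  stats <- alloc_statistics(y, enum$allocations, statistic, trial$pooled)
  n_deg <- sum(is.na(stats))
  b <- count_extreme(stats, obs, sided, two_sided_rule)

  if (mode == "exact") {
    total <- nrow(enum$allocations)
    p <- min(1, b / total)
    new_pvalue_report("permutation-exact", statistic, obs, sided, p,
                      n_allocations_used = total, exact = TRUE,
                      n_degenerate = n_deg, count = enum$count)
  } else {
    mm <- nrow(enum$allocations)
    p <- min(1, (b + 1) / (mm + 1))
    new_pvalue_report("permutation-mc", statistic, obs, sided, p,
                      n_allocations_used = mm, exact = FALSE,
                      n_degenerate = n_deg, count = enum$count, note = note)
  }
}

#' Permutation-averaged parametric p-value
#'
#' The hybrid remedy for parametric analyses that ignore randomization: the
#' arithmetic mean, over the admissible allocations of the randomization
#' scheme (enumerated exactly, or sampled with `exact = FALSE` beyond
#' `limit`), of the parametric normal-tail p-value of each allocation's
#' normalized difference — responses held fixed across allocations.
#' Allocations with a degenerate arm have no `z`; by default they are
#' dropped and counted (`degenerate = "drop"`), or they can be imputed the
#' maximally conservative `p = 1` (`degenerate = "one"`).
#'
#' @inheritParams permutation_pvalue
#' @param degenerate `"drop"` (default) or `"one"`, see above.
#' @return A `pvalue_report` with method `"perm-averaged-parametric"`.
#' @export
perm_averaged_parametric_pvalue <- function(trial, design,
                                            sided = c("two-sided", "right",
                                                      "left"),
                                            limit = 1e6, seed = NULL,
                                            degenerate = c("drop", "one")) {
  stopifnot(inherits(trial, "trial_result"), inherits(design, "trial_design"))
  sided <- match.arg(sided)
  degenerate <- match.arg(degenerate)

  y <- trial$observed
  enum <- allocation_set_for_trial(trial, design, limit = limit, seed = seed)
  z <- alloc_statistics(y, enum$allocations, "z", trial$pooled)
  deg <- is.na(z)
  if (all(deg)) {
    stop_config("every admissible allocation has a degenerate arm ",
                "(constant responses?); the permutation-averaged parametric ",
                "p-value is undefined")
  }
  pv <- rep(NA_real_, length(z))
  zz <- z[!deg]
  pv[!deg] <- switch(sided,
    "right"     = stats::pnorm(zz, lower.tail = FALSE),
    "left"      = stats::pnorm(zz),
    "two-sided" = pmin(1, 2 * pmin(stats::pnorm(zz),
                                   stats::pnorm(zz, lower.tail = FALSE)))
  )
  if (degenerate == "one") pv[deg] <- 1
  p <- mean(pv, na.rm = TRUE)
  new_pvalue_report("perm-averaged-parametric", "z",
                    statistic = if (trial$z_ok) trial$z else NA_real_,
                    sided = sided, p = p,
                    n_allocations_used = nrow(enum$allocations),
                    exact = enum$exact,
                    n_degenerate = sum(deg), count = enum$count,
                    note = if (sum(deg) > 0L)
                      paste0(sum(deg), " degenerate allocations ",
                             if (degenerate == "drop") "dropped"
                             else "imputed p = 1"))
}

#' Re-analyze a subject-level trial table
#'
#' Entry point for delimited-text re-analysis: the table must contain `arm`
#' (0/1 or the design's arm labels) and `response` columns.  The observed
#' responses are treated as fixed (sharp null) and the requested p-value
#' method is applied with the supplied design (default: complete-balanced
#' randomization of the observed subjects).
#'
#' @param data A `data.frame` with columns `arm` and `response`.
#' @param method One of `"parametric"`, `"permutation-exact"`,
#'   `"permutation-mc"`, `"perm-averaged-parametric"`.
#' @param design Optional [trial_design()]; defaults to complete-balanced
#'   with the observed subject count.
#' @param statistic,sided,m,limit,seed Passed to the underlying method.
#' @return A `pvalue_report`.
#' @export
analyze_trial_table <- function(data,
                                method = c("parametric", "permutation-exact",
                                           "permutation-mc",
                                           "perm-averaged-parametric"),
                                design = NULL,
                                statistic = "delta",
                                sided = "two-sided",
                                m = 999L, limit = 1e6, seed = NULL) {
  method <- match.arg(method)
  if (!all(c("arm", "response") %in% names(data))) {
    stop_config("`data` needs `arm` and `response` columns")
  }
  n <- nrow(data)
  if (is.null(design)) design <- trial_design(n, "complete-balanced")
  arm <- data$arm
  if (!is.numeric(arm)) arm <- match(as.character(arm), design$arms) - 1L
  if (anyNA(arm) || !all(arm %in% c(0L, 1L))) {
    stop_config("`arm` must be coded 0/1 or use the design's arm labels")
  }
  subj <- data.frame(subject_id = seq_len(n),
                     cluster_id = if ("cluster_id" %in% names(data))
                       data$cluster_id else seq_len(n),
                     category = if ("category" %in% names(data))
                       data$category else "observed",
                     y_arm0 = data$response, y_arm1 = data$response)
  trial <- realize_trial(subj, as.integer(arm), design)

  switch(method,
    "parametric" = {
      p <- parametric_pvalue(trial$z, sided)
      new_pvalue_report("parametric", "z", trial$z, sided, p,
                        n_allocations_used = 1L, exact = TRUE)
    },
    "permutation-exact" = permutation_pvalue(trial, design, statistic, sided,
                                             mode = "exact", limit = limit,
                                             seed = seed),
    "permutation-mc" = permutation_pvalue(trial, design, statistic, sided,
                                          mode = "mc", m = m, seed = seed),
    "perm-averaged-parametric" =
      perm_averaged_parametric_pvalue(trial, design, sided, limit, seed)
  )
}
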