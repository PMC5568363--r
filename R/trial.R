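#' Two-arm trial design
#'
#' Captures the randomization scheme and the sample-size regime of a two-arm
#' trial.  Allocation schemes: `"complete-balanced"` (a uniformly random
#' split with arm sizes differing by at most 1), `"simple-coin"` (independent
#' fair-coin assignment, so arm sizes are random), and `"permuted-block"`
#' (consecutive enrollment blocks of even length `block_length`, each an
#' independent uniformly random balanced arrangement; a final partial block
#' is the truncation of a random balanced block).
#'
#' Sample-size regimes model the ways a nominally fixed `n` is random in
#' practice: `"fixed"`, `"poisson-total"` (total enrollment `~ Poisson(lambda)`),
#' `"dropout"` (each subject retained independently with probability
#' `retention`), and `"event-driven"` (enrollment in order until
#' `event_target` responses exceed `event_threshold`).
#'
#' @param n Planned number of enrolled subjects (total).
#' @param allocation Randomization scheme, see above.
#' @param block_length Even integer `>= 2`, permuted-block only.
#' @param regime Sample-size regime, see above.
#' @param lambda Mean total enrollment for `"poisson-total"`.
#' @param retention Per-subject retention probability in `(0, 1]` for
#'   `"dropout"`.
#' @param event_threshold,event_target Event definition (response strictly
#'   greater than the threshold) and required event count for
#'   `"event-driven"`.
#' @param arms Labels of the two arms (control first).
#' @param pooled_variance Use the pooled-variance standardization for the
#'   normalized statistic `z` instead of the default unpooled (Welch-style)
#'   one.
#' @param randomization_unit `"subject"` (default) or `"cluster"`.  With
#'   `"cluster"`, the allocation scheme operates on intact clusters (e.g.
#'   twins enrolled and assigned together): all members of a cluster receive
#'   the same arm.  An analysis that then treats subjects as independent
#'   underestimates the variance of the arm means by the factor `1 + r`
#'   (pairs), which is the variance-inflation mechanism behind the
#'   dependence-distortion experiments.  Permutation inference conditions on
#'   the cluster-level randomization and remains valid.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n,
                         allocation = c("complete-balanced", "simple-coin",
                                        "permuted-block"),
                         block_length = 4L,
                         regime = c("fixed", "poisson-total", "dropout",
                                    "event-driven"),
                         lambda = NULL, retention = 1,
                         event_threshold = NULL, event_target = NULL,
                         arms = c("0", "1"),
                         pooled_variance = FALSE,
                         randomization_unit = c("subject", "cluster")) {
  allocation <- match.arg(allocation)
  regime <- match.arg(regime)
  randomization_unit <- match.arg(randomization_unit)
  n <- as.integer(check_scalar(n, "n", lower = 1, integerish = TRUE))
  if (length(arms) != 2L || anyDuplicated(arms)) {
    stop_config("a trial has exactly two distinct arms")
  }
  if (allocation == "permuted-block") {
    block_length <- as.integer(check_scalar(block_length, "block_length",
                                            lower = 2, integerish = TRUE))
    if (block_length %% 2L != 0L) {
      stop_config("`block_length` must be even")
    }
  }
  if (regime == "poisson-total") {
    check_scalar(lambda, "lambda", lower = 0, open_lower = TRUE)
  }
  if (regime == "dropout") {
    check_scalar(retention, "retention", lower = 0, upper = 1,
                 open_lower = TRUE)
  }
  if (regime == "event-driven") {
    check_scalar(event_threshold, "event_threshold")
    check_scalar(event_target, "event_target", lower = 1, integerish = TRUE)
  }
  structure(list(n = n, allocation = allocation,
                 block_length = as.integer(block_length),
                 regime = regime, lambda = lambda, retention = retention,
                 event_threshold = event_threshold,
                 event_target = event_target,
                 arms = as.character(arms),
                 pooled_variance = isTRUE(pooled_variance),
                 randomization_unit = randomization_unit),
            class = "trial_design")
}

# One random allocation as a 0/1 integer vector of length n (1 = arm 1).
draw_allocation <- function(n, design) {
  switch(design$allocation,
    "simple-coin" = stats::rbinom(n, 1L, 0.5),
    "complete-balanced" = {
      n1 <- n %/% 2L
      if (n %% 2L == 1L) n1 <- n1 + stats::rbinom(1L, 1L, 0.5)
      a <- integer(n)
      a[sample.int(n, n1)] <- 1L
      a
    },
    "permuted-block" = {
      b <- design$block_length
      a <- integer(n)
      start <- 1L
      while (start <= n) {
        s <- min(b, n - start + 1L)
        # a random balanced block, truncated to the partial-block length
        v <- sample(rep(0:1, b %/% 2L))[seq_len(s)]
        a[start:(start + s - 1L)] <- v
        start <- start + b
      }
      a
    }
  )
}

#' Randomize subjects to arms
#'
#' Draws one allocation from the exact distribution of the design's
#' randomization scheme.  Permuted-block fills blocks in enrollment order;
#' when the subject count is not a multiple of the block length, the final
#' partial block is the truncation of a uniformly random balanced block
#' (never an error).
#'
#' @param subjects Subject `data.frame` from [sample_subjects()].
#' @param design A [trial_design()].
#' @param seed Optional integer seed.
#' @return Integer vector of 0/1 arm indices, one per subject row, with the
#'   scheme recorded in attribute `"scheme"`.
#' @export
randomize <- function(subjects, design, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  n <- nrow(subjects)
  if (is.null(n) || n < 1L) stop_config("`subjects` must be nonempty")
  a <- if (design$randomization_unit == "cluster") {
    cl <- subjects$cluster_id
    if (is.null(cl)) {
      stop_config("cluster-unit randomization needs a `cluster_id` column")
    }
    uu <- unique(cl)                     # enrollment order of clusters
    with_seed(seed, draw_allocation(length(uu), design))[match(cl, uu)]
  } else {
    with_seed(seed, draw_allocation(n, design))
  }
  structure(a, scheme = design$allocation, unit = design$randomization_unit)
}

#' Apply the design's sample-size regime to a cohort
#'
#' Converts the planned cohort into the realized (retained) one.
#' `"fixed"` is the identity.  `"poisson-total"` draws `N ~ Poisson(lambda)`
#' and truncates the cohort to `N` (or extends it by re-running the
#' cohort-generating process when `N` exceeds the available subjects, which
#' requires `model`).  `"dropout"` keeps each subject independently with the
#' retention probability.  `"event-driven"` retains subjects in enrollment
#' order until the target number of events (control-arm potential outcome
#' exceeding the event threshold) has accrued.
#'
#' @param subjects Subject `data.frame`.
#' @param design A [trial_design()].
#' @param seed Optional integer seed.
#' @param model Optional [population_model()], needed only when
#'   `"poisson-total"` draws more subjects than supplied.
#' @return The retained subject `data.frame` (subject ids renumbered
#'   sequentially so downstream allocation vectors align with rows).
#' @export
apply_sample_size_regime <- function(subjects, design, seed = NULL,
                                     model = NULL) {
  stopifnot(inherits(design, "trial_design"))
  n <- nrow(subjects)
  out <- with_seed(seed, switch(design$regime,
    "fixed" = subjects,
    "poisson-total" = {
      N <- stats::rpois(1L, design$lambda)
      if (N < 1L) {
        stop_config("Poisson enrollment drew N = 0 subjects; no trial can ",
                    "be run (lambda = ", design$lambda, ")")
      }
      if (N <= n) {
        subjects[seq_len(N), , drop = FALSE]
      } else {
        if (is.null(model)) {
          stop_config("Poisson enrollment drew N = ", N, " > ", n,
                      " available subjects; pass `model` so the cohort-",
                      "generating process can be resampled")
        }
        extra <- sample_subjects(model, N - n)
        extra$subject_id <- n + seq_len(N - n)
        extra$cluster_id <- max(subjects$cluster_id) + extra$cluster_id
        rbind(subjects, extra)
      }
    },
    "dropout" = {
      keep <- stats::rbinom(n, 1L, design$retention) == 1L
      subjects[keep, , drop = FALSE]
    },
    "event-driven" = {
      ev <- cumsum(subjects$y_arm0 > design$event_threshold)
      if (max(ev) < design$event_target) {
        stop_config("event-driven regime requires ", design$event_target,
                    " events but only ", max(ev), " occur in the cohort; ",
                    "enroll more subjects or lower the threshold")
      }
      cut <- which(ev >= design$event_target)[1L]
      subjects[seq_len(cut), , drop = FALSE]
    }
  ))
  out$subject_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Welch-style (default) or pooled normalized difference; NA when either arm
# is degenerate (size < 2 or zero sample variance).
normalized_statistic <- function(y1, y0, pooled = FALSE) {
  n1 <- length(y1); n0 <- length(y0)
  if (n1 < 2L || n0 < 2L) return(NA_real_)
  v1 <- stats::var(y1); v0 <- stats::var(y0)
  if (v1 <= 0 || v0 <= 0) return(NA_real_)
  d <- mean(y1) - mean(y0)
  if (pooled) {
    vp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    d / sqrt(vp * (1 / n1 + 1 / n0))
  } else {
    d / sqrt(v1 / n1 + v0 / n0)
  }
}

#' Realize a trial from a cohort and an allocation
#'
#' Each subject's observed response is the pre-drawn potential outcome of the
#' assigned arm.  Computes the arm means `A1`, `A0`, the difference
#' `delta = A1 - A0`, the arm sizes, and the normalized difference
#' `z = delta / sqrt(s1^2/n1 + s0^2/n0)` (or the pooled version when the
#' design says so).  `z` is flagged unavailable — `delta` is still reported —
#' when either arm has fewer than two subjects or zero sample variance.
#'
#' @param subjects Retained subject `data.frame`.
#' @param allocation Integer 0/1 vector from [randomize()].
#' @param design Optional [trial_design()]; controls arm labels and the
#'   pooled-variance flag.
#' @return An object of class `trial_result`.
#' @export
realize_trial <- function(subjects, allocation, design = NULL) {
  n <- nrow(subjects)
  if (length(allocation) != n) {
    stop_config("allocation must cover all ", n, " retained subjects ",
                "(got ", length(allocation), ")")
  }
  pooled <- if (is.null(design)) FALSE else design$pooled_variance
  arm1 <- allocation == 1L
  y <- ifelse(arm1, subjects$y_arm1, subjects$y_arm0)
  y1 <- y[arm1]; y0 <- y[!arm1]
  A1 <- mean(y1); A0 <- mean(y0)
  z <- normalized_statistic(y1, y0, pooled)
  structure(list(
    allocation = as.integer(allocation),
    subject_id = subjects$subject_id,
    cluster_id = subjects$cluster_id %||% subjects$subject_id,
    observed = y,
    n1 = length(y1), n0 = length(y0),
    A1 = A1, A0 = A0,
    delta = A1 - A0,
    z = z, z_ok = is.finite(z),
    pooled = pooled
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Two-arm trial result\n")
  cat(sprintf("  arm sizes  n1 = %d, n0 = %d\n", x$n1, x$n0))
  cat(sprintf("  arm means  A1 = %.6g, A0 = %.6g\n", x$A1, x$A0))
  cat(sprintf("  delta      %.6g\n", x$delta))
  if (x$z_ok) {
    cat(sprintf("  z          %.6g (%s variance)\n", x$z,
                if (x$pooled) "pooled" else "unpooled"))
  } else {
    cat("  z          unavailable (degenerate arm)\n")
  }
  invisible(x)
}

# ---- allocation enumeration -------------------------------------------------

# 0/1 matrix with one row per subset of size k out of n (columns = subjects).
balanced_split_matrix <- function(n, k) {
  idx <- utils::combn(n, k)
  m <- matrix(0L, ncol(idx), n)
  m[cbind(rep(seq_len(ncol(idx)), each = k), as.vector(idx))] <- 1L
  m
}

# Truncations (length s) of all balanced 0/1 blocks of length b.  Duplicate
# truncations are kept deliberately: a partial final block is not uniform
# over its distinct truncated patterns, and the multiplicities here are
# exactly the scheme's probabilities.
truncated_block_matrix <- function(b, s) {
  full <- balanced_split_matrix(b, b %/% 2L)
  if (s >= b) full else full[, seq_len(s), drop = FALSE]
}

# Number of admissible allocations under the scheme (permuted-block counts
# the partial block with multiplicity, matching truncated_block_matrix).
count_allocations <- function(n, design) {
  switch(design$allocation,
    "simple-coin" = 2^n,
    "complete-balanced" = if (n %% 2L == 0L) choose(n, n %/% 2L) else
                            2 * choose(n, n %/% 2L),
    "permuted-block" = {
      b <- design$block_length
      n_blocks <- ceiling(n / b)
      choose(b, b %/% 2L)^n_blocks
    }
  )
}

# Cartesian product of per-block allocation matrices (rows bind columns).
cross_blocks <- function(blocks) {
  out <- blocks[[1L]]
  for (m in blocks[-1L]) {
    i <- rep(seq_len(nrow(out)), times = nrow(m))
    j <- rep(seq_len(nrow(m)), each = nrow(out))
    out <- cbind(out[i, , drop = FALSE], m[j, , drop = FALSE])
  }
  out
}

#' Enumerate or sample the admissible allocations of a design
#'
#' Randomization inference conditions on the set of allocations the scheme in
#' use could actually have produced.  When the scheme's allocation count does
#' not exceed `limit`, every admissible allocation is produced exactly once
#' (`exact = TRUE`): all balanced splits for `"complete-balanced"`, all
#' `2^n` label vectors for `"simple-coin"`, and the product over blocks of
#' balanced block arrangements for `"permuted-block"`.  Beyond the limit,
#' `limit` allocations are sampled iid from the scheme (`exact = FALSE`).
#'
#' @param n Number of retained subjects (or a subject `data.frame`).
#' @param design A [trial_design()].
#' @param limit Maximum number of allocations to enumerate before switching
#'   to Monte-Carlo sampling; default `1e6`.
#' @param seed Optional seed (used only on the sampling path).
#' @return A list with `allocations` (0/1 integer matrix, one row per
#'   allocation), `exact` (logical) and `count` (the scheme's total
#'   allocation count).
#' @export
enumerate_allocations <- function(n, design, limit = 1e6, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(check_scalar(n, "n", lower = 1, integerish = TRUE))
  check_scalar(limit, "limit", lower = 1)
  total <- count_allocations(n, design)

  if (is.finite(total) && total <= limit) {
    alloc <- switch(design$allocation,
      "simple-coin" = {
        g <- as.matrix(expand.grid(rep(list(0:1), n)))
        dimnames(g) <- NULL
        storage.mode(g) <- "integer"
        g
      },
      "complete-balanced" = {
        if (n %% 2L == 0L) {
          balanced_split_matrix(n, n %/% 2L)
        } else {
          rbind(balanced_split_matrix(n, n %/% 2L),
                balanced_split_matrix(n, n %/% 2L + 1L))
        }
      },
      "permuted-block" = {
        b <- design$block_length
        sizes <- c(rep(b, n %/% b), if (n %% b > 0L) n %% b)
        cross_blocks(lapply(sizes, function(s) truncated_block_matrix(b, s)))
      }
    )
    return(list(allocations = alloc, exact = TRUE, count = total))
  }

  m <- as.integer(limit)
  alloc <- with_seed(seed,
    t(vapply(seq_len(m), function(i) draw_allocation(n, design), integer(n))))
  list(allocations = alloc, exact = FALSE, count = total)
}
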