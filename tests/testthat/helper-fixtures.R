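# Shared fixtures, built in code.

# A deterministic four-subject cohort with responses {3, 1, 2, 0}.
four_subjects <- function(y = c(3, 1, 2, 0)) {
  data.frame(subject_id = seq_along(y), cluster_id = seq_along(y),
             category = "c", y_arm0 = y, y_arm1 = y,
             stringsAsFactors = FALSE)
}

# A single-category homogeneous normal population (identical in both arms).
iid_normal_model <- function(mean = 0, sd = 1) {
  d <- response_distribution("normal", mean = mean, sd = sd)
  population_model(categories = list(response_category("c", 1, d, d)))
}

# Equicorrelated pairs (clusters of 2) with a normal response.
clustered_model <- function(r = 0.5, cluster_size = 2L) {
  d <- response_distribution("normal")
  population_model(
    categories = list(response_category("c", 1, d, d)),
    dependence = dependence_spec("clustered",
                                 cluster_size_law = list(type = "constant",
                                                         size = cluster_size),
                                 icc = r))
}

# Independent brute-force enumeration of balanced splits: list of 0/1
# vectors, one per subset of size k (oracle for enumerate_allocations).
oracle_balanced_allocations <- function(n, k = n %/% 2L) {
  sets <- utils::combn(n, k, simplify = FALSE)
  lapply(sets, function(s) {
    a <- integer(n)
    a[s] <- 1L
    a
  })
}

# Canonical string form of an allocation multiset, for set comparisons.
alloc_key <- function(m) sort(apply(m, 1, paste, collapse = ""))

# Welch z computed independently of the package internals.
oracle_welch_z <- function(y, a) {
  y1 <- y[a == 1]; y0 <- y[a == 0]
  (mean(y1) - mean(y0)) /
    sqrt(stats::var(y1) / length(y1) + stats::var(y0) / length(y0))
}
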