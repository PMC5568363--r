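#' Latent response categories
#'
#' A heterogeneous population is modelled as a mixture of latent categories,
#' each with its own response law per trial arm.  A category's arm law may be
#' a [response_distribution()] or a single number, in which case the response
#' is fully deterministic for every member of the category — the
#' deterministic paradigm is a degenerate special case of the stochastic one,
#' not a separate code path.
#'
#' @param label Character label for the category.
#' @param weight Population weight in `(0, 1]`.
#' @param arm0,arm1 Response law in the control / treatment arm: either a
#'   [response_distribution()] or a single numeric (deterministic response).
#' @return An object of class `response_category`.
#' @export
response_category <- function(label, weight, arm0, arm1) {
  check_scalar(weight, "weight", lower = 0, upper = 1, open_lower = TRUE)
  as_law <- function(x, name) {
    if (inherits(x, "response_distribution")) return(x)
    if (is.numeric(x) && length(x) == 1L && is.finite(x)) return(x)
    stop_config("`", name, "` must be a response_distribution or a single ",
                "numeric (deterministic) value")
  }
  structure(list(label = as.character(label), weight = weight,
                 arm0 = as_law(arm0, "arm0"), arm1 = as_law(arm1, "arm1")),
            class = "response_category")
}

#' Dependence structure of subject responses
#'
#' Responses are either independent across subjects or equicorrelated within
#' clusters (twins, siblings, other relatives).  Clustered dependence is
#' induced constructively by an additive latent effect shared by all cluster
#' members: for a normal response with mean `mu` and sd `sigma`,
#' `Y = mu + sigma * (sqrt(r) * G_cluster + sqrt(1 - r) * E_subject)`, which
#' gives every within-cluster pair correlation exactly `r` and leaves the
#' marginal law unchanged.
#'
#' @param mode `"independent"` or `"clustered"`.
#' @param cluster_size_law List describing the distribution of cluster sizes:
#'   `list(type = "constant", size = k)` or
#'   `list(type = "poisson1", lambda = l)` for `1 + Poisson(l)`.
#' @param icc Pairwise within-cluster correlation `r` in `[0, 1)`.  Must be 0
#'   in independent mode.  Only the normal family supports `r > 0` (the
#'   additive construction would distort the marginal law of any bounded
#'   family).
#' @param allow_cross_category If `FALSE` (default) every cluster belongs to
#'   a single category.
#' @return An object of class `dependence_spec`.
#' @export
dependence_spec <- function(mode = c("independent", "clustered"),
                            cluster_size_law = list(type = "constant",
                                                    size = 2L),
                            icc = 0, allow_cross_category = FALSE) {
  mode <- match.arg(mode)
  check_scalar(icc, "icc", lower = 0, upper = 1, open_upper = TRUE)
  if (mode == "independent" && icc != 0) {
    stop_config("`icc` must be 0 when mode = 'independent'")
  }
  if (!is.list(cluster_size_law) || is.null(cluster_size_law$type)) {
    stop_config("`cluster_size_law` must be a list with a `type` field")
  }
  structure(list(mode = mode, cluster_size_law = cluster_size_law,
                 icc = icc, allow_cross_category = isTRUE(allow_cross_category)),
            class = "dependence_spec")
}

# Draw m cluster sizes from the configured positive-integer law.
draw_cluster_sizes <- function(law, m) {
  switch(law$type,
    "constant" = {
      k <- check_scalar(law$size, "cluster size", lower = 1, integerish = TRUE)
      rep(as.integer(k), m)
    },
    "poisson1" = {
      l <- check_scalar(law$lambda, "cluster size lambda", lower = 0,
                        open_lower = TRUE)
      1L + stats::rpois(m, l)
    },
    stop_config("unknown cluster_size_law type '", law$type, "'")
  )
}

#' Population model: mixture of latent categories
#'
#' Either a fixed list of [response_category()] objects (weights must sum to
#' 1 within 1e-12) or a category-generating law: the number of categories `K`
#' is drawn from a stated positive-integer distribution and the weights from
#' a symmetric Dirichlet.  The generating-law route models the reality that
#' the number of response categories in a trial and their population weights
#' are themselves unknown random quantities, which is the mechanism that
#' makes trial results vary between replications.
#'
#' @param categories List of [response_category()] (fixed-mixture mode), or
#'   `NULL` to use the generating law.
#' @param k_law Integer law for the number of categories:
#'   `list(type = "constant", k = k)` or `list(type = "poisson1", lambda = l)`
#'   meaning `K = 1 + Poisson(l)` (support starts at 1 by construction; laws
#'   whose support includes 0 are rejected).
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet for the
#'   category weights; must be strictly positive.
#' @param category_sampler Function `function(k)` returning a list of `k`
#'   [response_category()] objects (their `weight` fields are overwritten by
#'   the Dirichlet draw).  The default draws a common normal response with a
#'   category-specific mean `mu_j ~ N(0, 1)`, identical in both arms.
#' @param dependence A [dependence_spec()].
#' @return An object of class `population_model`.
#' @export
population_model <- function(categories = NULL, k_law = NULL,
                             dirichlet_alpha = 1,
                             category_sampler = NULL,
                             dependence = dependence_spec()) {
  stopifnot(inherits(dependence, "dependence_spec"))
  if (is.null(categories) == is.null(k_law)) {
    stop_config("supply exactly one of `categories` (fixed mixture) or ",
                "`k_law` (category-generating law)")
  }
  if (!is.null(categories)) {
    if (!length(categories) ||
        !all(vapply(categories, inherits, TRUE, "response_category"))) {
      stop_config("`categories` must be a nonempty list of response_category")
    }
    w <- vapply(categories, `[[`, 0, "weight")
    if (abs(sum(w) - 1) > 1e-12) {
      stop_config("category weights must sum to 1 within 1e-12 (got ",
                  format(sum(w), digits = 16), ")")
    }
  } else {
    check_scalar(dirichlet_alpha, "dirichlet_alpha", lower = 0,
                 open_lower = TRUE)
    if (!is.list(k_law) || is.null(k_law$type)) {
      stop_config("`k_law` must be a list with a `type` field")
    }
    if (k_law$type == "constant") {
      check_scalar(k_law$k, "k", lower = 1, integerish = TRUE)
    } else if (k_law$type == "poisson1") {
      check_scalar(k_law$lambda, "lambda", lower = 0, open_lower = TRUE)
    } else {
      stop_config("unknown k_law type '", k_law$type,
                  "' (laws whose support includes 0 are not allowed)")
    }
    if (is.null(category_sampler)) {
      category_sampler <- function(k) {
        mu <- stats::rnorm(k)
        lapply(seq_len(k), function(j) {
          d <- response_distribution("normal", mean = mu[j], sd = 1)
          response_category(paste0("cat", j), 1 / k, d, d)
        })
      }
    }
    if (!is.function(category_sampler)) {
      stop_config("`category_sampler` must be a function(k)")
    }
  }
  structure(list(categories = categories, k_law = k_law,
                 dirichlet_alpha = dirichlet_alpha,
                 category_sampler = category_sampler,
                 dependence = dependence),
            class = "population_model")
}

# Symmetric Dirichlet draw via normalized gammas.
rdirichlet_sym <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  while (sum(g) <= 0) g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

#' Realize a category composition from a generating law
#'
#' Draws the number of categories `K`, the category definitions and a
#' symmetric-Dirichlet weight vector, returning a concrete category list with
#' weights summing to 1.  Two trials simulated from the same generating law
#' generally see different compositions — the source of between-trial
#' irreproducibility under heterogeneity.
#'
#' @param model A [population_model()] built with `k_law`.
#' @param seed Optional integer seed.
#' @return List of [response_category()] with realized weights.
#' @export
sample_category_composition <- function(model, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  if (is.null(model$k_law)) {
    stop_config("model has fixed categories; composition sampling requires ",
                "a category-generating law (`k_law`)")
  }
  with_seed(seed, {
    k <- switch(model$k_law$type,
      "constant" = as.integer(model$k_law$k),
      "poisson1" = 1L + stats::rpois(1L, model$k_law$lambda)
    )
    cats <- model$category_sampler(k)
    if (length(cats) != k ||
        !all(vapply(cats, inherits, TRUE, "response_category"))) {
      stop_config("`category_sampler` must return k response_category objects")
    }
    w <- rdirichlet_sym(k, model$dirichlet_alpha)
    for (j in seq_len(k)) cats[[j]]$weight <- w[j]
    cats
  })
}

# Draw one subject-arm response column for a category law, given cluster ids.
# Shared additive latent effect per cluster induces equicorrelation r.
draw_arm_responses <- function(law, cluster_id, icc) {
  n <- length(cluster_id)
  if (is.numeric(law)) {           # deterministic category
    if (icc > 0) {
      stop_config("intra-cluster correlation r > 0 is infeasible for a ",
                  "deterministic response (zero variance)")
    }
    return(rep(law, n))
  }
  if (icc == 0) return(dist_sample(law, n))
  if (law$family != "normal") {
    stop_config("intra-cluster correlation r > 0 is only supported for the ",
                "'normal' family (requested family: '", law$family, "')")
  }
  mu <- law$params$mean
  sg <- law$params$sd
  cl <- match(cluster_id, unique(cluster_id))
  g <- stats::rnorm(max(cl))
  mu + sg * (sqrt(icc) * g[cl] + sqrt(1 - icc) * stats::rnorm(n))
}

#' Sample a cohort of subjects with per-arm potential outcomes
#'
#' Draws `n` subjects from the population model.  Every subject receives a
#' category label, a cluster id and a pair of potential outcomes
#' `(y_arm0, y_arm1)` drawn once and for all — re-randomizing the same cohort
#' never re-draws outcomes, which is what makes sharp-null permutation
#' inference well defined.  Under clustered dependence, cluster sizes are
#' drawn from the configured law, each cluster belongs to one category, and
#' within-cluster responses have pairwise correlation `r` by the shared
#' additive latent effect construction.
#'
#' @param model A [population_model()].
#' @param n Number of subjects, `>= 1`.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `subject_id`, `cluster_id`,
#'   `category`, `y_arm0`, `y_arm1`.
#' @export
sample_subjects <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  n <- as.integer(check_scalar(n, "n", lower = 1, integerish = TRUE))
  with_seed(seed, {
    cats <- if (is.null(model$categories)) {
      sample_category_composition(model)
    } else {
      model$categories
    }
    w <- vapply(cats, `[[`, 0, "weight")
    w <- w / sum(w)                      # renormalize realized weights
    dep <- model$dependence

    if (dep$mode == "independent") {
      cluster_id <- seq_len(n)
    } else {
      sizes <- integer()
      while (sum(sizes) < n) {
        sizes <- c(sizes, draw_cluster_sizes(dep$cluster_size_law,
                                             max(8L, n %/% 2L)))
      }
      keep <- cumsum(sizes) - sizes < n   # truncate the final cluster at n
      sizes <- sizes[keep]
      sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
      cluster_id <- rep(seq_along(sizes), sizes)
    }

    n_clusters <- max(cluster_id)
    # clusters never span categories (unless explicitly allowed)
    if (dep$allow_cross_category) {
      cat_idx <- sample.int(length(cats), n, replace = TRUE, prob = w)
    } else {
      cl_cat <- sample.int(length(cats), n_clusters, replace = TRUE, prob = w)
      cat_idx <- cl_cat[cluster_id]
    }

    y0 <- numeric(n)
    y1 <- numeric(n)
    for (j in seq_along(cats)) {
      sel <- cat_idx == j
      if (!any(sel)) next
      y0[sel] <- draw_arm_responses(cats[[j]]$arm0, cluster_id[sel], dep$icc)
      y1[sel] <- draw_arm_responses(cats[[j]]$arm1, cluster_id[sel], dep$icc)
    }

    data.frame(subject_id = seq_len(n),
               cluster_id = cluster_id,
               category = vapply(cats, `[[`, "", "label")[cat_idx],
               y_arm0 = y0, y_arm1 = y1,
               stringsAsFactors = FALSE)
  })
}

#' Read and write subject tables
#'
#' Subject tables are plain tab-separated text with header
#' `subject_id, cluster_id, category, y_arm0, y_arm1` (simulated cohorts) or
#' the re-analysis layout `subject_id, cluster_id, category, arm, response`.
#'
#' @param subjects A subject `data.frame`.
#' @param path File path.
#' @return `read_subject_table` returns a `data.frame`;
#'   `write_subject_table` returns `path` invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
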