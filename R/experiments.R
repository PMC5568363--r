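# Operating-characteristic experiments and worked-example demos tying the
# population, trial and inference modules together.

#' Define an operating-characteristics scenario
#'
#' A scenario names a population model, a trial design, a p-value method and
#' a hypothesis.  Under `hypothesis = "null"` the sharp null is imposed by
#' construction: each subject's treatment-arm potential outcome is set equal
#' to the control-arm one, so any rejection is a false positive.  Under
#' `hypothesis = "shift"` a constant `shift` is added to every treatment-arm
#' outcome.
#'
#' @param model A [population_model()].
#' @param design A [trial_design()].
#' @param method `"parametric"`, `"permutation-exact"`, `"permutation-mc"` or
#'   `"perm-averaged-parametric"`.
#' @param hypothesis `"null"` (sharp null) or `"shift"`.
#' @param shift Treatment effect added under `"shift"`.
#' @param statistic Permutation statistic, `"delta"` (default) or `"z"`.
#' @param sided Sidedness of the test.
#' @param m Monte-Carlo allocations for `"permutation-mc"`.
#' @param limit Enumeration limit for exact permutation methods.
#' @param id Scenario label.
#' @return A list of class `oc_scenario`.
#' @export
oc_scenario <- function(model, design,
                        method = c("parametric", "permutation-exact",
                                   "permutation-mc",
                                   "perm-averaged-parametric"),
                        hypothesis = c("null", "shift"), shift = 0,
                        statistic = "delta", sided = "two-sided",
                        m = 199L, limit = 1e6, id = "scenario") {
  stopifnot(inherits(model, "population_model"),
            inherits(design, "trial_design"))
  structure(list(model = model, design = design, method = match.arg(method),
                 hypothesis = match.arg(hypothesis), shift = shift,
                 statistic = statistic, sided = sided, m = m, limit = limit,
                 id = id),
            class = "oc_scenario")
}

# One simulated trial -> one p-value, under the scenario's hypothesis.
simulate_one_pvalue <- function(sc) {
  subj <- sample_subjects(sc$model, sc$design$n)
  subj <- apply_sample_size_regime(subj, sc$design, model = sc$model)
  if (sc$hypothesis == "null") {
    subj$y_arm1 <- subj$y_arm0               # sharp null by construction
  } else if (sc$shift != 0) {
    subj$y_arm1 <- subj$y_arm1 + sc$shift
  }
  alloc <- randomize(subj, sc$design)
  trial <- realize_trial(subj, alloc, sc$design)
  switch(sc$method,
    "parametric" = if (trial$z_ok) parametric_pvalue(trial$z, sc$sided)
                   else NA_real_,
    "permutation-exact" = permutation_pvalue(trial, sc$design, sc$statistic,
                                             sc$sided, mode = "exact",
                                             limit = sc$limit)$p,
    "permutation-mc" = permutation_pvalue(trial, sc$design, sc$statistic,
                                          sc$sided, mode = "mc", m = sc$m)$p,
    "perm-averaged-parametric" =
      perm_averaged_parametric_pvalue(trial, sc$design, sc$sided,
                                      limit = sc$limit)$p
  )
}

#' Monte-Carlo operating characteristics of a testing procedure
#'
#' Simulates `n_reps` independent trials under the scenario and reports the
#' rejection rate at `alpha` with its Monte-Carlo standard error
#' `sqrt(r * (1 - r) / n_reps)`.  Under the sharp null the rejection rate is
#' the procedure's effective type-I error; under a shift it is power.
#' Replicates where the method's statistic is undefined (degenerate arms
#' under `"parametric"`) count as non-rejections and are tallied.
#'
#' @param scenario An [oc_scenario()].
#' @param n_reps Number of simulated trials (a warning below 100).
#' @param seed Optional integer seed; the whole simulation runs in one
#'   reproducible stream.
#' @param alpha Nominal significance threshold.
#' @return An object of class `operating_characteristics`.
#' @export
run_operating_characteristics <- function(scenario, n_reps, seed = NULL,
                                          alpha = 0.05) {
  stopifnot(inherits(scenario, "oc_scenario"))
  n_reps <- as.integer(check_scalar(n_reps, "n_reps", lower = 1,
                                    integerish = TRUE))
  if (n_reps < 100L) {
    warning("n_reps < 100 gives a very noisy rejection-rate estimate",
            call. = FALSE)
  }
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE,
               open_upper = TRUE)
  p <- with_seed(seed,
                 vapply(seq_len(n_reps), function(i) simulate_one_pvalue(scenario),
                        0))
  undefined <- sum(is.na(p))
  r <- sum(!is.na(p) & p <= alpha) / n_reps
  structure(list(scenario_id = scenario$id, method = scenario$method,
                 hypothesis = scenario$hypothesis,
                 nominal_alpha = alpha, n_reps = n_reps,
                 rejection_rate = r,
                 mc_standard_error = sqrt(r * (1 - r) / n_reps),
                 n_undefined = undefined, seed = seed),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics [%s]\n", x$scenario_id))
  cat(sprintf("  method          %s (%s hypothesis)\n", x$method,
              x$hypothesis))
  cat(sprintf("  rejection rate  %.4f (MC se %.4f) at alpha = %g over %d reps\n",
              x$rejection_rate, x$mc_standard_error, x$nominal_alpha,
              x$n_reps))
  if (x$n_undefined > 0L) {
    cat(sprintf("  undefined stat  %d replicates counted as non-rejections\n",
                x$n_undefined))
  }
  invisible(x)
}

#' The averaging fallacy: three drugs on a half-and-half population
#'
#' The built-in worked example.  Drug A has efficacy 2 on one half of the
#' population and 0 on the other; drug B the mirror image; drug C a uniform
#' 1.1.  C wins every comparison of population averages (1.1 vs 1.0) yet is
#' almost twice less effective than the better of A and B for every single
#' patient, whose best-of-{A, B} efficacy is 2.  "Best on average" is not
#' best for anyone.
#'
#' @return An object of class `averaging_fallacy` with the per-drug
#'   population averages, the per-patient best-of-{A, B} efficacy, the
#'   best-on-average drug and the per-patient efficacy ratio.
#' @examples
#' averaging_fallacy_demo()
#' @export
averaging_fallacy_demo <- function() {
  # the fixture: two equal subpopulations, deterministic per-drug efficacies
  weights <- c(half1 = 0.5, half2 = 0.5)
  efficacy <- rbind(A = c(2, 0), B = c(0, 2), C = c(1.1, 1.1))
  colnames(efficacy) <- names(weights)

  drug_average <- as.vector(efficacy %*% weights)
  names(drug_average) <- rownames(efficacy)
  # each patient's best achievable efficacy over {A, B}
  per_patient_best <- apply(efficacy[c("A", "B"), , drop = FALSE], 2, max)
  best_on_average <- names(drug_average)[which.max(drug_average)]

  stopifnot(
    # C strictly beats A and B on the average ...
    drug_average["C"] > max(drug_average[c("A", "B")]),
    # ... yet is strictly inferior to the per-patient best for every patient
    all(efficacy["C", ] < per_patient_best)
  )
  structure(list(drug_average = drug_average,
                 per_patient_best = unname(per_patient_best[1]),
                 best_on_average = best_on_average,
                 efficacy_ratio = unname(per_patient_best[1]) /
                   drug_average["C"][[1]],
                 subpopulation_weights = weights,
                 efficacy = efficacy),
            class = "averaging_fallacy")
}

#' @export
print.averaging_fallacy <- function(x, ...) {
  cat("Averaging fallacy demo (three drugs, half-and-half population)\n")
  cat("  population-average efficacy: ",
      paste(names(x$drug_average),
            format(x$drug_average, digits = 3), sep = " = ",
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  best on average:             drug %s\n", x$best_on_average))
  cat(sprintf("  per-patient best of {A, B}:  %g for every patient\n",
              x$per_patient_best))
  cat(sprintf("  ratio best-for-patient / C:  %.4g\n", x$efficacy_ratio))
  invisible(x)
}

#' Random sample size and the central limit theorem
#'
#' Compares the normal approximation of the standardized sum
#' `(S_N - nu * mu) / (sigma * sqrt(nu))`, where `nu = E[N]` is the sample
#' size the analyst planned for, across sample-size laws at matched expected
#' size: `"fixed"` (`N = nu`), `"poisson"` (`N ~ Poisson(nu)`) and
#' `"geometric"` (`N ~ 1 + Geom(1/nu)`).  Fixed and Poisson sizes leave the
#' statistic close to normal; geometric sizes drive it towards a
#' Laplace-type limit with a visibly larger KS distance — the statistic a
#' fixed-`n` method would use is simply wrong there.
#'
#' @param mean_n Expected sample size `nu` for every law.
#' @param dist Summand [response_distribution()]; default standard normal
#'   (zero mean, so the planned-size standardization is exactly centred).
#' @param reps Monte-Carlo replicates per law.
#' @param seed Optional seed.
#' @param laws Subset of `c("fixed", "poisson", "geometric")`.
#' @return A `data.frame` with columns `law`, `ks`, `mc_se`, `reps`,
#'   `mean_n`.
#' @export
random_sample_size_demo <- function(mean_n = 200,
                                    dist = response_distribution("normal"),
                                    reps = 5000L, seed = NULL,
                                    laws = c("fixed", "poisson",
                                             "geometric")) {
  stopifnot(inherits(dist, "response_distribution"))
  mean_n <- check_scalar(mean_n, "mean_n", lower = 1)
  reps <- as.integer(check_scalar(reps, "reps", lower = 100,
                                  integerish = TRUE))
  laws <- match.arg(laws, several.ok = TRUE)
  mu <- dist_mean(dist)
  sg <- dist_sd(dist)

  random_sum <- function(N) {
    if (dist$family == "normal") {
      # exact shortcut: a sum of k iid normals is normal
      mu * N + sg * sqrt(N) * stats::rnorm(length(N))
    } else {
      tot <- sum(N)
      x <- dist_sample(dist, tot)
      grp <- rep.int(seq_along(N), N)
      s <- numeric(length(N))
      agg <- rowsum(x, grp)
      s[as.integer(rownames(agg))] <- agg
      s
    }
  }

  with_seed(seed, {
    rows <- lapply(laws, function(law) {
      N <- switch(law,
        "fixed"     = rep.int(as.integer(round(mean_n)), reps),
        "poisson"   = stats::rpois(reps, mean_n),
        "geometric" = 1L + stats::rgeom(reps, 1 / mean_n)
      )
      S <- random_sum(N)
      z <- (S - mean_n * mu) / (sg * sqrt(mean_n))
      data.frame(law = law, ks = ks_stat_normal(z),
                 mc_se = 0.5 / sqrt(reps), reps = reps, mean_n = mean_n)
    })
    do.call(rbind, rows)
  })
}

# --- declarative configs and report bundles ---------------------------------

#' Build package objects from declarative configuration lists
#'
#' Configurations are JSON documents (see `inst/extdata/` for shipped
#' examples).  A population config has `categories` (each with `label`,
#' `weight` and per-arm laws given either as a number or as
#' `{family, params...}`) or a generating law `{k_law, dirichlet_alpha}`,
#' plus an optional `dependence` block.  A design config mirrors the
#' [trial_design()] arguments.
#'
#' @param cfg A list parsed from JSON (or the path of a JSON file).
#' @return A [population_model()] / [trial_design()].
#' @export
model_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = FALSE)
  if (!is.null(cfg$population)) cfg <- cfg$population
  law_from <- function(x) {
    if (is.numeric(x) && length(x) == 1L) return(x)
    if (is.list(x) && !is.null(x$family)) {
      args <- x[setdiff(names(x), "family")]
      args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
      return(do.call(response_distribution, c(list(family = x$family), args)))
    }
    stop_config("cannot interpret a response law from the config")
  }
  dep <- if (is.null(cfg$dependence)) dependence_spec() else {
    d <- cfg$dependence
    dependence_spec(mode = d$mode %||% "independent",
                    cluster_size_law = d$cluster_size_law %||%
                      list(type = "constant", size = 2L),
                    icc = d$icc %||% 0)
  }
  if (!is.null(cfg$categories)) {
    cats <- lapply(cfg$categories, function(cc) {
      response_category(cc$label, cc$weight, law_from(cc$arm0),
                        law_from(cc$arm1))
    })
    population_model(categories = cats, dependence = dep)
  } else if (!is.null(cfg$k_law)) {
    population_model(k_law = cfg$k_law,
                     dirichlet_alpha = cfg$dirichlet_alpha %||% 1,
                     dependence = dep)
  } else {
    stop_config("population config needs `categories` or `k_law`")
  }
}

#' @rdname model_from_config
#' @export
design_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = FALSE)
  if (!is.null(cfg$design)) cfg <- cfg$design
  trial_design(n = cfg$n,
               allocation = cfg$allocation %||% "complete-balanced",
               block_length = cfg$block_length %||% 4L,
               regime = cfg$regime %||% "fixed",
               lambda = cfg$lambda,
               retention = cfg$retention %||% 1,
               event_threshold = cfg$event_threshold,
               event_target = cfg$event_target,
               pooled_variance = isTRUE(cfg$pooled_variance))
}

scenario_from_config <- function(cfg) {
  oc_scenario(model = model_from_config(cfg),
              design = design_from_config(cfg),
              method = cfg$method %||% "parametric",
              hypothesis = cfg$hypothesis %||% "null",
              shift = cfg$shift %||% 0,
              statistic = cfg$statistic %||% "delta",
              sided = cfg$sided %||% "two-sided",
              m = cfg$m %||% 199L,
              limit = cfg$limit %||% 1e6,
              id = cfg$id %||% "scenario")
}

#' Run a named bundle of experiments and write delimited-text tables
#'
#' Executes the scenarios listed in a config (a list or a JSON file path) and
#' writes one tab-separated table per experiment plus a JSON manifest with
#' the config hash, seed and package version.  Re-running with the same
#' config and seed reproduces every table byte-for-byte.
#'
#' Experiment types: `"oc"` (operating characteristics; needs a population,
#' design, method and `n_reps`), `"demo-averaging"` and `"demo-random-n"`.
#'
#' @param config A list with an `experiments` list, or a JSON file path.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; experiment `i` runs under `seed + i`.
#' @return Invisibly, the manifest list.
#' @export
run_report <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  experiments <- config$experiments %||% list()
  known <- c("oc", "demo-averaging", "demo-random-n")

  tables <- character()
  for (i in seq_along(experiments)) {
    ex <- experiments[[i]]
    id <- ex$id %||% paste0("experiment", i)
    type <- ex$type %||% "oc"
    if (!type %in% known) {
      stop_config("unknown experiment type '", type, "'; available: ",
                  paste(known, collapse = ", "))
    }
    ex_seed <- (seed + i) %% .Machine$integer.max
    tab <- switch(type,
      "oc" = {
        sc <- scenario_from_config(ex)
        oc <- run_operating_characteristics(sc, n_reps = ex$n_reps %||% 1000L,
                                            seed = ex_seed,
                                            alpha = ex$alpha %||% 0.05)
        data.frame(scenario = oc$scenario_id, method = oc$method,
                   hypothesis = oc$hypothesis, alpha = oc$nominal_alpha,
                   n_reps = oc$n_reps, rejection_rate = oc$rejection_rate,
                   mc_standard_error = oc$mc_standard_error,
                   n_undefined = oc$n_undefined, seed = ex_seed)
      },
      "demo-averaging" = {
        demo <- averaging_fallacy_demo()
        data.frame(drug = names(demo$drug_average),
                   population_average = as.vector(demo$drug_average),
                   per_patient_best = demo$per_patient_best,
                   best_on_average = demo$best_on_average)
      },
      "demo-random-n" = {
        random_sample_size_demo(mean_n = ex$mean_n %||% 200,
                                reps = ex$reps %||% 5000L, seed = ex_seed)
      }
    )
    path <- file.path(out_dir, paste0(id, ".tsv"))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tables <- c(tables, path)
  }

  cfg_path <- file.path(out_dir, "config.echo.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest <- list(
    package = "permtrial",
    version = as.character(utils::packageVersion("permtrial")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    tables = basename(tables),
    table_md5 = unname(tools::md5sum(tables))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
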