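#' Hierarchical prior for the race model
#'
#' Loads (or builds) the prior on the group-level distribution of each of
#' the 11 race-model parameters. Participant parameters are drawn from
#' independent truncated normals (positive parameters) or normals on the
#' probit scale (the two failure probabilities); the prior specifies, per
#' parameter, a truncated-normal prior on the group mean and a
#' truncated-normal (at zero) prior on the group SD.
#'
#' `default_priors()` reads the versioned YAML file shipped with the
#' package (`inst/priors/default_priors.yaml`). Only the three location
#' means for `mu_go_match` (1.5 s), `mu_go_mismatch` (1.5 s) and `mu_stop`
#' (1 s) are study-stated; the remaining locations and scales are
#' implementation defaults.
#'
#' @param path path to a YAML prior file with `mean:` and `sd:` blocks.
#' @return an object of class `hierarchical_prior`.
#' @examples
#' pr <- default_priors()
#' pr$mean_loc["mu_stop"]
#' @export
read_priors <- function(path) {
  y <- yaml::read_yaml(path)
  nm <- race_param_names()
  stopifnot(all(nm %in% names(y$mean)), all(nm %in% names(y$sd)))
  structure(list(
    mean_loc = vapply(y$mean[nm], `[[`, numeric(1), "loc"),
    mean_scale = vapply(y$mean[nm], `[[`, numeric(1), "scale"),
    sd_loc = vapply(y$sd[nm], `[[`, numeric(1), "loc"),
    sd_scale = vapply(y$sd[nm], `[[`, numeric(1), "scale"),
    positive = setNames(!(nm %in% c("p_tf", "p_gf")), nm),
    source = path
  ), class = "hierarchical_prior")
}

#' @rdname read_priors
#' @export
default_priors <- function() {
  read_priors(system.file("priors", "default_priors.yaml", package = "ssrace"))
}

#' Sampler configuration for the hierarchical fit
#'
#' Differential-evolution MCMC settings. By default the sampler runs three
#' chains per free participant-level parameter (33 for the full
#' 11-parameter model), thins to every 10th iteration, attempts a
#' migration step with probability 0.05 per iteration, and runs an
#' adaptive burn-in in chunks until every group-level split-chain R-hat
#' falls below `rhat_threshold`, after which `final_iterations` retained
#' (post-thinning) iterations per chain form the reported posterior.
#'
#' @param n_chains number of chains; `NULL` means 3 x number of free
#'   participant-level parameters.
#' @param thin keep every `thin`-th iteration.
#' @param migration_prob per-iteration probability of a migration step.
#' @param migration_chunks migration runs only during this many initial
#'   burn-in chunks; afterwards the population evolves by crossover alone
#'   so that migration cannot collapse chain diversity.
#' @param burn_chunk retained iterations per burn-in chunk between
#'   convergence checks.
#' @param max_burn_chunks burn-in budget; exceeding it flags the fit
#'   non-converged (sampling still proceeds).
#' @param rhat_window retained burn-in iterations used for the convergence
#'   check.
#' @param final_iterations retained iterations forming the posterior.
#' @param rhat_threshold convergence criterion on all group-level
#'   parameters.
#' @param jitter uniform proposal jitter half-width.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = NULL, thin = 10L,
                           migration_prob = 0.05, migration_chunks = 4L,
                           burn_chunk = 25L,
                           max_burn_chunks = 10L, rhat_window = 100L,
                           final_iterations = 500L, rhat_threshold = 1.1,
                           jitter = 1e-3) {
  stopifnot(migration_prob >= 0, migration_prob <= 1, thin >= 1)
  structure(list(n_chains = n_chains, thin = as.integer(thin),
                 migration_prob = migration_prob,
                 migration_chunks = as.integer(migration_chunks),
                 burn_chunk = as.integer(burn_chunk),
                 max_burn_chunks = as.integer(max_burn_chunks),
                 rhat_window = as.integer(rhat_window),
                 final_iterations = as.integer(final_iterations),
                 rhat_threshold = rhat_threshold, jitter = jitter),
            class = "sampler_config")
}
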