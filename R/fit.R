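#' Fit the hierarchical ex-Gaussian race model
#'
#' Differential-evolution MCMC (DE-MCMC) estimation of the race model with
#' trigger/go-failure mixtures. Participant-level parameters are drawn from
#' group-level truncated normals (probit-normals for the failure
#' probabilities). Each iteration updates, per participant, the stop block
#' (stop runner + trigger failure) and the go block (both go runners + go
#' failure) with crossover proposals across chains; the group-level
#' (mean, log SD) pair of every parameter with its own crossover; and one
#' runner block with an interweaved group-affine move that shifts the
#' group mean and rescales the group SD together with every participant's
#' value (this lets the sampler traverse the hierarchical funnel of weakly
#' identified parameters). Early in burn-in a migration step runs with
#' probability `config$migration_prob` to recycle stuck chains; migration
#' is then disabled so it cannot collapse the chain diversity that drives
#' the crossover proposals. Burn-in is adaptive: the sampler runs in
#' chunks until the split-chain R-hat of every group-level parameter falls
#' below `config$rhat_threshold`, then retains `config$final_iterations`
#' thinned iterations per chain as the posterior. Fit each group (e.g.
#' controls, patient-placebo, patient-atomoxetine) separately with
#' identical priors.
#'
#' @param trials preprocessed tidy trial table for one group, with columns
#'   `subject`, `kind`, `ssd`, `stimulus`, `response`, `rt` (at least two
#'   participants).
#' @param prior a [read_priors()] object.
#' @param config a [sampler_config()].
#' @param fix optional named list of parameters held at fixed natural-scale
#'   values (e.g. `list(p_tf = 0)` to ignore trigger failures); fixed
#'   parameters are removed from sampling.
#' @param seed integer seed; fits are deterministic given it.
#' @param verbose print chunk-level progress.
#' @return an object of class `race_fit` with retained draws
#'   (`group_draws`: iteration x chain x parameter, group SDs on the
#'   natural scale; `participant_draws`: iteration x chain x parameter x
#'   subject, probabilities on the probit scale), an `rhat` table, and
#'   convergence metadata. Use [tidy()], [glance()], [derive_ssrt()],
#'   [posterior_predictive()].
#' @export
fit_race_model <- function(trials, prior = default_priors(),
                           config = sampler_config(), fix = NULL,
                           seed = 1L, verbose = FALSE) {
  stopifnot(inherits(prior, "hierarchical_prior"),
            inherits(config, "sampler_config"))
  need <- c("subject", "kind", "ssd", "stimulus", "response", "rt")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  subjects <- sort(unique(trials$subject))
  if (length(subjects) < 2) stop("need at least 2 participants", call. = FALSE)
  data <- lapply(subjects, function(s) {
    prep_participant_data(trials[trials$subject == s, , drop = FALSE])
  })
  npart <- length(subjects)

  all_names <- race_param_names()
  if (!is.null(fix) && !all(names(fix) %in% all_names)) {
    stop("unknown parameter in `fix`", call. = FALSE)
  }
  active <- setdiff(all_names, names(fix))
  n_act <- length(active)
  pos <- which(prior$positive[active])
  nch <- if (is.null(config$n_chains)) 3L * n_act else
    as.integer(config$n_chains)
  if (nch < 4L) stop("need at least 4 chains for DE proposals", call. = FALSE)
  jit <- config$jitter

  set.seed(derive_seed(seed, "fit"))

  # ---- initialisation: per-participant method-of-moments centres with
  # per-chain jitter (the sampler needs the right scale, not the answer)
  theta <- array(NA_real_, c(nch, n_act, npart))
  for (i in seq_len(npart)) {
    init_i <- crude_init(trials[trials$subject == subjects[i], ,
                                drop = FALSE])[active]
    for (k in seq_len(n_act)) {
      v <- init_i[[k]]
      theta[, k, i] <- if (k %in% pos) v * exp(rnorm(nch, 0, 0.15)) else
        v + rnorm(nch, 0, 0.3)
    }
  }
  init <- crude_init(trials)[active]
  phi_m <- matrix(NA_real_, nch, n_act)    # group means, natural scale
  phi_ls <- matrix(NA_real_, nch, n_act)   # group SDs, log scale
  for (k in seq_len(n_act)) {
    v <- init[[k]]
    phi_m[, k] <- if (k %in% pos) v * exp(rnorm(nch, 0, 0.15)) else
      v + rnorm(nch, 0, 0.3)
    s0 <- if (k %in% pos) pmax(0.15 * abs(v), 0.02) else 0.3
    phi_ls[, k] <- log(s0) + rnorm(nch, 0, 0.3)
  }
  group_names <- c(paste0("mean_", active), paste0("sd_", active))

  loglik_go_i <- function(th_mat, i) {
    parmat <- build_parmat(th_mat, active, fix)
    d <- data[[i]]
    race_loglik_go_cpp(parmat, d$go_rt, d$go_match, d$n_go_omit)
  }
  loglik_sig_i <- function(th_mat, i) {
    parmat <- build_parmat(th_mat, active, fix)
    d <- data[[i]]
    race_loglik_sig_cpp(parmat, d$sr_rt, d$sr_ssd, d$sr_match, d$inh_ssd)
  }

  # caches: per-chain go-trial and stop/no-go log-likelihood components,
  # per-(chain, param, participant) log prior density, per-(chain, param)
  # hyper-prior density
  ll_go <- matrix(NA_real_, nch, npart)
  ll_sig <- matrix(NA_real_, nch, npart)
  prk <- array(NA_real_, c(nch, n_act, npart))
  for (i in seq_len(npart)) {
    th_i <- theta[, , i, drop = FALSE][, , 1]
    ll_go[, i] <- loglik_go_i(th_i, i)
    ll_sig[, i] <- loglik_sig_i(th_i, i)
    prk[, , i] <- theta_ldens(th_i, phi_m, exp(phi_ls), pos)
  }
  hyper_k <- hyper_ldens(phi_m, phi_ls, prior, active, pos)

  gamma2 <- 2.38 / sqrt(4)          # group (mean, log SD) pairs
  # participant sub-blocks: stop runner + p_tf touches only the stop/no-go
  # likelihood component; the go block touches both
  pb_stop <- which(active %in% c("mu_stop", "sigma_stop", "tau_stop", "p_tf"))
  pb_gm <- which(active %in% c("mu_go_match", "sigma_go_match",
                               "tau_go_match", "p_gf"))
  pb_gx <- which(active %in% c("mu_go_mismatch", "sigma_go_mismatch",
                               "tau_go_mismatch"))
  # affine runner blocks
  blk_defs <- list(c("mu_stop", "sigma_stop", "tau_stop", "p_tf"),
                   c("mu_go_match", "sigma_go_match", "tau_go_match", "p_gf"),
                   c("mu_go_mismatch", "sigma_go_mismatch",
                     "tau_go_mismatch"))
  blocks <- lapply(blk_defs, function(b) which(active %in% b))
  keep <- vapply(blocks, length, 1L) > 0
  blocks <- blocks[keep]
  block_sig_only <- vapply(blocks, function(b) all(b %in% pb_stop),
                           logical(1))
  # the matching go runner is well identified and mixes without help, so
  # its (expensive) affine move runs only on a subset of iterations
  block_prob <- vapply(blocks, function(b) {
    if (any(active[b] %in% c("mu_go_match", "p_gf"))) 1 / 3 else 1
  }, numeric(1))
  acc_count <- c(group = 0, affine = 0, participant = 0)
  try_count <- c(group = 0, affine = 0, participant = 0)

  update_participant_block <- function(i, B, sig_only) {
    th0 <- theta[, , i, drop = FALSE][, , 1]
    prop <- th0
    prop[, B] <- de_propose(th0[, B, drop = FALSE],
                            2.38 / sqrt(2 * length(B)), jit)
    ldB <- theta_ldens(prop[, B, drop = FALSE], phi_m[, B, drop = FALSE],
                       exp(phi_ls[, B, drop = FALSE]),
                       which(B %in% pos))
    pr_new <- rowSums(ldB)
    pr_old <- rowSums(matrix(prk[, B, i], nch))
    ok <- is.finite(pr_new)
    sig_new <- rep(-Inf, nch)
    go_new <- ll_go[, i]
    if (any(ok)) {
      sig_new[ok] <- loglik_sig_i(prop[ok, , drop = FALSE], i)
      if (!sig_only) {
        go_new <- rep(-Inf, nch)
        go_new[ok] <- loglik_go_i(prop[ok, , drop = FALSE], i)
      }
    }
    d_acc <- (go_new + sig_new + pr_new) -
      (ll_go[, i] + ll_sig[, i] + pr_old)
    acc <- ok & (log(runif(nch)) < d_acc)
    acc_count["participant"] <<- acc_count["participant"] + sum(acc)
    try_count["participant"] <<- try_count["participant"] + nch
    if (any(acc)) {
      theta[acc, B, i] <<- prop[acc, B, drop = FALSE]
      ll_sig[acc, i] <<- sig_new[acc]
      if (!sig_only) ll_go[acc, i] <<- go_new[acc]
      prk[acc, B, i] <<- ldB[acc, , drop = FALSE]
    }
  }

  one_iteration <- function(migrate_ok) {
    if (migrate_ok && runif(1) < config$migration_prob) {
      n_mig <- sample.int(nch, 1)
      if (n_mig >= 2) {
        sel <- sample.int(nch, n_mig)
        src <- sel[c(n_mig, seq_len(n_mig - 1L))]
        post <- rowSums(ll_go) + rowSums(ll_sig) + apply(prk, 1, sum) +
          rowSums(hyper_k)
        acc <- log(runif(n_mig)) < (post[src] - post[sel])
        take <- sel[acc]
        from <- src[acc]
        if (length(take)) {
          theta[take, , ] <<- theta[from, , , drop = FALSE]
          phi_m[take, ] <<- phi_m[from, , drop = FALSE]
          phi_ls[take, ] <<- phi_ls[from, , drop = FALSE]
          ll_go[take, ] <<- ll_go[from, , drop = FALSE]
          ll_sig[take, ] <<- ll_sig[from, , drop = FALSE]
          prk[take, , ] <<- prk[from, , , drop = FALSE]
          hyper_k[take, ] <<- hyper_k[from, , drop = FALSE]
        }
      }
      return(invisible())
    }
    # group-level crossover, one (mean, log SD) pair per parameter;
    # repeated sweeps are cheap (no likelihood) and decorrelate the group
    # block given the participant values
    for (sweep in 1:3) for (k in seq_len(n_act)) {
      X <- cbind(phi_m[, k], phi_ls[, k])
      prop <- de_propose(X, gamma2, jit)
      hy_prop <- hyper_ldens_k(prop[, 1], prop[, 2], prior, active[k],
                               k %in% pos)
      th_k <- theta[, k, ]                     # nch x npart
      pr_prop <- col_ldens(th_k, prop[, 1], exp(prop[, 2]), k %in% pos)
      d_new <- hy_prop + rowSums(pr_prop)
      d_old <- hyper_k[, k] + rowSums(matrix(prk[, k, ], nch))
      acc <- log(runif(nch)) < (d_new - d_old)
      acc[!is.finite(d_new)] <- FALSE
      acc_count["group"] <<- acc_count["group"] + sum(acc)
      try_count["group"] <<- try_count["group"] + nch
      if (any(acc)) {
        phi_m[acc, k] <<- prop[acc, 1]
        phi_ls[acc, k] <<- prop[acc, 2]
        hyper_k[acc, k] <<- hy_prop[acc]
        prk[acc, k, ] <<- pr_prop[acc, , drop = FALSE]
      }
    }
    # interweaved group-affine moves, one per runner block
    for (bi in sample.int(length(blocks))) {
    if (runif(1) > block_prob[bi]) next
    B <- blocks[[bi]]
    nb <- length(B)
    sig_only <- block_sig_only[bi]
    D <- cbind(phi_m[, B, drop = FALSE], phi_ls[, B, drop = FALSE])
    delta <- de_propose(D, 1.19 / sqrt(2 * 2 * nb), jit) - D
    dm <- delta[, seq_len(nb), drop = FALSE]
    ds <- delta[, nb + seq_len(nb), drop = FALSE]
    M_new <- phi_m[, B, drop = FALSE] + dm
    ls_new <- phi_ls[, B, drop = FALSE] + ds
    S_new <- exp(ls_new)
    scl <- exp(ds)
    hy_prop <- matrix(NA_real_, nch, nb)
    for (j in seq_len(nb)) {
      hy_prop[, j] <- hyper_ldens_k(M_new[, j], ls_new[, j], prior,
                                    active[B[j]], B[j] %in% pos)
    }
    d_acc <- rowSums(hy_prop) - rowSums(hyper_k[, B, drop = FALSE]) +
      npart * rowSums(ds)
    th_prop <- vector("list", npart)
    pr_prop <- vector("list", npart)
    for (i in seq_len(npart)) {
      thi <- theta[, , i, drop = FALSE][, , 1]
      thi[, B] <- M_new + (thi[, B, drop = FALSE] -
                             phi_m[, B, drop = FALSE]) * scl
      ldB <- theta_ldens(thi[, B, drop = FALSE], M_new, S_new,
                         which(B %in% pos))
      th_prop[[i]] <- thi
      pr_prop[[i]] <- ldB
      d_acc <- d_acc + rowSums(ldB) - rowSums(matrix(prk[, B, i], nch))
    }
    okc <- is.finite(d_acc)
    if (any(okc)) {
      sig_new <- matrix(-Inf, nch, npart)
      go_new <- ll_go
      for (i in seq_len(npart)) {
        sig_new[okc, i] <- loglik_sig_i(th_prop[[i]][okc, , drop = FALSE], i)
        if (!sig_only) {
          go_new[, i] <- -Inf
          go_new[okc, i] <- loglik_go_i(th_prop[[i]][okc, , drop = FALSE], i)
        }
      }
      d_acc <- d_acc + rowSums(sig_new) - rowSums(ll_sig) +
        rowSums(go_new) - rowSums(ll_go)
      acc <- okc & (log(runif(nch)) < d_acc)
      acc_count["affine"] <<- acc_count["affine"] + sum(acc)
      try_count["affine"] <<- try_count["affine"] + nch
      if (any(acc)) {
        phi_m[acc, B] <<- M_new[acc, , drop = FALSE]
        phi_ls[acc, B] <<- ls_new[acc, , drop = FALSE]
        hyper_k[acc, B] <<- hy_prop[acc, , drop = FALSE]
        ll_sig[acc, ] <<- sig_new[acc, , drop = FALSE]
        if (!sig_only) ll_go[acc, ] <<- go_new[acc, , drop = FALSE]
        for (i in seq_len(npart)) {
          theta[acc, B, i] <<- th_prop[[i]][acc, B, drop = FALSE]
          prk[acc, B, i] <<- pr_prop[[i]][acc, , drop = FALSE]
        }
      }
    }
    }
    # participant-level sub-block crossovers
    for (i in seq_len(npart)) {
      if (length(pb_stop)) update_participant_block(i, pb_stop, TRUE)
      if (length(pb_gm)) update_participant_block(i, pb_gm, FALSE)
      if (length(pb_gx)) update_participant_block(i, pb_gx, FALSE)
    }
    invisible()
  }

  record_phi <- function() cbind(phi_m, exp(phi_ls))

  # ---- adaptive burn-in (migration active early) -------------------------
  max_burn <- config$max_burn_chunks * config$burn_chunk
  burn_buf <- array(NA_real_, c(max_burn, nch, 2L * n_act))
  n_burn <- 0L
  converged <- FALSE
  for (chunk in seq_len(config$max_burn_chunks)) {
    for (r in seq_len(config$burn_chunk)) {
      for (s in seq_len(config$thin)) {
        one_iteration(migrate_ok = chunk <= config$migration_chunks)
      }
      n_burn <- n_burn + 1L
      burn_buf[n_burn, , ] <- record_phi()
    }
    win <- min(config$rhat_window, n_burn)
    idx <- (n_burn - win + 1L):n_burn
    rh <- if (win >= 4L) {
      apply(burn_buf[idx, , , drop = FALSE], 3, rhat_split)
    } else {
      Inf  # window too short to assess convergence
    }
    if (verbose) {
      message(sprintf("burn-in chunk %d: max R-hat = %.3f | acc %s",
                      chunk, max(rh),
                      paste(names(acc_count),
                            sprintf("%.2f", acc_count / pmax(try_count, 1)),
                            collapse = " ")))
    }
    # only declare convergence from a window that contains no
    # migration-era draws (migration homogenises chains and would make
    # the criterion too lenient)
    clean_from <- config$migration_chunks +
      ceiling(config$rhat_window / config$burn_chunk)
    if (chunk >= clean_from && all(rh < config$rhat_threshold)) {
      converged <- TRUE
      break
    }
  }

  # ---- final posterior (no migration) ------------------------------------
  nfin <- config$final_iterations
  group_draws <- array(NA_real_, c(nfin, nch, 2L * n_act),
                       dimnames = list(NULL, NULL, group_names))
  part_draws <- array(NA_real_, c(nfin, nch, n_act, npart),
                      dimnames = list(NULL, NULL, active, subjects))
  for (r in seq_len(nfin)) {
    for (s in seq_len(config$thin)) one_iteration(migrate_ok = FALSE)
    group_draws[r, , ] <- record_phi()
    part_draws[r, , , ] <- theta
  }

  rh_final <- if (nfin >= 4L) {
    apply(group_draws, 3, rhat_split)
  } else {
    rep(NA_real_, 2L * n_act)  # too few retained draws for split R-hat
  }
  structure(list(
    group_draws = group_draws,
    participant_draws = part_draws,
    rhat = tibble::tibble(parameter = group_names, rhat = rh_final),
    converged = converged,
    max_rhat = if (all(is.na(rh_final))) NA_real_ else max(rh_final),
    burn_iterations = n_burn * config$thin,
    subjects = subjects,
    active = active,
    fix = fix,
    config = config,
    prior = prior,
    acceptance = acc_count / pmax(try_count, 1),
    seed = seed
  ), class = "race_fit")
}

# split trial table into the compiled likelihood's sufficient arrays
prep_participant_data <- function(tr) {
  responded <- !is.na(tr$response) & tr$response != "none"
  go <- tr$kind == "go"
  sig <- !go
  list(
    go_rt = tr$rt[go & responded],
    go_match = as.integer(tr$response[go & responded] ==
                            tr$stimulus[go & responded]),
    n_go_omit = sum(go & !responded),
    sr_rt = tr$rt[sig & responded],
    sr_ssd = tr$ssd[sig & responded],
    sr_match = as.integer(tr$response[sig & responded] ==
                            tr$stimulus[sig & responded]),
    inh_ssd = tr$ssd[sig & !responded]
  )
}

# method-of-moments starting centres; the sampler only needs rough scale
crude_init <- function(trials) {
  responded <- !is.na(trials$rt)
  go_rt <- trials$rt[trials$kind == "go" & responded]
  mg <- if (length(go_rt)) mean(go_rt) else 0.6
  sg <- if (length(go_rt) > 1) sd(go_rt) else 0.15
  ssd <- trials$ssd[trials$kind == "stop"]
  mssd <- if (any(is.finite(ssd))) mean(ssd, na.rm = TRUE) else 0.3
  ssrt0 <- clamp(mg - mssd, 0.15, 0.6)
  omit_rate <- mean(is.na(trials$rt[trials$kind == "go"]))
  list(mu_stop = 0.7 * ssrt0, sigma_stop = 0.05, tau_stop = 0.3 * ssrt0,
       mu_go_match = max(0.2, mg - 0.5 * sg),
       sigma_go_match = max(0.04, 0.5 * sg),
       tau_go_match = max(0.05, 0.5 * sg),
       mu_go_mismatch = mg + 0.4, sigma_go_mismatch = 0.2,
       tau_go_mismatch = 0.3,
       p_tf = qnorm(0.05),
       p_gf = qnorm(clamp(omit_rate + 0.01, 0.005, 0.3)))
}

# DE crossover proposal: x + gamma (x_r1 - x_r2) + U(-jit, jit), with the
# step size drawn uniformly in [0.5, 1] times the optimal 2.38 / sqrt(2d)
de_propose <- function(X, gamma, jit) {
  nch <- nrow(X)
  d <- ncol(X)
  idx <- seq_len(nch)
  # partner 1: uniform over the other chains
  r1 <- sample.int(nch - 1L, nch, replace = TRUE)
  r1 <- r1 + (r1 >= idx)
  # partner 2: uniform over the chains excluding self and partner 1
  lo <- pmin(idx, r1)
  hi <- pmax(idx, r1)
  r2 <- sample.int(nch - 2L, nch, replace = TRUE)
  r2 <- r2 + (r2 >= lo)
  r2 <- r2 + (r2 >= hi)
  g <- gamma * runif(nch, 0.5, 1)
  X + g * (X[r1, , drop = FALSE] - X[r2, , drop = FALSE]) +
    matrix(runif(nch * d, -jit, jit), nch, d)
}

# natural-scale 11-column parameter matrix from active sampling-scale block
build_parmat <- function(th_mat, active, fix) {
  nch <- nrow(th_mat)
  all_names <- race_param_names()
  parmat <- matrix(NA_real_, nch, 11L, dimnames = list(NULL, all_names))
  for (k in seq_along(active)) {
    v <- th_mat[, k]
    if (active[k] %in% c("p_tf", "p_gf")) v <- pnorm(v)
    parmat[, active[k]] <- v
  }
  for (nm in names(fix)) parmat[, nm] <- fix[[nm]]
  parmat
}

# log density matrix of theta (nch x n_act) under TN(M, S, >0) columns
# (plain normal for probit columns)
theta_ldens <- function(th, M, S, pos) {
  ld <- dnorm(th, M, S, log = TRUE)
  if (length(pos)) {
    corr <- pnorm(0, M[, pos, drop = FALSE], S[, pos, drop = FALSE],
                  lower.tail = FALSE, log.p = TRUE)
    sub <- ld[, pos, drop = FALSE] - corr
    sub[th[, pos, drop = FALSE] <= 0] <- -Inf
    ld[, pos] <- sub
  }
  ld
}

# same for a single parameter: theta column block (nch x m), M/S vectors
col_ldens <- function(th_k, M, S, positive) {
  ld <- dnorm(th_k, M, S, log = TRUE)
  if (positive) {
    ld <- ld - pnorm(0, M, S, lower.tail = FALSE, log.p = TRUE)
    ld[th_k <= 0] <- -Inf
  }
  ld
}

# hyper-prior density per (chain, parameter): TN prior on the group mean
# plus TN(>0) prior on the group SD evaluated on the log scale (Jacobian)
hyper_ldens <- function(phi_m, phi_ls, prior, active, pos) {
  out <- matrix(NA_real_, nrow(phi_m), length(active))
  for (k in seq_along(active)) {
    out[, k] <- hyper_ldens_k(phi_m[, k], phi_ls[, k], prior, active[k],
                              k %in% pos)
  }
  out
}

hyper_ldens_k <- function(m, ls, prior, name, positive) {
  ldm <- dnorm(m, prior$mean_loc[name], prior$mean_scale[name], log = TRUE)
  if (positive) {
    ldm <- ldm - pnorm(0, prior$mean_loc[name], prior$mean_scale[name],
                       lower.tail = FALSE, log.p = TRUE)
    ldm[m <= 0] <- -Inf
  }
  s <- exp(ls)
  lds <- dnorm(s, prior$sd_loc[name], prior$sd_scale[name], log = TRUE) -
    pnorm(0, prior$sd_loc[name], prior$sd_scale[name],
          lower.tail = FALSE, log.p = TRUE) + ls
  ldm + lds
}

#' @export
print.race_fit <- function(x, ...) {
  cat("Hierarchical ex-Gaussian race model fit\n")
  cat(sprintf("  %d participants, %d chains, %d retained iterations\n",
              length(x$subjects), dim(x$group_draws)[2],
              dim(x$group_draws)[1]))
  cat(sprintf("  burn-in: %d iterations; converged: %s; max R-hat: %.3f\n",
              x$burn_iterations, x$converged, x$max_rhat))
  invisible(x)
}

#' @export
tidy.race_fit <- function(x, ...) {
  draws <- x$group_draws
  purrr::map_dfr(dimnames(draws)[[3]], function(p) {
    v <- as.numeric(draws[, , p])
    tibble::tibble(term = p, estimate = median(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  }) |>
    dplyr::left_join(x$rhat, by = c(term = "parameter"))
}

#' @export
glance.race_fit <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$subjects),
                 n_chains = dim(x$group_draws)[2],
                 n_retained = dim(x$group_draws)[1],
                 burn_iterations = x$burn_iterations,
                 max_rhat = x$max_rhat,
                 converged = x$converged)
}
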