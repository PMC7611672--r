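#' Split-chain potential scale reduction statistic
#'
#' Gelman-Rubin R-hat with each chain split in half, comparing between- and
#' within-chain variance. Values near 1 indicate convergence; the fit
#' criterion is < 1.1 for all group-level parameters. A set of identical
#' constant chains returns exactly 1.
#'
#' @param draws an iterations x chains matrix, or a `race_fit`.
#' @param ... unused.
#' @return a number (matrix method) or a tibble of per-parameter values
#'   (`race_fit` method).
#' @examples
#' rhat(matrix(rnorm(4000), 1000, 4))  # ~ 1
#' @export
rhat <- function(draws, ...) UseMethod("rhat")

#' @export
rhat.matrix <- function(draws, ...) rhat_split(draws)

#' @export
rhat.race_fit <- function(draws, ...) draws$rhat

rhat_split <- function(mat) {
  n <- nrow(mat)
  if (n < 4L || ncol(mat) < 2L) {
    stop("need at least 4 iterations and 2 chains", call. = FALSE)
  }
  half <- n %/% 2L
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

#' Posterior SSRT and go-RT draws
#'
#' The stop-signal reaction time is the mean of the stop runner's
#' ex-Gaussian finish-time distribution, `mu_stop + tau_stop`, computed per
#' MCMC sample to give a posterior distribution; go RT is likewise
#' `mu_go_match + tau_go_match`.
#'
#' @param fit a [fit_race_model()] result.
#' @param level `"group"` (group-level means) or `"participant"`.
#' @param what `"ssrt"` or `"go_rt"`.
#' @return a tibble of posterior draws with columns `iteration`, `chain`,
#'   `value` (and `subject` at participant level). Summarise with
#'   [posterior_summary()].
#' @export
derive_ssrt <- function(fit, level = c("group", "participant"),
                        what = c("ssrt", "go_rt")) {
  stopifnot(inherits(fit, "race_fit"))
  level <- match.arg(level)
  what <- match.arg(what)
  parts <- if (what == "ssrt") c("mu_stop", "tau_stop") else
    c("mu_go_match", "tau_go_match")
  if (level == "group") {
    v <- fit$group_draws[, , paste0("mean_", parts[1])] +
      fit$group_draws[, , paste0("mean_", parts[2])]
    dn <- dim(fit$group_draws)
    tibble::tibble(iteration = rep(seq_len(dn[1]), dn[2]),
                   chain = rep(seq_len(dn[2]), each = dn[1]),
                   value = as.numeric(v))
  } else {
    if (!all(parts %in% fit$active)) {
      stop("participant-level parameters ", paste(parts, collapse = "+"),
           " were fixed in this fit", call. = FALSE)
    }
    dn <- dim(fit$participant_draws)
    purrr::map_dfr(seq_along(fit$subjects), function(i) {
      v <- fit$participant_draws[, , parts[1], i] +
        fit$participant_draws[, , parts[2], i]
      tibble::tibble(subject = fit$subjects[i],
                     iteration = rep(seq_len(dn[1]), dn[2]),
                     chain = rep(seq_len(dn[2]), each = dn[1]),
                     value = as.numeric(v))
    })
  }
}

#' Summarise posterior draws
#'
#' Posterior median and central 95% quantile interval, per subject when a
#' `subject` column is present.
#'
#' @param draws a tibble with a `value` column (e.g. from [derive_ssrt()]).
#' @param level quantile-interval mass.
#' @return a tibble with `median`, `qi_low`, `qi_high`.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  keys <- intersect("subject", names(draws))
  draws |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(median = median(.data$value),
                     qi_low = unname(quantile(.data$value, a)),
                     qi_high = unname(quantile(.data$value, 1 - a)),
                     .groups = "drop")
}

#' Posterior contrast between two sets of MCMC samples
#'
#' Element-wise difference `a - b` between two posterior sample vectors
#' (e.g. group-level SSRT draws from two separate fits), giving an
#' approximate posterior of the difference. If the runs have unequal
#' length, the longer is subsampled (evenly spaced, deterministic) to
#' match. The difference is "reliably different from zero" when the 95%
#' quantile interval excludes 0.
#'
#' @param draws_a,draws_b numeric vectors of posterior samples, or tibbles
#'   with a `value` column.
#' @param level quantile-interval mass.
#' @return an object of class `posterior_contrast` with elements `draws`,
#'   `median`, `qi_low`, `qi_high`, `reliable`; `tidy()` gives a one-row
#'   tibble.
#' @export
posterior_contrast <- function(draws_a, draws_b, level = 0.95) {
  a <- if (is.data.frame(draws_a)) draws_a$value else as.numeric(draws_a)
  b <- if (is.data.frame(draws_b)) draws_b$value else as.numeric(draws_b)
  n <- min(length(a), length(b))
  thin_to <- function(x) x[round(seq(1, length(x), length.out = n))]
  d <- thin_to(a) - thin_to(b)
  alpha <- (1 - level) / 2
  qi <- unname(quantile(d, c(alpha, 1 - alpha)))
  structure(list(draws = d, median = median(d), qi_low = qi[1],
                 qi_high = qi[2], level = level,
                 reliable = qi[1] > 0 || qi[2] < 0),
            class = "posterior_contrast")
}

#' @export
print.posterior_contrast <- function(x, ...) {
  cat(sprintf("Posterior contrast: median %.3f, %d%% QI [%.3f, %.3f]%s\n",
              x$median, round(100 * x$level), x$qi_low, x$qi_high,
              if (x$reliable) " (reliably different from zero)" else ""))
  invisible(x)
}

#' @export
tidy.posterior_contrast <- function(x, ...) {
  tibble::tibble(estimate = x$median, conf.low = x$qi_low,
                 conf.high = x$qi_high, reliable = x$reliable)
}

#' Posterior predictive check
#'
#' Simulates datasets from draws of the participant-level posterior, using
#' the observed trial structure (trial kinds, SSDs and stimuli are held
#' fixed; only responses are regenerated), and summarises predicted
#' go-RT deciles, signal-respond RT deciles and the inhibition function
#' (stop accuracy against SSD bins) with 95% predictive bands for
#' comparison against the observed summaries.
#'
#' @param fit a [fit_race_model()] result.
#' @param trials the observed trial table the model was fitted to.
#' @param n_draws number of posterior draws to simulate from.
#' @param seed integer seed.
#' @return an object of class `ssrt_ppc`: a list of tibbles `go_deciles`,
#'   `sr_deciles`, `inhibition` with observed values and predictive bands.
#'   Plot with [autoplot()].
#' @export
posterior_predictive <- function(fit, trials, n_draws = 100, seed = 1L) {
  stopifnot(inherits(fit, "race_fit"))
  set.seed(derive_seed(seed, "ppc"))
  dn <- dim(fit$participant_draws)
  pick <- cbind(sample.int(dn[1], n_draws, replace = TRUE),
                sample.int(dn[2], n_draws, replace = TRUE))
  sims <- purrr::map(seq_len(n_draws), function(j) {
    sim <- purrr::map_dfr(seq_along(fit$subjects), function(i) {
      p <- draw_to_params(fit, pick[j, 1], pick[j, 2], i)
      tr <- trials[trials$subject == fit$subjects[i], , drop = FALSE]
      simulate_fixed_trials(tr, p)
    })
    ppc_summaries(sim)
  })
  obs <- ppc_summaries(trials)
  band <- function(field, keyvars) {
    pred <- dplyr::bind_rows(purrr::map(sims, field))
    pred |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keyvars))) |>
      dplyr::summarise(pred_low = unname(quantile(.data$value, 0.025,
                                                  na.rm = TRUE)),
                       pred_med = median(.data$value, na.rm = TRUE),
                       pred_high = unname(quantile(.data$value, 0.975,
                                                   na.rm = TRUE)),
                       .groups = "drop") |>
      dplyr::left_join(dplyr::rename(obs[[field]], observed = "value"),
                       by = keyvars)
  }
  structure(list(go_deciles = band("go_deciles", "decile"),
                 sr_deciles = band("sr_deciles", "decile"),
                 inhibition = band("inhibition", "ssd_bin")),
            class = "ssrt_ppc")
}

# map one retained draw to a race_params for subject i (probit -> prob)
draw_to_params <- function(fit, iter, chain, i) {
  v <- fit$participant_draws[iter, chain, , i]
  names(v) <- fit$active
  out <- as.list(v)
  for (nm in intersect(c("p_tf", "p_gf"), names(out))) {
    out[[nm]] <- pnorm(out[[nm]])
  }
  for (nm in names(fit$fix)) out[[nm]] <- fit$fix[[nm]]
  do.call(race_params, out[race_param_names()])
}

# regenerate responses on a fixed trial/SSD structure (no staircase)
simulate_fixed_trials <- function(trials, params,
                                  response_window = 4.5) {
  n <- nrow(trials)
  gf <- runif(n) < params$p_gf
  t_m <- rexgauss(n, params$mu_go_match, params$sigma_go_match,
                  params$tau_go_match)
  t_x <- rexgauss(n, params$mu_go_mismatch, params$sigma_go_mismatch,
                  params$tau_go_mismatch)
  go_time <- ifelse(gf, Inf, pmin(t_m, t_x))
  match_win <- !gf & t_m <= t_x
  other <- ifelse(trials$stimulus == "left", "right", "left")
  go_side <- ifelse(match_win, trials$stimulus, other)
  is_sig <- trials$kind != "go"
  tf <- runif(n) < params$p_tf
  stop_time <- ifelse(is_sig & !tf,
                      trials$ssd + rexgauss(n, params$mu_stop,
                                            params$sigma_stop,
                                            params$tau_stop), Inf)
  responded <- is.finite(go_time) & go_time <= response_window &
    (!is_sig | go_time < stop_time)
  out <- trials
  out$response <- ifelse(responded, go_side, NA_character_)
  out$rt <- ifelse(responded, go_time, NA_real_)
  out
}

ppc_summaries <- function(trials) {
  dec <- seq(0.1, 0.9, by = 0.1)
  go_rt <- trials$rt[trials$kind == "go" & !is.na(trials$rt)]
  sr_rt <- trials$rt[trials$kind == "stop" & !is.na(trials$rt)]
  stop_tr <- trials[trials$kind == "stop", , drop = FALSE]
  bins <- quantile(stop_tr$ssd, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  bins <- unique(bins)
  bin_id <- if (length(bins) > 1) {
    cut(stop_tr$ssd, bins, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, nrow(stop_tr))
  }
  inh <- tapply(is.na(stop_tr$response) | stop_tr$response == "none",
                bin_id, mean)
  list(
    go_deciles = tibble::tibble(decile = dec,
                                value = unname(quantile(go_rt, dec,
                                                        na.rm = TRUE))),
    sr_deciles = tibble::tibble(decile = dec,
                                value = if (length(sr_rt) >= 5) {
                                  unname(quantile(sr_rt, dec))
                                } else rep(NA_real_, length(dec))),
    inhibition = tibble::tibble(ssd_bin = as.integer(names(inh)),
                                value = as.numeric(inh))
  )
}

#' @export
autoplot.ssrt_ppc <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$go_deciles, panel = "go RT deciles",
                  x = .data$decile),
    dplyr::mutate(object$sr_deciles, panel = "signal-respond RT deciles",
                  x = .data$decile),
    dplyr::mutate(object$inhibition, panel = "inhibition function",
                  x = as.numeric(.data$ssd_bin))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred_low,
                                      ymax = .data$pred_high),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_med),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Posterior predictive check",
                  subtitle = "points: observed; band: 95% predictive interval")
}
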