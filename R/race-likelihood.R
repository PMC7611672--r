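#' Trial-level log-likelihoods under the ex-Gaussian race model
#'
#' Probability machinery for the three-runner race with attentional
#' failures. On a go trial a response on side `s` at time `t` has defective
#' density `(1 - p_gf) f_s(t) S_other(t)`; an omission has probability
#' `p_gf`. On stop and no-go trials (no-go is a stop trial with SSD 0) a
#' response additionally requires that the stop runner either never
#' launched (probability `p_tf`) or had not finished by `t`, giving the
#' right-censoring factor `p_tf + (1 - p_tf) S_stop(t - d)`; a successfully
#' inhibited trial has probability
#' `p_gf + (1 - p_gf)(1 - p_tf) P(stop wins)`, where `P(stop wins)` is the
#' integral of the stop finish density against both go survivals.
#'
#' `stop_inhibit_loglik()` evaluates that integral by adaptive quadrature
#' ([stats::integrate()]) to absolute tolerance `abs_tol`; the vectorised
#' fast path used by [trial_loglik()] and the sampler uses fixed composite
#' Gauss-Legendre quadrature (the two agree to well below either
#' tolerance).
#'
#' @param rt response time, seconds (vector).
#' @param response `"left"`, `"right"` or `NA` for an omission.
#' @param stimulus `"left"` or `"right"`.
#' @param ssd stop-signal delay, seconds (0 for no-go trials).
#' @param params a [race_params()].
#' @param abs_tol absolute tolerance for the adaptive quadrature.
#' @return log-probability vector; `-Inf` marks impossible observations
#'   (samplers reject rather than error).
#' @examples
#' p <- race_params()
#' go_trial_loglik(0.5, "left", "left", p)
#' stop_inhibit_loglik(0.2, p)
#' @name race-loglik
NULL

#' @rdname race-loglik
#' @export
go_trial_loglik <- function(rt, response, stimulus, params) {
  stopifnot(inherits(params, "race_params"))
  n <- max(length(rt), length(response), length(stimulus))
  rt <- rep_len(rt, n)
  response <- rep_len(response, n)
  stimulus <- rep_len(stimulus, n)
  out <- numeric(n)
  omit <- is.na(response) | response == "none"
  out[omit] <- ifelse(params$p_gf > 0, log(params$p_gf), -Inf)
  if (any(!omit)) {
    i <- which(!omit)
    out[i] <- responded_go_ll(rt[i], response[i] == stimulus[i], params)
    out[i][rt[i] < 0 | !is.finite(rt[i])] <- -Inf
  }
  out
}

# density of a response at rt from the winning go runner (log scale)
responded_go_ll <- function(rt, match, params) {
  win <- ifelse(match, "go_match", "go_mismatch")
  lose <- ifelse(match, "go_mismatch", "go_match")
  log1p(-params$p_gf) +
    exg_logpdf_cpp(rt, pvec(params, "mu", win), pvec(params, "sigma", win),
                   pvec(params, "tau", win)) +
    exg_logsf_cpp(rt, pvec(params, "mu", lose), pvec(params, "sigma", lose),
                  pvec(params, "tau", lose))
}

# element-wise parameter lookup for a character vector of runner names
pvec <- function(params, stat, runner) {
  vapply(runner, function(r) params[[paste0(stat, "_", r)]], numeric(1),
         USE.NAMES = FALSE)
}

#' @rdname race-loglik
#' @export
stop_respond_loglik <- function(rt, ssd, response, stimulus, params) {
  stopifnot(inherits(params, "race_params"))
  n <- max(length(rt), length(ssd), length(response), length(stimulus))
  rt <- rep_len(rt, n); ssd <- rep_len(ssd, n)
  response <- rep_len(response, n); stimulus <- rep_len(stimulus, n)
  if (any(rt < 0, na.rm = TRUE)) stop("negative response times", call. = FALSE)
  base <- responded_go_ll(rt, response == stimulus, params)
  surv_stop <- exp(exg_logsf_cpp(rt - ssd, params$mu_stop, params$sigma_stop,
                                 params$tau_stop))
  cens <- params$p_tf + (1 - params$p_tf) * surv_stop
  out <- base + ifelse(cens > 0, log(cens), -Inf)
  out[is.na(response) | response == "none"] <- NA_real_
  out
}

#' @rdname race-loglik
#' @export
stop_inhibit_loglik <- function(ssd, params, abs_tol = 1e-9) {
  stopifnot(inherits(params, "race_params"))
  vapply(ssd, function(d) {
    p_race <- if (params$p_tf >= 1) 0 else inhibit_prob_quad(d, params, abs_tol)
    p <- params$p_gf + (1 - params$p_gf) * (1 - params$p_tf) * p_race
    if (p > 0) log(p) else -Inf
  }, numeric(1))
}

# adaptive-quadrature inhibition probability (reference path)
inhibit_prob_quad <- function(d, params, abs_tol = 1e-9) {
  f <- function(u) {
    dexgauss(u, params$mu_stop, params$sigma_stop, params$tau_stop) *
      sexgauss(d + u, params$mu_go_match, params$sigma_go_match,
               params$tau_go_match) *
      sexgauss(d + u, params$mu_go_mismatch, params$sigma_go_mismatch,
               params$tau_go_mismatch)
  }
  res <- tryCatch(
    integrate(f, lower = -Inf, upper = Inf, abs.tol = abs_tol,
              rel.tol = abs_tol * 100, subdivisions = 500L),
    error = function(e) {
      stop("quadrature for the inhibition integral failed at ssd = ", d,
           ": ", conditionMessage(e), call. = FALSE)
    })
  min(max(res$value, 0), 1)
}

#' Per-trial and dataset log-likelihood for a trial table
#'
#' `trial_loglik()` appends a `loglik` column to a tidy trial table;
#' `dataset_loglik()` returns the sum (0 for an empty table; `-Inf`
#' propagates). Both use the compiled likelihood path shared with the
#' sampler.
#'
#' @param trials tibble with columns `kind`, `ssd`, `stimulus`, `response`,
#'   `rt` (as produced by [simulate_participant()]).
#' @param params a [race_params()].
#' @return `trial_loglik()`: the tibble with a `loglik` column;
#'   `dataset_loglik()`: a single number.
#' @export
trial_loglik <- function(trials, params) {
  stopifnot(inherits(params, "race_params"))
  n <- nrow(trials)
  ll <- numeric(n)
  is_go <- trials$kind == "go"
  is_sig <- !is_go
  responded <- !is.na(trials$response) & trials$response != "none"
  if (any(is_go)) {
    ll[is_go] <- go_trial_loglik(trials$rt[is_go], trials$response[is_go],
                                 trials$stimulus[is_go], params)
  }
  sr <- is_sig & responded
  if (any(sr)) {
    ll[sr] <- stop_respond_loglik(trials$rt[sr], trials$ssd[sr],
                                  trials$response[sr], trials$stimulus[sr],
                                  params)
  }
  inh <- is_sig & !responded
  if (any(inh)) {
    p_race <- if (params$p_tf >= 1) {
      rep(0, sum(inh))
    } else {
      inhibit_prob_cpp(trials$ssd[inh],
                       c(params$mu_stop, params$sigma_stop, params$tau_stop),
                       c(params$mu_go_match, params$sigma_go_match,
                         params$tau_go_match),
                       c(params$mu_go_mismatch, params$sigma_go_mismatch,
                         params$tau_go_mismatch))
    }
    p <- params$p_gf + (1 - params$p_gf) * (1 - params$p_tf) * p_race
    ll[inh] <- ifelse(p > 0, log(p), -Inf)
  }
  dplyr::mutate(trials, loglik = ll)
}

#' @rdname trial_loglik
#' @export
dataset_loglik <- function(trials, params) {
  if (nrow(trials) == 0) return(0)
  sum(trial_loglik(trials, params)$loglik)
}

#' Reaction-time preprocessing rule
#'
#' Responded trials with implausibly short (< `rt_floor`) or long
#' (> `rt_ceiling`) RTs are removed first; then, among the surviving go-trial
#' RTs only, values more extreme than `sd_mult` SDs from that
#' participant-session's go-RT mean are removed. Omissions are untouched,
#' and signal-respond RTs are not subject to the SD rule.
#'
#' @param rt_floor,rt_ceiling absolute plausibility bounds, seconds.
#' @param sd_mult SD multiplier for the go-RT trim.
#' @export
preprocess_rule <- function(rt_floor = 0.25, rt_ceiling = 4.5,
                            sd_mult = 2.5) {
  stopifnot(rt_floor < rt_ceiling, sd_mult > 0)
  structure(list(rt_floor = rt_floor, rt_ceiling = rt_ceiling,
                 sd_mult = sd_mult), class = "preprocess_rule")
}

#' Trim implausible and outlying reaction times
#'
#' Applies a [preprocess_rule()] to a trial table. If the table contains
#' `subject`/`session`/`drug` columns the SD rule is applied within each
#' participant-session; otherwise the whole table is treated as one
#' session. The removed-trial counts are attached as the `"trim_report"`
#' attribute (see [trim_report()]).
#'
#' @param trials a tidy trial table.
#' @param rule a [preprocess_rule()].
#' @return the kept trials, with a `trim_report` attribute.
#' @export
preprocess_rts <- function(trials, rule = preprocess_rule()) {
  stopifnot(inherits(rule, "preprocess_rule"))
  keys <- intersect(c("subject", "group", "session", "drug"), names(trials))
  if (length(keys) == 0) {
    trials$.grp <- 1L
    keys <- ".grp"
  }
  parts <- dplyr::group_split(dplyr::group_by(trials,
                                              dplyr::across(dplyr::all_of(keys))))
  kept <- list()
  reports <- list()
  for (p in parts) {
    responded <- !is.na(p$rt)
    abs_bad <- responded & (p$rt < rule$rt_floor | p$rt > rule$rt_ceiling)
    p2 <- p[!abs_bad, , drop = FALSE]
    go_rts <- p2$rt[p2$kind == "go" & !is.na(p2$rt)]
    sd_bad <- rep(FALSE, nrow(p2))
    if (length(go_rts) < 2) {
      warning("fewer than 2 go RTs; SD trimming skipped", call. = FALSE)
    } else {
      m <- mean(go_rts)
      s <- sd(go_rts)
      lim <- rule$sd_mult * s
      sd_bad <- p2$kind == "go" & !is.na(p2$rt) & abs(p2$rt - m) > lim
    }
    kept[[length(kept) + 1]] <- p2[!sd_bad, , drop = FALSE]
    rep_row <- p[1, keys, drop = FALSE]
    rep_row$n_in <- nrow(p)
    rep_row$removed_bounds <- sum(abs_bad)
    rep_row$removed_sd <- sum(sd_bad)
    rep_row$n_out <- nrow(p) - sum(abs_bad) - sum(sd_bad)
    reports[[length(reports) + 1]] <- rep_row
  }
  out <- dplyr::bind_rows(kept)
  out$.grp <- NULL
  report <- dplyr::bind_rows(reports)
  report$.grp <- NULL
  attr(out, "trim_report") <- tibble::as_tibble(report)
  out
}

#' @rdname preprocess_rts
#' @param trials_out a table returned by `preprocess_rts()`.
#' @export
trim_report <- function(trials_out) {
  attr(trials_out, "trim_report")
}
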