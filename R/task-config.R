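#' Stop-signal task configuration
#'
#' Parameters of the stop-signal go/no-go design: four blocks of 140 trials
#' (110 go, 10 no-go, 20 stop), a 20-trial all-go lead-in per block used to
#' set the starting stop-signal delay (mean lead-in RT minus 200 ms), and an
#' adaptive staircase that moves the SSD by 50 ms within \[50, 1500\] ms to
#' target 50% stop accuracy. No-go trials carry an SSD of zero.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block; must equal
#'   `go_per_block + nogo_per_block + stop_per_block`.
#' @param go_per_block,nogo_per_block,stop_per_block per-block trial counts.
#' @param lead_go_trials go trials opening each block (SSD calibration).
#' @param ssd_min,ssd_max,ssd_step staircase range and step, seconds.
#' @param ssd_start_offset subtracted from the mean lead-in go RT to obtain
#'   the starting SSD, seconds.
#' @param max_consec_go,max_consec_signal run-length limits in the
#'   interleaved remainder of a block (signal = no-go and stop pooled).
#' @param fixation fixation-cross duration, seconds (bookkeeping only).
#' @param response_window seconds after stimulus onset before a trial is
#'   scored as an omission; matches the upper RT plausibility bound.
#' @param staircase_continues logical; if `TRUE` the staircase carries its
#'   final SSD over to the next block instead of restarting from the
#'   lead-in rule.
#' @return an object of class `task_config` (a validated named list).
#' @examples
#' cfg <- task_config()
#' cfg$stop_per_block
#' @export
task_config <- function(n_blocks = 4L, trials_per_block = 140L,
                        go_per_block = 110L, nogo_per_block = 10L,
                        stop_per_block = 20L, lead_go_trials = 20L,
                        ssd_min = 0.050, ssd_max = 1.500, ssd_step = 0.050,
                        ssd_start_offset = 0.200, max_consec_go = 7L,
                        max_consec_signal = 2L, fixation = 0.500,
                        response_window = 4.5,
                        staircase_continues = FALSE) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    go_per_block = as.integer(go_per_block),
    nogo_per_block = as.integer(nogo_per_block),
    stop_per_block = as.integer(stop_per_block),
    lead_go_trials = as.integer(lead_go_trials),
    ssd_min = ssd_min, ssd_max = ssd_max, ssd_step = ssd_step,
    ssd_start_offset = ssd_start_offset,
    max_consec_go = as.integer(max_consec_go),
    max_consec_signal = as.integer(max_consec_signal),
    fixation = fixation, response_window = response_window,
    staircase_continues = isTRUE(staircase_continues)
  )
  if (cfg$go_per_block + cfg$nogo_per_block + cfg$stop_per_block !=
      cfg$trials_per_block) {
    stop("go + no-go + stop counts must sum to `trials_per_block`",
         call. = FALSE)
  }
  if (cfg$ssd_min > cfg$ssd_max) stop("ssd_min must be <= ssd_max", call. = FALSE)
  if (cfg$ssd_step <= 0) stop("ssd_step must be positive", call. = FALSE)
  if (cfg$lead_go_trials > cfg$go_per_block) {
    stop("lead_go_trials cannot exceed go_per_block", call. = FALSE)
  }
  structure(cfg, class = "task_config")
}

#' Race-model parameters for one participant
#'
#' Ex-Gaussian finish-time parameters for the three racing processes (stop,
#' stimulus-matching go, mismatching go) plus the two attentional-failure
#' probabilities: `p_tf`, the probability that the stop process fails to
#' launch on a stop/no-go trial ("trigger failure"), and `p_gf`, the
#' probability that the go processes fail to launch ("go failure",
#' producing an omission).
#'
#' @param mu_stop,sigma_stop,tau_stop stop runner, seconds.
#' @param mu_go_match,sigma_go_match,tau_go_match matching go runner.
#' @param mu_go_mismatch,sigma_go_mismatch,tau_go_mismatch mismatching go
#'   runner (commission errors).
#' @param p_tf,p_gf failure probabilities in \[0, 1\].
#' @return an object of class `race_params`.
#' @examples
#' race_params(mu_stop = 0.2, tau_stop = 0.05)
#' @export
race_params <- function(mu_stop = 0.25, sigma_stop = 0.04, tau_stop = 0.12,
                        mu_go_match = 0.55, sigma_go_match = 0.08,
                        tau_go_match = 0.15,
                        mu_go_mismatch = 0.95, sigma_go_mismatch = 0.25,
                        tau_go_mismatch = 0.35,
                        p_tf = 0.05, p_gf = 0.02) {
  p <- list(mu_stop = mu_stop, sigma_stop = sigma_stop, tau_stop = tau_stop,
            mu_go_match = mu_go_match, sigma_go_match = sigma_go_match,
            tau_go_match = tau_go_match,
            mu_go_mismatch = mu_go_mismatch,
            sigma_go_mismatch = sigma_go_mismatch,
            tau_go_mismatch = tau_go_mismatch,
            p_tf = p_tf, p_gf = p_gf)
  mus <- unlist(p[c("mu_stop", "mu_go_match", "mu_go_mismatch")])
  sds <- unlist(p[grepl("^sigma|^tau", names(p))])
  if (any(mus <= 0) || any(sds <= 0)) {
    stop("mu, sigma and tau must all be strictly positive", call. = FALSE)
  }
  if (p$p_tf < 0 || p$p_tf > 1 || p$p_gf < 0 || p$p_gf > 1) {
    stop("p_tf and p_gf must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race-model parameters (ex-Gaussian runners, seconds):\n")
  for (r in c("stop", "go_match", "go_mismatch")) {
    cat(sprintf("  %-12s mu = %.3f  sigma = %.3f  tau = %.3f\n", r,
                x[[paste0("mu_", r)]], x[[paste0("sigma_", r)]],
                x[[paste0("tau_", r)]]))
  }
  cat(sprintf("  p_tf = %.3f  p_gf = %.3f\n", x$p_tf, x$p_gf))
  invisible(x)
}

# canonical 11-parameter order used throughout the package
race_param_names <- function() {
  c("mu_stop", "sigma_stop", "tau_stop",
    "mu_go_match", "sigma_go_match", "tau_go_match",
    "mu_go_mismatch", "sigma_go_mismatch", "tau_go_mismatch",
    "p_tf", "p_gf")
}

as_param_vector <- function(params) {
  unlist(params[race_param_names()])
}
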