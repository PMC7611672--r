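#' Generate a stop-signal task trial sequence
#'
#' Builds the trial list for one run of the task: every block opens with
#' `lead_go_trials` go trials (used to calibrate the starting SSD), and the
#' remaining go/no-go/stop trials are pseudorandomly interleaved under the
#' run-length constraints (no more than `max_consec_go` consecutive go
#' trials; no more than `max_consec_signal` consecutive signal trials,
#' pooling no-go and stop). Interleavings are drawn by seeded rejection
#' resampling with a bounded retry count.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the sequence is a deterministic function of it.
#' @param max_tries shuffle attempts per block before giving up.
#' @return a tibble with columns `block`, `trial`, `kind` (go/nogo/stop),
#'   `ssd` (NA for go and for stop trials before simulation; 0 for no-go),
#'   `stimulus` (left/right), `response` (NA), `rt` (NA).
#' @examples
#' trials <- generate_trial_sequence(task_config(), seed = 1)
#' dplyr::count(trials, block, kind)
#' @export
generate_trial_sequence <- function(config = task_config(), seed = 1L,
                                    max_tries = 10000L) {
  stopifnot(inherits(config, "task_config"))
  set.seed(as.integer(seed))
  labels <- c("go", "nogo", "stop")
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    rest <- c(rep(1L, config$go_per_block - config$lead_go_trials),
              rep(2L, config$nogo_per_block),
              rep(3L, config$stop_per_block))
    nr <- length(rest)
    ok <- FALSE
    for (i in seq_len(max_tries)) {
      cand <- rest[sample.int(nr)]
      if (runs_ok(cand != 1L, config$max_consec_go,
                  config$max_consec_signal)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not satisfy run-length constraints in ", max_tries,
           " attempts; relax the configuration", call. = FALSE)
    }
    kind <- c(rep("go", config$lead_go_trials), labels[cand])
    tibble::tibble(
      block = b,
      trial = seq_along(kind),
      kind = kind,
      ssd = ifelse(kind == "nogo", 0, NA_real_),
      stimulus = sample(c("left", "right"), length(kind), replace = TRUE),
      response = NA_character_,
      rt = NA_real_
    )
  })
  dplyr::bind_rows(blocks)
}

# run-length constraint check via signal positions: a go run is a gap
# between consecutive signals; a signal run of length max_signal + 1
# exists iff two signal positions max_signal apart are max_signal indices
# apart in the sequence. `sig` is the logical is-signal vector.
runs_ok <- function(sig, max_go, max_signal) {
  s <- which(sig)
  n <- length(sig)
  if (length(s) == 0) return(n <= max_go)
  if (max(diff(c(0L, s, n + 1L)) - 1L) > max_go) return(FALSE)
  m <- length(s) - max_signal
  if (m >= 1L &&
      any(s[(max_signal + 1L):length(s)] - s[seq_len(m)] == max_signal)) {
    return(FALSE)
  }
  TRUE
}

#' One step of the adaptive SSD staircase
#'
#' After a successful stop the SSD increases by one step (stopping is made
#' harder); after a failed stop it decreases by one step. The delay
#' saturates at the configured bounds.
#'
#' @param ssd current stop-signal delay, seconds.
#' @param stop_success logical; was the response successfully inhibited?
#' @param config a [task_config()].
#' @return updated SSD in `[ssd_min, ssd_max]`.
#' @examples
#' staircase_update(0.30, TRUE)   # 0.35
#' staircase_update(1.50, TRUE)   # clamped at 1.50
#' @export
staircase_update <- function(ssd, stop_success, config = task_config()) {
  step <- ifelse(stop_success, config$ssd_step, -config$ssd_step)
  clamp(ssd + step, config$ssd_min, config$ssd_max)
}

#' Starting SSD from the lead-in go trials
#'
#' The staircase starts at the mean lead-in go reaction time minus
#' `ssd_start_offset` (200 ms by default), clamped to the staircase range.
#' Omitted trials carry no RT and must be excluded before calling.
#'
#' @param lead_go_rts non-empty vector of lead-in go RTs, seconds.
#' @inheritParams staircase_update
#' @return starting SSD, seconds.
#' @export
initial_ssd <- function(lead_go_rts, config = task_config()) {
  lead_go_rts <- lead_go_rts[is.finite(lead_go_rts)]
  if (length(lead_go_rts) == 0) {
    stop("no lead-in go RTs available to set the starting SSD", call. = FALSE)
  }
  clamp(mean(lead_go_rts) - config$ssd_start_offset,
        config$ssd_min, config$ssd_max)
}

#' Simulate one participant performing the task
#'
#' Plays an agent defined by [race_params()] through a generated trial
#' sequence. On go trials the matching and mismatching go runners race
#' (unless a go failure occurs, which yields an omission); the faster
#' runner determines response side and RT. On stop and no-go trials the
#' stop runner joins the race after the trial's SSD unless a trigger
#' failure occurs; a response is emitted only if the winning go time beats
#' the stop finish time. The SSD follows the staircase online, starting
#' from [initial_ssd()] on the block's lead-in go RTs (no-go trials use
#' SSD = 0 and do not move the staircase). Responses slower than
#' `config$response_window` are scored as omissions.
#'
#' @param params a [race_params()].
#' @inheritParams generate_trial_sequence
#' @return tibble of trials with `ssd`, `response` and `rt` filled in.
#' @examples
#' trials <- simulate_participant(race_params(), task_config(), seed = 7)
#' mean(is.na(trials$response[trials$kind == "stop"]))  # ~ 0.5
#' @export
simulate_participant <- function(params, config = task_config(), seed = 1L) {
  stopifnot(inherits(params, "race_params"))
  trials <- generate_trial_sequence(config, seed = seed)
  set.seed(derive_seed(seed, "simulate"))
  n <- nrow(trials)
  kind <- trials$kind
  stimulus <- trials$stimulus

  # go-runner outcomes are independent of the staircase, so draw them for
  # every trial in one pass; only signal trials need the sequential loop
  gf <- runif(n) < params$p_gf
  t_match <- rexgauss(n, params$mu_go_match, params$sigma_go_match,
                      params$tau_go_match)
  t_mism <- rexgauss(n, params$mu_go_mismatch, params$sigma_go_mismatch,
                     params$tau_go_mismatch)
  go_time <- ifelse(gf, Inf, pmin(t_match, t_mism))
  other <- ifelse(stimulus == "left", "right", "left")
  go_side <- ifelse(!gf & t_match <= t_mism, stimulus, other)

  is_go <- kind == "go"
  go_resp <- is_go & is.finite(go_time) & go_time <= config$response_window
  response <- ifelse(go_resp, go_side, NA_character_)
  rt <- ifelse(go_resp, go_time, NA_real_)
  ssd_out <- trials$ssd

  is_sig <- which(!is_go)
  tf <- runif(length(is_sig)) < params$p_tf
  stop_draw <- rexgauss(length(is_sig), params$mu_stop, params$sigma_stop,
                        params$tau_stop)

  ssd <- NA_real_  # staircase state; set once the lead-in completes
  for (b in seq_len(config$n_blocks)) {
    in_block <- trials$block == b
    if (!config$staircase_continues || b == 1L) {
      lead <- which(in_block & is_go &
                      trials$trial <= config$lead_go_trials)
      ssd <- if (any(is.finite(rt[lead]))) {
        initial_ssd(rt[lead], config)
      } else {
        NA_real_  # no usable lead-in RT; stop trials fall back to ssd_min
      }
    }
    for (j in which(in_block[is_sig])) {
      i <- is_sig[j]
      d <- if (kind[i] == "nogo") 0 else if (is.na(ssd)) config$ssd_min
      else ssd
      stop_time <- if (tf[j]) Inf else d + stop_draw[j]
      responded <- is.finite(go_time[i]) && go_time[i] < stop_time &&
        go_time[i] <= config$response_window
      if (responded) {
        response[i] <- go_side[i]
        rt[i] <- go_time[i]
      }
      ssd_out[i] <- d
      if (kind[i] == "stop") ssd <- staircase_update(d, !responded, config)
    }
  }
  trials$ssd <- ssd_out
  trials$response <- response
  trials$rt <- rt
  trials
}

#' Cohort-level group parameter distributions
#'
#' Group-level means and between-participant SDs from which participant
#' [race_params()] are drawn in [simulate_study()]. Positive parameters are
#' drawn from normals truncated at zero; the failure probabilities are
#' drawn on the probit scale. The defaults plant a slower stop process in
#' patients than controls (group SSRT means near 0.39 s and 0.46 s) with
#' realistic go-RT and attentional-failure levels for older adults.
#'
#' @param mean named numeric vector over [race_param_names()] (probabilities
#'   on the natural scale; converted internally).
#' @param sd named numeric vector of between-participant SDs (probit scale
#'   for the probabilities).
#' @return list with elements `mean` and `sd` (probit-scale entries for
#'   `p_tf`, `p_gf`).
#' @export
group_dist <- function(mean, sd) {
  nm <- race_param_names()
  stopifnot(all(nm %in% names(mean)), all(nm %in% names(sd)))
  mean <- mean[nm]
  mean[c("p_tf", "p_gf")] <- qnorm(mean[c("p_tf", "p_gf")])
  list(mean = mean, sd = sd[nm])
}

#' @rdname group_dist
#' @export
study_groups <- function() {
  base_sd <- c(mu_stop = 0.04, sigma_stop = 0.01, tau_stop = 0.04,
               mu_go_match = 0.08, sigma_go_match = 0.02, tau_go_match = 0.06,
               mu_go_mismatch = 0.15, sigma_go_mismatch = 0.05,
               tau_go_mismatch = 0.10, p_tf = 0.5, p_gf = 0.5)
  list(
    controls = group_dist(
      mean = c(mu_stop = 0.25, sigma_stop = 0.04, tau_stop = 0.14,
               mu_go_match = 0.52, sigma_go_match = 0.08, tau_go_match = 0.16,
               mu_go_mismatch = 0.95, sigma_go_mismatch = 0.25,
               tau_go_mismatch = 0.35, p_tf = 0.05, p_gf = 0.02),
      sd = base_sd),
    patients = group_dist(
      mean = c(mu_stop = 0.30, sigma_stop = 0.05, tau_stop = 0.16,
               mu_go_match = 0.56, sigma_go_match = 0.09, tau_go_match = 0.18,
               mu_go_mismatch = 1.00, sigma_go_mismatch = 0.25,
               tau_go_mismatch = 0.35, p_tf = 0.08, p_gf = 0.03),
      sd = base_sd)
  )
}

# draw one participant's race_params from a group distribution
draw_participant_params <- function(dist) {
  nm <- race_param_names()
  out <- numeric(11)
  names(out) <- nm
  for (k in nm) {
    if (k %in% c("p_tf", "p_gf")) {
      out[k] <- pnorm(rnorm(1, dist$mean[k], dist$sd[k]))
    } else {
      repeat {
        v <- rnorm(1, dist$mean[k], dist$sd[k])
        if (v > 0) break
      }
      out[k] <- v
    }
  }
  do.call(race_params, as.list(out))
}

#' Permuted-block drug-order randomization
#'
#' Assigns the first-session drug for each patient in successive blocks of
#' six recruits, with exactly three randomized to placebo-first and three
#' to atomoxetine-first within each block.
#'
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @return character vector of first-session drugs.
#' @export
randomize_drug_order <- function(n_patients, seed = 1L) {
  set.seed(as.integer(seed))
  n_blocks <- ceiling(n_patients / 6)
  first <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(c("placebo", "atomoxetine"), each = 3))
  }))
  first[seq_len(n_patients)]
}

#' Simulate a full crossover study
#'
#' Generates trial-level stop-signal data for a control cohort (one session)
#' and a patient cohort tested twice in a double-blind placebo/atomoxetine
#' crossover (drug order randomized in permuted blocks of six). Participant
#' parameters are drawn from [study_groups()]-style distributions. Each
#' patient receives a latent locus-coeruleus CNR value; if `cnr_link` is
#' supplied, the atomoxetine-session stop-runner mean is shifted by
#' `slope * (cnr - cnr_mean)` so that a drug-by-CNR interaction on SSRT is
#' planted and recoverable by the downstream mixed model. A `session_shift`
#' (seconds, applied to `mu_stop` in the second session regardless of drug)
#' emulates a practice effect.
#'
#' @param n_controls,n_patients cohort sizes (must be positive).
#' @param groups list with `controls` and `patients` [group_dist()]s.
#' @param cnr_link `NULL` or a list with `slope` (seconds of `mu_stop` shift
#'   per CNR unit under atomoxetine), `cnr_mean`, `cnr_sd`.
#' @param session_shift seconds added to `mu_stop` in session two.
#' @param config a [task_config()].
#' @param seed integer seed; every participant-session has a derived
#'   substream so it is reproducible in isolation.
#' @return an object of class `ssrt_study`: a list with `trials` (tidy
#'   trial-level tibble: subject, group, session, drug, block, trial, kind,
#'   ssd, stimulus, response, rt) and `subjects` (one row per
#'   subject-session with latent CNR, drawn parameters and true SSRT).
#' @examples
#' \donttest{
#' study <- simulate_study(n_controls = 2, n_patients = 2, seed = 1)
#' dplyr::count(study$trials, group, drug)
#' }
#' @export
simulate_study <- function(n_controls = 26, n_patients = 19,
                           groups = study_groups(), cnr_link = NULL,
                           session_shift = -0.02,
                           config = task_config(), seed = 1L) {
  if (n_controls < 1 || n_patients < 1) {
    stop("cohort sizes must be positive", call. = FALSE)
  }
  if (!is.null(cnr_link)) {
    cnr_link <- utils::modifyList(list(slope = 0, cnr_mean = 3, cnr_sd = 1),
                                  cnr_link)
  } else {
    cnr_link <- list(slope = 0, cnr_mean = 3, cnr_sd = 1)
  }
  first_drug <- randomize_drug_order(n_patients,
                                     seed = derive_seed(seed, "randomize"))
  subject_rows <- list()
  trial_rows <- list()

  add_session <- function(id, group, session, drug, params, cnr, sseed) {
    tr <- simulate_participant(params, config, seed = sseed)
    tr <- dplyr::mutate(tr, subject = id, group = group, session = session,
                        drug = drug, .before = 1)
    trial_rows[[length(trial_rows) + 1]] <<- tr
    subject_rows[[length(subject_rows) + 1]] <<- tibble::tibble(
      subject = id, group = group, session = session, drug = drug,
      cnr = cnr, !!!as.list(as_param_vector(params)),
      true_ssrt = params$mu_stop + params$tau_stop)
  }

  for (i in seq_len(n_controls)) {
    id <- sprintf("C%02d", i)
    set.seed(derive_seed(seed, paste0("params-", id)))
    params <- draw_participant_params(groups$controls)
    cnr <- rnorm(1, cnr_link$cnr_mean, cnr_link$cnr_sd)
    add_session(id, "control", "first", "none", params, cnr,
                derive_seed(seed, paste0(id, "-first")))
  }
  for (i in seq_len(n_patients)) {
    id <- sprintf("P%02d", i)
    set.seed(derive_seed(seed, paste0("params-", id)))
    base <- draw_participant_params(groups$patients)
    cnr <- rnorm(1, cnr_link$cnr_mean, cnr_link$cnr_sd)
    drugs <- c(first_drug[i],
               setdiff(c("placebo", "atomoxetine"), first_drug[i]))
    for (s in 1:2) {
      p <- unclass(base)
      if (s == 2) p$mu_stop <- p$mu_stop + session_shift
      if (drugs[s] == "atomoxetine") {
        p$mu_stop <- p$mu_stop + cnr_link$slope * (cnr - cnr_link$cnr_mean)
      }
      p$mu_stop <- max(p$mu_stop, 0.01)
      params <- do.call(race_params, p)
      add_session(id, "patient", c("first", "second")[s], drugs[s], params,
                  cnr, derive_seed(seed, paste0(id, "-", drugs[s])))
    }
  }
  structure(list(trials = dplyr::bind_rows(trial_rows),
                 subjects = dplyr::bind_rows(subject_rows)),
            class = "ssrt_study")
}

#' @export
print.ssrt_study <- function(x, ...) {
  cat("Simulated stop-signal study:",
      dplyr::n_distinct(x$subjects$subject), "subjects,",
      nrow(x$trials), "trials\n")
  print(dplyr::count(x$subjects, .data$group, .data$drug))
  invisible(x)
}

#' Read or write tidy trial tables
#'
#' Trial tables round-trip as plain CSV with times in seconds and missing
#' values as empty fields.
#'
#' @param trials a trial tibble.
#' @param path file path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns the
#'   path invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  tibble::as_tibble(df)
}
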