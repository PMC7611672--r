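# shared fixtures: simulated multi-participant trial tables and small
# phantom cohorts, all generated in code under fixed seeds

make_group_trials <- function(n_subjects, n_blocks = 2, dist = NULL,
                              seed = 1, prefix = "S") {
  if (is.null(dist)) dist <- study_groups()$patients
  cfg <- task_config(n_blocks = n_blocks)
  dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    set.seed(seed * 1000 + i)
    p <- ssrace:::draw_participant_params(dist)
    tr <- simulate_participant(p, cfg, seed = seed * 2000 + i)
    dplyr::mutate(tr, subject = sprintf("%s%02d", prefix, i), .before = 1)
  }))
}

# Monte-Carlo race probabilities used as the independent oracle for the
# analytic likelihood: simulate n races at a fixed SSD
mc_race <- function(params, d, n, seed = 1) {
  set.seed(seed)
  tf <- stats::runif(n) < params$p_tf
  gf <- stats::runif(n) < params$p_gf
  tm <- rexgauss(n, params$mu_go_match, params$sigma_go_match,
                 params$tau_go_match)
  tx <- rexgauss(n, params$mu_go_mismatch, params$sigma_go_mismatch,
                 params$tau_go_mismatch)
  ts <- d + rexgauss(n, params$mu_stop, params$sigma_stop, params$tau_stop)
  go_time <- ifelse(gf, Inf, pmin(tm, tx))
  stop_time <- ifelse(tf, Inf, ts)
  respond <- is.finite(go_time) & go_time < stop_time
  list(p_inhibit = mean(!respond),
       sr_rt = go_time[respond],
       match = (tm <= tx)[respond])
}
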