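test_that("ex-Gaussian density matches the normal-exponential convolution", {
  mu <- 0.5
  sigma <- 0.05
  tau <- 0.1
  conv <- function(t) {
    integrate(function(u) dnorm(t - u, mu, sigma) * dexp(u, 1 / tau),
              0, Inf, rel.tol = 1e-10)$value
  }
  ts <- c(0.3, 0.45, 0.6, 0.9, 1.5)
  expect_equal(dexgauss(ts, mu, sigma, tau), vapply(ts, conv, numeric(1)),
               tolerance = 1e-8)
  # normalisation and moment identity
  expect_equal(integrate(function(t) dexgauss(t, mu, sigma, tau),
                         -Inf, Inf)$value, 1, tolerance = 1e-7)
  set.seed(1)
  expect_equal(mean(rexgauss(1e6, mu, sigma, tau)), mu + tau,
               tolerance = 5e-3)
})

test_that("survival function is one minus the CDF and stays in [0, 1]", {
  ts <- seq(-0.5, 3, by = 0.1)
  s <- sexgauss(ts, 0.5, 0.05, 0.1)
  p <- pexgauss(ts, 0.5, 0.05, 0.1)
  expect_equal(s + p, rep(1, length(ts)), tolerance = 1e-12)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s) <= 0))
  # stable for small tau relative to sigma
  expect_true(is.finite(dexgauss(0.5, 0.5, 0.1, 1e-3, log = TRUE)))
  expect_error(dexgauss(0.5, 0.5, -0.1, 0.1), "sigma")
  expect_error(dexgauss(0.5, 0.5, 0.1, 0), "tau")
})

test_that("go-trial likelihood matches the defective-density structure", {
  p <- race_params(p_gf = 0.1)
  ll <- go_trial_loglik(0.5, "left", "left", p)
  by_hand <- log(0.9) +
    dexgauss(0.5, p$mu_go_match, p$sigma_go_match, p$tau_go_match,
             log = TRUE) +
    log(sexgauss(0.5, p$mu_go_mismatch, p$sigma_go_mismatch,
                 p$tau_go_mismatch))
  expect_equal(ll, by_hand, tolerance = 1e-10)
  # omissions
  expect_equal(go_trial_loglik(NA, NA, "left", p), log(0.1))
  expect_identical(go_trial_loglik(NA, NA, "left",
                                   race_params(p_gf = 0)), -Inf)
  # symmetric runners make either response equally likely
  sym <- race_params(mu_go_mismatch = 0.55, sigma_go_mismatch = 0.08,
                     tau_go_mismatch = 0.15)
  expect_equal(go_trial_loglik(0.6, "left", "left", sym),
               go_trial_loglik(0.6, "right", "left", sym))
  # implausible support
  expect_identical(go_trial_loglik(-0.2, "left", "left", p), -Inf)
})

test_that("signal-respond likelihood reduces to the go likelihood when the stop runner never starts", {
  p <- race_params(p_tf = 1)
  rt <- c(0.4, 0.55, 0.8)
  expect_equal(stop_respond_loglik(rt, 0.2, "left", "left", p),
               go_trial_loglik(rt, "left", "left", p), tolerance = 1e-12)
})

test_that("signal-respond density is censored by the stop survival", {
  p <- race_params(p_tf = 0.1)
  t <- 0.6
  d <- 0.2
  by_hand <- go_trial_loglik(t, "left", "left", p) +
    log(p$p_tf + (1 - p$p_tf) *
          sexgauss(t - d, p$mu_stop, p$sigma_stop, p$tau_stop))
  expect_equal(stop_respond_loglik(t, d, "left", "left", p), by_hand,
               tolerance = 1e-12)
  expect_error(stop_respond_loglik(-0.1, 0.2, "left", "left", p),
               "negative")
})

test_that("inhibition likelihood handles the degenerate mixtures", {
  expect_identical(stop_inhibit_loglik(0.2, race_params(p_gf = 0, p_tf = 1)),
                   -Inf)
  expect_equal(stop_inhibit_loglik(0.2, race_params(p_gf = 0.2, p_tf = 1)),
               log(0.2), tolerance = 1e-12)
})

test_that("analytic race probabilities match Monte-Carlo frequencies", {
  sets <- list(
    race_params(),
    race_params(mu_stop = 0.2, sigma_stop = 0.03, tau_stop = 0.05,
                p_tf = 0.15, p_gf = 0.05),
    race_params(mu_stop = 0.35, sigma_stop = 0.08, tau_stop = 0.2,
                p_tf = 0, p_gf = 0)
  )
  n <- 2e5
  for (si in seq_along(sets)) {
    p <- sets[[si]]
    for (d in c(0.05, 0.25, 0.45)) {
      r <- mc_race(p, d, n, seed = 100 * si + round(100 * d))
      p_inh <- exp(stop_inhibit_loglik(d, p))
      se <- sqrt(p_inh * (1 - p_inh) / n)
      expect_lt(abs(p_inh - r$p_inhibit), 3.5 * se + 1e-9)
    }
  }
})

test_that("inhibition and signal-respond mass sum to one", {
  # runners with negligible finish-time mass below zero, as in real RT data
  p <- race_params(p_tf = 0.1, p_gf = 0.05, sigma_go_mismatch = 0.15)
  for (d in c(0, 0.2, 0.5)) {
    p_inh <- exp(stop_inhibit_loglik(d, p))
    dens <- function(t, resp) {
      exp(stop_respond_loglik(t, d, resp, "left", p))
    }
    p_match <- integrate(function(t) dens(t, "left"), 0, Inf,
                         rel.tol = 1e-10)$value
    p_mism <- integrate(function(t) dens(t, "right"), 0, Inf,
                        rel.tol = 1e-10)$value
    expect_equal(p_inh + p_match + p_mism, 1, tolerance = 1e-6)
  }
})

test_that("signal-respond mass grows with later stop signals", {
  p <- race_params(p_tf = 0, p_gf = 0)
  mass <- vapply(c(0.05, 0.2, 0.4, 0.8), function(d) {
    1 - exp(stop_inhibit_loglik(d, p))
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("fast quadrature path agrees with adaptive quadrature", {
  p <- race_params()
  for (d in c(0, 0.15, 0.3, 0.6, 1.2)) {
    gl <- ssrace:::inhibit_prob_cpp(
      d, c(p$mu_stop, p$sigma_stop, p$tau_stop),
      c(p$mu_go_match, p$sigma_go_match, p$tau_go_match),
      c(p$mu_go_mismatch, p$sigma_go_mismatch, p$tau_go_mismatch))
    expect_equal(gl, ssrace:::inhibit_prob_quad(d, p), tolerance = 1e-6)
  }
})

test_that("dataset log-likelihood sums per-trial contributions", {
  p <- race_params()
  tr <- simulate_participant(p, task_config(n_blocks = 1), seed = 9)
  ll <- trial_loglik(tr, p)
  expect_equal(dataset_loglik(tr, p), sum(ll$loglik))
  # permutation invariance and the empty case
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(dataset_loglik(perm, p), dataset_loglik(tr, p))
  expect_identical(dataset_loglik(tr[0, ], p), 0)
})

test_that("trigger failure raises the likelihood of data generated with it", {
  gen <- race_params(p_tf = 0.2)
  trials <- dplyr::bind_rows(lapply(1:6, function(i) {
    simulate_participant(gen, task_config(n_blocks = 2), seed = 400 + i)
  }))
  at_truth <- dataset_loglik(trials, gen)
  no_tf <- gen
  no_tf$p_tf <- 0
  expect_gt(at_truth, dataset_loglik(trials, no_tf))
})

test_that("RT preprocessing applies bounds then the SD rule to go RTs only", {
  base <- tibble::tibble(
    block = 1, trial = seq_len(8), kind = "go", ssd = NA_real_,
    stimulus = "left", response = "left",
    rt = c(0.1, 0.5, 0.55, 0.6, 0.62, 0.58, 5.0, NA))
  base$response[8] <- NA
  out <- preprocess_rts(base)
  rep <- trim_report(out)
  expect_equal(rep$removed_bounds, 2)  # 0.1 and 5.0
  expect_equal(rep$removed_sd, 0)
  expect_equal(nrow(out), 6)           # omission kept

  # constructed outlier: survivors computed by hand
  set.seed(3)
  rts <- c(round(rnorm(97, 0.6, 0.05), 3), 1.9, 0.15, 4.8)
  tr <- tibble::tibble(block = 1, trial = seq_along(rts), kind = "go",
                       ssd = NA_real_, stimulus = "left",
                       response = "left", rt = rts)
  clean <- rts[rts >= 0.25 & rts <= 4.5]
  lim <- mean(clean) + c(-1, 1) * 2.5 * sd(clean)
  survivors <- sum(clean >= lim[1] & clean <= lim[2])
  out2 <- preprocess_rts(tr)
  expect_equal(nrow(out2), survivors)
  expect_equal(trim_report(out2)$removed_bounds, 2)

  # signal-respond RTs are exempt from the SD rule
  tr$kind[1:50] <- "stop"
  tr$ssd[1:50] <- 0.3
  out3 <- preprocess_rts(tr)
  expect_true(all(out3$rt[out3$kind == "stop"] <= 4.5))

  # identity when everything is plausible
  tame <- tibble::tibble(block = 1, trial = 1:3, kind = "go",
                         ssd = NA_real_, stimulus = "left",
                         response = "left", rt = c(0.5, 0.55, 0.6))
  expect_equal(nrow(preprocess_rts(tame)), 3)
  # fewer than two go RTs: SD rule skipped with a warning
  lone <- tame[1, ]
  expect_warning(preprocess_rts(lone), "SD trimming")
})
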