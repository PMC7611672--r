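test_that("trial sequences respect the block design for many seeds", {
  cfg <- task_config()
  for (seed in 1:100) {
    tr <- generate_trial_sequence(cfg, seed = seed)
    counts <- dplyr::count(tr, block, kind)
    expect_equal(nrow(tr), cfg$n_blocks * cfg$trials_per_block)
    expect_true(all(counts$n[counts$kind == "go"] == 110))
    expect_true(all(counts$n[counts$kind == "nogo"] == 10))
    expect_true(all(counts$n[counts$kind == "stop"] == 20))
    for (b in seq_len(cfg$n_blocks)) {
      blk <- tr$kind[tr$block == b]
      expect_true(all(blk[1:20] == "go"))
      rest <- rle(ifelse(blk[-(1:20)] == "go", "go", "signal"))
      expect_lte(max(rest$lengths[rest$values == "go"]), 7)
      expect_lte(max(rest$lengths[rest$values == "signal"]), 2)
    }
  }
})

test_that("sequences are deterministic in the seed and no-go trials carry SSD 0", {
  a <- generate_trial_sequence(seed = 42)
  b <- generate_trial_sequence(seed = 42)
  expect_identical(a, b)
  expect_true(all(a$ssd[a$kind == "nogo"] == 0))
  expect_true(all(is.na(a$ssd[a$kind == "go"])))
})

test_that("unsatisfiable run-length constraints raise a sequencing error", {
  cfg <- task_config(go_per_block = 30, nogo_per_block = 50,
                     stop_per_block = 60, lead_go_trials = 20)
  expect_error(generate_trial_sequence(cfg, seed = 1, max_tries = 50),
               "constraints")
})

test_that("staircase updates by one step and clamps at the range bounds", {
  expect_equal(staircase_update(0.300, TRUE), 0.350)
  expect_equal(staircase_update(0.300, FALSE), 0.250)
  expect_equal(staircase_update(1.500, TRUE), 1.500)
  expect_equal(staircase_update(0.050, FALSE), 0.050)
})

test_that("initial SSD is mean lead-in RT minus 200 ms, clamped", {
  expect_equal(initial_ssd(c(0.5, 0.6, 0.7)), 0.400)
  expect_equal(initial_ssd(0.210), 0.050)
  expect_equal(initial_ssd(2.0), 1.500)
  expect_error(initial_ssd(numeric(0)), "lead-in")
})

test_that("degenerate failure probabilities behave as expected", {
  cfg <- task_config(n_blocks = 1)
  all_gf <- simulate_participant(race_params(p_gf = 1), cfg, seed = 1)
  expect_true(all(is.na(all_gf$response)))

  no_stop <- simulate_participant(race_params(p_tf = 1, p_gf = 0,
                                              mu_go_match = 0.4,
                                              tau_go_match = 0.05),
                                  cfg, seed = 2)
  stops <- no_stop[no_stop$kind == "stop", ]
  expect_true(all(!is.na(stops$response)))
})

test_that("SSD trace stays in range and moves by exactly one step", {
  tr <- simulate_participant(race_params(), task_config(n_blocks = 4),
                             seed = 3)
  ssd <- tr$ssd[tr$kind == "stop"]
  expect_true(all(ssd >= 0.050 - 1e-12 & ssd <= 1.500 + 1e-12))
  per_block <- split(tr[tr$kind == "stop", ], tr$block[tr$kind == "stop"])
  for (blk in per_block) {
    d <- diff(blk$ssd)
    interior <- blk$ssd[-nrow(blk)] > 0.050 & blk$ssd[-nrow(blk)] < 1.500
    expect_true(all(abs(abs(d[interior]) - 0.050) < 1e-12))
  }
})

test_that("staircase targets 50% stop accuracy in the long run", {
  cfg <- task_config(n_blocks = 100)
  p <- race_params(mu_stop = 0.2, sigma_stop = 0.03, tau_stop = 0.05,
                   p_tf = 0, p_gf = 0)
  tr <- simulate_participant(p, cfg, seed = 7)
  stops <- tr[tr$kind == "stop", ]
  expect_gte(nrow(stops), 2000)
  acc <- mean(is.na(stops$response))
  expect_gt(acc, 0.45)
  expect_lt(acc, 0.55)
})

test_that("a fast stop runner at minimal SSD inhibits almost everything", {
  p <- race_params(mu_stop = 0.05, sigma_stop = 0.01, tau_stop = 0.01,
                   mu_go_match = 0.6, p_tf = 0, p_gf = 0)
  r <- mc_race(p, d = 0.05, n = 20000, seed = 1)
  expect_gt(r$p_inhibit, 0.99)
})

test_that("signal-respond RTs are faster than go RTs (censoring)", {
  tr <- simulate_participant(race_params(), task_config(n_blocks = 8),
                             seed = 11)
  sr <- tr$rt[tr$kind == "stop" & !is.na(tr$rt)]
  go <- tr$rt[tr$kind == "go" & !is.na(tr$rt)]
  expect_lt(mean(sr), mean(go))
})

test_that("drug order is randomized 3/3 within each block of six", {
  for (seed in 1:20) {
    ord <- randomize_drug_order(18, seed = seed)
    for (b in 1:3) {
      blk <- ord[(6 * b - 5):(6 * b)]
      expect_equal(sum(blk == "placebo"), 3)
    }
  }
})

test_that("simulate_study wires the crossover design and the CNR link", {
  study <- simulate_study(n_controls = 3, n_patients = 4,
                          cnr_link = list(slope = 0.05), seed = 21)
  subj <- study$subjects
  expect_equal(sum(subj$group == "control"), 3)
  expect_equal(sum(subj$group == "patient"), 8)  # 4 patients x 2 sessions
  pat <- subj[subj$group == "patient", ]
  per <- split(pat, pat$subject)
  for (p in per) {
    expect_setequal(p$drug, c("placebo", "atomoxetine"))
    expect_setequal(p$session, c("first", "second"))
    expect_equal(length(unique(p$cnr)), 1L)
  }
  # planted link: atomoxetine mu_stop shifted by slope * (cnr - cnr_mean),
  # on top of the session practice shift
  wide <- tidyr::pivot_wider(pat[, c("subject", "drug", "session", "cnr",
                                     "mu_stop")],
                             names_from = drug,
                             values_from = c(mu_stop, session))
  shift <- ifelse(wide$session_atomoxetine == "second", -0.02, 0.02)
  delta <- wide$mu_stop_atomoxetine - wide$mu_stop_placebo - shift
  expect_equal(delta, 0.05 * (wide$cnr - 3), tolerance = 1e-8)
  expect_equal(nrow(study$trials),
               (3 + 8) * 4 * 140)
})

test_that("trial tables round-trip through CSV", {
  study <- simulate_study(n_controls = 1, n_patients = 1,
                          config = task_config(n_blocks = 1), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_trials(study$trials, path)
  back <- read_trials(path)
  expect_equal(nrow(back), nrow(study$trials))
  expect_equal(back$rt, study$trials$rt)
  expect_equal(back$response, study$trials$response)
  unlink(path)
})
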