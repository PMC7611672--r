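# rows with a known standardized drug x CNR interaction; variances chosen
# so the outcome is approximately unit-variance before z-scoring
make_moderation_rows <- function(n, b_int, b_drug = 0, b_cnr = 0.1,
                                 b_session = 0.2, sd_subj = 0.3,
                                 sd_resid = 0.15, seed = 1) {
  set.seed(seed)
  cnr <- rnorm(n)
  u <- rnorm(n, 0, sd_subj)
  first <- rep(c("placebo", "atomoxetine"), length.out = n)
  purrr::map_dfr(seq_len(n), function(i) {
    drugs <- c(first[i], setdiff(c("placebo", "atomoxetine"), first[i]))
    purrr::map_dfr(1:2, function(s) {
      drug01 <- as.numeric(drugs[s] == "atomoxetine")
      y <- b_drug * drug01 + b_cnr * cnr[i] + b_int * drug01 * cnr[i] +
        b_session * (s - 1) + u[i] + rnorm(1, 0, sd_resid)
      tibble::tibble(subject = sprintf("P%03d", i), drug = drugs[s],
                     session = c("first", "second")[s],
                     lc_cnr = cnr[i], ssrt_median = y)
    })
  })
}

test_that("descriptives compute stop accuracy, error rates and logits", {
  tr <- tibble::tibble(
    subject = "a",
    kind = c(rep("stop", 4), rep("go", 4)),
    ssd = c(rep(0.3, 4), rep(NA, 4)),
    stimulus = "left",
    response = c(NA, NA, "left", "left", "left", "left", "right", NA),
    rt = c(NA, NA, 0.5, 0.6, 0.5, 0.52, 0.61, NA))
  d <- descriptives(tr)
  expect_equal(d$stop_accuracy, 0.5)
  expect_equal(d$go_error_rate, 0.5)  # one commission + one omission of 4
  expect_equal(d$go_error_logit, log((2 + 0.5) / (4 - 2 + 0.5)))
})

test_that("empirical logit stays finite at zero and full error counts", {
  expect_equal(empirical_logit(20, 40), 0)
  expect_true(is.finite(empirical_logit(0, 100)))
  expect_true(is.finite(empirical_logit(100, 100)))
  expect_equal(empirical_logit(0, 100), log(0.5 / 100.5))
})

test_that("integration SSRT tracks the planted stop-process speed", {
  fast <- simulate_participant(
    race_params(mu_stop = 0.15, tau_stop = 0.05),
    task_config(n_blocks = 4), seed = 1)
  slow <- simulate_participant(
    race_params(mu_stop = 0.35, tau_stop = 0.15),
    task_config(n_blocks = 4), seed = 1)
  fast$subject <- "fast"
  slow$subject <- "slow"
  d <- descriptives(dplyr::bind_rows(fast, slow))
  expect_lt(d$ssrt_integration[d$subject == "fast"],
            d$ssrt_integration[d$subject == "slow"])
})

test_that("moderation LMM recovers a planted interaction slope", {
  rows <- make_moderation_rows(100, b_int = 0.27, seed = 7)
  fit <- fit_moderation_lmm(rows, outcome = "ssrt_median")
  td <- tidy(fit)
  # the model z-scores the outcome, so map the standardized estimate back
  # to the generator scale before comparing with the planted slope
  est <- td$estimate[td$term == "drug:cnr"] * sd(rows$ssrt_median)
  expect_lt(abs(est - 0.27), 0.05)
  expect_lt(td$p.value[td$term == "drug:cnr"], 0.01)
  expect_equal(glance(fit)$ddf_method, "Kenward-Roger")
  expect_setequal(td$term, c("drug", "cnr", "session", "drug:cnr"))
})

test_that("interaction estimate is invariant to CNR centring and outcome shifts", {
  rows <- make_moderation_rows(40, b_int = 0.3, seed = 11)
  base <- tidy(fit_moderation_lmm(rows))
  shifted <- rows
  shifted$lc_cnr <- shifted$lc_cnr + 5
  t1 <- tidy(fit_moderation_lmm(shifted))
  expect_equal(t1$estimate[t1$term == "drug:cnr"],
               base$estimate[base$term == "drug:cnr"], tolerance = 1e-8)
  added <- rows
  added$ssrt_median <- added$ssrt_median + 2.5
  t2 <- tidy(fit_moderation_lmm(added))
  expect_equal(t2$estimate[t2$term == "drug:cnr"],
               base$estimate[base$term == "drug:cnr"], tolerance = 1e-8)
})

test_that("subjects with one missing session are retained by the LMM", {
  rows <- make_moderation_rows(30, b_int = 0.3, seed = 13)
  dropped <- rows[-c(1, 4), ]  # two subjects lose one session each
  fit <- fit_moderation_lmm(dropped)
  expect_equal(glance(fit)$n_subjects, 30)
  expect_error(fit_moderation_lmm(rows[rows$session == "first", ]),
               "both sessions")
})

test_that("type-I error of the interaction test is near nominal", {
  reps <- 60
  pvals <- vapply(seq_len(reps), function(r) {
    rows <- make_moderation_rows(30, b_int = 0, seed = 1000 + r)
    td <- tidy(fit_moderation_lmm(rows))
    td$p.value[td$term == "drug:cnr"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  # binomial 99% band around 0.05 at 60 replicates
  expect_lte(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / reps))
  expect_gt(mean(pvals), 0.3)  # roughly uniform, not piled near zero
})

test_that("drug-change correlation recovers a strong planted link", {
  rows <- make_moderation_rows(50, b_int = 0.5, b_session = 0.3,
                               sd_resid = 0.1, seed = 17)
  ct <- drug_change_correlation(rows)
  expect_gt(ct$estimate, 0.5)
  expect_lt(ct$p.value, 0.001)
  expect_equal(ct$n, 50)
})

test_that("session adjustment is a no-op when there is no session effect", {
  rows <- make_moderation_rows(40, b_int = 0.4, b_session = 0, sd_resid = 0.1,
                               seed = 19)
  ct <- drug_change_correlation(rows)
  # raw correlation computed by hand
  wide <- tidyr::pivot_wider(rows, names_from = drug,
                             values_from = c(ssrt_median, session))
  raw <- cor(wide$ssrt_median_atomoxetine - wide$ssrt_median_placebo,
             wide$lc_cnr)
  expect_equal(ct$estimate, raw, tolerance = 0.1)
  # estimated session effect is pure sampling noise here
  expect_lt(abs(ct$session_effect), 0.15)
})

test_that("constant drug effects make the correlation undefined", {
  rows <- make_moderation_rows(10, b_int = 0, b_drug = 0.2, sd_resid = 0,
                               sd_subj = 0.2, b_session = 0, seed = 23)
  expect_error(drug_change_correlation(rows), "constant|undefined")
})

test_that("subdivision ANOVA detects a planted caudal-only group deficit", {
  set.seed(29)
  make_cohort <- function(n, caudal_shift, prefix) {
    purrr::map_dfr(seq_len(n), function(i) {
      base <- rnorm(1, 5, 0.6)
      tibble::tibble(
        subject = paste0(prefix, i),
        group = ifelse(prefix == "P", "patient", "control"),
        subdivision = c("caudal", "middle", "rostral"),
        mean_cnr = c(base - 1.5 + caudal_shift, base, base + 0.3) +
          rnorm(3, 0, 0.3))
    })
  }
  lc <- dplyr::bind_rows(make_cohort(25, -1.2, "P"),
                         make_cohort(25, 0, "C"))
  res <- subdivision_anova(lc)
  eff <- tidy(res)
  expect_lt(eff$p.value[eff$term == "subdivision"], 0.001)
  expect_lt(eff$p.value[eff$term == "group:subdivision"], 0.01)
  gc <- res$group_contrasts
  expect_lt(gc$p.value[gc$subdivision == "caudal"], 0.01)
  expect_gt(gc$p.value[gc$subdivision == "rostral"], 0.05)
})

test_that("equal subdivision means produce no subdivision effect", {
  set.seed(31)
  pvals <- vapply(1:10, function(r) {
    lc <- purrr::map_dfr(1:20, function(i) {
      base <- rnorm(1, 5, 0.5)
      tibble::tibble(subject = paste0("s", i),
                     group = rep(c("patient", "control"), 10)[i],
                     subdivision = c("caudal", "middle", "rostral"),
                     mean_cnr = base + rnorm(3, 0, 0.1))
    })
    tidy(subdivision_anova(lc))$p.value[2]
  }, numeric(1))
  # under the null the test should fire at roughly the nominal rate
  expect_lte(sum(pvals < 0.05), 2)
  expect_gt(median(pvals), 0.1)
})
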