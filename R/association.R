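#' Behavioural descriptives per subject and condition
#'
#' Stop accuracy (proportion of stop trials with no response), go error
#' rate (commission plus omission errors over go trials) and its empirical
#' logit. Because error rates are bounded at zero, the logit uses the
#' empirical-logit adjustment `log((k + 0.5) / (n - k + 0.5))`, which stays
#' finite for zero counts. Also reports the mean go RT, mean stop-trial
#' SSD and the tracking-based integration estimate of SSRT (mean go RT
#' minus mean SSD; valid under ~50% stop accuracy), useful for quick
#' model-free summaries.
#'
#' @param trials tidy trial table; grouped by any of `subject`, `group`,
#'   `session`, `drug` columns present.
#' @return a tibble, one row per subject-condition.
#' @export
descriptives <- function(trials) {
  keys <- intersect(c("subject", "group", "session", "drug"), names(trials))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_go = sum(.data$kind == "go"),
      n_stop = sum(.data$kind == "stop"),
      stop_accuracy = mean(is.na(.data$response[.data$kind == "stop"])),
      go_errors = sum(.data$kind == "go" &
                        (is.na(.data$response) |
                           .data$response != .data$stimulus)),
      go_rt_mean = mean(.data$rt[.data$kind == "go"], na.rm = TRUE),
      ssd_mean = mean(.data$ssd[.data$kind == "stop"], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      go_error_rate = .data$go_errors / .data$n_go,
      go_error_logit = empirical_logit(.data$go_errors, .data$n_go),
      ssrt_integration = .data$go_rt_mean - .data$ssd_mean
    )
}

#' @rdname descriptives
#' @param k error count.
#' @param n trial count.
#' @export
empirical_logit <- function(k, n) {
  log((k + 0.5) / (n - k + 0.5))
}

#' Drug-by-CNR moderation mixed model
#'
#' Tests whether locus coeruleus CNR moderates the drug effect on a
#' behavioural outcome with the random-intercept model
#' `outcome ~ drug * cnr + session + (1 | subject)`, fitted by REML on the
#' patient rows. The outcome and CNR are z-scored across the analysis
#' sample (so fixed effects are standardized coefficients); drug is coded
#' placebo = 0, atomoxetine = 1 and session first = 0, second = 1. F tests
#' use Kenward-Roger denominator degrees of freedom, falling back to
#' Satterthwaite if that fails (the method used is recorded). Subjects
#' with a single session are retained: the random-effect structure handles
#' the missingness.
#'
#' @param rows one row per subject-condition, with columns `subject`,
#'   `drug` (`placebo`/`atomoxetine`), `session` (`first`/`second`),
#'   `lc_cnr` and the outcome.
#' @param outcome name of the outcome column (e.g. `"ssrt_median"`).
#' @return an object of class `moderation_fit`; `tidy()` returns the fixed
#'   effects with F statistics and p-values, `glance()` the fit metadata.
#' @export
fit_moderation_lmm <- function(rows, outcome = "ssrt_median") {
  stopifnot(outcome %in% names(rows))
  d <- rows[rows$drug %in% c("placebo", "atomoxetine"), , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("subject", "drug", "session", "lc_cnr",
                                     outcome)]), , drop = FALSE]
  both <- names(which(table(unique(d[, c("subject", "drug")])$subject) == 2))
  if (length(both) < 3) {
    stop("need at least 3 subjects with both sessions", call. = FALSE)
  }
  d$y <- as.numeric(scale(d[[outcome]]))
  d$cnr <- as.numeric(scale(d$lc_cnr))
  d$drug_c <- as.numeric(d$drug == "atomoxetine")
  d$session_c <- as.numeric(d$session == "second")
  model <- lmerTest::lmer(y ~ drug_c * cnr + session_c + (1 | subject),
                          data = d, REML = TRUE)
  singular <- lme4::isSingular(model)
  ddf <- "Kenward-Roger"
  ftab <- tryCatch(stats::anova(model, ddf = "Kenward-Roger"),
                   error = function(e) NULL)
  if (is.null(ftab)) {
    ddf <- "Satterthwaite"
    ftab <- stats::anova(model, ddf = "Satterthwaite")
  }
  structure(list(model = model, anova = ftab, data = d, outcome = outcome,
                 ddf_method = ddf, singular = singular),
            class = "moderation_fit")
}

#' @export
tidy.moderation_fit <- function(x, ...) {
  fe <- lme4::fixef(x$model)
  an <- as.data.frame(x$anova)
  term_map <- c(drug_c = "drug", cnr = "cnr", session_c = "session",
                `drug_c:cnr` = "drug:cnr")
  tibble::tibble(
    term = unname(term_map[rownames(an)]),
    estimate = unname(fe[rownames(an)]),
    statistic = an$`F value`,
    num.df = an$NumDF,
    den.df = an$DenDF,
    p.value = an$`Pr(>F)`
  )
}

#' @export
glance.moderation_fit <- function(x, ...) {
  tibble::tibble(n_obs = nrow(x$data),
                 n_subjects = dplyr::n_distinct(x$data$subject),
                 outcome = x$outcome, ddf_method = x$ddf_method,
                 singular = x$singular,
                 REMLcrit = lme4::REMLcrit(x$model))
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat("Drug x CNR moderation model (", x$outcome, " ~ drug * cnr + session",
      " + (1 | subject); ", x$ddf_method, " df)\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Correlation between CNR and the drug-induced change
#'
#' Per-patient drug effect `delta = outcome(atomoxetine) - outcome(placebo)`,
#' adjusted for the session fixed effect (estimated from the within-subject
#' session-two minus session-one differences), correlated with whole-LC
#' CNR (Pearson). Subjects missing a session are excluded here (the mixed
#' model retains them).
#'
#' @inheritParams fit_moderation_lmm
#' @return tibble with the correlation estimate, test statistic, df,
#'   p-value and confidence interval.
#' @export
drug_change_correlation <- function(rows, outcome = "ssrt_median") {
  d <- rows[rows$drug %in% c("placebo", "atomoxetine"), , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("subject", "drug", "session", "lc_cnr",
                                     outcome)]), , drop = FALSE]
  wide <- d |>
    dplyr::select(dplyr::all_of(c("subject", "drug", "session", "lc_cnr",
                                  outcome))) |>
    tidyr::pivot_wider(names_from = "drug",
                       values_from = dplyr::all_of(c(outcome, "session")))
  ocol <- function(drug) wide[[paste0(outcome, "_", drug)]]
  complete <- !is.na(ocol("atomoxetine")) & !is.na(ocol("placebo"))
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 3) stop("need >= 3 complete crossover subjects",
                           call. = FALSE)
  # x = +1 when atomoxetine was the second session, -1 otherwise
  x <- ifelse(wide$session_atomoxetine == "second", 1, -1)
  dy <- ifelse(x == 1,
               ocol("atomoxetine") - ocol("placebo"),
               ocol("placebo") - ocol("atomoxetine"))
  session_effect <- if (length(unique(x)) > 1) {
    unname(stats::coef(lm(dy ~ x))[1])
  } else {
    0
  }
  delta_adj <- x * (dy - session_effect)
  if (sd(delta_adj) < 1e-10 || sd(wide$lc_cnr) < 1e-10) {
    stop("drug-induced change (or CNR) is constant; correlation undefined",
         call. = FALSE)
  }
  ct <- cor.test(delta_adj, wide$lc_cnr)
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p.value = ct$p.value,
                 conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
                 n = nrow(wide), session_effect = session_effect)
}

#' Group-by-subdivision mixed ANOVA on locus coeruleus CNR
#'
#' Between-subject factor group, within-subject factor subdivision
#' (caudal/middle/rostral), with Greenhouse-Geisser sphericity correction
#' (via a multivariate linear model and [car::Anova()]). Follow-up
#' contrasts: Welch two-sample group comparisons within each subdivision,
#' and paired subdivision comparisons pooled across groups.
#'
#' @param lc_df long tibble with columns `subject`, `group`, `subdivision`
#'   (caudal/middle/rostral) and `mean_cnr` (e.g. stacked
#'   [extract_lc_cnr()] rows with `side == "both"`).
#' @return an object of class `subdivision_anova` with `effects` (F table
#'   with GG-corrected p-values), `group_contrasts` and
#'   `subdivision_contrasts` tibbles; `tidy()` returns `effects`.
#' @export
subdivision_anova <- function(lc_df) {
  need <- c("subject", "group", "subdivision", "mean_cnr")
  stopifnot(all(need %in% names(lc_df)))
  wide <- lc_df |>
    dplyr::filter(.data$subdivision %in% c("caudal", "middle", "rostral")) |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = "subdivision",
                       values_from = "mean_cnr")
  wide$group <- factor(wide$group)
  mlm <- lm(cbind(caudal, middle, rostral) ~ group, data = wide)
  idata <- data.frame(subdivision = factor(c("caudal", "middle", "rostral")))
  aovres <- car::Anova(mlm, idata = idata, idesign = ~subdivision, type = 3)
  s <- suppressWarnings(summary(aovres, multivariate = FALSE))
  ut <- s$univariate.tests
  adj <- s$pval.adjustments
  pick <- c("subdivision", "group:subdivision")
  has_gg <- !is.null(adj) && all(pick %in% rownames(adj)) &&
    !any(is.na(adj[pick, "GG eps"]))
  if (has_gg) {
    eps <- adj[pick, "GG eps"]
    p_within <- adj[pick, "Pr(>F[GG])"]
  } else {
    # degenerate error covariance: sphericity correction unavailable,
    # report the uncorrected repeated-measures test
    eps <- rep(NA_real_, 2)
    p_within <- ut[pick, "Pr(>F)"]
  }
  effects <- tibble::tibble(
    term = c("group", pick),
    df1 = ut[c("group", pick), "num Df"],
    df2 = ut[c("group", pick), "den Df"],
    statistic = ut[c("group", pick), "F value"],
    gg_epsilon = c(NA, eps),
    df1_gg = c(NA, eps * ut[pick, "num Df"]),
    df2_gg = c(NA, eps * ut[pick, "den Df"]),
    p.value = c(ut["group", "Pr(>F)"], p_within)
  )
  group_contrasts <- purrr::map_dfr(c("caudal", "middle", "rostral"),
    function(sx) {
      tt <- stats::t.test(wide[[sx]] ~ wide$group)
      tibble::tibble(subdivision = sx, estimate = diff(rev(tt$estimate)),
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p.value = tt$p.value)
    })
  pairs <- list(c("caudal", "middle"), c("caudal", "rostral"),
                c("middle", "rostral"))
  subdivision_contrasts <- purrr::map_dfr(pairs, function(pr) {
    tt <- stats::t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    tibble::tibble(contrast = paste(pr, collapse = " - "),
                   estimate = unname(tt$estimate),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p.value = tt$p.value)
  })
  structure(list(effects = effects, group_contrasts = group_contrasts,
                 subdivision_contrasts = subdivision_contrasts,
                 anova = aovres),
            class = "subdivision_anova")
}

#' @export
tidy.subdivision_anova <- function(x, ...) x$effects

#' @export
print.subdivision_anova <- function(x, ...) {
  cat("Group x subdivision mixed ANOVA (Greenhouse-Geisser corrected):\n")
  print(x$effects)
  invisible(x)
}
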