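#' Ground-truth specification for synthetic cohorts
#'
#' Defines a full generative model with the statistical structure the
#' analysis assumes, so that every pipeline stage — cleaning, imputation,
#' compliance audit, parameter learning, counterfactual queries — can be
#' exercised and scored against a known truth without the clinical dataset.
#'
#' Demographic marginals mimic the cohort's descriptive table (77% male,
#' 71% cirrhosis, mean age 71, the observed aetiology and presentation-mode
#' mix); an MDM follows the shipped BCLC rule table with probability
#' `p_comply` (default 0.16, the compliant fraction seen in the audit);
#' non-compliant decisions draw from the remaining treatments with realistic
#' weights.  Waiting time is a truncated-Poisson conditional on treatment and
#' survival a negative-binomial conditional on treatment and waiting (capped
#' at 40 months), both *realised through a 12-level latent rank variable via
#' the inverse-CDF construction* — so quantile-mode abduction is exactly
#' correct on synthetic data and copy mode is a measurable approximation.
#' Potential survival outcomes under all seven treatments are recorded per
#' case.  Missingness defaults are the cohort's observed rates: 4% of sizes,
#' 1.6% of performance statuses, 62% of waiting times, masked completely at
#' random.
#'
#' @param deterministic If `TRUE`, the waiting and survival conditionals are
#'   point masses (waiting fixed at 3 months for every treatment); used by
#'   recovery experiments where the counterfactual engine must reproduce the
#'   hidden potential outcomes exactly.
#' @param p_comply Probability an MDM follows the rule table.
#' @param missingness Named rates for `size_mm`, `ps`, `waiting_months`.
#' @param waiting_max,survival_max State-space caps in months.
#' @return Object of class `"hcc_cohort_spec"`.
#' @export
cohort_spec <- function(deterministic = FALSE, p_comply = 0.16,
                        missingness = c(size_mm = 0.04, ps = 0.016,
                                        waiting_months = 0.62),
                        waiting_max = 24L, survival_max = 40L) {
  trts <- hcc_treatments()
  wstates <- 0:waiting_max
  sstates <- 0:survival_max
  wait_mu <- c(resection = 4, transplant = 10, TACE = 3, SIRT = 4,
               ablation = 3, `medical therapy` = 2, `supportive care` = 1)
  surv_base <- c(resection = 25, transplant = 28, TACE = 22, SIRT = 18,
                 ablation = 26, `medical therapy` = 14,
                 `supportive care` = 4)
  # P(waiting | treatment): truncated Poisson (or the fixed 3-month point
  # mass in the deterministic variant)
  p_wait <- sapply(trts, function(y) {
    if (deterministic) {
      as.numeric(wstates == 3L)
    } else {
      p <- stats::dpois(wstates, wait_mu[[y]])
      p[length(p)] <- p[length(p)] +
        stats::ppois(waiting_max, wait_mu[[y]], lower.tail = FALSE)
      p / sum(p)
    }
  })
  # P(survival | treatment, waiting): negative binomial around a
  # treatment-specific mean with a waiting penalty, tail mass at the cap
  p_surv <- array(0, dim = c(length(sstates), length(trts),
                             length(wstates)),
                  dimnames = list(as.character(sstates), trts,
                                  as.character(wstates)))
  for (yi in seq_along(trts)) {
    for (ti in seq_along(wstates)) {
      m <- max(1, surv_base[[trts[yi]]] - 0.3 * wstates[ti])
      if (deterministic) {
        p <- as.numeric(sstates == min(survival_max, round(m)))
      } else {
        p <- stats::dnbinom(sstates, size = 8, mu = m)
        p[length(p)] <- p[length(p)] +
          stats::pnbinom(survival_max, size = 8, mu = m,
                         lower.tail = FALSE)
        p <- p / sum(p)
      }
      p_surv[, yi, ti] <- p
    }
  }
  u_states <- 12L
  # inverse-CDF lookups: u -> realised waiting (per treatment) and survival
  q_of <- function(p, q) which(cumsum(p) >= q - 1e-12)[1L]
  wait_q <- sapply(trts, function(y) {
    vapply(seq_len(u_states), function(u)
      wstates[q_of(p_wait[, y], (u - 0.5) / u_states)], 1L)
  })
  surv_q <- array(0L, dim = c(u_states, length(trts), length(wstates)),
                  dimnames = list(NULL, trts, as.character(wstates)))
  for (yi in seq_along(trts)) {
    for (ti in seq_along(wstates)) {
      surv_q[, yi, ti] <- vapply(seq_len(u_states), function(u)
        sstates[q_of(p_surv[, yi, ti], (u - 0.5) / u_states)], 1L)
    }
  }
  structure(list(
    deterministic = deterministic,
    p_male = 0.77, p_cirrhosis = 0.71, age_mean = 71, age_sd = 10,
    aetiology = c(`Alcoholic Liver Disease` = 62, Autoimmune = 8,
                  `Chronic hepatitis B` = 3, `Chronic hepatitis C` = 20,
                  Haemochromatosis = 6,
                  `Non-Alcoholic Fatty Liver Disease` = 69,
                  Unknown = 22) / 190,
    present_mode = c(incidental = 80, surveillance = 64,
                     symptomatic = 46) / 190,
    stage = c(`0` = 0.29, A = 0.16, B = 0.08, C = 0.41, D = 0.06),
    ps_given_stage = list(
      `0` = c(`0` = 0.90, `1` = 0.10),
      A = c(`0` = 0.90, `1` = 0.10),
      B = c(`0` = 0.85, `1` = 0.15),
      C = c(`0` = 0.20, `1` = 0.45, `2` = 0.35),
      D = c(`3` = 0.60, `4` = 0.40)),
    size_meanlog = log(c(`0` = 15, A = 25, B = 45, C = 50, D = 60)),
    size_sdlog = 0.4,
    p_comply = p_comply,
    noncomply_weights = c(resection = 0.20, transplant = 0.10, TACE = 0.30,
                          SIRT = 0.05, ablation = 0.20,
                          `medical therapy` = 0.07,
                          `supportive care` = 0.08),
    p_wait = p_wait, p_surv = p_surv,
    wait_q = wait_q, surv_q = surv_q, u_states = u_states,
    missingness = missingness,
    waiting_max = waiting_max, survival_max = survival_max
  ), class = "hcc_cohort_spec")
}

#' Sample a synthetic cohort with hidden ground truth
#'
#' Ancestral sampling from a [cohort_spec()].  Each case records, besides
#' its observable fields, the latent rank draws `Us`/`Ut`, the compliance
#' draw, and the potential survival under every treatment (holding the
#' realised waiting time fixed); by construction the potential outcome of
#' the factual treatment equals the observed survival.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of cases (0 allowed).
#' @param seed Integer seed; identical `(spec, n, seed)` give byte-identical
#'   output.
#' @param rules Rule table defining guideline compliance (default shipped
#'   BCLC-2022 table).
#' @return Object of class `"hcc_sim"`: list with `records` (data.frame in
#'   the cohort CSV schema, no missingness yet) and `truth` (data.frame with
#'   `id`, `Us`, `Ut`, `compliant`, `leaf` and `po_1`..`po_7`, the potential
#'   survival months per treatment in [hcc_treatments()] order).
#' @export
sample_cohort <- function(spec, n, seed = 1L, rules = bclc_rules()) {
  stopifnot(inherits(spec, "hcc_cohort_spec"), n >= 0)
  trts <- hcc_treatments()
  if (n == 0) {
    return(structure(list(
      records = data.frame(id = character(0)),
      truth = data.frame(id = character(0))), class = "hcc_sim"))
  }
  .with_seed(seed, {
    id <- sprintf("case%05d", seq_len(n))
    sex <- ifelse(stats::runif(n) < spec$p_male, "M", "F")
    cirrhosis <- ifelse(stats::runif(n) < spec$p_cirrhosis, "Yes", "No")
    age <- pmin(95, pmax(18, round(stats::rnorm(n, spec$age_mean,
                                                spec$age_sd))))
    aetiology <- sample(names(spec$aetiology), n, replace = TRUE,
                        prob = spec$aetiology)
    present_mode <- sample(names(spec$present_mode), n, replace = TRUE,
                           prob = spec$present_mode)
    stage <- sample(names(spec$stage), n, replace = TRUE, prob = spec$stage)
    ps <- vapply(stage, function(s) {
      p <- spec$ps_given_stage[[s]]
      sample(names(p), 1L, prob = p)
    }, "")
    size <- round(stats::rlnorm(n, spec$size_meanlog[stage],
                                spec$size_sdlog))
    size <- pmin(150, pmax(2, size))
    comply <- stats::runif(n) < spec$p_comply
    treatment <- character(n)
    leaf <- character(n)
    for (i in seq_len(n)) {
      r <- recommend_treatment(ps[i], stage[i], size[i], rules)
      leaf[i] <- r$leaf
      if (comply[i]) {
        treatment[i] <- if (length(r$recommended) == 1L) r$recommended else
          sample(r$recommended, 1L)
      } else {
        w <- spec$noncomply_weights[setdiff(trts, r$recommended)]
        treatment[i] <- sample(names(w), 1L, prob = w)
      }
    }
    ut <- sample.int(spec$u_states, n, replace = TRUE)
    us <- sample.int(spec$u_states, n, replace = TRUE)
    yi <- match(treatment, trts)
    waiting <- spec$wait_q[cbind(ut, yi)]
    po <- matrix(0L, n, length(trts),
                 dimnames = list(NULL, paste0("po_", seq_along(trts))))
    for (j in seq_along(trts)) {
      po[, j] <- spec$surv_q[cbind(us, j, waiting + 1L)]
    }
    survival <- po[cbind(seq_len(n), yi)]
    mdm_date <- as.Date("2019-03-01") +
      sample.int(365L, n, replace = TRUE) - 1L
    records <- data.frame(
      id = id, age = age, sex = sex, aetiology = aetiology,
      cirrhosis = cirrhosis, present_mode = present_mode,
      size_mm = size, ps = ps, bclc_stage = stage, treatment = treatment,
      waiting_months = waiting, survival_months = survival,
      alive_dead = ifelse(survival >= spec$survival_max, "Alive", "Dead"),
      mdm_date = mdm_date, stringsAsFactors = FALSE)
    truth <- data.frame(id = id, Us = us, Ut = ut, compliant = comply,
                        leaf = leaf, stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(po))
    structure(list(records = records, truth = truth), class = "hcc_sim")
  })
}

#' Mask fields completely at random
#'
#' Masks `size_mm`, `ps` and `waiting_months` independently of everything
#' (a fortiori missing-at-random), at the given rates.
#'
#' @param x An `"hcc_sim"` or a records data.frame.
#' @param rates Named rates in `[0, 1]` for `size_mm`, `ps`,
#'   `waiting_months`.
#' @param seed Integer seed.
#' @return Same type as `x`, with masked cells set to `NA`; realised
#'   fractions attached as attribute `"realised_rates"`.
#' @export
inject_missingness <- function(x, rates = c(size_mm = 0.04, ps = 0.016,
                                            waiting_months = 0.62),
                               seed = 1L) {
  if (any(rates < 0 | rates > 1)) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  rec <- if (inherits(x, "hcc_sim")) x$records else x
  n <- nrow(rec)
  realised <- stats::setNames(numeric(length(rates)), names(rates))
  .with_seed(seed, {
    for (f in names(rates)) {
      mask <- stats::runif(n) < rates[[f]]
      rec[[f]][mask] <- NA
      realised[f] <- mean(mask)
    }
  })
  attr(rec, "realised_rates") <- realised
  if (inherits(x, "hcc_sim")) {
    x$records <- rec
    attr(x, "realised_rates") <- realised
    x
  } else {
    rec
  }
}

#' Wrap a records data.frame as a cohort
#'
#' @param records Data.frame in the cohort schema (see [load_cohort()]).
#' @return An `"hcc_cohort"` with an empty cleaning log.
#' @export
as_cohort <- function(records) {
  structure(list(
    records = records,
    report = list(n_input = nrow(records),
                  n_after_window_filter = nrow(records),
                  missing_before = .missing_counts(records),
                  missing_after = NULL,
                  imputations = data.frame(id = character(0),
                                           field = character(0),
                                           value = character(0),
                                           method = character(0),
                                           stringsAsFactors = FALSE))),
    class = "hcc_cohort")
}

#' End-to-end recovery experiment against hidden ground truth
#'
#' Generates a cohort, masks fields at the spec's rates, runs the full
#' pipeline (clean sizes and performance status, discretise, audit
#' compliance, two-pass waiting-time imputation, parameter learning, noise
#' attachment) and scores three things against the generator's hidden truth:
#' (a) the learned survival CPT against the generator's (12-level-quantised)
#' conditional, on parent configurations with at least `min_rows` realised
#' complete cases; (b) per-case counterfactual MAP survival under every
#' treatment against the hidden potential outcomes, for the first `n_eval`
#' cases; (c) the measured non-compliance fraction against the generative
#' compliance probability.
#'
#' @param spec A [cohort_spec()].
#' @param n Cohort size.
#' @param seed Integer seed (all derived seeds stay close to it).
#' @param weight Smoothing pseudo-count for learning.
#' @param mode Noise-mechanism mode for the counterfactual engine.
#' @param n_eval Number of cases scored in (b).
#' @param min_rows Population threshold for (a).
#' @return List with `n`, `cpt_max_error`, `cpt_n_configs`,
#'   `cf_agreement`, `cf_n_checked`, `noncompliant_measured`,
#'   `noncompliant_drawn`, `p_comply_spec`, `n_imputed`.
#' @export
recovery_experiment <- function(spec, n, seed = 1L, weight = 0.001,
                                mode = c("copy", "quantile"),
                                n_eval = 100L, min_rows = 200L) {
  mode <- match.arg(mode)
  trts <- hcc_treatments()
  sim <- sample_cohort(spec, n, seed = seed)
  masked <- inject_missingness(sim, spec$missingness, seed = seed + 1L)
  cohort <- as_cohort(masked$records)
  cohort <- clean_size(cohort)
  cohort <- clean_ps(cohort)
  cohort <- discretize_months(cohort, spec$survival_max, spec$waiting_max)
  traces <- assess_compliance(cohort)
  cohort$records$compliance <- traces$compliant
  n_missing_wait <- sum(is.na(cohort$records$waiting_months))
  cohort <- impute_waiting_time(cohort, weight = weight)
  net <- attach_noise_nodes(cohort$bn, mode = mode,
                            u_states = spec$u_states)

  # (a) survival-CPT recovery from the complete (pre-masking) cohort
  complete <- as_cohort(sim$records)
  complete$records$compliance <- traces$compliant
  fit_c <- bn_fit(hcc_dag(spec$waiting_max, spec$survival_max),
                  .cohort_bn_data(complete$records), weight = weight)
  truth_cpt <- .quantised_survival_cpt(spec)
  counts <- table(factor(sim$records$treatment, levels = trts),
                  factor(sim$records$waiting_months,
                         levels = 0:spec$waiting_max))
  cpt_err <- 0; n_cfg <- 0L
  for (yi in seq_along(trts)) {
    for (ti in seq_len(spec$waiting_max + 1L)) {
      if (counts[yi, ti] >= min_rows) {
        e <- max(abs(fit_c$cpts$Survival_fromMDM[, yi, ti] -
                       truth_cpt[, yi, ti]))
        cpt_err <- max(cpt_err, e)
        n_cfg <- n_cfg + 1L
      }
    }
  }

  # (b) counterfactual MAP vs hidden potential outcomes
  n_eval <- min(n_eval, n)
  agree <- 0L; checked <- 0L
  rec <- cohort$records
  for (i in seq_len(n_eval)) {
    prof <- case_profile(
      compliance = ifelse(rec$compliance[i], "Yes", "No"),
      treatment = rec$treatment[i],
      waiting_months = rec$waiting_months[i],
      survival_months = rec$survival_months[i],
      id = rec$id[i])
    tbl <- enumerate_treatment_counterfactuals(net, prof)
    for (j in seq_along(trts)) {
      pred <- tbl$map_months[tbl$treatment == trts[j]]
      truth_po <- sim$truth[[paste0("po_", j)]][i]
      checked <- checked + 1L
      if (pred == truth_po) agree <- agree + 1L
    }
  }

  list(
    n = n,
    cpt_max_error = cpt_err,
    cpt_n_configs = n_cfg,
    cf_agreement = if (checked) agree / checked else NA_real_,
    cf_n_checked = checked,
    noncompliant_measured = mean(!traces$compliant),
    noncompliant_drawn = mean(!sim$truth$compliant),
    p_comply_spec = spec$p_comply,
    n_imputed = n_missing_wait
  )
}

# the generator's survival conditional after 12-level rank quantisation:
# what a consistent learner converges to
.quantised_survival_cpt <- function(spec) {
  trts <- hcc_treatments()
  k <- spec$survival_max + 1L
  out <- array(0, dim = dim(spec$p_surv), dimnames = dimnames(spec$p_surv))
  for (yi in seq_along(trts)) {
    for (ti in seq_len(spec$waiting_max + 1L)) {
      tab <- tabulate(spec$surv_q[, yi, ti] + 1L, nbins = k)
      out[, yi, ti] <- tab / spec$u_states
    }
  }
  out
}
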