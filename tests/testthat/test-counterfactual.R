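# shared fixture: a trained clinical network on a synthetic cohort
fit_clinical <- function(n = 300, seed = 23, weight = 0.001) {
  bn_fit(hcc_dag(), toy_clinical_data(n, seed = seed), weight = weight)
}

test_that("noise priors are uniform and copy mode replicates the conditional", {
  net <- attach_noise_nodes(fit_clinical(), mode = "copy")
  expect_equal(as.vector(net$cpts$Us), rep(1 / 12, 12))
  expect_equal(as.vector(net$cpts$Ut), rep(1 / 12, 12))
  s_cpt <- net$cpts$Survival_fromMDM
  for (u in 2:12) {
    expect_identical(s_cpt[, , , u], s_cpt[, , , 1L])
  }
  expect_setequal(net$parents$Survival_fromMDM,
                  c("Treatment_grps", "T_MDM_first_treatment", "Us"))
})

test_that("marginalising uniform noise in quantile mode recovers the learned conditional", {
  fit <- fit_clinical()
  net <- attach_noise_nodes(fit, mode = "quantile")
  learned <- fit$cpts$Survival_fromMDM
  sq <- net$cpts$Survival_fromMDM
  for (y in c("TACE", "supportive care")) {
    for (t in c("0", "3", "10")) {
      marg <- apply(sq[, y, t, ], 1L, mean)   # uniform mixture over Us
      # 12-bin inverse-CDF quantisation bounds the Kolmogorov distance to
      # the learned conditional by half a bin
      ks <- max(abs(cumsum(marg) - cumsum(learned[, y, t])))
      expect_lt(ks, 1 / 12)
      expect_equal(sum(marg), 1, tolerance = 1e-12)
    }
  }
})

test_that("copy-mode abduction leaves the noise uniform", {
  net <- attach_noise_nodes(fit_clinical(), mode = "copy")
  prof <- case_profile("No", "TACE", 3, 35)
  ab <- abduct(net, prof)
  expect_equal(as.vector(ab$cpts$Us), rep(1 / 12, 12), tolerance = 1e-10)
  expect_equal(as.vector(ab$cpts$Ut), rep(1 / 12, 12), tolerance = 1e-10)
  # abduction never alters CPTs of observed variables
  expect_identical(ab$cpts$Survival_fromMDM, net$cpts$Survival_fromMDM)
  expect_identical(ab$cpts$Treatment_grps, net$cpts$Treatment_grps)
})

test_that("quantile-mode abduction concentrates on the matching rank", {
  # hand-built mechanism: survival uniform over 12 states, so the quantile
  # map is the identity u -> state u; observing the top state must pin Us
  vars <- list(Treatment_grps = c("a", "b"),
               T_MDM_first_treatment = c("0", "1"),
               Survival_fromMDM = as.character(1:12))
  dag <- bn_dag(vars, list(c("Treatment_grps", "Survival_fromMDM"),
                           c("T_MDM_first_treatment", "Survival_fromMDM")))
  unif <- rep(1 / 12, 12)
  cpts <- list(
    Treatment_grps = oracle_cpt(vars, "Treatment_grps", NULL, c(0.5, 0.5)),
    T_MDM_first_treatment = oracle_cpt(vars, "T_MDM_first_treatment", NULL,
                                       c(0.5, 0.5)),
    Survival_fromMDM = oracle_cpt(vars, "Survival_fromMDM",
                                  c("Treatment_grps",
                                    "T_MDM_first_treatment"),
                                  rep(unif, 4))
  )
  bn <- make_bn(dag, cpts)
  # Compliance is absent here on purpose: abduction only needs the factual
  # evidence the network can hold
  net <- attach_noise_nodes(bn, mode = "quantile")
  ev <- c(Treatment_grps = "a", T_MDM_first_treatment = "0",
          Survival_fromMDM = "12")
  post <- joint_posterior(net, ev, c("Us", "Ut"))
  us_marg <- apply(post, 1L, sum)
  expect_identical(unname(which.max(us_marg)), 12L)
  expect_gt(us_marg[12L], 0.8)
})

test_that("marginal and joint abduction differ when a collider couples the noises", {
  # with all four clinical variables observed the noise posterior
  # factorises, so a coupling needs a net where both noises feed the one
  # observed child
  vars <- list(Ut = as.character(1:3), Us = as.character(1:3),
               T = c("t0", "t1"), S = c("s0", "s1"))
  dag <- bn_dag(vars, list(c("Ut", "T"), c("Ut", "S"), c("Us", "S")))
  set.seed(61)
  pt <- stats::runif(3, 0.1, 0.9)
  ps <- stats::runif(9, 0.1, 0.9)
  bn <- make_bn(dag, list(
    Ut = oracle_cpt(vars, "Ut", NULL, rep(1 / 3, 3)),
    Us = oracle_cpt(vars, "Us", NULL, rep(1 / 3, 3)),
    T = oracle_cpt(vars, "T", "Ut", as.vector(rbind(pt, 1 - pt))),
    S = oracle_cpt(vars, "S", c("Ut", "Us"),
                   as.vector(rbind(ps, 1 - ps)))))
  ev <- c(S = "s1")   # conditioning on the collider child couples Us, Ut
  ab_m <- abduct(bn, ev, joint = FALSE)
  ab_j <- abduct(bn, ev, joint = TRUE)
  p_m <- infer_posterior(do_intervention(ab_m, c(T = "t0")), NULL, "S")
  p_j <- infer_posterior(do_intervention(ab_j, c(T = "t0")), NULL, "S")
  expect_gt(max(abs(p_m - p_j)), 1e-6)
  # both remain proper distributions
  expect_equal(sum(p_m), 1, tolerance = 1e-9)
  expect_equal(sum(p_j), 1, tolerance = 1e-9)
})

test_that("null counterfactuals on a deterministic mechanism return the factual outcome", {
  # deterministic generator: waiting fixed, survival a point mass per
  # treatment; learning with w = 0 keeps the mechanism deterministic
  spec <- cohort_spec(deterministic = TRUE)
  sim <- sample_cohort(spec, 400, seed = 29)
  dat <- data.frame(
    Compliance = ifelse(sim$truth$compliant, "Yes", "No"),
    Treatment_grps = sim$records$treatment,
    T_MDM_first_treatment = as.character(sim$records$waiting_months),
    Survival_fromMDM = as.character(sim$records$survival_months))
  fit <- bn_fit(hcc_dag(), dat, weight = 0)
  net <- attach_noise_nodes(fit, mode = "copy")
  for (i in c(1L, 7L, 42L)) {
    prof <- case_profile(dat$Compliance[i], dat$Treatment_grps[i],
                         dat$T_MDM_first_treatment[i],
                         dat$Survival_fromMDM[i])
    cf <- counterfactual(net, prof,
                         c(Compliance = dat$Compliance[i],
                           Treatment_grps = dat$Treatment_grps[i],
                           T_MDM_first_treatment =
                             dat$T_MDM_first_treatment[i]))
    expect_identical(cf$map_state, dat$Survival_fromMDM[i])
    expect_equal(cf$map_probability, 1, tolerance = 1e-12)
  }
})

test_that("after do(treatment, waiting), compliance evidence is screened off", {
  net <- attach_noise_nodes(fit_clinical(seed = 37), mode = "copy")
  iv <- c(Treatment_grps = "ablation", T_MDM_first_treatment = "2")
  p_no <- counterfactual(net, case_profile("No", "TACE", 3, 20), iv)
  p_yes <- counterfactual(net, case_profile("Yes", "TACE", 3, 20), iv)
  expect_equal(p_no$posterior, p_yes$posterior, tolerance = 1e-10)
})

test_that("copy-mode predictions reduce to the learned conditional's MAP", {
  for (s in 1:10) {
    fit <- fit_clinical(n = 150, seed = 600 + s)
    net <- attach_noise_nodes(fit, mode = "copy")
    set.seed(700 + s)
    y <- sample(hcc_treatments(), 1L)
    t <- as.character(sample(0:24, 1L))
    prof <- case_profile("No", sample(hcc_treatments(), 1L), t,
                         sample(0:40, 1L))
    cf <- counterfactual(net, prof, c(Treatment_grps = y))
    row <- fit$cpts$Survival_fromMDM[, y, t]
    expect_equal(unname(cf$posterior), unname(row), tolerance = 1e-10)
    expect_identical(cf$map_state, names(which.max(row)))
  }
})

test_that("MAP ties break toward the smaller month", {
  vars <- list(Treatment_grps = c("a", "b"),
               T_MDM_first_treatment = c("0", "1"),
               Survival_fromMDM = as.character(0:3))
  dag <- bn_dag(vars, list(c("Treatment_grps", "Survival_fromMDM"),
                           c("T_MDM_first_treatment", "Survival_fromMDM")))
  tied <- c(0.1, 0.4, 0.4, 0.1)
  cpts <- list(
    Treatment_grps = oracle_cpt(vars, "Treatment_grps", NULL, c(0.5, 0.5)),
    T_MDM_first_treatment = oracle_cpt(vars, "T_MDM_first_treatment", NULL,
                                       c(0.5, 0.5)),
    Survival_fromMDM = oracle_cpt(vars, "Survival_fromMDM",
                                  c("Treatment_grps",
                                    "T_MDM_first_treatment"),
                                  rep(tied, 4)))
  net <- attach_noise_nodes(make_bn(dag, cpts), mode = "copy")
  prof <- case_profile("No", "a", 0, 1)
  cf <- counterfactual(net, prof, c(Treatment_grps = "b"))
  expect_identical(cf$map_months, 1L)
})

test_that("treatment enumeration is exhaustive, ordered, and symmetric when rows coincide", {
  net <- attach_noise_nodes(fit_clinical(), mode = "copy")
  prof <- case_profile("No", "TACE", 3, 35, id = "CaseX")
  tbl <- enumerate_treatment_counterfactuals(net, prof)
  expect_setequal(tbl$treatment, hcc_treatments())
  expect_true(all(diff(tbl$map_months) <= 0))
  expect_identical(tbl$treatment[tbl$factual], "TACE")
  # a network whose survival CPT ignores the treatment gives 7 identical
  # predictions
  flat <- net
  k <- dim(flat$cpts$Survival_fromMDM)
  one <- flat$cpts$Survival_fromMDM[, 1L, , ]
  for (j in seq_len(k[2L])) flat$cpts$Survival_fromMDM[, j, , ] <- one
  tbl2 <- enumerate_treatment_counterfactuals(flat, prof)
  expect_identical(unique(tbl2$map_months), tbl2$map_months[1L])
})

test_that("joint queries with one intervention equal the single-intervention path", {
  net <- attach_noise_nodes(fit_clinical(), mode = "quantile")
  prof <- case_profile("No", "resection", 4, 25)
  a <- counterfactual(net, prof, c(Treatment_grps = "TACE"))
  b <- joint_query(net, prof, c(Treatment_grps = "TACE"))
  expect_equal(a$posterior, b$posterior, tolerance = 0)
  # intervening on all three upstream variables makes the abduced waiting
  # noise irrelevant
  iv <- c(Compliance = "Yes", Treatment_grps = "TACE",
          T_MDM_first_treatment = "2")
  c1 <- joint_query(net, prof, iv)
  forced <- replace_prior(abduct(net, prof), "Ut",
                          c(1, rep(0, 11)))
  c2 <- infer_posterior(do_intervention(forced, iv), iv["Treatment_grps"],
                        "Survival_fromMDM")
  # compare under identical do-surgery but different Ut priors
  bn_a <- do_intervention(abduct(net, prof), iv)
  p_a <- infer_posterior(bn_a, NULL, "Survival_fromMDM")
  bn_b <- do_intervention(replace_prior(abduct(net, prof), "Ut",
                                        rep(1 / 12, 12)), iv)
  p_b <- infer_posterior(bn_b, NULL, "Survival_fromMDM")
  expect_equal(p_a, p_b, tolerance = 1e-12)
})

test_that("the outcome can never be intervened on", {
  net <- attach_noise_nodes(fit_clinical(), mode = "copy")
  prof <- case_profile("No", "TACE", 3, 35)
  expect_error(counterfactual(net, prof, c(Survival_fromMDM = "10")),
               "outcome")
})

test_that("case reports pair factual and primed counterfactual rows", {
  net <- attach_noise_nodes(fit_clinical(), mode = "copy")
  profs <- list(
    case_profile("No", "TACE", 3, 35, id = "Case1", age = 73, sex = "M",
                 size_mm = 21, ps = "0", bclc_stage = "A"),
    case_profile("No", "resection", 4, 25, id = "Case8", age = 77,
                 sex = "M", size_mm = 53, ps = "1", bclc_stage = "C"))
  res <- list(
    counterfactual(net, profs[[1]], c(Compliance = "Yes",
                                      Treatment_grps = "resection")),
    counterfactual(net, profs[[2]], c(Compliance = "Yes",
                                      Treatment_grps = "medical therapy")))
  rep <- case_report(profs, res)
  expect_identical(nrow(rep), 4L)
  expect_identical(rep$case, c("Case1", "Case1′", "Case8", "Case8′"))
  expect_identical(rep$treatment[2L], "resection")
  expect_identical(rep$waiting_months[2L], 3L)  # factual waiting retained
  expect_identical(rep$survival_months[1L], 35L)
  # header-only for an empty batch
  expect_identical(nrow(case_report(list(), list())), 0L)
})

test_that("smoothing sweeps flatten the survival posterior monotonically", {
  dat <- toy_clinical_data(300, seed = 41)
  sw <- smoothing_sensitivity(hcc_dag(), dat,
                              weights = c(1e-4, 1e-3, 0.1, 1, 1e4),
                              evidence = c(Treatment_grps = "TACE",
                                           T_MDM_first_treatment = "3"))
  expect_true(all(diff(sw$summary$entropy) >= -1e-12))
  expect_equal(sw$summary$entropy[5L], log(41), tolerance = 1e-3)
  expect_error(smoothing_sensitivity(hcc_dag(), dat, weights = c(0, 1)),
               "positive")
})
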