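write_fixture_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

fixture_rows <- function() {
  data.frame(
    id = c("p1", "p2", "p3"),
    age = c(73, 61, 77),
    sex = c("M", "F", "M"),
    aetiology = c("NAFLD", "HCV", "NAFLD"),
    cirrhosis = c("Yes", "Yes", "No"),
    present_mode = c("incidental", "surveillance", "incidental"),
    size_mm = c(21, 13, 53),
    ps = c("0", "0", "1"),
    bclc_stage = c("A", "A", "C"),
    treatment = c("TACE", "ablation", "resection"),
    waiting_months = c(3, 4, 4),
    survival_months = c(35, 30, 25),
    alive_dead = c("Dead", "Dead", "Dead"),
    mdm_date = c("2019-05-01", "2019-07-12", "2020-01-20"),
    stringsAsFactors = FALSE
  )
}

test_that("a clean fixture loads with zero imputations", {
  co <- load_cohort(write_fixture_csv(fixture_rows()))
  expect_identical(nrow(co$records), 3L)
  rep <- cleaning_report(co)
  expect_identical(nrow(rep$imputations), 0L)
  expect_identical(unname(rep$missing_before), c(0L, 0L, 0L, 0L))
})

test_that("unparseable cells become missing, never dropped rows", {
  rows <- fixture_rows()
  rows$size_mm <- c("21", "NA", "not-a-number")
  co <- load_cohort(write_fixture_csv(rows))
  expect_identical(nrow(co$records), 3L)
  expect_identical(sum(is.na(co$records$size_mm)), 2L)
})

test_that("missing mandatory columns are named in the error", {
  rows <- fixture_rows()
  rows$treatment <- NULL
  expect_error(load_cohort(write_fixture_csv(rows)), "treatment")
})

test_that("centimetre input and the date window filter are honoured", {
  rows <- fixture_rows()
  rows$size_mm <- c(2.1, 1.3, 5.3)
  co <- load_cohort(write_fixture_csv(rows),
                    config = list(size_unit = "cm"))
  expect_equal(co$records$size_mm, c(21, 13, 53))
  co2 <- load_cohort(write_fixture_csv(fixture_rows()),
                     config = list(window = list(from = "2019-03-01",
                                                 to = "2019-12-31")))
  expect_identical(co2$report$n_input, 3L)
  expect_identical(co2$report$n_after_window_filter, 2L)
  expect_identical(nrow(co2$records), 2L)
})

test_that("mean size filling is exact, logged, and idempotent", {
  rows <- fixture_rows()
  rows$size_mm <- c(10, 20, NA)
  co <- load_cohort(write_fixture_csv(rows))
  co <- clean_size(co)
  expect_equal(co$records$size_mm, c(10, 20, 15))
  rep <- cleaning_report(co)
  imp <- rep$imputations[rep$imputations$field == "size_mm", ]
  expect_identical(nrow(imp), 1L)
  expect_identical(imp$id, "p3")
  # idempotent: a second pass changes nothing and logs nothing
  co2 <- clean_size(co)
  expect_identical(co2$records, co$records)
  expect_identical(co2$report$imputations, co$report$imputations)
  # all-missing is an error
  rows$size_mm <- c(NA, NA, NA)
  expect_error(clean_size(load_cohort(write_fixture_csv(rows))),
               "all tumour sizes")
})

test_that("missing performance status becomes the explicit 'unknown' level", {
  rows <- fixture_rows()
  rows$ps <- c("0", "", "1")
  co <- clean_ps(load_cohort(write_fixture_csv(rows)))
  expect_identical(co$records$ps, c("0", "unknown", "1"))
  expect_identical(clean_ps(co)$records$ps, co$records$ps)
})

test_that("durations are rounded half-up and survival is capped at 40", {
  rows <- fixture_rows()
  rows$waiting_months <- c(3.5, 2.4, 0)
  rows$survival_months <- c(45.2, 25, 39.5)
  co <- discretize_months(load_cohort(write_fixture_csv(rows)))
  expect_equal(co$records$waiting_months, c(4, 2, 0))
  expect_equal(co$records$survival_months, c(40, 25, 40))
  rows$waiting_months <- c(-1, 2, 3)
  expect_error(discretize_months(load_cohort(write_fixture_csv(rows))),
               "p1")
})

test_that("waiting-time imputation fills the exact posterior mode", {
  # toy 3-node network with hand-set state spaces small enough to enumerate
  vars <- list(Treatment_grps = c("resection", "supportive care"),
               T_MDM_first_treatment = c("0", "1", "2"),
               Survival_fromMDM = c("0", "1"))
  dag <- bn_dag(vars, list(c("T_MDM_first_treatment", "Survival_fromMDM"),
                           c("Treatment_grps", "Survival_fromMDM")))
  rec <- data.frame(
    id = sprintf("r%d", 1:8),
    size_mm = 20, ps = "0", bclc_stage = "A",
    treatment = c(rep("resection", 6), "supportive care",
                  "supportive care"),
    waiting_months = c(0, 0, 1, 2, 2, 2, 1, NA),
    survival_months = c(1, 1, 1, 0, 0, 1, 0, 0),
    stringsAsFactors = FALSE
  )
  co <- impute_waiting_time(as_cohort(rec), dag = dag, weight = 0.001)
  # oracle: available-case counts, then P(T | Y = supportive, S = 0) by
  # direct enumeration over the 3 waiting states
  w <- 0.001
  obs <- rec[!is.na(rec$waiting_months), ]
  p_t <- (table(factor(obs$waiting_months, levels = 0:2)) + w) /
    (nrow(obs) + 3 * w)
  post <- sapply(0:2, function(t) {
    sub <- rec[!is.na(rec$waiting_months) & rec$waiting_months == t &
                 rec$treatment == "supportive care", ]
    n_jk <- sum(sub$survival_months == 0)
    n_j <- nrow(sub)
    p_s <- (n_jk + w) / (n_j + 2 * w)
    p_t[[t + 1]] * p_s
  })
  oracle_mode <- (0:2)[which.max(post)]
  expect_identical(co$records$waiting_months[8], as.numeric(oracle_mode))
  # observed values never altered
  expect_identical(co$records$waiting_months[1:7],
                   rec$waiting_months[1:7])
  # report log agrees with the before/after missing-count difference
  rep <- cleaning_report(co)
  expect_identical(
    nrow(rep$imputations[rep$imputations$field == "waiting_months", ]), 1L)
  expect_identical(unname(rep$missing_after["waiting_months"]), 0L)
  # idempotent: nothing left to fill
  co2 <- impute_waiting_time(co, dag = dag, weight = 0.001)
  expect_identical(co2$records$waiting_months, co$records$waiting_months)
})

test_that("posterior-mean imputation is available and stays in range", {
  spec <- cohort_spec()
  sim <- sample_cohort(spec, 150, seed = 13)
  rec <- inject_missingness(sim$records,
                            c(size_mm = 0, ps = 0, waiting_months = 0.5),
                            seed = 14)
  co <- impute_waiting_time(as_cohort(rec), statistic = "mean")
  w <- co$records$waiting_months
  expect_false(anyNA(w))
  expect_true(all(w >= 0 & w <= 24 & w == round(w)))
})
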