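#' Load a patient cohort from CSV
#'
#' Reads a patient-level table (RFC-4180 CSV with a header) into typed
#' records and a cleaning report.  The canonical columns are `id`, `age`,
#' `sex` (M/F), `aetiology`, `cirrhosis` (Yes/No), `present_mode`
#' (incidental/surveillance/symptomatic), `size_mm` (solitary tumour
#' diameter), `ps` (performance status 0-4), `bclc_stage` (0/A/B/C/D),
#' `treatment` (one of [hcc_treatments()]), `waiting_months`,
#' `survival_months`, `alive_dead` (Alive/Dead) and `mdm_date`.  Deposited
#' files with different headers are mapped through `config`.
#'
#' Unparseable numeric cells become missing values and are counted in the
#' report; they are never silently dropped.  If `config$window` gives a date
#' range, rows whose `mdm_date` falls outside it are removed (the COVID-era
#' filter) and the report records the count before and after.
#'
#' @param path CSV file.
#' @param config Optional list (or YAML file path) with elements `columns`
#'   (named list mapping canonical name -> file header), `size_unit`
#'   (`"mm"`, the Table-style convention, or `"cm"`), and `window` (list
#'   with `from`, `to` dates for the treatment-window filter).
#' @return An object of class `"hcc_cohort"`: list with `records` (a
#'   data.frame) and `report` (see [cleaning_report()]).
#' @export
load_cohort <- function(path, config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  canon <- c("id", "age", "sex", "aetiology", "cirrhosis", "present_mode",
             "size_mm", "ps", "bclc_stage", "treatment", "waiting_months",
             "survival_months", "alive_dead", "mdm_date")
  cols <- stats::setNames(as.list(canon), canon)
  if (!is.null(config$columns)) cols[names(config$columns)] <- config$columns
  mandatory <- setdiff(canon, c("id", "mdm_date", "alive_dead", "age",
                                "sex", "aetiology", "cirrhosis",
                                "present_mode"))
  for (cn in mandatory) {
    if (!cols[[cn]] %in% names(raw)) {
      stop(sprintf("mandatory column '%s' (mapped from '%s') is missing",
                   cols[[cn]], cn), call. = FALSE)
    }
  }
  get <- function(cn) if (cols[[cn]] %in% names(raw)) raw[[cols[[cn]]]] else
    rep(NA, nrow(raw))
  num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  chr <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("", "NA", "N/A", "na", "unknown?")] <- NA
    x
  }
  rec <- data.frame(
    id = {
      v <- chr(get("id"))
      if (all(is.na(v))) sprintf("case%03d", seq_len(nrow(raw))) else v
    },
    age = num(get("age")),
    sex = chr(get("sex")),
    aetiology = chr(get("aetiology")),
    cirrhosis = chr(get("cirrhosis")),
    present_mode = chr(get("present_mode")),
    size_mm = num(get("size_mm")),
    ps = chr(get("ps")),
    bclc_stage = chr(get("bclc_stage")),
    treatment = chr(get("treatment")),
    waiting_months = num(get("waiting_months")),
    survival_months = num(get("survival_months")),
    alive_dead = chr(get("alive_dead")),
    mdm_date = as.Date(chr(get("mdm_date"))),
    stringsAsFactors = FALSE
  )
  unit <- if (is.null(config$size_unit)) "mm" else config$size_unit
  if (identical(unit, "cm")) rec$size_mm <- rec$size_mm * 10
  bad_trt <- which(!is.na(rec$treatment) &
                     !(rec$treatment %in% hcc_treatments()))
  if (length(bad_trt)) {
    stop(sprintf("row %d: unknown treatment '%s'",
                 bad_trt[1L], rec$treatment[bad_trt[1L]]), call. = FALSE)
  }
  n_input <- nrow(rec)
  if (!is.null(config$window)) {
    from <- as.Date(config$window$from); to <- as.Date(config$window$to)
    keep <- !is.na(rec$mdm_date) & rec$mdm_date >= from & rec$mdm_date <= to
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
  }
  report <- list(
    n_input = n_input,
    n_after_window_filter = nrow(rec),
    missing_before = .missing_counts(rec),
    missing_after = NULL,
    imputations = data.frame(id = character(0), field = character(0),
                             value = character(0), method = character(0),
                             stringsAsFactors = FALSE)
  )
  structure(list(records = rec, report = report), class = "hcc_cohort")
}

.missing_counts <- function(rec) {
  vapply(c("size_mm", "ps", "waiting_months", "survival_months"),
         function(f) sum(is.na(rec[[f]])), 1L)
}

.log_imputations <- function(cohort, id, field, value, method) {
  add <- data.frame(id = as.character(id), field = field,
                    value = as.character(value), method = method,
                    stringsAsFactors = FALSE)
  cohort$report$imputations <- rbind(cohort$report$imputations, add)
  cohort
}

#' Cleaning report of a cohort
#'
#' @param cohort An `"hcc_cohort"`.
#' @return List with input/filtered row counts, per-field missing counts
#'   before and after cleaning, and a log of every imputed cell (id, field,
#'   value, method).
#' @export
cleaning_report <- function(cohort) {
  rep <- cohort$report
  rep$missing_after <- .missing_counts(cohort$records)
  rep
}

#' Write the cleaning report as JSON
#'
#' @param cohort An `"hcc_cohort"`.
#' @param path Output file.
#' @export
write_cleaning_report <- function(cohort, path) {
  jsonlite::write_json(cleaning_report(cohort), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Fill missing tumour sizes with the population mean
#'
#' Missing `size_mm` values are replaced by the arithmetic mean of the
#' observed sizes (unrounded, in millimetres); every fill is logged.
#'
#' @param cohort An `"hcc_cohort"`.
#' @return The cohort with sizes completed.
#' @export
clean_size <- function(cohort) {
  rec <- cohort$records
  obs <- rec$size_mm[!is.na(rec$size_mm)]
  if (!length(obs)) stop("all tumour sizes are missing", call. = FALSE)
  miss <- which(is.na(rec$size_mm))
  if (length(miss)) {
    m <- mean(obs)
    rec$size_mm[miss] <- m
    cohort <- .log_imputations(cohort, rec$id[miss], "size_mm", m,
                               "population mean")
  }
  cohort$records <- rec
  cohort
}

#' Map missing performance status to the explicit level "unknown"
#'
#' @param cohort An `"hcc_cohort"`.
#' @return The cohort with `ps` completed; "unknown" is kept as a level, the
#'   rows are never dropped.
#' @export
clean_ps <- function(cohort) {
  rec <- cohort$records
  miss <- which(is.na(rec$ps))
  if (length(miss)) {
    rec$ps[miss] <- "unknown"
    cohort <- .log_imputations(cohort, rec$id[miss], "ps", "unknown",
                               "explicit unknown level")
  }
  cohort$records <- rec
  cohort
}

#' Discretise waiting and survival to integer months and cap survival
#'
#' Durations are rounded half-up to whole months; survival values above the
#' cap are set to the cap (the cohort's censoring horizon).
#'
#' @param cohort An `"hcc_cohort"`.
#' @param survival_cap Cap in months (default 40).
#' @param waiting_cap Largest representable waiting time (default 24).
#' @return The cohort with integer month values.
#' @export
discretize_months <- function(cohort, survival_cap = 40L, waiting_cap = 24L) {
  rec <- cohort$records
  neg <- which(!is.na(rec$waiting_months) & rec$waiting_months < 0 |
                 !is.na(rec$survival_months) & rec$survival_months < 0)
  if (length(neg)) {
    stop(sprintf("negative duration in row id '%s'", rec$id[neg[1L]]),
         call. = FALSE)
  }
  half_up <- function(x) floor(x + 0.5)
  rec$waiting_months <- pmin(half_up(rec$waiting_months), waiting_cap)
  rec$survival_months <- pmin(half_up(rec$survival_months), survival_cap)
  cohort$records <- rec
  cohort
}

# project cohort records onto the network's variable columns
.cohort_bn_data <- function(rec, waiting_max = 24L, survival_max = 40L) {
  d <- data.frame(
    Treatment_grps = rec$treatment,
    T_MDM_first_treatment = ifelse(is.na(rec$waiting_months), NA,
                                   as.character(as.integer(rec$waiting_months))),
    Survival_fromMDM = as.character(as.integer(rec$survival_months)),
    stringsAsFactors = FALSE
  )
  if ("compliance" %in% names(rec)) {
    d$Compliance <- ifelse(rec$compliance, "Yes", "No")
  }
  d
}

#' Impute missing waiting times by exact posterior inference
#'
#' Two-pass protocol: (1) learn the network's CPTs from the rows available
#' for each table (rows missing the waiting time still contribute to every
#' CPT that does not involve it, so supportive-care cases are not lost);
#' (2) for each row with a missing waiting time, compute the exact posterior
#' over waiting-time states given the row's treatment and survival (and
#' compliance when present) and fill with the posterior mode (ties to the
#' smallest month) or, optionally, the rounded posterior mean; (3) relearn
#' the CPTs on the completed table.  Observed values are never altered.
#'
#' @param cohort An `"hcc_cohort"` whose records carry treatment and integer
#'   survival (run [discretize_months()] first).
#' @param dag Network structure; defaults to [hcc_dag()] (with `Compliance`
#'   only if the records have a `compliance` column).
#' @param weight Smoothing pseudo-count for both learning passes.
#' @param statistic `"mode"` (default) or `"mean"` of the exact posterior.
#' @return The cohort, completed; the relearned network is attached as
#'   `cohort$bn`.
#' @export
impute_waiting_time <- function(cohort, dag = NULL, weight = 0.001,
                                statistic = c("mode", "mean")) {
  statistic <- match.arg(statistic)
  rec <- cohort$records
  data <- .cohort_bn_data(rec)
  if (is.null(dag)) {
    dag <- hcc_dag()
    if (!"Compliance" %in% names(data)) {
      keep <- setdiff(names(dag$variables), "Compliance")
      dag <- bn_dag(dag$variables[keep],
                    dag$edges[dag$edges[, 1L] != "Compliance" &
                                dag$edges[, 2L] != "Compliance", ,
                              drop = FALSE])
    }
  }
  need <- c("T_MDM_first_treatment", "Treatment_grps", "Survival_fromMDM")
  miss_nodes <- setdiff(need, names(dag$variables))
  if (length(miss_nodes)) {
    stop(sprintf("network lacks required node '%s'", miss_nodes[1L]),
         call. = FALSE)
  }
  fit1 <- bn_fit(dag, data, weight = weight, na_action = "available")
  wstates <- dag$variables$T_MDM_first_treatment
  miss <- which(is.na(data$T_MDM_first_treatment))
  for (i in miss) {
    ev <- c(Treatment_grps = data$Treatment_grps[i],
            Survival_fromMDM = data$Survival_fromMDM[i])
    if ("Compliance" %in% names(data)) {
      ev <- c(ev, Compliance = data$Compliance[i])
    }
    post <- infer_posterior(fit1, ev, "T_MDM_first_treatment")
    fill <- if (statistic == "mode") {
      wstates[which.max(post)]  # which.max takes the first (smallest month)
    } else {
      as.character(floor(sum(as.numeric(wstates) * post) + 0.5))
    }
    rec$waiting_months[i] <- as.numeric(fill)
    cohort <- .log_imputations(cohort, rec$id[i], "waiting_months", fill,
                               paste0("exact posterior ", statistic))
  }
  cohort$records <- rec
  cohort$bn <- bn_fit(dag, .cohort_bn_data(rec), weight = weight)
  cohort
}

#' @export
print.hcc_cohort <- function(x, ...) {
  cat(sprintf("HCC cohort: %d records (%d read, %d after window filter)\n",
              nrow(x$records), x$report$n_input,
              x$report$n_after_window_filter))
  m <- .missing_counts(x$records)
  cat("missing:", paste(sprintf("%s=%d", names(m), m), collapse = ", "),
      "\n")
  cat(sprintf("imputations logged: %d\n", nrow(x$report$imputations)))
  invisible(x)
}
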