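#' A case profile for counterfactual queries
#'
#' Bundles the four factual values a counterfactual query conditions on —
#' guideline compliance, treatment received, waiting time and survival, all
#' as recorded — together with descriptive fields carried only for
#' reporting.
#'
#' @param compliance `"Yes"` or `"No"`.
#' @param treatment One of [hcc_treatments()].
#' @param waiting_months Integer months from MDM to first treatment.
#' @param survival_months Integer months of survival from MDM (0-40).
#' @param id Case label (default `"case"`).
#' @param ... Descriptive fields (age, sex, aetiology, cirrhosis,
#'   present_mode, size_mm, ps, bclc_stage) kept for [case_report()].
#' @return Object of class `"hcc_case"` with elements `id`, `evidence`
#'   (named character vector over the four network variables) and `info`.
#' @export
case_profile <- function(compliance, treatment, waiting_months,
                         survival_months, id = "case", ...) {
  ev <- c(Compliance = as.character(compliance),
          Treatment_grps = as.character(treatment),
          T_MDM_first_treatment = as.character(as.integer(waiting_months)),
          Survival_fromMDM = as.character(as.integer(survival_months)))
  structure(list(id = id, evidence = ev, info = list(...)),
            class = "hcc_case")
}

#' Attach the exogenous noise variables Us and Ut
#'
#' Extends the trained observed-variable network with the two unobserved
#' personalisation variables: `Ut` feeding the waiting time and `Us` feeding
#' survival, each with `u_states` states (1..12 by default) and a uniform
#' prior.  Two constructions of the child mechanisms are available:
#'
#' * `mode = "copy"`: the learned conditional is replicated for every noise
#'   state, so the noise is a priori uninformative; abduction then leaves it
#'   uniform and predictions reduce to the learned conditional.  This is the
#'   default and reproduces the behaviour in which identical interventions
#'   yield identical predicted months across cases.
#' * `mode = "quantile"`: given its other parents, the child is set to the
#'   \eqn{(u - 0.5)/12} quantile of the learned conditional (with a small
#'   residual mass `epsilon` spread along the learned conditional, so every
#'   state keeps positive likelihood and abduction is always well defined),
#'   making the noise a rank-preserving individual effect.  Marginalising a
#'   uniform noise recovers the learned conditional up to 12-bin
#'   discretisation.
#'
#' @param bn Trained `"hccbn"` over the observed variables.
#' @param mode `"copy"` or `"quantile"`.
#' @param u_states Number of noise states (default 12).
#' @param epsilon Residual mass of the quantile mechanism (default 0.02;
#'   ignored in copy mode).
#' @return A `"hccbn"` with variables `Ut`, `Us` and edges
#'   `Ut -> T_MDM_first_treatment`, `Us -> Survival_fromMDM`.
#' @export
attach_noise_nodes <- function(bn, mode = c("copy", "quantile"),
                               u_states = 12L, epsilon = 0.02) {
  mode <- match.arg(mode)
  stopifnot(inherits(bn, "hccbn"))
  targets <- c(Ut = "T_MDM_first_treatment", Us = "Survival_fromMDM")
  miss <- setdiff(targets, names(bn$variables))
  if (length(miss)) {
    stop(sprintf("network lacks node '%s'", miss[1L]), call. = FALSE)
  }
  ust <- as.character(seq_len(u_states))
  for (u in names(targets)) {
    child <- targets[[u]]
    bn$variables[[u]] <- ust
    bn$cpts[[u]] <- array(rep(1 / u_states, u_states), dim = u_states,
                          dimnames = stats::setNames(list(ust), u))
    bn$parents[[u]] <- character(0)
    bn$edges <- rbind(bn$edges, c(u, child))
    bn$cpts[[child]] <- .noise_child_cpt(bn$cpts[[child]], child, u, ust,
                                         mode, epsilon)
    bn$parents[[child]] <- c(bn$parents[[child]], u)
  }
  bn$order <- validate_dag(.as_dag(bn))$order
  bn$noise_mode <- mode
  bn
}

# extend a CPT with a trailing noise parent, by replication or by the
# inverse-CDF (quantile) construction.  The quantile mechanism keeps a small
# residual mass (`epsilon`) on the learned conditional so that every state
# retains positive likelihood: a purely deterministic mechanism with 12 noise
# levels can explain at most 12 child states, which would make abduction
# impossible for factual values outside the quantile image.
.noise_child_cpt <- function(cpt, child, uname, ust, mode, epsilon = 0.02) {
  k <- dim(cpt)[1L]
  nu <- length(ust)
  old_dim <- dim(cpt)
  m <- matrix(cpt, nrow = k)          # columns = old parent configurations
  out <- array(0, dim = c(k, ncol(m), nu))
  if (mode == "copy") {
    for (u in seq_len(nu)) out[, , u] <- m
  } else {
    for (j in seq_len(ncol(m))) {
      cdf <- cumsum(m[, j])
      for (u in seq_len(nu)) {
        q <- (u - 0.5) / nu
        s <- which(cdf >= q - 1e-12)[1L]
        if (is.na(s)) s <- k
        row <- epsilon * m[, j]
        row[s] <- row[s] + (1 - epsilon)
        out[, j, u] <- row
      }
    }
  }
  new_dim <- c(old_dim, nu)
  dn <- c(dimnames(cpt), stats::setNames(list(ust), uname))
  array(out, dim = new_dim, dimnames = dn)
}

#' Abduction: absorb a case's factual profile into the noise priors
#'
#' Computes the exact posterior of `(Us, Ut)` given the case's four factual
#' values.  By default each noise variable's prior is replaced by its
#' posterior *marginal* (one modification per node); with `joint = TRUE` the
#' full joint posterior is preserved by additionally making `Ut` a child of
#' `Us` (the twin-network reading — conditioning on the observed survival
#' makes the two noise variables dependent through the collider).
#'
#' CPTs of the observed variables are never altered by abduction.
#'
#' @param bn Network with noise nodes attached.
#' @param profile An [case_profile()] (or named evidence vector over the four
#'   observed variables).
#' @param joint Preserve the joint noise posterior instead of the marginals.
#' @return The modified network; the abduced posterior is attached as
#'   attribute `"abduction"`.
#' @export
abduct <- function(bn, profile, joint = FALSE) {
  stopifnot(inherits(bn, "hccbn"))
  if (!all(c("Us", "Ut") %in% names(bn$variables))) {
    stop("attach_noise_nodes() first", call. = FALSE)
  }
  ev <- if (inherits(profile, "hcc_case")) profile$evidence else
    unlist(profile)
  ev <- ev[names(ev) %in% names(bn$variables)]
  ev <- .check_evidence(bn, ev)
  post <- joint_posterior(bn, ev, c("Us", "Ut"))
  p_us <- .f_marg(post, "Ut")
  p_ut <- .f_marg(post, "Us")
  bn2 <- replace_prior(bn, "Us", as.vector(p_us))
  if (!joint) {
    bn2 <- replace_prior(bn2, "Ut", as.vector(p_ut))
  } else {
    # P(Ut | Us) = joint / marginal; smoothing keeps the marginal positive
    cond <- sweep(post, 1L, as.vector(p_us), "/")
    cpt <- t(cond)                    # child (Ut) dimension first
    dn <- list(Ut = bn$variables$Ut, Us = bn$variables$Us)
    bn2$cpts$Ut <- array(cpt, dim = dim(cpt), dimnames = dn)
    bn2$parents$Ut <- "Us"
    bn2$edges <- rbind(bn2$edges, c("Us", "Ut"))
    bn2$order <- validate_dag(.as_dag(bn2))$order
  }
  attr(bn2, "abduction") <- list(joint = post, evidence = ev,
                                 mode = if (joint) "joint" else "marginal")
  bn2
}

#' Counterfactual survival query (abduction → action → prediction)
#'
#' Runs the three-step algorithm for one case: absorb the factual profile
#' into the noise priors ([abduct()]), apply [do_intervention()] for every
#' intervened variable, and predict the outcome's posterior.  During
#' prediction, factual evidence is retained on variables that are neither
#' intervened, nor the outcome, nor downstream of an intervened variable in
#' the mutilated graph; the factual outcome itself is always dropped — it
#' enters only through abduction.
#'
#' @param bn Network with noise nodes attached (see [attach_noise_nodes()]).
#' @param profile An [case_profile()].
#' @param interventions Named character vector of do-assignments over any
#'   subset of `Compliance`, `Treatment_grps`, `T_MDM_first_treatment`.
#' @param outcome Outcome variable (default survival); may not be
#'   intervened.
#' @param joint Use the joint-abduction (twin-network) option.
#' @return Object of class `"hccbn_cf"`: `posterior` (named numeric over the
#'   outcome states), `map_months` (maximum-a-posteriori state as integer;
#'   ties break toward the smaller month), `map_probability`, plus the
#'   interventions and retained evidence.
#' @examples
#' \donttest{
#' spec <- cohort_spec()
#' sim <- sample_cohort(spec, 400, seed = 1)
#' dat <- data.frame(Compliance = ifelse(sim$truth$compliant, "Yes", "No"),
#'                   Treatment_grps = sim$records$treatment,
#'                   T_MDM_first_treatment = as.character(sim$records$waiting_months),
#'                   Survival_fromMDM = as.character(sim$records$survival_months))
#' fit <- bn_fit(hcc_dag(), dat)
#' net <- attach_noise_nodes(fit)
#' prof <- case_profile("No", "TACE", 3, 35)
#' counterfactual(net, prof, c(Compliance = "Yes", Treatment_grps = "resection"))
#' }
#' @export
counterfactual <- function(bn, profile, interventions,
                           outcome = "Survival_fromMDM", joint = FALSE) {
  stopifnot(inherits(bn, "hccbn"), inherits(profile, "hcc_case"))
  interventions <- unlist(interventions)
  if (!length(interventions)) {
    stop("at least one intervention is required", call. = FALSE)
  }
  if (outcome %in% names(interventions)) {
    stop("the outcome may not be intervened on", call. = FALSE)
  }
  bn2 <- abduct(bn, profile, joint = joint)
  bn3 <- do_intervention(bn2, interventions)
  downstream <- .descendants(bn3$edges, names(interventions))
  keep <- setdiff(intersect(names(profile$evidence),
                            names(bn$variables)),
                  c(names(interventions), outcome, downstream))
  ev <- c(profile$evidence[keep], interventions)
  post <- infer_posterior(bn3, ev, outcome)
  map_i <- which.max(post)            # first max = smaller month
  structure(
    list(posterior = post,
         map_months = suppressWarnings(as.integer(names(post)[map_i])),
         map_state = names(post)[map_i],
         map_probability = unname(post[map_i]),
         interventions = interventions,
         retained_evidence = profile$evidence[keep],
         outcome = outcome,
         mode = bn$noise_mode,
         case = profile$id),
    class = "hccbn_cf")
}

#' @export
print.hccbn_cf <- function(x, ...) {
  cat(sprintf("Counterfactual for %s [%s mechanism]\n", x$case,
              if (is.null(x$mode)) "?" else x$mode))
  cat("  do(", paste(sprintf("%s=%s", names(x$interventions),
                             x$interventions), collapse = ", "), ")\n",
      sep = "")
  if (length(x$retained_evidence)) {
    cat("  retained evidence:",
        paste(sprintf("%s=%s", names(x$retained_evidence),
                      x$retained_evidence), collapse = ", "), "\n")
  }
  cat(sprintf("  predicted %s: %s months (posterior %.2f%%)\n",
              x$outcome, x$map_state, 100 * x$map_probability))
  invisible(x)
}

#' Counterfactual survival under every treatment option
#'
#' One counterfactual per treatment, everything else held at the case's
#' factual values; answers "what would the survival time have been had the
#' patient received each of the other treatment options?".
#'
#' @inheritParams counterfactual
#' @return Data.frame with one row per treatment (`treatment`, `map_months`,
#'   `map_probability`, `factual` flag), ordered by predicted months
#'   descending.
#' @export
enumerate_treatment_counterfactuals <- function(bn, profile, joint = FALSE) {
  res <- lapply(hcc_treatments(), function(y)
    counterfactual(bn, profile, c(Treatment_grps = y), joint = joint))
  out <- data.frame(
    treatment = hcc_treatments(),
    map_months = vapply(res, `[[`, 1L, "map_months"),
    map_probability = vapply(res, `[[`, 1.0, "map_probability"),
    factual = hcc_treatments() == profile$evidence[["Treatment_grps"]],
    stringsAsFactors = FALSE
  )
  out[order(-out$map_months), , drop = FALSE]
}

#' Joint counterfactual query
#'
#' Applies several do-interventions (e.g. compliance, waiting time and
#' treatment together) in a single counterfactual pass.  With a single
#' intervention this reduces exactly to [counterfactual()].
#'
#' @inheritParams counterfactual
#' @export
joint_query <- function(bn, profile, interventions,
                        outcome = "Survival_fromMDM", joint = FALSE) {
  counterfactual(bn, profile, interventions, outcome = outcome,
                 joint = joint)
}

#' Sensitivity of predictions to the smoothing prior
#'
#' Relearns the network for each smoothing weight and recomputes the
#' survival posterior under fixed evidence, reporting the posterior's
#' Shannon entropy per weight.  As the weight grows the smoothed rows move
#' toward the uniform distribution, so the entropy is non-decreasing; at the
#' small end of the sweep the predictions become insensitive to the exact
#' weight.
#'
#' @param dag Network structure.
#' @param data Complete training table.
#' @param weights Positive smoothing weights to sweep.
#' @param evidence Evidence for the reference prediction (e.g. a treatment
#'   and waiting time).
#' @param outcome Outcome variable (default survival).
#' @return List with `summary` (data.frame of weight and entropy in nats)
#'   and `posteriors` (one named vector per weight).
#' @export
smoothing_sensitivity <- function(dag, data, weights = c(1e-5, 1e-4, 1e-3,
                                                         0.01, 0.1, 1.0),
                                  evidence = NULL,
                                  outcome = "Survival_fromMDM") {
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  posteriors <- lapply(weights, function(w) {
    fit <- bn_fit(dag, data, weight = w)
    infer_posterior(fit, evidence, outcome)
  })
  names(posteriors) <- as.character(weights)
  ent <- vapply(posteriors, function(p) -sum(p[p > 0] * log(p[p > 0])), 1.0)
  list(summary = data.frame(weight = weights, entropy = unname(ent)),
       posteriors = posteriors)
}

#' Tabulate factual and counterfactual rows per case
#'
#' Renders a batch of counterfactual results in the two-rows-per-case layout
#' used for case reviews: the factual row carries the descriptive fields,
#' the counterfactual row (case id with a prime) carries the intervened
#' waiting time/treatment and the predicted survival.
#'
#' @param profiles List of [case_profile()] objects.
#' @param results List of `"hccbn_cf"` results, parallel to `profiles`.
#' @return Data.frame with columns case, age, sex, aetiology, cirrhosis,
#'   present_mode, size, ps, bclc_stage, waiting_months, treatment,
#'   survival_months, mechanism.
#' @export
case_report <- function(profiles, results) {
  stopifnot(length(profiles) == length(results))
  cols <- c("age", "sex", "aetiology", "cirrhosis", "present_mode",
            "size_mm", "ps", "bclc_stage")
  rows <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]; r <- results[[i]]
    info <- lapply(cols, function(cn)
      if (is.null(p$info[[cn]])) NA else p$info[[cn]])
    names(info) <- cols
    fact <- data.frame(
      case = p$id, info,
      waiting_months = as.integer(p$evidence[["T_MDM_first_treatment"]]),
      treatment = p$evidence[["Treatment_grps"]],
      survival_months = as.integer(p$evidence[["Survival_fromMDM"]]),
      mechanism = "factual", stringsAsFactors = FALSE)
    cf_wait <- if ("T_MDM_first_treatment" %in% names(r$interventions)) {
      as.integer(r$interventions[["T_MDM_first_treatment"]])
    } else fact$waiting_months
    cf_trt <- if ("Treatment_grps" %in% names(r$interventions)) {
      r$interventions[["Treatment_grps"]]
    } else fact$treatment
    blank <- stats::setNames(rep(list(NA), length(cols)), cols)
    cf <- data.frame(
      case = paste0(p$id, "′"), blank,
      waiting_months = cf_wait, treatment = cf_trt,
      survival_months = r$map_months,
      mechanism = if (is.null(r$mode)) "counterfactual" else
        paste0("counterfactual (", r$mode, ")"),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- fact
    rows[[length(rows) + 1L]] <- cf
  }
  if (!length(rows)) {
    return(data.frame(case = character(0)))
  }
  do.call(rbind, rows)
}
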