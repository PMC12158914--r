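#' Exact posterior marginal of one variable
#'
#' Computes \eqn{P(\mathrm{target} \mid \mathrm{evidence})} by variable
#' elimination with a greedy min-fill elimination order.  The result is exact;
#' the elimination order only affects cost, not the answer.
#'
#' @param bn A fitted `"hccbn"` network.
#' @param evidence Named character vector/list `variable = state`; may be
#'   empty.
#' @param target Variable name, not among the evidence.
#' @return Named numeric vector over the target's states, summing to 1.
#' @examples
#' d <- bn_dag(list(A = c("a", "b"), B = c("x", "y")), list(c("A", "B")))
#' fit <- bn_fit(d, data.frame(A = c("a", "a", "b"), B = c("x", "y", "y")))
#' infer_posterior(fit, c(B = "y"), "A")
#' @export
infer_posterior <- function(bn, evidence = NULL, target) {
  stopifnot(inherits(bn, "hccbn"))
  f <- .ve_query(bn, evidence, target)
  stats::setNames(as.vector(f), dimnames(f)[[1L]])
}

#' Exact joint posterior of several variables
#'
#' @inheritParams infer_posterior
#' @param targets Character vector of variables, disjoint from the evidence.
#' @return Array over the joint state space of `targets` (in the given
#'   order), summing to 1.  Marginalising it reproduces [infer_posterior()]
#'   for each target.
#' @export
joint_posterior <- function(bn, evidence = NULL, targets) {
  stopifnot(inherits(bn, "hccbn"), length(targets) >= 1L)
  .ve_query(bn, evidence, targets)
}

#' Graph surgery for interventions (the do-operator)
#'
#' Returns the mutilated network of the truncated factorisation: each
#' variable in `assignments` loses its incoming edges and its CPT becomes a
#' point mass on the assigned state; every other CPT is unchanged.  Querying
#' the result gives interventional, not observational, distributions.
#'
#' @param bn A `"hccbn"` network.
#' @param assignments Named character vector/list `variable = state`.
#' @return A new `"hccbn"` network.
#' @export
do_intervention <- function(bn, assignments) {
  stopifnot(inherits(bn, "hccbn"))
  assignments <- .check_evidence(bn, assignments)
  if (!length(assignments)) return(bn)
  for (v in names(assignments)) {
    st <- bn$variables[[v]]
    p <- as.numeric(st == assignments[[v]])
    bn$cpts[[v]] <- array(p, dim = length(st),
                          dimnames = stats::setNames(list(st), v))
    bn$parents[[v]] <- character(0)
    bn$edges <- bn$edges[bn$edges[, 2L] != v, , drop = FALSE]
  }
  bn$order <- validate_dag(.as_dag(bn))$order
  bn
}

#' Replace the prior of a root variable
#'
#' Used by abduction: after inferring the posterior of an exogenous noise
#' variable from a case's factual evidence, that posterior becomes the
#' variable's new prior.
#'
#' @param bn A `"hccbn"` network.
#' @param variable A parentless variable of `bn`.
#' @param distribution Numeric vector over the variable's states; must sum to
#'   1 within 1e-9.
#' @return A new `"hccbn"` network sharing all other CPTs.
#' @export
replace_prior <- function(bn, variable, distribution) {
  stopifnot(inherits(bn, "hccbn"))
  if (!variable %in% names(bn$variables)) {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  if (length(bn$parents[[variable]])) {
    stop(sprintf("'%s' has parents; replace_prior applies to roots only",
                 variable), call. = FALSE)
  }
  st <- bn$variables[[variable]]
  distribution <- as.numeric(distribution)
  if (length(distribution) != length(st)) {
    stop(sprintf("distribution for '%s' must have %d entries",
                 variable, length(st)), call. = FALSE)
  }
  if (any(distribution < 0) || abs(sum(distribution) - 1) > 1e-9) {
    stop("distribution must be non-negative and sum to 1 (tol 1e-9)",
         call. = FALSE)
  }
  bn$cpts[[variable]] <- array(distribution, dim = length(st),
                               dimnames = stats::setNames(list(st), variable))
  bn
}
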