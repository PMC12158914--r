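#' Fit a discrete Bayesian network by smoothed maximum likelihood
#'
#' Learns one conditional probability table (CPT) per variable of `dag` from a
#' table of categorical observations.  For child state \eqn{k} under parent
#' configuration \eqn{j}, with cell count \eqn{n_{jk}}, row total \eqn{n_j}
#' and \eqn{K} child states, the estimate is the Dirichlet-smoothed frequency
#' \deqn{\hat p_{jk} = (n_{jk} + w) / (n_j + wK),}
#' where `weight` \eqn{w \ge 0} is a pseudo-count added to every cell.  The
#' default \eqn{w = 0.001} keeps the real data at 99.9% weight while removing
#' the structural zeros that would otherwise make counterfactual queries about
#' rarely observed treatment combinations impossible.
#'
#' Variables of the DAG that have no column in `data` must be parentless;
#' they receive `latent_prior` (uniform by default).  Conditioning observed
#' children on such latent variables is the job of [attach_noise_nodes()],
#' not of parameter learning.
#'
#' @param dag An [bn_dag()] object.
#' @param data A data.frame of state labels (character or factor), one column
#'   per observed variable.  Extra columns are ignored.
#' @param weight Non-negative smoothing pseudo-count per CPT cell.
#' @param latent_prior Either `"uniform"` or a named list of probability
#'   vectors for the variables absent from `data`.
#' @param na_action `"error"` refuses missing values; `"available"` learns
#'   each CPT from the rows complete on that CPT's own child + parent columns
#'   (used by the two-pass waiting-time imputation).
#' @return An object of class `"hccbn"`: a list with `variables`, `parents`,
#'   `cpts` (child dimension first), `order`, `weight`, `nobs`.
#' @examples
#' d <- bn_dag(list(A = c("a", "b"), B = c("x", "y")), list(c("A", "B")))
#' fit <- bn_fit(d, data.frame(A = c("a", "a", "b"), B = c("x", "y", "y")))
#' coef(fit)$B
#' @seealso [infer_posterior()], [do_intervention()], [simulate.hccbn()]
#' @export
bn_fit <- function(dag, data, weight = 0.001, latent_prior = "uniform",
                   na_action = c("error", "available")) {
  na_action <- match.arg(na_action)
  stopifnot(inherits(dag, "hccbn_dag"))
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0) {
    stop("smoothing weight must be a single non-negative number",
         call. = FALSE)
  }
  data <- as.data.frame(data)
  vars <- names(dag$variables)
  observed <- intersect(vars, names(data))
  latent <- setdiff(vars, observed)
  for (v in latent) {
    if (length(dag$parents[[v]]) > 0L) {
      stop(sprintf(
        "variable '%s' has no data column but has parents; latent variables must be roots (see attach_noise_nodes)",
        v), call. = FALSE)
    }
  }
  for (v in observed) {
    unobs_par <- setdiff(dag$parents[[v]], observed)
    if (length(unobs_par)) {
      stop(sprintf(
        "cannot learn P(%s | %s): parent '%s' has no data column (see attach_noise_nodes)",
        v, paste(dag$parents[[v]], collapse = ", "), unobs_par[1L]),
        call. = FALSE)
    }
  }
  # state-label sanity, with the first offending row index
  for (v in observed) {
    x <- as.character(data[[v]])
    bad <- which(!is.na(x) & !(x %in% dag$variables[[v]]))
    if (length(bad)) {
      stop(sprintf("row %d: '%s' is not a state of '%s'",
                   bad[1L], x[bad[1L]], v), call. = FALSE)
    }
    if (na_action == "error" && anyNA(x)) {
      stop(sprintf("missing value in column '%s' (row %d); use na_action = \"available\" or impute first",
                   v, which(is.na(x))[1L]), call. = FALSE)
    }
  }
  cpts <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    if (v %in% latent) {
      cpts[[v]] <- .latent_cpt(dag, v, latent_prior)
      next
    }
    fam <- c(v, dag$parents[[v]])
    sub <- data[fam]
    keep <- stats::complete.cases(sub)
    sub <- sub[keep, , drop = FALSE]
    fct <- lapply(fam, function(u)
      factor(as.character(sub[[u]]), levels = dag$variables[[u]]))
    counts <- table(fct)
    cpts[[v]] <- .normalise_counts(array(as.numeric(counts), dim = dim(counts),
                                         dimnames = stats::setNames(
                                           lapply(fam, function(u)
                                             dag$variables[[u]]), fam)),
                                   weight)
  }
  structure(
    list(variables = dag$variables, parents = dag$parents,
         edges = dag$edges, order = dag$order, cpts = cpts,
         weight = weight, nobs = nrow(data), call = match.call()),
    class = "hccbn"
  )
}

# (counts + w) / (rowtotal + wK), normalising along the child dimension
.normalise_counts <- function(counts, w) {
  k <- dim(counts)[1L]
  sm <- counts + w
  if (length(dim(counts)) == 1L) {
    tot <- sum(sm)
    if (tot == 0) return(array(rep(1 / k, k), dim = k,
                               dimnames = dimnames(counts)))
    return(sm / tot)
  }
  tot <- apply(sm, seq_along(dim(sm))[-1L], sum)
  denom <- array(rep(as.vector(tot), each = k), dim = dim(sm))
  out <- ifelse(denom == 0, 1 / k, sm / denom)
  array(out, dim = dim(sm), dimnames = dimnames(counts))
}

.latent_cpt <- function(dag, v, latent_prior) {
  st <- dag$variables[[v]]
  if (identical(latent_prior, "uniform")) {
    p <- rep(1 / length(st), length(st))
  } else {
    p <- latent_prior[[v]]
    if (is.null(p)) p <- rep(1 / length(st), length(st))
    if (length(p) != length(st) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("prior for '%s' must have %d probabilities summing to 1",
                   v, length(st)), call. = FALSE)
    }
  }
  array(p, dim = length(st), dimnames = stats::setNames(list(st), v))
}

.as_dag <- function(bn) {
  structure(list(variables = bn$variables, edges = bn$edges,
                 parents = bn$parents, order = bn$order),
            class = "hccbn_dag")
}

#' @export
print.hccbn <- function(x, ...) {
  cat(sprintf(
    "Discrete Bayesian network: %d variables, %d edges (smoothing w = %g, n = %s)\n",
    length(x$variables), nrow(x$edges), x$weight,
    if (is.null(x$nobs)) "?" else x$nobs))
  for (v in x$order) {
    p <- x$parents[[v]]
    cat(sprintf("  %s [%d states]%s\n", v, length(x$variables[[v]]),
                if (length(p)) paste0(" | ", paste(p, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' @export
summary.hccbn <- function(object, ...) {
  rows <- vapply(names(object$variables), function(v) {
    prod(vapply(object$parents[[v]],
                function(p) length(object$variables[[p]]), 1L))
  }, 1L)
  out <- data.frame(
    variable = names(object$variables),
    states = lengths(object$variables),
    parents = vapply(object$parents, function(p)
      paste(p, collapse = ","), ""),
    cpt_rows = rows,
    row.names = NULL
  )
  structure(list(table = out, weight = object$weight, nobs = object$nobs),
            class = "summary.hccbn")
}

#' @export
print.summary.hccbn <- function(x, ...) {
  cat(sprintf("Smoothing weight: %g; observations: %s\n", x$weight,
              if (is.null(x$nobs)) "?" else x$nobs))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Extract the conditional probability tables
#'
#' @param object A fitted `"hccbn"` network.
#' @param ... Unused.
#' @return Named list of CPT arrays, child dimension first.
#' @export
coef.hccbn <- function(object, ...) object$cpts

#' Posterior prediction for new observations
#'
#' For each row of `newdata`, computes the exact posterior distribution of
#' `target` given the row's non-missing values on the other network
#' variables.  This is what turns the network into a classifier and what the
#' waiting-time imputation uses.
#'
#' @param object A fitted `"hccbn"` network.
#' @param newdata Data.frame of state labels; columns not in the network are
#'   ignored, `NA` cells are treated as unobserved.
#' @param target Variable to predict.
#' @param type `"distribution"` (matrix of posteriors, one row per case),
#'   `"map"` (most probable state, ties to the first state in order) or
#'   `"prob"` (posterior probability of `positive` states).
#' @param positive For `type = "prob"`, the target states counted as positive.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.hccbn <- function(object, newdata, target,
                          type = c("distribution", "map", "prob"),
                          positive = NULL, ...) {
  type <- match.arg(type)
  if (!target %in% names(object$variables)) {
    stop(sprintf("unknown target '%s'", target), call. = FALSE)
  }
  newdata <- as.data.frame(newdata)
  evcols <- setdiff(intersect(names(object$variables), names(newdata)),
                    target)
  states <- object$variables[[target]]
  post <- matrix(NA_real_, nrow(newdata), length(states),
                 dimnames = list(NULL, states))
  for (i in seq_len(nrow(newdata))) {
    ev <- vapply(evcols, function(v) as.character(newdata[[v]][i]), "")
    ev <- ev[!is.na(ev)]
    post[i, ] <- as.vector(infer_posterior(object, ev, target))
  }
  switch(type,
    distribution = post,
    map = states[max.col(post, ties.method = "first")],
    prob = {
      if (is.null(positive)) stop("`positive` required for type = \"prob\"",
                                  call. = FALSE)
      rowSums(post[, states %in% positive, drop = FALSE])
    })
}

#' Draw complete rows by ancestral sampling
#'
#' @param bn A `"hccbn"` network.
#' @param n Number of rows (0 allowed).
#' @param seed Integer seed; the same seed reproduces the same table.  The
#'   caller's random-number state is left untouched.
#' @return Data.frame of state labels with one column per variable, in
#'   topological order.
#' @export
sample_rows <- function(bn, n, seed = 1L) {
  stopifnot(inherits(bn, "hccbn"), n >= 0)
  out <- stats::setNames(
    vector("list", length(bn$order)), bn$order)
  if (n == 0) {
    for (v in bn$order) out[[v]] <- character(0)
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  .with_seed(seed, {
    for (v in bn$order) {
      states <- bn$variables[[v]]
      k <- length(states)
      cpt <- bn$cpts[[v]]
      pars <- bn$parents[[v]]
      if (!length(pars)) {
        idx <- sample.int(k, n, replace = TRUE, prob = as.vector(cpt))
      } else {
        cards <- vapply(pars, function(p) length(bn$variables[[p]]), 1L)
        cfg <- rep(1L, n)
        mult <- 1L
        for (j in seq_along(pars)) {
          pi <- match(out[[pars[j]]], bn$variables[[pars[j]]])
          cfg <- cfg + (pi - 1L) * mult
          mult <- mult * cards[j]
        }
        m <- matrix(cpt, nrow = k)
        cdf <- apply(m, 2L, cumsum)
        u <- stats::runif(n)
        idx <- colSums(cdf[, cfg, drop = FALSE] < rep(u, each = k)) + 1L
      }
      out[[v]] <- states[idx]
    }
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @rdname sample_rows
#' @param object,nsim,... Standard [stats::simulate()] arguments; `nsim` is
#'   the number of rows.
#' @export
simulate.hccbn <- function(object, nsim = 1, seed = 1L, ...) {
  sample_rows(object, nsim, seed)
}

#' @export
plot.hccbn <- function(x, ...) {
  g <- igraph::graph_from_edgelist(x$edges, directed = TRUE)
  iso <- setdiff(names(x$variables), igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  igraph::plot.igraph(g, layout = igraph::layout_with_sugiyama(g)$layout,
                      vertex.size = 28, vertex.label.cex = 0.8,
                      edge.arrow.size = 0.5, ...)
  invisible(x)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
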