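# Internal factor algebra for exact inference.
#
# A factor is a numeric array whose dimnames are the state labels of its
# variables and whose dimnames *names* are the variable names.  Probabilities
# are kept in linear space: the networks here are tiny and every elimination
# step renormalises, so log-space bookkeeping is unnecessary.

.f_vars <- function(f) names(dimnames(f))

# CPT of variable v as a factor (child dimension first)
.f_from_cpt <- function(bn, v) {
  cpt <- bn$cpts[[v]]
  stopifnot(!is.null(dimnames(cpt)))
  cpt
}

# expand/permute a factor to the full table over `vars` with dimnames `dn`
.f_align <- function(f, vars, dn) {
  fv <- .f_vars(f)
  miss <- setdiff(vars, fv)
  if (length(miss)) {
    g <- array(f, dim = c(dim(f), lengths(dn[miss])))
    dimnames(g) <- c(dimnames(f), dn[miss])
  } else {
    g <- f
  }
  aperm(g, match(vars, .f_vars(g)))
}

.f_prod <- function(a, b) {
  va <- .f_vars(a); vb <- .f_vars(b)
  vars <- union(va, vb)
  dn <- c(dimnames(a), dimnames(b))
  dn <- dn[!duplicated(names(dn))][vars]
  out <- .f_align(a, vars, dn) * .f_align(b, vars, dn)
  dimnames(out) <- dn
  out
}

# sum out `drop` variables; returns a factor over the rest, or a scalar
.f_marg <- function(f, drop) {
  keep <- setdiff(.f_vars(f), drop)
  if (!length(keep)) return(sum(f))
  r <- apply(f, keep, sum)
  if (length(keep) == 1L) {
    r <- array(r, dim = length(r), dimnames = dimnames(f)[keep])
  } else {
    dimnames(r) <- dimnames(f)[keep]
  }
  r
}

# condition on observed states and drop those dimensions
.f_reduce <- function(f, evidence) {
  fv <- .f_vars(f)
  ev <- evidence[names(evidence) %in% fv]
  if (!length(ev)) return(f)
  idx <- lapply(fv, function(v) {
    if (v %in% names(ev)) {
      i <- match(ev[[v]], dimnames(f)[[v]])
      if (is.na(i)) {
        stop(sprintf("state '%s' is not a state of '%s'", ev[[v]], v),
             call. = FALSE)
      }
      i
    } else {
      seq_len(dim(f)[match(v, fv)])
    }
  })
  g <- do.call(`[`, c(list(f), idx, list(drop = FALSE)))
  keep <- setdiff(fv, names(ev))
  if (!length(keep)) return(sum(g))
  array(as.vector(g), dim = dim(f)[match(keep, fv)],
        dimnames = dimnames(f)[keep])
}

# greedy min-fill elimination order over the current factor scopes
.min_fill_order <- function(scopes, elim) {
  order <- character(0)
  scopes <- lapply(scopes, unique)
  while (length(elim)) {
    best <- NULL; best_fill <- Inf
    for (v in elim) {
      nb <- setdiff(unique(unlist(scopes[vapply(scopes, function(s)
        v %in% s, TRUE)])), v)
      fill <- 0L
      if (length(nb) > 1L) {
        for (i in seq_len(length(nb) - 1L)) {
          for (j in seq(i + 1L, length(nb))) {
            linked <- any(vapply(scopes, function(s)
              nb[i] %in% s && nb[j] %in% s, TRUE))
            if (!linked) fill <- fill + 1L
          }
        }
      }
      if (fill < best_fill) { best <- v; best_fill <- fill }
    }
    # simulate elimination: factors touching `best` merge into one clique
    touched <- vapply(scopes, function(s) best %in% s, TRUE)
    clique <- setdiff(unique(unlist(scopes[touched])), best)
    scopes <- c(scopes[!touched], list(clique))
    order <- c(order, best)
    elim <- setdiff(elim, best)
  }
  order
}

# Variable elimination.  Returns the (normalised) posterior over `targets`
# as a factor, permuted to the order of `targets`.
.ve_query <- function(bn, evidence, targets) {
  evidence <- .check_evidence(bn, evidence)
  if (length(intersect(targets, names(evidence)))) {
    stop("targets must be disjoint from evidence", call. = FALSE)
  }
  bad <- setdiff(targets, names(bn$variables))
  if (length(bad)) {
    stop(sprintf("unknown target variable '%s'", bad[1L]), call. = FALSE)
  }
  factors <- lapply(names(bn$variables), function(v) .f_from_cpt(bn, v))
  const <- 1.0
  reduced <- list()
  for (f in factors) {
    g <- .f_reduce(f, evidence)
    if (is.null(dim(g))) const <- const * as.numeric(g)
    else reduced[[length(reduced) + 1L]] <- g
  }
  elim <- setdiff(names(bn$variables), c(targets, names(evidence)))
  ord <- .min_fill_order(lapply(reduced, .f_vars), elim)
  for (v in ord) {
    touches <- vapply(reduced, function(f) v %in% .f_vars(f), TRUE)
    if (!any(touches)) next
    prod <- Reduce(.f_prod, reduced[touches])
    g <- .f_marg(prod, v)
    reduced <- reduced[!touches]
    if (is.null(dim(g))) const <- const * as.numeric(g)
    else reduced[[length(reduced) + 1L]] <- g
  }
  if (!length(reduced)) stop("no target factor remains", call. = FALSE)
  out <- Reduce(.f_prod, reduced) * const
  total <- sum(out)
  if (!is.finite(total) || total <= 0) {
    stop("impossible evidence: observed configuration has zero probability",
         call. = FALSE)
  }
  out <- out / total
  aperm(out, match(targets, .f_vars(out)))
}

.check_evidence <- function(bn, evidence) {
  if (is.null(evidence) || length(evidence) == 0L) return(character(0))
  evidence <- unlist(evidence)
  if (is.null(names(evidence)) || any(!nzchar(names(evidence)))) {
    stop("evidence must be a named vector/list of variable = state",
         call. = FALSE)
  }
  for (v in names(evidence)) {
    if (!v %in% names(bn$variables)) {
      stop(sprintf("evidence variable '%s' is not in the network", v),
           call. = FALSE)
    }
    if (!evidence[[v]] %in% bn$variables[[v]]) {
      stop(sprintf("'%s' is not a state of '%s'", evidence[[v]], v),
           call. = FALSE)
    }
  }
  evidence
}
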