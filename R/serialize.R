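#' Write a network to a YAML document
#'
#' The document lists the variables with their state labels, the edges, and
#' one block per CPT whose rows are the child distributions for every joint
#' parent configuration, in row-major order over parent state indices with
#' the *first* parent slowest.  Probabilities are printed with 17 significant
#' digits so that [read_bn()] reproduces the network bit for bit.
#'
#' @param bn A `"hccbn"` network.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_bn <- function(bn, path) {
  stopifnot(inherits(bn, "hccbn"))
  doc <- list(
    variables = lapply(names(bn$variables), function(v)
      list(name = v, states = as.list(bn$variables[[v]]))),
    edges = if (nrow(bn$edges)) {
      lapply(seq_len(nrow(bn$edges)), function(i)
        list(bn$edges[i, 1L], bn$edges[i, 2L]))
    } else list(),
    weight = bn$weight,
    cpts = lapply(names(bn$variables), function(v) {
      cpt <- bn$cpts[[v]]
      pars <- bn$parents[[v]]
      k <- length(bn$variables[[v]])
      rows <- .cpt_rows_first_parent_slowest(cpt, k, pars, bn$variables)
      list(child = v, parents = as.list(pars),
           rows = lapply(rows, function(r)
             paste(sprintf("%.17g", r), collapse = " ")))
    })
  )
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

# list of child-distribution rows, first parent slowest, last parent fastest
.cpt_rows_first_parent_slowest <- function(cpt, k, pars, variables) {
  if (!length(pars)) return(list(as.vector(cpt)))
  cards <- vapply(pars, function(p) length(variables[[p]]), 1L)
  # expand.grid varies its first argument fastest; feed parents reversed so
  # the last parent is fastest, i.e. the first parent slowest
  grid <- do.call(expand.grid, c(rev(lapply(cards, seq_len)),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  grid <- grid[, rev(seq_along(pars)), drop = FALSE]  # back to parent order
  m <- matrix(cpt, nrow = k)
  lapply(seq_len(nrow(grid)), function(i) {
    idx <- as.integer(grid[i, ])
    lin <- 1L + sum((idx - 1L) * cumprod(c(1L, cards))[seq_along(cards)])
    m[, lin]
  })
}

#' Read a network written by [write_bn()]
#'
#' @param path YAML file produced by [write_bn()].
#' @return A `"hccbn"` network identical to the one written.
#' @export
read_bn <- function(path) {
  doc <- yaml::read_yaml(path)
  variables <- stats::setNames(
    lapply(doc$variables, function(v) as.character(unlist(v$states))),
    vapply(doc$variables, function(v) v$name, ""))
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e)
      c(as.character(e[[1L]]), as.character(e[[2L]]))))
  } else NULL
  dag <- bn_dag(variables, edges)
  cpts <- stats::setNames(vector("list", length(variables)),
                          names(variables))
  for (blk in doc$cpts) {
    v <- blk$child
    pars <- as.character(unlist(blk$parents))
    k <- length(variables[[v]])
    cards <- vapply(pars, function(p) length(variables[[p]]), 1L)
    rows <- lapply(blk$rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]]))
    if (length(rows) != prod(cards)) {
      stop(sprintf("CPT for '%s' has %d rows, expected %d",
                   v, length(rows), prod(cards)), call. = FALSE)
    }
    vals <- numeric(k * prod(cards))
    grid <- if (length(pars)) {
      g <- do.call(expand.grid, c(rev(lapply(cards, seq_len)),
                                  list(KEEP.OUT.ATTRS = FALSE)))
      g[, rev(seq_along(pars)), drop = FALSE]
    } else NULL
    for (i in seq_along(rows)) {
      lin <- if (is.null(grid)) 1L else {
        idx <- as.integer(grid[i, ])
        1L + sum((idx - 1L) * cumprod(c(1L, cards))[seq_along(cards)])
      }
      vals[(lin - 1L) * k + seq_len(k)] <- rows[[i]]
    }
    fam <- c(v, pars)
    cpts[[v]] <- array(vals, dim = c(k, unname(cards)),
                       dimnames = stats::setNames(
                         lapply(fam, function(u) variables[[u]]), fam))
    if (!length(pars)) {
      cpts[[v]] <- array(vals, dim = k,
                         dimnames = stats::setNames(list(variables[[v]]), v))
    }
  }
  structure(
    list(variables = dag$variables, parents = dag$parents,
         edges = dag$edges, order = dag$order, cpts = cpts,
         weight = if (is.null(doc$weight)) NA_real_ else doc$weight,
         nobs = NULL, call = NULL),
    class = "hccbn"
  )
}
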