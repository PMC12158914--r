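#' Directed acyclic graph over finite-state variables
#'
#' Constructs the graphical skeleton of a discrete Bayesian network: a set of
#' named variables, each with a fixed, ordered list of at least two state
#' labels, and a set of directed edges between them.  The graph is validated
#' (declared endpoints, acyclicity) at construction and a topological order is
#' stored; that order is what ancestral sampling and exact inference use.
#'
#' @param variables Named list; one entry per variable giving its ordered
#'   character vector of state labels.  Month-valued variables use consecutive
#'   integers rendered as labels (e.g. `"0"` ... `"40"`).
#' @param edges Two-column character matrix (or coercible data.frame / list of
#'   length-2 vectors), one row per directed edge `parent -> child`.  `NULL`
#'   means an edgeless graph.
#' @return An object of class `"hccbn_dag"`: a list with elements `variables`,
#'   `edges` (2-column matrix), `parents` (named list of character vectors, in
#'   edge order) and `order` (a topological order of the variable names).
#' @examples
#' d <- bn_dag(list(A = c("a1", "a2"), B = c("b1", "b2")), list(c("A", "B")))
#' d$order
#' @seealso [hcc_dag()] for the four-node clinical network, [bn_fit()].
#' @export
bn_dag <- function(variables, edges = NULL) {
  if (is.null(names(variables)) || any(!nzchar(names(variables))) ||
      anyDuplicated(names(variables))) {
    stop("`variables` must be a uniquely named list", call. = FALSE)
  }
  variables <- lapply(variables, as.character)
  for (v in names(variables)) {
    st <- variables[[v]]
    if (length(st) < 2L) {
      stop(sprintf("variable '%s' needs at least 2 states", v), call. = FALSE)
    }
    if (anyDuplicated(st)) {
      stop(sprintf("variable '%s' has duplicated state labels", v),
           call. = FALSE)
    }
  }
  edges <- .as_edge_matrix(edges)
  parents <- stats::setNames(
    lapply(names(variables), function(v)
      unname(edges[edges[, 2L] == v, 1L])),
    names(variables)
  )
  dag <- structure(
    list(variables = variables, edges = edges, parents = parents,
         order = NULL),
    class = "hccbn_dag"
  )
  validate_dag(dag)
}

.as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.list(edges) && length(edges) == 0L)) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child"))))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.character(edges), ncol = 2L)
  colnames(edges) <- c("parent", "child")
  edges
}

#' Validate a DAG and establish its topological order
#'
#' Checks that every edge endpoint is a declared variable and that the graph
#' is acyclic; on failure the error names the offending endpoint or one cycle.
#'
#' @param dag An `"hccbn_dag"` object (or a bare list with `variables`,
#'   `edges`, `parents`).
#' @return The dag, with `$order` set to a topological order.
#' @export
validate_dag <- function(dag) {
  vars <- names(dag$variables)
  ep <- unique(as.vector(dag$edges))
  bad <- setdiff(ep, vars)
  if (length(bad)) {
    stop(sprintf("edge endpoint '%s' is not a declared variable", bad[1L]),
         call. = FALSE)
  }
  # Kahn's algorithm; on a cycle, walk the residual graph to name it
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (ch in dag$edges[, 2L]) indeg[ch] <- indeg[ch] + 1L
  order <- character(0)
  queue <- vars[indeg == 0L]
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    kids <- dag$edges[dag$edges[, 1L] == v, 2L]
    for (k in kids) {
      indeg2[k] <- indeg2[k] - 1L
      if (indeg2[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < length(vars)) {
    residual <- vars[!(vars %in% order)]
    cyc <- .find_cycle(dag$edges, residual)
    stop(sprintf("cycle %s", paste(cyc, collapse = "→")), call. = FALSE)
  }
  dag$order <- order
  dag
}

.find_cycle <- function(edges, residual) {
  v0 <- residual[1L]
  path <- v0
  v <- v0
  repeat {
    nxt <- edges[edges[, 1L] == v & edges[, 2L] %in% residual, 2L][1L]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
    v <- nxt
  }
}

# descendants of `roots` in the graph given by `edges` (excluding the roots)
.descendants <- function(edges, roots) {
  out <- character(0)
  frontier <- roots
  while (length(frontier)) {
    kids <- unique(edges[edges[, 1L] %in% frontier, 2L])
    kids <- setdiff(kids, c(out, roots))
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' @export
print.hccbn_dag <- function(x, ...) {
  cat(sprintf("DAG: %d variables, %d edges\n",
              length(x$variables), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s → %s\n", x$edges[i, 1L], x$edges[i, 2L]))
  }
  invisible(x)
}

#' The seven HCC treatment options
#'
#' Treatment categories used throughout: liver resection, liver transplant,
#' trans-arterial chemoembolisation (TACE), selective internal radiation
#' therapy (SIRT), ablation, medical therapy and supportive care.
#'
#' @return Character vector of length 7.
#' @export
hcc_treatments <- function() {
  c("resection", "transplant", "TACE", "SIRT", "ablation",
    "medical therapy", "supportive care")
}

#' The four-node clinical decision network
#'
#' The expert-specified DAG over guideline compliance, treatment group,
#' waiting time from the multidisciplinary meeting (MDM) to first treatment,
#' and survival from MDM: whether the MDM decides to follow the guideline
#' determines the treatment given, and both the treatment and the waiting
#' time affect survival.  Waiting time and survival are integer months;
#' survival is capped at `survival_max` and waiting at `waiting_max`.
#'
#' @param waiting_max Largest waiting-time state in months (default 24).
#' @param survival_max Largest survival state in months (default 40, the
#'   cohort's censoring horizon).
#' @return An `"hccbn_dag"` with variables `Compliance` (No/Yes),
#'   `Treatment_grps` (see [hcc_treatments()]), `T_MDM_first_treatment`
#'   (0..`waiting_max`) and `Survival_fromMDM` (0..`survival_max`).
#' @export
hcc_dag <- function(waiting_max = 24L, survival_max = 40L) {
  bn_dag(
    variables = list(
      Compliance = c("No", "Yes"),
      Treatment_grps = hcc_treatments(),
      T_MDM_first_treatment = as.character(0:waiting_max),
      Survival_fromMDM = as.character(0:survival_max)
    ),
    edges = list(
      c("Compliance", "Treatment_grps"),
      c("Treatment_grps", "Survival_fromMDM"),
      c("T_MDM_first_treatment", "Survival_fromMDM")
    )
  )
}
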