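# Independent brute-force oracles used to cross-check the inference engine.
# They enumerate the full joint state space and multiply CPT entries by
# direct array indexing — no code shared with the package's factor algebra.

make_bn <- function(dag, cpts, weight = 0) {
  structure(list(variables = dag$variables, parents = dag$parents,
                 edges = dag$edges, order = dag$order, cpts = cpts,
                 weight = weight, nobs = NULL, call = NULL),
            class = "hccbn")
}

# CPT array with given family and values (child dimension first)
oracle_cpt <- function(variables, child, parents, values) {
  fam <- c(child, parents)
  dims <- unname(vapply(fam, function(u) length(variables[[u]]), 1L))
  array(values, dim = dims,
        dimnames = stats::setNames(lapply(fam, function(u) variables[[u]]),
                                   fam))
}

# full joint table: one row per assignment, with its probability
enum_joint <- function(bn, do = NULL) {
  grid <- expand.grid(bn$variables, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (v in names(bn$variables)) {
    if (!is.null(do) && v %in% names(do)) {
      # truncated factorisation: indicator instead of the CPT factor
      p <- p * as.numeric(grid[[v]] == do[[v]])
      next
    }
    pars <- bn$parents[[v]]
    fam <- c(v, pars)
    cards <- vapply(fam, function(u) length(bn$variables[[u]]), 1L)
    idx <- sapply(fam, function(u) match(grid[[u]], bn$variables[[u]]))
    idx <- matrix(idx, ncol = length(fam))
    stride <- cumprod(c(1L, cards))[seq_along(cards)]
    lin <- 1L + as.vector((idx - 1L) %*% stride)
    p <- p * as.vector(bn$cpts[[v]])[lin]
  }
  cbind(grid, prob = p)
}

enum_posterior <- function(bn, evidence, target, do = NULL) {
  j <- enum_joint(bn, do = do)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & j[[v]] == evidence[[v]]
  j <- j[keep, , drop = FALSE]
  agg <- tapply(j$prob, factor(j[[target]], levels = bn$variables[[target]]),
                sum, default = 0)
  agg / sum(agg)
}

enum_joint_posterior <- function(bn, evidence, targets) {
  j <- enum_joint(bn)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & j[[v]] == evidence[[v]]
  j <- j[keep, , drop = FALSE]
  fcts <- lapply(targets, function(v)
    factor(j[[v]], levels = bn$variables[[v]]))
  agg <- tapply(j$prob, fcts, sum, default = 0)
  agg / sum(agg)
}

# random network with <= max_vars variables and <= max_states states each,
# Dirichlet(1) CPT rows
rand_bn <- function(seed, max_vars = 5L, max_states = 4L,
                    edge_prob = 0.5) {
  set.seed(seed)
  nv <- sample(2:max_vars, 1L)
  vars <- stats::setNames(lapply(seq_len(nv), function(i) {
    k <- sample(2:max_states, 1L)
    paste0("s", seq_len(k))
  }), paste0("V", seq_len(nv)))
  edges <- list()
  for (i in seq_len(nv)) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < edge_prob) {
        edges[[length(edges) + 1L]] <- c(paste0("V", j), paste0("V", i))
      }
    }
  }
  dag <- bn_dag(vars, edges)
  cpts <- lapply(names(vars), function(v) {
    fam <- c(v, dag$parents[[v]])
    k <- length(vars[[v]])
    nconf <- prod(vapply(dag$parents[[v]],
                         function(p) length(vars[[p]]), 1L))
    m <- matrix(stats::rgamma(k * max(1L, nconf), 1), nrow = k)
    m <- sweep(m, 2L, colSums(m), "/")
    oracle_cpt(vars, v, dag$parents[[v]], as.vector(m))
  })
  names(cpts) <- names(vars)
  make_bn(dag, cpts)
}

rand_evidence <- function(bn, exclude = character(0)) {
  cand <- setdiff(names(bn$variables), exclude)
  nev <- sample(0:(length(cand) - 1L), 1L)  # leave at least one target free
  if (nev == 0L) return(NULL)
  vs <- sample(cand, nev)
  stats::setNames(vapply(vs, function(v)
    sample(bn$variables[[v]], 1L), ""), vs)
}

# small complete cohort-like data frame on the clinical network
toy_clinical_data <- function(n = 200, seed = 7) {
  spec <- cohort_spec()
  sim <- sample_cohort(spec, n, seed = seed)
  data.frame(
    Compliance = ifelse(sim$truth$compliant, "Yes", "No"),
    Treatment_grps = sim$records$treatment,
    T_MDM_first_treatment = as.character(sim$records$waiting_months),
    Survival_fromMDM = as.character(sim$records$survival_months),
    stringsAsFactors = FALSE
  )
}
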