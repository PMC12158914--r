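#' BCLC decision rules
#'
#' Loads a declarative rule table encoding the BCLC management flowchart.
#' Each rule has a predicate over performance status (`ps`), BCLC stage
#' (`stage`) and solitary tumour size in millimetres (`size_min`/`size_max`),
#' a `leaf` label naming the decision point (the labels mirror the flowchart:
#' e.g. `"PS=0→BCLC=0"`, `"BCLC=C→medical therapy"`), and the set of
#' treatments the flowchart recommends for cases routed there.  Rules are
#' evaluated in order and the first match wins, so routing is deterministic;
#' [validate_rules()] checks the table is exhaustive before any
#' classification runs.
#'
#' The shipped default encodes the three-level 2022 flowchart reading —
#' performance status first (PS 3-4 or stage D to supportive care, PS 1-2 or
#' stage C to medical therapy), then stage, then the 2 cm size threshold that
#' separates very-early (stage 0) routing from early (stage A) routing:
#' stage 0 ≤ 20 mm -> ablation or resection; stage A (or stage 0 above the
#' threshold) -> resection, transplant or ablation; stage B -> TACE or
#' transplant.  A single-level 2018-style table can be supplied as a custom
#' YAML file instead.
#'
#' @param path YAML rule file; `NULL` loads the shipped default
#'   (`inst/extdata/bclc2022_rules.yaml`).
#' @return A validated object of class `"bclc_rules"` (list of rules with a
#'   `source` attribute).
#' @export
bclc_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bclc2022_rules.yaml", package = "hccbn")
  }
  doc <- yaml::read_yaml(path)
  rules <- lapply(doc$rules, function(r) {
    list(
      ps = if (is.null(r$ps)) NULL else as.character(unlist(r$ps)),
      stage = if (is.null(r$stage)) NULL else as.character(unlist(r$stage)),
      size_min = if (is.null(r$size_min)) -Inf else as.numeric(r$size_min),
      size_max = if (is.null(r$size_max)) Inf else as.numeric(r$size_max),
      leaf = as.character(r$leaf),
      recommend = as.character(unlist(r$recommend))
    )
  })
  out <- structure(rules, class = "bclc_rules", source = path)
  validate_rules(out)
  out
}

#' Validate a BCLC rule table
#'
#' Rejects empty or non-treatment recommendation sets and non-exhaustive
#' predicates: every combination of performance status (0-4 and "unknown"),
#' stage (0/A/B/C/D) and size (probed on both sides of every size bound)
#' must route to a rule.  First-match ordering makes the routing unique.
#'
#' @param rules A `"bclc_rules"` object.
#' @return The rules, invisibly; errors name the first uncovered
#'   combination.
#' @export
validate_rules <- function(rules) {
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!length(r$recommend)) {
      stop(sprintf("rule %d has an empty recommendation set", i),
           call. = FALSE)
    }
    bad <- setdiff(r$recommend, hcc_treatments())
    if (length(bad)) {
      stop(sprintf("rule %d recommends unknown treatment '%s'", i, bad[1L]),
           call. = FALSE)
    }
  }
  bounds <- sort(unique(unlist(lapply(rules, function(r)
    c(r$size_min, r$size_max)))))
  bounds <- bounds[is.finite(bounds)]
  probe_sizes <- unique(c(1, bounds - 0.5, bounds, bounds + 0.5, 500))
  probe_sizes <- probe_sizes[probe_sizes > 0]
  for (ps in c("0", "1", "2", "3", "4", "unknown")) {
    for (st in c("0", "A", "B", "C", "D")) {
      for (sz in probe_sizes) {
        hit <- .first_rule(rules, ps, st, sz)
        if (is.na(hit)) {
          stop(sprintf(
            "rule table gap: no rule covers PS=%s, stage=%s, size=%gmm",
            ps, st, sz), call. = FALSE)
        }
      }
    }
  }
  invisible(rules)
}

.first_rule <- function(rules, ps, stage, size_mm) {
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!is.null(r$ps) && !(ps %in% r$ps)) next
    if (!is.null(r$stage) && !(stage %in% r$stage)) next
    if (!is.na(size_mm) && (size_mm < r$size_min || size_mm > r$size_max))
      next
    if (is.na(size_mm) && (is.finite(r$size_min) || is.finite(r$size_max)))
      next
    return(i)
  }
  NA_integer_
}

#' Route one case through the flowchart
#'
#' @param ps Performance status (`"0"`..`"4"` or `"unknown"`).
#' @param bclc_stage Stage `"0"`, `"A"`, `"B"`, `"C"` or `"D"`.
#' @param size_mm Solitary tumour size in millimetres.
#' @param rules A `"bclc_rules"` table (default: shipped BCLC-2022 table).
#' @return List with `leaf` (decision-point label) and `recommended`
#'   (character vector of guideline treatments for that leaf).
#' @export
recommend_treatment <- function(ps, bclc_stage, size_mm,
                                rules = bclc_rules()) {
  i <- .first_rule(rules, as.character(ps), as.character(bclc_stage),
                   size_mm)
  if (is.na(i)) {
    stop(sprintf("no rule covers PS=%s, stage=%s, size=%smm",
                 ps, bclc_stage, format(size_mm)), call. = FALSE)
  }
  r <- rules[[i]]
  list(leaf = r$leaf, recommended = r$recommend)
}

#' Classify guideline compliance for each record
#'
#' Routes every cleaned record through the rule table and compares the
#' treatment actually given with the recommended set.  Classification is a
#' pure function of the record and the rules.
#'
#' @param records Data.frame of cleaned records (needs `id`, `ps`,
#'   `bclc_stage`, `size_mm`, `treatment`) or an `"hcc_cohort"`.
#' @param rules A `"bclc_rules"` table.
#' @return Data.frame of pathway traces: `id`, `leaf`, `recommended`
#'   (comma-separated), `actual`, `compliant` (logical), and
#'   `divergence_point` (the decision-point label where the case left the
#'   guideline trajectory; `NA` for compliant cases).
#' @export
assess_compliance <- function(records, rules = bclc_rules()) {
  if (inherits(records, "hcc_cohort")) records <- records$records
  n <- nrow(records)
  leaf <- character(n); recs <- character(n); comp <- logical(n)
  for (i in seq_len(n)) {
    r <- recommend_treatment(records$ps[i], records$bclc_stage[i],
                             records$size_mm[i], rules)
    leaf[i] <- r$leaf
    recs[i] <- paste(r$recommended, collapse = ", ")
    comp[i] <- records$treatment[i] %in% r$recommended
  }
  data.frame(
    id = records$id,
    leaf = leaf,
    recommended = recs,
    actual = records$treatment,
    compliant = comp,
    divergence_point = ifelse(comp, NA_character_, leaf),
    stringsAsFactors = FALSE
  )
}

#' Aggregate pathway traces by decision point
#'
#' @param traces Output of [assess_compliance()].
#' @return List with `n`, `n_compliant`, `n_noncompliant` and `by_point`, a
#'   data.frame of non-compliant counts per divergence point (descending).
#'   The per-point counts always partition the non-compliant total.
#' @export
pathway_summary <- function(traces) {
  tab <- sort(table(traces$divergence_point[!traces$compliant]),
              decreasing = TRUE)
  list(
    n = nrow(traces),
    n_compliant = sum(traces$compliant),
    n_noncompliant = sum(!traces$compliant),
    by_point = data.frame(divergence_point = names(tab),
                          n = as.integer(tab),
                          stringsAsFactors = FALSE)
  )
}
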