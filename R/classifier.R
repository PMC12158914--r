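#' ROC validation of the network as a probabilistic classifier
#'
#' Splits the data into a train and a held-out part, relearns the CPTs on the
#' training part (same structure and smoothing weight as `bn`), scores every
#' row by the exact posterior probability that `target` falls in
#' `positive_states` given the row's other observed variables, and reports
#' the area under the ROC curve on both parts.
#'
#' @param bn A fitted `"hccbn"` network supplying structure and smoothing
#'   weight.
#' @param data Data.frame of state labels with one column per network
#'   variable.
#' @param target Variable to predict.
#' @param positive_states Target states counted as the positive class.
#' @param split_fraction Fraction of rows used for training (default 0.7).
#' @param seed Integer seed for the random split.
#' @return List with `auc_train`, `auc_test`, the two `pROC::roc` objects,
#'   the held-out scores, and the split sizes.
#' @export
bn_classifier_auc <- function(bn, data, target, positive_states,
                              split_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(bn, "hccbn"))
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  data <- as.data.frame(data)
  n <- nrow(data)
  idx <- .with_seed(seed, sample.int(n, size = round(split_fraction * n)))
  train <- data[idx, , drop = FALSE]
  test <- data[-idx, , drop = FALSE]
  lab <- function(d) as.character(d[[target]]) %in% positive_states
  for (part in list(train = train, test = test)) {
    y <- lab(part)
    if (length(unique(y)) < 2L) {
      stop("a split contains only one class of the target; change the split or seed",
           call. = FALSE)
    }
  }
  fit <- bn_fit(.as_dag(bn), train, weight = bn$weight)
  score <- function(d) predict(fit, d, target, type = "prob",
                               positive = positive_states)
  roc_tr <- pROC::roc(lab(train), score(train), quiet = TRUE,
                      direction = "<", levels = c(FALSE, TRUE))
  roc_te <- pROC::roc(lab(test), score(test), quiet = TRUE,
                      direction = "<", levels = c(FALSE, TRUE))
  list(auc_train = as.numeric(pROC::auc(roc_tr)),
       auc_test = as.numeric(pROC::auc(roc_te)),
       roc_train = roc_tr, roc_test = roc_te,
       scores_test = score(test),
       n_train = nrow(train), n_test = nrow(test))
}
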