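#' Order-wise accuracy profile
#'
#' For each prediction order \eqn{j}, the accuracy is the fraction of
#' evaluated drugs whose j-th ranked side effect is one of their true side
#' effects: \eqn{AC(j) = P(j) / N}, where \eqn{P(j)} counts drugs whose
#' j-th order prediction exists and is true, and \eqn{N} is the number of
#' structure-different drugs evaluated. Drugs whose prediction list is
#' shorter than \eqn{j} (or empty) simply contribute misses; \eqn{N} never
#' shrinks.
#'
#' @param predictions Named list of `ranked_prediction` objects, one per
#'   evaluated drug (names are drug identifiers).
#' @param truth [label_matrix()] holding the true labels of every
#'   evaluated drug.
#' @param m Number of prediction orders to report (default: number of
#'   side-effect categories in `truth`).
#' @param mode,method Optional tags recorded on the result (evaluation
#'   mode, scoring method).
#' @return Object of class `accuracy_profile`: data.frame with columns
#'   `order`, `hits` (P(j)), `n` (N) and `accuracy` (AC(j)).
#' @export
accuracy_profile <- function(predictions, truth, m = ncol(truth),
                             mode = NA_character_, method = NA_character_) {
  drugs <- names(predictions)
  if (is.null(drugs) && length(predictions) > 0L) {
    drugs <- vapply(predictions, function(rp) rp$drug, character(1))
    names(predictions) <- drugs
  }
  missing_truth <- setdiff(drugs, rownames(truth))
  if (length(missing_truth) > 0L) {
    stop("no truth labels for drug(s): ",
         paste(missing_truth, collapse = ", "))
  }
  n <- length(predictions)
  hits <- integer(m)
  for (d in drugs) {
    rp <- predictions[[d]]$ranking
    if (nrow(rp) == 0L) next
    true_eff <- colnames(truth)[truth[d, ] == 1L]
    ok <- rp$rank[rp$rank <= m & rp$side_effect %in% true_eff]
    hits[ok] <- hits[ok] + 1L
  }
  structure(data.frame(order = seq_len(m), hits = hits, n = n,
                       accuracy = if (n > 0) hits / n else rep(NaN, m)),
            class = c("accuracy_profile", "data.frame"),
            mode = mode, method = method)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each drug in the dataset is singled out in turn and predicted by the
#' model trained on the remaining drugs: the left-out drug's labels are
#' removed from the training matrix (its interaction-network edges and
#' similarity scores remain available — the network is external knowledge),
#' the chosen method predicts it, and the hit at each prediction order is
#' recorded. Deterministic.
#'
#' @param labels [label_matrix()] of the evaluated dataset (at least two
#'   drugs).
#' @param cc An [interaction_table()] (interaction method).
#' @param pc A [protein_chemical_table()] (interaction method).
#' @param method `"interaction"` (two-step direct/hybrid predictor) or
#'   `"similarity"` (structural-similarity baseline).
#' @param provider Similarity provider, required for the similarity method.
#' @return An `accuracy_profile` over \eqn{N} = number of drugs, with
#'   attribute `drug_log`: data.frame (`drug`, `method_used`,
#'   `n_predicted`) recording the evidence route per drug.
#' @export
jackknife_evaluate <- function(labels, cc = NULL, pc = NULL,
                               method = c("interaction", "similarity"),
                               provider = NULL) {
  method <- match.arg(method)
  drugs <- rownames(labels)
  if (length(drugs) < 2L) {
    stop("jackknife requires at least 2 drugs")
  }
  preds <- vector("list", length(drugs))
  names(preds) <- drugs
  for (d in drugs) {
    train <- labels[setdiff(drugs, d), , drop = FALSE]
    preds[[d]] <- predict_one(d, train, cc, pc, method, provider)
  }
  finish_profile(preds, labels, mode = "jackknife", method = method)
}

#' Hold-out evaluation
#'
#' Predicts each test drug against the full training label matrix and
#' reports the order-wise accuracy profile over \eqn{N} = number of test
#' drugs. Training and test drug sets must be disjoint.
#'
#' @param train [label_matrix()] of the training drugs.
#' @param test [label_matrix()] of the test drugs (same side-effect
#'   columns), carrying their true labels.
#' @inheritParams jackknife_evaluate
#' @return An `accuracy_profile` with attribute `drug_log` as in
#'   [jackknife_evaluate()].
#' @export
holdout_evaluate <- function(train, test, cc = NULL, pc = NULL,
                             method = c("interaction", "similarity"),
                             provider = NULL) {
  method <- match.arg(method)
  overlap <- intersect(rownames(train), rownames(test))
  if (length(overlap) > 0L) {
    stop("train and test sets overlap: ", paste(overlap, collapse = ", "))
  }
  if (!identical(colnames(train), colnames(test))) {
    stop("train and test label matrices must share the same side-effect columns")
  }
  preds <- vector("list", nrow(test))
  names(preds) <- rownames(test)
  for (d in rownames(test)) {
    preds[[d]] <- predict_one(d, train, cc, pc, method, provider)
  }
  finish_profile(preds, test, mode = "holdout", method = method)
}

predict_one <- function(d, train, cc, pc, method, provider) {
  if (method == "interaction") {
    if (is.null(cc) || is.null(pc)) {
      stop("the interaction method needs both interaction tables")
    }
    predict_two_step(d, train, cc, pc)
  } else {
    if (is.null(provider)) {
      stop("the similarity method needs a similarity provider")
    }
    scores <- score_similarity(d, train, provider)
    rank_side_effects(scores, prevalence = colSums(train), drug = d,
                      method = "similarity")
  }
}

finish_profile <- function(preds, truth, mode, method) {
  prof <- accuracy_profile(preds, truth, m = ncol(truth),
                           mode = mode, method = method)
  attr(prof, "drug_log") <- data.frame(
    drug = names(preds),
    method_used = vapply(preds, function(rp) rp$method, character(1)),
    n_predicted = vapply(preds, function(rp) nrow(rp$ranking), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  prof
}

#' Expected first-order accuracy of random ranking
#'
#' The no-skill reference for AC(1): a predictor emitting a uniformly
#' random permutation of the catalog has per-drug hit probability
#' (number of true side effects) / m, so its expected AC(1) is the mean of
#' that ratio over drugs.
#'
#' @param labels [label_matrix()] of the evaluated drugs.
#' @return Scalar in \[0, 1\].
#' @export
no_skill_ac1 <- function(labels) {
  mean(rowSums(labels) / ncol(labels))
}
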