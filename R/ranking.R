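#' Score side effects by direct chemical-chemical interactions
#'
#' The likelihood that query drug `d` carries side effect \eqn{C_j} is the
#' confidence-weighted vote of its interactive training drugs,
#' \deqn{\Pi^c(d \to C_j) = \sum_{d_i \in S'} Q^c(d, d_i)\, c_{i,j},}
#' summed over the training set \eqn{S'}. A training drug with the same
#' identifier as the query is skipped (self-exclusion).
#'
#' @param d Query drug identifier.
#' @param train [label_matrix()] of the training drugs.
#' @param cc An [interaction_table()].
#' @return A score vector: named numeric over the catalog side effects,
#'   with attribute `method = "direct"`.
#' @export
score_direct <- function(d, train, cc) {
  drugs <- setdiff(rownames(train), d)
  q <- cc$adj[[as.character(d)]]
  nb <- intersect(names(q), drugs)
  scores <- if (length(nb) == 0L) {
    numeric(ncol(train))
  } else {
    as.numeric(q[nb] %*% train[nb, , drop = FALSE])
  }
  score_vector(setNames(scores, colnames(train)), "direct")
}

#' Score side effects by hybrid shared-neighbour interactions
#'
#' Fallback evidence for drugs with no direct interactive training partner:
#' \deqn{\Pi^h(d \to C_j) = \sum_{d_i \in S'} Q^h(d, d_i)\, c_{i,j},}
#' where \eqn{Q^h} is the [hybrid_score()] built from shared chemical
#' neighbours and shared protein partners.
#'
#' @inheritParams score_direct
#' @param pc A [protein_chemical_table()].
#' @return A score vector with attribute `method = "hybrid"`.
#' @export
score_hybrid <- function(d, train, cc, pc) {
  drugs <- setdiff(rownames(train), d)
  q <- vapply(drugs, function(di) hybrid_score(d, di, cc, pc), numeric(1))
  scores <- if (length(drugs) == 0L) {
    numeric(ncol(train))
  } else {
    as.numeric(q %*% train[drugs, , drop = FALSE])
  }
  score_vector(setNames(scores, colnames(train)), "hybrid")
}

#' Score side effects by structural similarity
#'
#' Baseline using molecular similarity instead of network evidence: the
#' score of side effect \eqn{C_j} is the best structural match among the
#' training drugs carrying it,
#' \deqn{\Pi^s(d \to C_j) = \max_{d_i \in S'} Q^s(d, d_i)\, c_{i,j},}
#' with \eqn{Q^s \in [0, 1]} from a [similarity provider][precomputed_provider].
#' A side effect carried by no training drug scores 0.
#'
#' @inheritParams score_direct
#' @param provider A similarity provider ([fingerprint_provider()] or
#'   [precomputed_provider()]).
#' @return A score vector with attribute `method = "similarity"`.
#' @export
score_similarity <- function(d, train, provider) {
  drugs <- setdiff(rownames(train), d)
  if (length(drugs) == 0L) {
    return(score_vector(setNames(numeric(ncol(train)), colnames(train)),
                        "similarity"))
  }
  sim <- vapply(drugs, function(di) sim_score(provider, d, di), numeric(1))
  # column-wise max of sim * c_ij; sim >= 0 so masking by the label works
  scores <- apply(train[drugs, , drop = FALSE] * sim, 2, max)
  score_vector(setNames(as.numeric(scores), colnames(train)), "similarity")
}

score_vector <- function(scores, method) {
  structure(scores, method = method, class = c("score_vector", "numeric"))
}

#' Rank side effects from a score vector
#'
#' Orders the strictly positive scores descending; the top side effect is
#' the "1st order" prediction, the next the 2nd order, and so on.
#' Zero-score side effects are never emitted. Ties break deterministically:
#' first by higher training prevalence \eqn{N(C_i)}, then by catalog
#' position.
#'
#' @param scores Named numeric score vector (one entry per catalog side
#'   effect), e.g. from [score_direct()].
#' @param prevalence Optional named vector of per-side-effect training drug
#'   counts used for tie-breaking; defaults to all zero (ties then break by
#'   catalog position alone).
#' @param drug Query drug identifier recorded in the result.
#' @param method Evidence route tag; defaults to the score vector's own.
#' @return An object of class `ranked_prediction`: list with `drug`,
#'   `method` and `ranking`, a data.frame of (`rank`, `side_effect`,
#'   `score`) with consecutive ranks from 1 and non-increasing positive
#'   scores.
#' @export
rank_side_effects <- function(scores, prevalence = NULL, drug = NA_character_,
                              method = NULL) {
  method <- method %||% attr(scores, "method") %||% "direct"
  s <- as.numeric(scores)
  eff <- names(scores)
  prev <- rep(0, length(s))
  if (!is.null(prevalence)) {
    p <- prevalence[eff]
    p[is.na(p)] <- 0
    prev <- as.numeric(p)
  }
  pos <- which(s > 0)
  o <- pos[order(-s[pos], -prev[pos], pos)]
  ranking <- data.frame(rank = seq_along(o), side_effect = eff[o],
                        score = s[o], stringsAsFactors = FALSE)
  structure(list(drug = drug, method = method, ranking = ranking),
            class = "ranked_prediction")
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat("<ranked_prediction> drug ", x$drug, " (", x$method, "): ",
      nrow(x$ranking), " side effects\n", sep = "")
  if (nrow(x$ranking) > 0) print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' Two-step interaction-based prediction
#'
#' The interaction-based predictor: direct chemical-chemical evidence is
#' used first ([score_direct()]); only when every direct score is zero —
#' the query has no interactive training partner — does the hybrid
#' shared-neighbour score take over ([score_hybrid()]). If both routes
#' yield all-zero scores the prediction is empty (every order then counts
#' as a miss in evaluation).
#'
#' @inheritParams score_hybrid
#' @param prevalence Optional tie-break counts, see [rank_side_effects()];
#'   defaults to the training-matrix column sums.
#' @return A `ranked_prediction` whose `method` records the route used
#'   (`"direct"` or `"hybrid"`).
#' @export
predict_two_step <- function(d, train, cc, pc, prevalence = NULL) {
  prevalence <- prevalence %||% colSums(train)
  direct <- score_direct(d, train, cc)
  if (any(direct > 0)) {
    return(rank_side_effects(direct, prevalence, drug = d, method = "direct"))
  }
  hybrid <- score_hybrid(d, train, cc, pc)
  rank_side_effects(hybrid, prevalence, drug = d, method = "hybrid")
}
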