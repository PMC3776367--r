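#' Build a binary drug-by-side-effect label matrix
#'
#' Encodes side-effect membership as \eqn{c_{i,j} = 1} if drug \eqn{d_i}
#' carries side effect \eqn{C_j}, else 0.
#'
#' @param pairs data.frame with columns `drug` and `side_effect` (one row
#'   per assignment, as from [read_label_table()]).
#' @param drugs,effects Optional row/column orderings; default is
#'   first-seen order in `pairs`.
#' @return Integer matrix with drug row names and side-effect column names.
#' @export
label_matrix <- function(pairs, drugs = NULL, effects = NULL) {
  drugs <- drugs %||% unique(pairs$drug)
  effects <- effects %||% unique(pairs$side_effect)
  m <- matrix(0L, nrow = length(drugs), ncol = length(effects),
              dimnames = list(drugs, effects))
  keep <- pairs$drug %in% drugs & pairs$side_effect %in% effects
  m[cbind(match(pairs$drug[keep], drugs),
          match(pairs$side_effect[keep], effects))] <- 1L
  m
}

#' Select the k most frequent side effects
#'
#' Benchmark criterion (i): keep only the `k` side effects carried by the
#' most drugs, together with the drugs carrying them. Label pairs outside
#' the selected catalog are dropped, and drugs left with no label are
#' removed. Ties at the cutoff break by first-seen order in the input, so
#' the selection is deterministic.
#'
#' @param pairs data.frame of (drug, side_effect) assignments.
#' @param k Number of side-effect categories to keep (default 100).
#' @return List with `catalog` (data.frame `side_effect`, `n_drugs`,
#'   ordered by descending drug count) and `labels` (the [label_matrix()]
#'   restricted to the catalog, columns in catalog order).
#' @export
select_top_side_effects <- function(pairs, k = 100) {
  stopifnot(k >= 1)
  effects <- unique(pairs$side_effect)
  counts <- vapply(effects, function(e) {
    length(unique(pairs$drug[pairs$side_effect == e]))
  }, integer(1))
  if (k > length(effects)) {
    warning("requested top ", k, " side effects but only ", length(effects),
            " available; keeping all")
    k <- length(effects)
  }
  ord <- order(-counts, seq_along(effects))   # stable: first-seen breaks ties
  top <- effects[ord[seq_len(k)]]
  kept <- pairs[pairs$side_effect %in% top, , drop = FALSE]
  labels <- label_matrix(kept, drugs = unique(kept$drug), effects = top)
  catalog <- data.frame(side_effect = top,
                        n_drugs = as.integer(colSums(labels)),
                        stringsAsFactors = FALSE)
  list(catalog = catalog, labels = labels)
}

#' Drop drugs with no interaction coverage
#'
#' Benchmark criterion (ii): a drug with neither a chemical-chemical nor a
#' protein-chemical interaction carries no network evidence and is removed.
#' Drugs with at least one neighbour of either kind are kept. Idempotent.
#'
#' @param labels A [label_matrix()].
#' @param cc An [interaction_table()].
#' @param pc A [protein_chemical_table()].
#' @return The label matrix restricted to covered drugs.
#' @export
filter_uncovered_drugs <- function(labels, cc, pc) {
  covered <- vapply(rownames(labels), function(d) {
    length(chemical_neighbors(d, cc)) > 0L ||
      length(protein_neighbors(d, pc)) > 0L
  }, logical(1))
  labels[covered, , drop = FALSE]
}

#' Count structure-different and virtual drugs
#'
#' A drug belonging to several side-effect categories is counted once per
#' category as a "virtual drug": \eqn{N(vir) = \sum_i N(C_i)}, the total
#' number of positive labels, against \eqn{N(str)}, the number of distinct
#' structures.
#'
#' @param labels A [label_matrix()].
#' @return List with `n_structural` and `n_virtual`.
#' @export
count_virtual_drugs <- function(labels) {
  list(n_structural = nrow(labels), n_virtual = as.integer(sum(labels)))
}

#' Random train/test split of the benchmark drugs
#'
#' Samples `fraction` of the drugs uniformly without replacement as the
#' test set; the remainder is the training set. The test-set size is the
#' half-down rounding of `fraction * n` (so 10% of 835 drugs gives 83, not
#' 84). Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param drugs Character vector of drug identifiers.
#' @param fraction Test-set proportion in (0, 1); default 0.1.
#' @param seed Integer RNG seed for the split (required; there is no
#'   default so the split is always an explicit, reproducible choice).
#' @return List with character vectors `train` and `test`; a partition of
#'   `drugs`.
#' @export
split_train_test <- function(drugs, fraction = 0.1, seed) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction < 1)
  if (missing(seed)) stop("split_train_test() requires an explicit seed")
  n <- length(drugs)
  n_test <- as.integer(ceiling(fraction * n - 0.5 - 1e-9))  # half-down
  if (n_test < 1L || n_test >= n) {
    stop("fraction ", fraction, " produces an empty train or test side for ",
         n, " drugs")
  }
  test <- with_seed(seed, sample(drugs, n_test))
  list(train = setdiff(drugs, test), test = sort(test))
}

#' Assemble the benchmark dataset
#'
#' Applies the two collection criteria in order — (i) keep the `top_k`
#' most frequent side effects and their drugs, (ii) drop drugs without any
#' chemical-chemical or protein-chemical interaction — then removes any
#' side-effect category emptied by (ii) and splits the remaining drugs into
#' training and test sets.
#'
#' @param pairs data.frame of (drug, side_effect) assignments.
#' @param cc An [interaction_table()].
#' @param pc A [protein_chemical_table()].
#' @param top_k Number of side-effect categories to keep (default 100).
#' @param test_fraction Test-set proportion (default 0.1).
#' @param split_seed Integer seed for the random split.
#' @return An object of class `benchmark_dataset`: list with `labels`
#'   (label matrix over all benchmark drugs), `catalog` (side effects with
#'   drug counts, descending), `train`, `test` (drug identifier vectors),
#'   `counts` (`n_structural`, `n_virtual`, `n_single_label`) and
#'   `split_seed`.
#' @export
build_benchmark <- function(pairs, cc, pc, top_k = 100, test_fraction = 0.1,
                            split_seed) {
  sel <- select_top_side_effects(pairs, k = top_k)
  labels <- filter_uncovered_drugs(sel$labels, cc, pc)
  if (nrow(labels) < 2L) {
    stop("fewer than 2 drugs remain after the coverage filter")
  }
  emptied <- colSums(labels) == 0L
  if (any(emptied)) {
    message("dropping ", sum(emptied),
            " side-effect categories emptied by the coverage filter")
    labels <- labels[, !emptied, drop = FALSE]
  }
  catalog <- data.frame(side_effect = colnames(labels),
                        n_drugs = as.integer(colSums(labels)),
                        stringsAsFactors = FALSE)
  counts <- count_virtual_drugs(labels)
  counts$n_single_label <- as.integer(sum(rowSums(labels) == 1L))
  split <- split_train_test(rownames(labels), fraction = test_fraction,
                            seed = split_seed)
  structure(list(labels = labels, catalog = catalog,
                 train = split$train, test = split$test,
                 counts = counts, split_seed = split_seed),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat("<benchmark_dataset> ", x$counts$n_structural, " drugs (",
      x$counts$n_virtual, " virtual) x ", nrow(x$catalog),
      " side effects; train ", length(x$train), " / test ",
      length(x$test), " (seed ", x$split_seed, ")\n", sep = "")
  invisible(x)
}
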