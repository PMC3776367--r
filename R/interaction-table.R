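#' Chemical-chemical interaction table
#'
#' A symmetric sparse map from unordered drug pairs to a confidence score
#' \eqn{Q^c(d_1, d_2) \ge 0}, the STITCH `combined_score` of the pair.
#' Pairs listed in both directions or duplicated are collapsed by taking the
#' maximum score; self-interactions are dropped; absent pairs score 0.
#'
#' @param pairs data.frame with columns `chemical_a`, `chemical_b`, `score`.
#' @return An object of class `interaction_table`.
#' @seealso [cc_score()], [chemical_neighbors()], [read_chemical_links()]
#' @export
interaction_table <- function(pairs = data.frame(chemical_a = character(),
                                                 chemical_b = character(),
                                                 score = numeric())) {
  stopifnot(is.data.frame(pairs),
            all(c("chemical_a", "chemical_b", "score") %in% names(pairs)))
  a <- as.character(pairs$chemical_a)
  b <- as.character(pairs$chemical_b)
  s <- as.numeric(pairs$score)
  if (any(is.na(s)) || any(s < 0)) {
    stop("interaction scores must be non-negative numbers")
  }
  keep <- a != b & s > 0
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  # canonical unordered key, collapse duplicates by max
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    s <- tapply(s, key, max)
    parts <- strsplit(names(s), "\r", fixed = TRUE)
    lo <- vapply(parts, `[`, character(1), 1L)
    hi <- vapply(parts, `[`, character(1), 2L)
    s <- as.numeric(s)
  }
  # adjacency: one named numeric vector of neighbour scores per drug
  ends <- c(lo, hi)
  others <- c(hi, lo)
  ss <- c(s, s)
  adj <- lapply(split(seq_along(ends), ends),
                function(i) setNames(ss[i], others[i]))
  structure(list(adj = adj, n_pairs = length(s)), class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> ", x$n_pairs, " pairs over ",
      length(x$adj), " chemicals\n", sep = "")
  invisible(x)
}

#' @export
length.interaction_table <- function(x) x$n_pairs

#' Interaction confidence score of a drug pair
#'
#' Returns \eqn{Q^c(a, b)}; 0 for pairs absent from the table (the
#' non-interacting convention).
#'
#' @param cc An [interaction_table()].
#' @param a,b Drug identifiers.
#' @return Non-negative scalar; `cc_score(cc, a, b) == cc_score(cc, b, a)`.
#' @export
cc_score <- function(cc, a, b) {
  v <- cc$adj[[as.character(a)]]
  if (is.null(v)) return(0)
  s <- unname(v[as.character(b)])
  if (is.na(s)) 0 else s
}

#' Chemical neighbours of a drug
#'
#' The set \eqn{I^c(d) = \{d' : Q^c(d', d) > 0\}} of compounds with a
#' positive interaction score against `d`.
#'
#' @inheritParams cc_score
#' @param d Drug identifier.
#' @return Character vector of drug identifiers (possibly empty).
#' @export
chemical_neighbors <- function(d, cc) {
  v <- cc$adj[[as.character(d)]]
  if (is.null(v)) character(0) else names(v)
}

#' Protein-chemical interaction table
#'
#' Sparse map from (protein, drug) to a confidence score
#' \eqn{Q^p(p, d) \ge 0}; absent pairs score 0.
#'
#' @param links data.frame with columns `chemical`, `protein`, `score`.
#' @return An object of class `protein_chemical_table`.
#' @seealso [pc_score()], [protein_neighbors()], [read_protein_links()]
#' @export
protein_chemical_table <- function(links = data.frame(chemical = character(),
                                                      protein = character(),
                                                      score = numeric())) {
  stopifnot(is.data.frame(links),
            all(c("chemical", "protein", "score") %in% names(links)))
  d <- as.character(links$chemical)
  p <- as.character(links$protein)
  s <- as.numeric(links$score)
  if (any(is.na(s)) || any(s < 0)) {
    stop("interaction scores must be non-negative numbers")
  }
  keep <- s > 0
  d <- d[keep]; p <- p[keep]; s <- s[keep]
  key <- paste(d, p, sep = "\r")
  if (anyDuplicated(key)) {
    s <- tapply(s, key, max)
    parts <- strsplit(names(s), "\r", fixed = TRUE)
    d <- vapply(parts, `[`, character(1), 1L)
    p <- vapply(parts, `[`, character(1), 2L)
    s <- as.numeric(s)
  }
  by_drug <- lapply(split(seq_along(d), d), function(i) setNames(s[i], p[i]))
  structure(list(by_drug = by_drug, n_links = length(s)),
            class = "protein_chemical_table")
}

#' @export
print.protein_chemical_table <- function(x, ...) {
  cat("<protein_chemical_table> ", x$n_links, " links over ",
      length(x$by_drug), " chemicals\n", sep = "")
  invisible(x)
}

#' @export
length.protein_chemical_table <- function(x) x$n_links

#' Protein-chemical confidence score
#'
#' Returns \eqn{Q^p(p, d)}; 0 when the protein and drug are not linked.
#'
#' @param pc A [protein_chemical_table()].
#' @param p Protein identifier.
#' @param d Drug identifier.
#' @export
pc_score <- function(pc, p, d) {
  v <- pc$by_drug[[as.character(d)]]
  if (is.null(v)) return(0)
  s <- unname(v[as.character(p)])
  if (is.na(s)) 0 else s
}

#' Protein neighbours of a drug
#'
#' The set \eqn{I^p(d) = \{p : Q^p(p, d) > 0\}} of proteins with a positive
#' interaction score against `d`.
#'
#' @inheritParams pc_score
#' @return Character vector of protein identifiers (possibly empty).
#' @export
protein_neighbors <- function(d, pc) {
  v <- pc$by_drug[[as.character(d)]]
  if (is.null(v)) character(0) else names(v)
}

#' Shared neighbours of two drugs
#'
#' Intersections \eqn{I^c(d_1, d_2) = I^c(d_1) \cap I^c(d_2)} and
#' \eqn{I^p(d_1, d_2) = I^p(d_1) \cap I^p(d_2)}: the chemicals and proteins
#' interacting with both drugs.
#'
#' @param d1,d2 Drug identifiers.
#' @param cc An [interaction_table()].
#' @param pc A [protein_chemical_table()].
#' @return List with components `chemicals` and `proteins`.
#' @export
shared_neighbors <- function(d1, d2, cc, pc) {
  list(chemicals = intersect(chemical_neighbors(d1, cc),
                             chemical_neighbors(d2, cc)),
       proteins = intersect(protein_neighbors(d1, pc),
                            protein_neighbors(d2, pc)))
}

#' Hybrid interaction likelihood of two drugs
#'
#' When two drugs have no recorded direct interaction, the likelihood that
#' they interact is estimated from their shared neighbourhood: the sum of
#' both drugs' confidence scores against every shared chemical neighbour and
#' every shared protein partner, averaged over twice the size of the union
#' of those shared entities,
#' \deqn{Q^h(d_1,d_2) = \frac{\sum_{d' \in I^c(d_1,d_2)}\left(Q^c(d_1,d') +
#'   Q^c(d_2,d')\right) + \sum_{p' \in I^p(d_1,d_2)}\left(Q^p(p',d_1) +
#'   Q^p(p',d_2)\right)}{2\,|I^c(d_1,d_2) \cup I^p(d_1,d_2)|}.}
#' Chemical and protein identifiers are treated as disjoint namespaces, so
#' the union cardinality is the sum of the two intersection sizes. With no
#' shared neighbours of either kind the score is defined as 0 (no evidence).
#'
#' @inheritParams shared_neighbors
#' @return Non-negative scalar, symmetric in `d1` and `d2`; never exceeds
#'   the largest single confidence score in the tables.
#' @export
hybrid_score <- function(d1, d2, cc, pc) {
  n1 <- cc$adj[[as.character(d1)]]
  n2 <- cc$adj[[as.character(d2)]]
  shared_c <- intersect(names(n1), names(n2))
  p1 <- pc$by_drug[[as.character(d1)]]
  p2 <- pc$by_drug[[as.character(d2)]]
  shared_p <- intersect(names(p1), names(p2))
  k <- length(shared_c) + length(shared_p)
  if (k == 0L) return(0)
  num <- sum(n1[shared_c]) + sum(n2[shared_c]) +
    sum(p1[shared_p]) + sum(p2[shared_p])
  num / (2 * k)
}
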