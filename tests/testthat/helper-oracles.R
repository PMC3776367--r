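# Independent brute-force oracles. These work directly on raw edge lists /
# link tables and materialise every set explicitly; they never touch the
# package's adjacency structures.

bf_cc_score <- function(edges, a, b) {
  hit <- (edges$a == a & edges$b == b) | (edges$a == b & edges$b == a)
  if (any(hit)) max(edges$score[hit]) else 0
}

bf_pc_score <- function(plinks, p, d) {
  hit <- plinks$protein == p & plinks$chemical == d
  if (any(hit)) max(plinks$score[hit]) else 0
}

bf_chem_neighbors <- function(edges, d) {
  unique(c(edges$b[edges$a == d & edges$score > 0],
           edges$a[edges$b == d & edges$score > 0]))
}

bf_prot_neighbors <- function(plinks, d) {
  unique(plinks$protein[plinks$chemical == d & plinks$score > 0])
}

bf_hybrid_score <- function(d1, d2, edges, plinks) {
  sc <- intersect(bf_chem_neighbors(edges, d1), bf_chem_neighbors(edges, d2))
  sp <- intersect(bf_prot_neighbors(plinks, d1), bf_prot_neighbors(plinks, d2))
  # sprintf keeps zero-length inputs zero-length (paste0 would not)
  k <- length(union(sprintf("chem:%s", sc), sprintf("prot:%s", sp)))
  if (k == 0) return(0)
  num <- 0
  for (x in sc) num <- num + bf_cc_score(edges, d1, x) + bf_cc_score(edges, d2, x)
  for (p in sp) num <- num + bf_pc_score(plinks, p, d1) + bf_pc_score(plinks, p, d2)
  num / (2 * k)
}

# triple loop over (effect, training drug) pairs
bf_score_direct <- function(d, train, edges) {
  out <- setNames(numeric(ncol(train)), colnames(train))
  for (j in colnames(train)) {
    for (di in rownames(train)) {
      if (di == d) next
      out[j] <- out[j] + bf_cc_score(edges, d, di) * train[di, j]
    }
  }
  out
}

bf_score_hybrid <- function(d, train, edges, plinks) {
  out <- setNames(numeric(ncol(train)), colnames(train))
  for (j in colnames(train)) {
    for (di in rownames(train)) {
      if (di == d) next
      out[j] <- out[j] + bf_hybrid_score(d, di, edges, plinks) * train[di, j]
    }
  }
  out
}

bf_accuracy_profile <- function(predictions, truth, m) {
  hits <- integer(m)
  for (d in names(predictions)) {
    rk <- predictions[[d]]$ranking
    true_eff <- colnames(truth)[truth[d, ] == 1]
    for (j in seq_len(m)) {
      row <- rk[rk$rank == j, ]
      if (nrow(row) == 1 && row$side_effect %in% true_eff) {
        hits[j] <- hits[j] + 1
      }
    }
  }
  hits / length(predictions)
}

# Random small instance: raw edge list (unique unordered pairs, integer
# scores), protein links, and a label matrix. Sized for exhaustive checks.
random_instance <- function(seed, n_drugs = NULL, n_proteins = NULL,
                            n_effects = NULL) {
  set.seed(seed)
  n_drugs <- n_drugs %||% sample(3:12, 1)
  n_proteins <- n_proteins %||% sample(1:6, 1)
  n_effects <- n_effects %||% sample(2:8, 1)
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  prots <- sprintf("p%02d", seq_len(n_proteins))
  effects <- sprintf("e%02d", seq_len(n_effects))
  pairs <- t(combn(drugs, 2))
  keep <- runif(nrow(pairs)) < 0.4
  edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                      score = sample(1:999, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  grid <- expand.grid(chemical = drugs, protein = prots,
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < 0.3
  plinks <- data.frame(chemical = grid$chemical[keep],
                       protein = grid$protein[keep],
                       score = sample(1:999, sum(keep), replace = TRUE),
                       stringsAsFactors = FALSE)
  labels <- matrix(as.integer(runif(n_drugs * n_effects) < 0.35),
                   n_drugs, n_effects, dimnames = list(drugs, effects))
  # every drug needs at least one label for evaluation paths
  for (i in seq_len(n_drugs)) {
    if (sum(labels[i, ]) == 0) labels[i, sample(n_effects, 1)] <- 1L
  }
  list(drugs = drugs, proteins = prots, effects = effects, edges = edges,
       plinks = plinks, labels = labels,
       cc = interaction_table(data.frame(chemical_a = edges$a,
                                         chemical_b = edges$b,
                                         score = edges$score)),
       pc = protein_chemical_table(data.frame(chemical = plinks$chemical,
                                              protein = plinks$protein,
                                              score = plinks$score)))
}

# similarity provider derived from an instance's edge list (scores mapped
# into [0, 1)); deterministic given the instance
inst_provider <- function(inst) {
  precomputed_provider(data.frame(drug_a = inst$edges$a,
                                  drug_b = inst$edges$b,
                                  score = inst$edges$score / 1000))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
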