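#' Specification for a synthetic community fixture
#'
#' Describes a toy dataset emulating the premise that interactive
#' compounds share side effects: drugs are partitioned into communities,
#' each community has a characteristic subset of side effects, chemical
#' edges are dense within communities and sparse across, and each drug is
#' also linked to its community's proteins. A fraction of drugs is kept
#' free of chemical edges so that prediction must fall back on the
#' protein-mediated hybrid route.
#'
#' @param n_drugs,n_proteins,n_side_effects,n_communities Entity counts.
#' @param p_edge_within,p_edge_between Chemical edge probabilities inside
#'   and across communities.
#' @param p_label_within Probability a drug carries each of its
#'   community's characteristic side effects.
#' @param p_label_noise Probability a drug carries each non-characteristic
#'   side effect.
#' @param p_chem_isolated Fraction of drugs given no chemical edges (they
#'   keep protein links, exercising the hybrid fallback).
#' @param labels_per_drug Target size of each community's characteristic
#'   side-effect set (mean positive labels per drug at
#'   `p_label_within = 1`, `p_label_noise = 0`).
#' @param p_protein_link Probability a drug links to each of its
#'   community's proteins.
#' @param score_range Length-2 numeric, (low, high) of the uniform
#'   confidence-score draw (STITCH-like positive scale).
#' @param seed Integer RNG seed; all randomness in [generate_fixture()]
#'   derives from it.
#' @return Object of class `fixture_spec` (a validated list).
#' @export
fixture_spec <- function(n_drugs = 40, n_proteins = 12, n_side_effects = 10,
                         n_communities = 4, p_edge_within = 0.8,
                         p_edge_between = 0.05, p_label_within = 0.9,
                         p_label_noise = 0.05, p_chem_isolated = 0.2,
                         labels_per_drug = 3, p_protein_link = 0.8,
                         score_range = c(150, 999), seed = 1L) {
  spec <- list(n_drugs = as.integer(n_drugs),
               n_proteins = as.integer(n_proteins),
               n_side_effects = as.integer(n_side_effects),
               n_communities = as.integer(n_communities),
               p_edge_within = p_edge_within,
               p_edge_between = p_edge_between,
               p_label_within = p_label_within,
               p_label_noise = p_label_noise,
               p_chem_isolated = p_chem_isolated,
               labels_per_drug = as.integer(labels_per_drug),
               p_protein_link = p_protein_link,
               score_range = as.numeric(score_range),
               seed = as.integer(seed))
  probs <- c(spec$p_edge_within, spec$p_edge_between, spec$p_label_within,
             spec$p_label_noise, spec$p_chem_isolated, spec$p_protein_link)
  stopifnot(all(probs >= 0 & probs <= 1),
            spec$n_drugs >= 1, spec$n_proteins >= 1,
            spec$n_side_effects >= 1, spec$n_communities >= 1,
            spec$n_communities <= spec$n_drugs,
            spec$labels_per_drug >= 1,
            length(spec$score_range) == 2,
            spec$score_range[1] <= spec$score_range[2],
            spec$score_range[1] > 0)
  structure(spec, class = "fixture_spec")
}

# split ids into k contiguous near-equal blocks
block_assign <- function(n, k) sort(rep_len(seq_len(k), n))

#' Generate a synthetic fixture dataset
#'
#' Builds a deterministic toy dataset from a [fixture_spec()]: a symmetric
#' self-loop-free chemical interaction table, protein-chemical links, a
#' label matrix in which communities share their characteristic side
#' effects, and a precomputed similarity provider in which same-community
#' drugs look structurally alike. Each random component (chemical edges,
#' protein links, confidence scores, labels, similarity) draws from its
#' own RNG stream derived from `spec$seed`, so changing one parameter
#' perturbs only its component. Every drug is guaranteed at least one
#' label; a spec that cannot deliver one within 100 redraws per drug is
#' rejected.
#'
#' @param spec A [fixture_spec()].
#' @return Object of class `adrnet_fixture`: list with `cc`
#'   ([interaction_table()]), `pc` ([protein_chemical_table()]), `labels`
#'   ([label_matrix()]), `similarity` (a `similarity_provider`),
#'   `similarity_table` (its data.frame form), `community` (named
#'   membership vector) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  drugs <- sprintf("D%03d", seq_len(spec$n_drugs))
  proteins <- sprintf("P%03d", seq_len(spec$n_proteins))
  effects <- sprintf("SE%02d", seq_len(spec$n_side_effects))
  community <- setNames(block_assign(spec$n_drugs, spec$n_communities), drugs)
  prot_comm <- block_assign(spec$n_proteins, spec$n_communities)
  eff_comm <- block_assign(spec$n_side_effects, spec$n_communities)
  # characteristic side effects per community: its block, capped at
  # labels_per_drug; blocks are disjoint by construction
  char_effects <- lapply(seq_len(spec$n_communities), function(k) {
    e <- effects[eff_comm == k]
    if (length(e) == 0L) e <- effects[((k - 1L) %% spec$n_side_effects) + 1L]
    utils::head(e, spec$labels_per_drug)
  })

  # chemical edges (stream 1): which drugs are chemically isolated, then
  # Bernoulli edges among the rest
  edges <- with_seed(spec$seed + 1L, {
    isolated <- runif(spec$n_drugs) < spec$p_chem_isolated
    idx <- which(!isolated)
    pairs <- if (length(idx) >= 2L) t(utils::combn(idx, 2L)) else
      matrix(integer(0), ncol = 2L)
    same <- community[pairs[, 1]] == community[pairs[, 2]]
    p <- ifelse(same, spec$p_edge_within, spec$p_edge_between)
    keep <- runif(nrow(pairs)) < p
    list(a = drugs[pairs[keep, 1]], b = drugs[pairs[keep, 2]],
         isolated = isolated)
  })

  # protein links (stream 2): each drug links to its community's proteins;
  # a drug with no chemical edge and no protein link gets one forced link
  # so the benchmark coverage criterion holds for every drug
  plinks <- with_seed(spec$seed + 2L, {
    pd <- character(0); pp <- character(0)
    for (i in seq_len(spec$n_drugs)) {
      own <- proteins[prot_comm == community[i]]
      if (length(own) == 0L) own <- proteins[1]
      take <- runif(length(own)) < spec$p_protein_link
      chosen <- own[take]
      has_edge <- drugs[i] %in% c(edges$a, edges$b)
      if (length(chosen) == 0L && !has_edge) chosen <- own[1]
      pd <- c(pd, rep(drugs[i], length(chosen)))
      pp <- c(pp, chosen)
    }
    list(drug = pd, protein = pp)
  })

  # confidence scores (stream 3)
  scores <- with_seed(spec$seed + 3L, {
    list(cc = round(runif(length(edges$a), spec$score_range[1],
                          spec$score_range[2])),
         pc = round(runif(length(plinks$drug), spec$score_range[1],
                          spec$score_range[2])))
  })

  # labels (stream 4): characteristic effects with p_label_within, noise
  # effects with p_label_noise; redraw per drug until >= 1 label
  labels <- with_seed(spec$seed + 4L, {
    m <- matrix(0L, spec$n_drugs, spec$n_side_effects,
                dimnames = list(drugs, effects))
    for (i in seq_len(spec$n_drugs)) {
      char <- char_effects[[community[i]]]
      is_char <- effects %in% char
      for (try in seq_len(100L)) {
        p <- ifelse(is_char, spec$p_label_within, spec$p_label_noise)
        row <- as.integer(runif(spec$n_side_effects) < p)
        if (sum(row) >= 1L) break
        if (try == 100L) {
          stop("generation error: drug ", drugs[i],
               " drew no label in 100 attempts; raise p_label_within or ",
               "p_label_noise")
        }
      }
      m[i, ] <- row
    }
    m
  })

  # similarity (stream 5): same-community pairs look alike
  sim_tab <- with_seed(spec$seed + 5L, {
    pairs <- if (spec$n_drugs >= 2L)
      t(utils::combn(seq_len(spec$n_drugs), 2L)) else
        matrix(integer(0), ncol = 2L)
    same <- community[pairs[, 1]] == community[pairs[, 2]]
    s <- ifelse(same, runif(nrow(pairs), 0.55, 0.95),
                runif(nrow(pairs), 0, 0.25))
    data.frame(drug_a = drugs[pairs[, 1]], drug_b = drugs[pairs[, 2]],
               score = round(s, 6), stringsAsFactors = FALSE)
  })

  cc <- interaction_table(data.frame(chemical_a = edges$a,
                                     chemical_b = edges$b,
                                     score = scores$cc))
  pc <- protein_chemical_table(data.frame(chemical = plinks$drug,
                                          protein = plinks$protein,
                                          score = scores$pc))
  structure(list(cc = cc, pc = pc, labels = labels,
                 similarity = precomputed_provider(sim_tab),
                 similarity_table = sim_tab,
                 community = community, spec = spec),
            class = "adrnet_fixture")
}

#' @export
print.adrnet_fixture <- function(x, ...) {
  cat("<adrnet_fixture> ", nrow(x$labels), " drugs, ",
      ncol(x$labels), " side effects, ", x$cc$n_pairs,
      " chemical pairs, ", x$pc$n_links, " protein links (seed ",
      x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a fixture to disk as STITCH-dialect files
#'
#' Emits `chemical_links.tsv` (7-column STITCH chemical dialect, each edge
#' listed in both directions as real dumps do), `protein_links.tsv`
#' (6-column protein dialect), `labels.tsv` (two-column drug/side-effect
#' pairs) and `similarity.tsv` into `dir`, such that reading them back
#' through the io readers reproduces the fixture tables exactly.
#'
#' @param fixture An `adrnet_fixture` from [generate_fixture()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "adrnet_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(chemical_links = file.path(dir, "chemical_links.tsv"),
             protein_links = file.path(dir, "protein_links.tsv"),
             labels = file.path(dir, "labels.tsv"),
             similarity = file.path(dir, "similarity.tsv"))

  adj <- fixture$cc$adj
  cl <- do.call(rbind, c(lapply(names(adj), function(d) {
    data.frame(chemical1 = d, chemical2 = names(adj[[d]]),
               similarity = 0L, experimental = 0L, database = 0L,
               textmining = 0L, combined_score = unname(adj[[d]]),
               stringsAsFactors = FALSE)
  }), list(data.frame(chemical1 = character(), chemical2 = character(),
                      similarity = integer(), experimental = integer(),
                      database = integer(), textmining = integer(),
                      combined_score = numeric()))))
  write.table(cl, paths["chemical_links"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  byd <- fixture$pc$by_drug
  pl <- do.call(rbind, c(lapply(names(byd), function(d) {
    data.frame(chemical = d, protein = names(byd[[d]]),
               experimental = 0L, database = 0L, textmining = 0L,
               combined_score = unname(byd[[d]]), stringsAsFactors = FALSE)
  }), list(data.frame(chemical = character(), protein = character(),
                      experimental = integer(), database = integer(),
                      textmining = integer(), combined_score = numeric()))))
  write.table(pl, paths["protein_links"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  lab <- which(fixture$labels == 1L, arr.ind = TRUE)
  lab <- lab[order(lab[, "row"], lab[, "col"]), , drop = FALSE]
  write.table(data.frame(drug = rownames(fixture$labels)[lab[, "row"]],
                         side_effect = colnames(fixture$labels)[lab[, "col"]]),
              paths["labels"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  write.table(fixture$similarity_table, paths["similarity"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
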