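test_that("accuracy profile counts per-order hits over a fixed denominator", {
  truth <- matrix(c(1L, 0L, 0L), 1, 3, dimnames = list("d1",
                                                       c("C1", "C2", "C3")))
  rp <- rank_side_effects(setNames(c(5, 0, 0), colnames(truth)), drug = "d1")
  prof <- accuracy_profile(list(d1 = rp), truth)
  expect_equal(prof$accuracy, c(1, 0, 0))
  expect_equal(prof$hits, c(1L, 0L, 0L))
  expect_equal(prof$n, rep(1L, 3))

  # drugs with short or empty predictions are misses, N unchanged
  truth2 <- rbind(truth, d2 = c(0L, 1L, 0L))
  rownames(truth2) <- c("d1", "d2")
  empty <- rank_side_effects(setNames(numeric(3), colnames(truth)),
                             drug = "d2")
  prof2 <- accuracy_profile(list(d1 = rp, d2 = empty), truth2)
  expect_equal(prof2$n, rep(2L, 3))
  expect_equal(prof2$accuracy[1], 0.5)

  expect_error(accuracy_profile(list(ghost = rp), truth), "ghost")
})

test_that("accuracy profile matches the brute-force oracle on random instances", {
  for (seed in 201:220) {
    inst <- random_instance(seed)
    preds <- lapply(inst$drugs, function(d) {
      train <- inst$labels[setdiff(inst$drugs, d), , drop = FALSE]
      predict_two_step(d, train, inst$cc, inst$pc)
    })
    names(preds) <- inst$drugs
    m <- ncol(inst$labels)
    prof <- accuracy_profile(preds, inst$labels, m = m)
    expect_equal(prof$accuracy, bf_accuracy_profile(preds, inst$labels, m),
                 tolerance = 1e-12)
  }
})

test_that("two mutually interactive identically-labelled drugs jackknife to AC(1)=1", {
  labels <- matrix(c(1L, 1L, 1L, 1L), 2, 2,
                   dimnames = list(c("d1", "d2"), c("C1", "C2")))
  cc <- interaction_table(data.frame(chemical_a = "d1", chemical_b = "d2",
                                     score = 500))
  prof <- jackknife_evaluate(labels, cc, protein_chemical_table(),
                             method = "interaction")
  expect_equal(prof$accuracy[1], 1.0)
  expect_error(jackknife_evaluate(labels[1, , drop = FALSE], cc,
                                  protein_chemical_table()),
               "at least 2")
})

test_that("jackknife equals a naive drug-by-drug re-implementation on a fixture", {
  fx <- generate_fixture(fixture_spec(n_drugs = 15, n_proteins = 6,
                                      n_side_effects = 6, n_communities = 3,
                                      seed = 5))
  prof <- jackknife_evaluate(fx$labels, fx$cc, fx$pc, method = "interaction")
  # naive oracle: rebuild the training matrix per drug and count hits by hand
  drugs <- rownames(fx$labels)
  naive <- lapply(drugs, function(d) {
    train <- fx$labels[setdiff(drugs, d), , drop = FALSE]
    predict_two_step(d, train, fx$cc, fx$pc)
  })
  names(naive) <- drugs
  expect_equal(prof$accuracy,
               bf_accuracy_profile(naive, fx$labels, ncol(fx$labels)),
               tolerance = 1e-12)
})

test_that("a drug with only protein-mediated evidence shows the hybrid route in the log", {
  # d3 has no chemical edges at all, but shares a protein with d1
  labels <- matrix(1L, 3, 2, dimnames = list(c("d1", "d2", "d3"),
                                             c("C1", "C2")))
  labels["d3", "C2"] <- 0L
  cc <- interaction_table(data.frame(chemical_a = "d1", chemical_b = "d2",
                                     score = 100))
  pc <- protein_chemical_table(data.frame(chemical = c("d1", "d3"),
                                          protein = c("pX", "pX"),
                                          score = c(200, 300)))
  prof <- jackknife_evaluate(labels, cc, pc, method = "interaction")
  log <- attr(prof, "drug_log")
  expect_equal(log$method_used[log$drug == "d3"], "hybrid")
  expect_equal(log$method_used[log$drug == "d1"], "direct")
})

test_that("jackknife never lets a drug's own labels reach its scores", {
  fx <- generate_fixture(fixture_spec(n_drugs = 12, n_side_effects = 6,
                                      n_communities = 3, seed = 9))
  d <- rownames(fx$labels)[1]
  train <- fx$labels[setdiff(rownames(fx$labels), d), , drop = FALSE]
  base <- predict_two_step(d, train, fx$cc, fx$pc)
  # saturating the left-out drug's own label row must change nothing
  poisoned <- fx$labels
  poisoned[d, ] <- 1L
  train2 <- poisoned[setdiff(rownames(poisoned), d), , drop = FALSE]
  expect_identical(predict_two_step(d, train2, fx$cc, fx$pc), base)
  # same if a training matrix still contains a row under the query's id
  with_self <- rbind(train, setNames(rep(1L, ncol(train)), colnames(train)))
  rownames(with_self)[nrow(with_self)] <- d
  expect_identical(predict_two_step(d, with_self, fx$cc, fx$pc)$ranking,
                   base$ranking)
})

test_that("profiles are invariant to drug evaluation order and hits bounded by virtual drugs", {
  fx <- generate_fixture(fixture_spec(n_drugs = 12, n_side_effects = 6,
                                      n_communities = 3, seed = 13))
  prof <- jackknife_evaluate(fx$labels, fx$cc, fx$pc)
  shuffled <- fx$labels[rev(rownames(fx$labels)), , drop = FALSE]
  prof_rev <- jackknife_evaluate(shuffled, fx$cc, fx$pc)
  expect_equal(prof$accuracy, prof_rev$accuracy)
  expect_lte(sum(prof$hits), count_virtual_drugs(fx$labels)$n_virtual)
})

test_that("holdout evaluation predicts test drugs against the full training matrix", {
  fx <- generate_fixture(fixture_spec(seed = 21))
  sp <- split_train_test(rownames(fx$labels), 0.25, seed = 2)
  train <- fx$labels[sp$train, , drop = FALSE]
  test <- fx$labels[sp$test, , drop = FALSE]
  prof <- holdout_evaluate(train, test, fx$cc, fx$pc)
  expect_equal(unique(prof$n), nrow(test))
  expect_true(all(prof$accuracy >= 0 & prof$accuracy <= 1))
  # determinism: same split evaluated twice gives identical profiles
  expect_identical(as.data.frame(holdout_evaluate(train, test, fx$cc, fx$pc)),
                   as.data.frame(prof))
  expect_error(holdout_evaluate(fx$labels, test, fx$cc, fx$pc), "overlap")

  # a test drug with no evidence of any kind contributes only misses
  lone <- matrix(c(1L, rep(0L, ncol(train) - 1)), 1, ncol(train),
                 dimnames = list("stranger", colnames(train)))
  prof1 <- holdout_evaluate(train, lone, fx$cc, fx$pc)
  expect_true(all(prof1$hits == 0L))
  expect_equal(unique(prof1$n), 1L)
})

test_that("similarity-method evaluation runs through the same machinery", {
  fx <- generate_fixture(fixture_spec(seed = 23))
  prof <- jackknife_evaluate(fx$labels, method = "similarity",
                             provider = fx$similarity)
  expect_equal(attr(prof, "method"), "similarity")
  expect_true(all(attr(prof, "drug_log")$method_used == "similarity"))
  expect_error(jackknife_evaluate(fx$labels, method = "similarity"),
               "provider")
})
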