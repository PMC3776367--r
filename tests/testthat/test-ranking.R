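toy_train <- function() {
  m <- matrix(0L, 2, 3, dimnames = list(c("d1", "d2"), c("C1", "C2", "C3")))
  m["d1", "C1"] <- 1L
  m["d2", c("C1", "C2")] <- 1L
  m
}

test_that("direct scoring sums confidence-weighted labels over the training set", {
  train <- toy_train()
  cc <- interaction_table(data.frame(chemical_a = c("q", "q"),
                                     chemical_b = c("d1", "d2"),
                                     score = c(0.4, 0.6)))
  s <- score_direct("q", train, cc)
  expect_equal(as.numeric(s), c(1.0, 0.6, 0))
  expect_equal(attr(s, "method"), "direct")

  # no interactive training drug -> the all-zero (trivial) outcome
  s0 <- score_direct("isolated", train, cc)
  expect_true(all(s0 == 0))
})

test_that("direct scoring excludes a training drug with the query's identifier", {
  train <- toy_train()
  cc <- interaction_table(data.frame(chemical_a = c("d1", "d1"),
                                     chemical_b = c("d2", "x"),
                                     score = c(5, 7)))
  s <- score_direct("d1", train, cc)   # only d2 may vote
  expect_equal(as.numeric(s), c(5, 5, 0))
})

test_that("direct and hybrid scoring match the brute-force triple loop", {
  for (seed in 101:130) {
    inst <- random_instance(seed)
    q <- inst$drugs[1]
    train <- inst$labels[-1, , drop = FALSE]
    expect_equal(as.numeric(score_direct(q, train, inst$cc)),
                 unname(bf_score_direct(q, train, inst$edges)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(score_hybrid(q, train, inst$cc, inst$pc)),
                 unname(bf_score_hybrid(q, train, inst$edges, inst$plinks)),
                 tolerance = 1e-12)
  }
})

test_that("hybrid scoring spreads one hybrid score over the drug's labels", {
  # single training drug with Q^h = 0.75 and labels {C1, C3}
  train <- matrix(c(1L, 0L, 1L), 1, 3,
                  dimnames = list("d2", c("C1", "C2", "C3")))
  cc <- interaction_table(data.frame(chemical_a = c("q", "d2"),
                                     chemical_b = c("x", "x"),
                                     score = c(0.9, 0.7)))
  pc <- protein_chemical_table(data.frame(chemical = c("q", "d2"),
                                          protein = c("p1", "p1"),
                                          score = c(0.8, 0.6)))
  s <- score_hybrid("q", train, cc, pc)
  expect_equal(as.numeric(s), c(0.75, 0, 0.75))

  s0 <- score_hybrid("q", train, interaction_table(),
                     protein_chemical_table())
  expect_true(all(s0 == 0))
})

test_that("similarity scoring takes the maximum over labelled training drugs", {
  train <- matrix(c(1L, 1L, 0L, 0L), 2, 2,
                  dimnames = list(c("d1", "d2"), c("C1", "C5")))
  prov <- precomputed_provider(data.frame(drug_a = c("q", "q"),
                                          drug_b = c("d1", "d2"),
                                          score = c(0.8, 0.5)))
  s <- score_similarity("q", train, prov)
  expect_equal(as.numeric(s), c(0.8, 0))   # max(0.8, 0.5); C5 unlabelled

  # an identical duplicate structure under a different ID scores 1.0
  dup <- precomputed_provider(data.frame(drug_a = "q", drug_b = "d1",
                                         score = 1.0))
  expect_equal(as.numeric(score_similarity("q", train, dup)), c(1.0, 0))
})

test_that("ranking orders positive scores and drops zeros", {
  effects <- sprintf("C%d", 1:5)
  scores <- setNames(c(0, 5, 0, 3, 1), c("C1", "C2", "C3", "C4", "C90"))
  rp <- rank_side_effects(scores, drug = "q")
  expect_equal(rp$ranking$side_effect, c("C2", "C4", "C90"))
  expect_equal(rp$ranking$rank, 1:3)
  expect_true(all(diff(rp$ranking$score) <= 0))
  expect_true(all(rp$ranking$score > 0))

  empty <- rank_side_effects(setNames(numeric(3), effects[1:3]))
  expect_equal(nrow(empty$ranking), 0)
})

test_that("rank ties break by training prevalence then catalog position", {
  scores <- setNames(c(2, 2, 2), c("C1", "C2", "C3"))
  prev <- c(C1 = 50, C2 = 40, C3 = 60)
  rp <- rank_side_effects(scores, prevalence = prev)
  expect_equal(rp$ranking$side_effect, c("C3", "C1", "C2"))
  # without prevalence the catalog position decides
  rp2 <- rank_side_effects(scores)
  expect_equal(rp2$ranking$side_effect, c("C1", "C2", "C3"))
  # deterministic: identical calls give identical orderings
  expect_identical(rank_side_effects(scores, prevalence = prev),
                   rank_side_effects(scores, prevalence = prev))
})

test_that("two-step prediction prefers direct evidence and falls back to hybrid", {
  train <- toy_train()
  cc <- interaction_table(data.frame(chemical_a = "q", chemical_b = "d1",
                                     score = 10))
  pc <- protein_chemical_table(data.frame(chemical = c("q", "d2"),
                                          protein = c("p", "p"),
                                          score = c(3, 4)))
  direct <- predict_two_step("q", train, cc, pc)
  expect_equal(direct$method, "direct")
  expect_equal(direct$ranking$side_effect, "C1")

  # no direct edge into the training set -> hybrid route
  cc2 <- interaction_table(data.frame(chemical_a = "other",
                                      chemical_b = "d1", score = 1))
  hy <- predict_two_step("q", train, cc2, pc)
  expect_equal(hy$method, "hybrid")
  expect_gt(nrow(hy$ranking), 0)

  # both routes empty -> empty prediction tagged hybrid
  none <- predict_two_step("q", train, interaction_table(),
                           protein_chemical_table())
  expect_equal(none$method, "hybrid")
  expect_equal(nrow(none$ranking), 0)
})

test_that("score vectors are invariant to training-drug order and additive", {
  for (seed in 131:140) {
    inst <- random_instance(seed)
    q <- inst$drugs[1]
    train <- inst$labels[-1, , drop = FALSE]
    perm <- train[sample(nrow(train)), , drop = FALSE]
    expect_equal(as.numeric(score_direct(q, train, inst$cc)),
                 as.numeric(score_direct(q, perm, inst$cc)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(score_similarity(q, train, inst_provider(inst))),
                 as.numeric(score_similarity(q, perm, inst_provider(inst))),
                 tolerance = 1e-12)
    # additivity over any partition of the training set
    half <- seq_len(floor(nrow(train) / 2))
    a <- score_direct(q, train[half, , drop = FALSE], inst$cc)
    b <- score_direct(q, train[-half, , drop = FALSE], inst$cc)
    expect_equal(as.numeric(a) + as.numeric(b),
                 as.numeric(score_direct(q, train, inst$cc)),
                 tolerance = 1e-12)
  }
})
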