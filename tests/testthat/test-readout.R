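test_that("sc_drive sums unit activations and is monotone", {
  u <- msn_unit(c(X = 0.6, Y = 1), objects = c("A", "B"))
  d1 <- sc_drive(u, c("A", "B"), "X")
  expect_equal(unname(d1["A"]), msn_response(u, "A", "X"))  # singleton identity

  pop <- msn_population(objects = c("A", "B"))
  d <- sc_drive(pop, c("A", "B"), "X")
  expect_equal(unname(d["A"]), unname(d["B"]))  # mirrored units, initial weights
  expect_equal(unname(d["A"]),
               msn_response(pop[[1]], "A", "X") + msn_response(pop[[2]], "A", "X"))

  # monotone: raising one unit's weight for A raises A's drive only
  pop2 <- pop
  pop2[[1]]$object_weights[["A"]] <- pop2[[1]]$object_weights[["A"]] + 0.5
  d2 <- sc_drive(pop2, c("A", "B"), "X")
  expect_gt(d2[["A"]], d[["A"]])
  expect_equal(d2[["B"]], d[["B"]])

  # works off a response matrix too, and flags missing labels
  rm <- passive_probe(pop)
  expect_equal(sc_drive(rm, c("A", "B"), "X"), d)
  expect_error(sc_drive(rm, c("A", "Q"), "X"), "lacks entries")
})

test_that("softmax choice probabilities follow the logistic closed form", {
  expect_equal(unname(choice_prob(c(A = 1, B = 1))["A"]), 0.5)
  p <- choice_prob(c(A = 1.5, B = 0.5), choice_policy(beta = 1))
  expect_equal(unname(p["A"]), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  # invariance to adding a constant to both drives
  p2 <- choice_prob(c(A = 11.5, B = 10.5), choice_policy(beta = 1))
  expect_equal(p, p2)
  expect_error(choice_prob(c(A = Inf, B = 0)), "finite")
  expect_error(choice_policy(beta = -1))
  expect_error(choice_policy("argmax_epsilon", epsilon = 1.5))
})

test_that("choices are near-uniform as beta approaches zero (binomial oracle)", {
  set.seed(123)
  pol <- choice_policy(beta = 1e-9)
  draws <- replicate(10000, choose_object(c(A = 3, B = -2), pol))
  phat <- mean(draws == "A")
  expect_lt(abs(phat - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("scene preference follows mean activation with deterministic tie-breaks", {
  pop <- msn_population(objects = c("A", "B"))
  rm <- passive_probe(pop)
  prefX <- scene_preference(rm, "MSN_Xpref")
  expect_equal(prefX$scene, "X")   # 1.4 vs 1.0 mean activation
  expect_false(prefX$tie)
  prefY <- scene_preference(rm, "MSN_Ypref")
  expect_equal(prefY$scene, "Y")

  flat <- msn_unit(c(X = 0.7, Y = 0.7), objects = c("A", "B"))
  rmf <- passive_probe(flat)
  pf <- scene_preference(rmf, 1)
  expect_true(pf$tie)
  expect_equal(pf$scene, "X")      # first-declared scene wins ties
})

test_that("value_coding_index is zero for symmetric weights and signed correctly", {
  tk <- task_config("two_object_two_scene")
  pop <- msn_population(objects = c("A", "B"))
  rm <- passive_probe(pop)
  expect_equal(value_coding_index(rm, "MSN_Xpref", tk, "X"), 0)
  expect_equal(value_coding_index(rm, "MSN_Xpref", tk, "Y"), 0)

  pop[[1]]$object_weights <- c(A = 1.5, B = 0.8)
  rm2 <- passive_probe(pop)
  expect_gt(value_coding_index(rm2, "MSN_Xpref", tk, "X"), 0)  # A good in X
  expect_lt(value_coding_index(rm2, "MSN_Xpref", tk, "Y"), 0)  # A bad in Y
  expect_error(value_coding_index(rm2, "MSN_Xpref", tk, "Q"), "absent")
})

test_that("low-FSI units are equivariant under joint scene and object exchange", {
  # With FSI equal across scenes, relabelling the trial stream (A<->B, X<->Y)
  # relabels the learned weights: no scene-conditional asymmetry can arise.
  flat <- c(X = 0.5, Y = 0.5)
  seqn <- oracle_sequence()
  swap_o <- c(A = "B", B = "A")
  swap_s <- c(X = "Y", Y = "X")
  u1 <- msn_unit(flat, objects = c("A", "B"))
  u2 <- msn_unit(flat, objects = c("A", "B"))
  for (t in seq_len(nrow(seqn))) {
    u1 <- apply_update(u1, seqn$object[t], seqn$scene[t], seqn$reward[t])
    u2 <- apply_update(u2, swap_o[[seqn$object[t]]], swap_s[[seqn$scene[t]]],
                       seqn$reward[t])
  }
  expect_equal(u1$object_weights[["A"]], u2$object_weights[["B"]])
  expect_equal(u1$object_weights[["B"]], u2$object_weights[["A"]])
  expect_equal(u1$scene_weights[["X"]], u2$scene_weights[["Y"]])
  expect_equal(u1$scene_weights[["Y"]], u2$scene_weights[["X"]])
})

test_that("mirrored population drives obey drive(A|X) = drive(B|Y) under symmetric training", {
  # Deterministic scene-balanced sequence in which the agent always takes the
  # currently good object; after every mirrored pair of trials the population
  # must satisfy drive(A|X) = drive(B|Y) and drive(B|X) = drive(A|Y).
  pop <- msn_population(objects = c("A", "B"))
  for (pair in 1:10) {
    for (step in list(c("A", "X"), c("B", "Y"))) {
      for (i in seq_along(pop)) {
        pop[[i]] <- apply_update(pop[[i]], step[1], step[2], reward = 1)
      }
    }
    dX <- sc_drive(pop, c("A", "B"), "X")
    dY <- sc_drive(pop, c("A", "B"), "Y")
    expect_equal(dX[["A"]], dY[["B"]], tolerance = 1e-12)
    expect_equal(dX[["B"]], dY[["A"]], tolerance = 1e-12)
  }
})

test_that("scene preference is stable under scene-balanced correct experience", {
  # Under a balanced stream of rewarded correct choices the FSI asymmetry
  # keeps each unit's preferred scene fixed throughout training. (Closed-loop
  # sessions do not guarantee balance and can reverse the preference; see the
  # methods vignette.)
  pop <- msn_population(objects = c("A", "B"))
  tk <- task_config("two_object_two_scene")
  stream <- data.frame(object = rep(c("A", "B"), 40),
                       scene = rep(c("X", "Y"), 40))
  for (t in seq_len(nrow(stream))) {
    for (i in seq_along(pop)) {
      pop[[i]] <- apply_update(pop[[i]], stream$object[t], stream$scene[t],
                               reward = 1)
    }
    rm <- passive_probe(pop)
    expect_equal(scene_preference(rm, "MSN_Xpref")$scene, "X")
    expect_equal(scene_preference(rm, "MSN_Ypref")$scene, "Y")
  }
})
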