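small_task <- function(n = 40) task_config("two_object_two_scene", n_trials = n)

test_that("learning_curve bins tile the session and aggregate correctly", {
  tr <- data.frame(correct = rep(TRUE, 60))
  lc <- learning_curve(tr, 20)
  expect_equal(lc$accuracy, c(1, 1, 1))
  expect_equal(lc$from, c(1, 21, 41))
  expect_equal(lc$to, c(20, 40, 60))

  # bin_size = session length -> one point equal to overall accuracy
  tr2 <- data.frame(correct = c(rep(TRUE, 30), rep(FALSE, 10)))
  lc2 <- learning_curve(tr2, 40)
  expect_equal(nrow(lc2), 1)
  expect_equal(lc2$accuracy, 0.75)

  # coin-flip chooser stays within binomial bounds of 0.5
  set.seed(99)
  tr3 <- data.frame(correct = runif(10000) < 0.5)
  lc3 <- learning_curve(tr3, 100)
  expect_true(all(abs(lc3$accuracy - 0.5) < 4 * sqrt(0.25 / 100) + 1e-9))
  expect_error(learning_curve(tr3[0, , drop = FALSE], 10), "empty")
})

test_that("switch-aligned accuracy aligns on scene changes", {
  # an agent that always chooses the object that was good before the switch:
  # exactly wrong at position 0
  scenes <- rep(c("X", "Y"), each = 5, times = 4)
  correct <- logical(length(scenes))
  for (t in seq_along(scenes)) {
    prev_change <- if (t == 1) NA else scenes[t] != scenes[t - 1]
    correct[t] <- !(t > 1 && prev_change)  # wrong exactly on switch trials
  }
  tr <- data.frame(scene = scenes, correct = correct)
  sa <- switch_aligned_accuracy(tr, max_position = 4)
  expect_equal(sa$accuracy[sa$position == 0], 0)
  expect_equal(sa$accuracy[sa$position == 1], 1)

  # a random agent is flat near 0.5
  set.seed(5)
  tr2 <- data.frame(scene = sample(c("X", "Y"), 8000, TRUE),
                    correct = runif(8000) < 0.5)
  sa2 <- switch_aligned_accuracy(tr2, max_position = 3)
  expect_true(all(abs(sa2$accuracy - 0.5) < 0.06))

  expect_error(switch_aligned_accuracy(data.frame(scene = rep("X", 10),
                                                  correct = TRUE)),
               "no scene switches")
})

test_that("fits are byte-identical under the same seed", {
  f1 <- svl(small_task(), seed = 21)
  f2 <- svl(small_task(), seed = 21)
  expect_identical(f1$trials, f2$trials)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$weights, f2$weights)
  f3 <- svl(small_task(), seed = 22)
  expect_false(identical(f1$trials$chosen, f3$trials$chosen))
})

test_that("the fitted object exposes the standard modelling interface", {
  fit <- svl(small_task(), seed = 4)
  expect_s3_class(fit, "svl")
  expect_equal(dim(coef(fit)), c(2, 4))  # 2 units x (2 objects + 2 scenes)
  expect_length(fitted(fit), 40)
  expect_true(all(fitted(fit) >= 0 & fitted(fit) <= 1))
  expect_equal(residuals(fit), as.numeric(fit$trials$correct) - fitted(fit))

  rm <- predict(fit, type = "response")
  expect_s3_class(rm, "response_matrix")
  expect_equal(dimnames(rm)$object, c("A", "B"))

  skel <- generate_trials(small_task(4), seed = 2)
  p <- predict(fit, skel, type = "prob")
  expect_length(p, 4)
  expect_true(all(p >= 0 & p <= 1))
  ch <- predict(fit, skel, type = "choice")
  expect_true(all(ch %in% c("A", "B")))

  s <- summary(fit)
  expect_s3_class(s, "summary.svl")
  expect_output(print(s), "Final synaptic weights")

  # weight trajectory starts at the initial weights and has one row per trial
  w0 <- subset(fit$weights, trial == 0)
  expect_true(all(w0$weight == 1))
  expect_equal(max(fit$weights$trial), 40)
})

test_that("simulate() evaluates with frozen weights and honours manipulations", {
  fit <- svl(small_task(), seed = 8)
  sims <- simulate(fit, nsim = 2, seed = 3, n_trials = 10)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 10)
  # learning frozen: the stored population is unchanged
  expect_identical(attr(sims, "population"), fit$population)

  sims0 <- simulate(fit, nsim = 1, seed = 3, n_trials = 10, fsi_input = 0,
                    zero_scene_weights = TRUE)
  pop <- attr(sims0, "population")
  expect_true(all(vapply(pop, function(u) all(u$fsi_input == 0), logical(1))))
  expect_true(all(vapply(pop, function(u) all(u$scene_weights == 0), logical(1))))

  expect_identical(simulate(fit, nsim = 1, seed = 3)[[1]],
                   simulate(fit, nsim = 1, seed = 3)[[1]])
})

test_that("run_experiment builds the conditions it advertises", {
  ex <- run_experiment("low_fsi_during_learning", n_seeds = 2, seed = 1,
                       n_trials = 30)
  expect_equal(ex$condition, "low_fsi_during_learning")
  fsis <- lapply(ex$fits[[1]]$population, function(u) unname(u$fsi_input))
  expect_equal(fsis[[1]], c(0.5, 0.5))
  expect_equal(fsis[[2]], c(0.5, 0.5))

  ex2 <- run_experiment("fsi_removed_after_learning", n_seeds = 2, seed = 1,
                        n_trials = 30, n_eval = 20)
  expect_length(ex2$evals, 2)
  expect_equal(nrow(ex2$evals[[1]]), 20)

  expect_error(run_experiment("normal", preset = "no_scene_eight_object"),
               "scene-based")
  expect_error(run_experiment("no_scene", preset = "two_object_two_scene"),
               "no-scene")
  expect_output(print(ex), "low_fsi_during_learning")
})

test_that("the no-scene object-value task is learned with and without FSI asymmetry", {
  for (cond in c("normal", "low_fsi")) {
    acc <- vapply(1:10, function(s) {
      fit <- svl(task_config("no_scene_eight_object"), condition = cond,
                 seed = s, keep_weights = FALSE)
      mean(utils::tail(fit$trials$correct, 40))
    }, numeric(1))
    expect_gt(mean(acc), 0.75)
  }
})
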