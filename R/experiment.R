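#' Fit (train) a scene-gated value-learning agent
#'
#' Runs one closed-loop session of the circuit model on an object-value task:
#' on each trial the scene and offered object pair come from the task
#' generator, the MSN population's SC drives are converted to a choice by the
#' policy, the obtained reward is mapped to the model teaching signal, and the
#' delta-rule update is applied to every unit for the presented elements
#' (chosen object and current scene by default).
#'
#' Conditions:
#' * `"normal"` -- mirrored two-unit population with FSI inputs
#'   (0.6, 1) and (1, 0.6).
#' * `"low_fsi"` -- scene-selectivity of the FSI input removed during
#'   learning (both units at 0.5, 0.5), the model analogue of blocking
#'   excitatory drive to FSIs with IEM-1460 before learning.
#' * For tasks without scenes the FSI and scene-weight terms never enter and
#'   the condition only labels the fit.
#'
#' @param task An [task_config()]; default the two-object two-scene task.
#' @param condition `"normal"` or `"low_fsi"`.
#' @param policy A [choice_policy()]; default softmax with beta = 5.
#' @param learning_rate Learning-speed coefficient LS; default 0.01.
#' @param rectify Clamp negative activations to zero in responses and
#'   updates. Default `FALSE` (the model equations are linear).
#' @param inhibition `"subtractive"` (default) or `"divisive"` FSI term.
#' @param update_policy `"chosen"` (default): the chosen object plus the
#'   current scene drive the update. `"offered"`: both offered objects are
#'   treated as presented, so the trial response includes both object weights
#'   and both are updated by the same amount.
#' @param fsi_preferred,fsi_nonpreferred FSI magnitudes of the mirrored
#'   normal-condition population.
#' @param fsi_low FSI magnitude (both scenes, both units) under `"low_fsi"`.
#' @param n_trials Session length; default the task's `n_trials`.
#' @param seed Integer seed; trials, choices and everything downstream are
#'   reproducible from `(arguments, seed)`.
#' @param keep_weights Record the full weight trajectory (default `TRUE`).
#' @return An object of class `svl` with components `trials` (completed log
#'   with `chosen`, `reward_volume`, `reward_signal`, `correct`, `p_correct`),
#'   `population` (trained units), `population_initial`, `weights` (long
#'   trajectory: `trial`, `unit`, `element`, `weight`), and the fit settings.
#'   Supports `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
#'   `simulate` and `plot`.
#' @examples
#' fit <- svl(task_config("two_object_two_scene", n_trials = 40), seed = 1)
#' summary(fit)
#' @seealso [run_experiment()], [learning_curve()], [switch_aligned_accuracy()]
#' @export
svl <- function(task = task_config("two_object_two_scene"),
                condition = c("normal", "low_fsi"),
                policy = choice_policy(),
                learning_rate = 0.01,
                rectify = FALSE,
                inhibition = c("subtractive", "divisive"),
                update_policy = c("chosen", "offered"),
                fsi_preferred = 0.6, fsi_nonpreferred = 1, fsi_low = 0.5,
                n_trials = NULL,
                seed = 1L,
                keep_weights = TRUE) {
  condition <- match.arg(condition)
  inhibition <- match.arg(inhibition)
  update_policy <- match.arg(update_policy)
  task <- validate_task_config(task)
  if (!is.null(n_trials)) task$n_trials <- as.integer(n_trials)

  scene_based <- length(task$scene_ids) > 0
  pop <- if (!scene_based) {
    msn_population(task$object_ids, scenes = character(0),
                   fsi_input = list(numeric(0), numeric(0)),
                   learning_rate = learning_rate)
  } else if (condition == "low_fsi") {
    flat <- stats::setNames(rep(fsi_low, length(task$scene_ids)), task$scene_ids)
    msn_population(task$object_ids, task$scene_ids,
                   fsi_input = list(flat, flat), learning_rate = learning_rate)
  } else {
    msn_population(task$object_ids, task$scene_ids,
                   fsi_preferred = fsi_preferred,
                   fsi_nonpreferred = fsi_nonpreferred,
                   learning_rate = learning_rate)
  }

  trials <- generate_trials(task, child_seed(seed, 1L))
  res <- run_session(pop, task, trials, policy, rectify, inhibition,
                     update_policy, learning = TRUE,
                     seed = child_seed(seed, 2L), keep_weights = keep_weights)

  structure(list(
    call = match.call(),
    task = task,
    condition = condition,
    policy = policy,
    rectify = rectify,
    inhibition = inhibition,
    update_policy = update_policy,
    seed = seed,
    trials = res$trials,
    population_initial = pop,
    population = res$population,
    weights = res$weights
  ), class = "svl")
}

# Core session loop shared by svl() and simulate.svl(). `trials` is an
# sg_trials skeleton; returns the completed log, final population and (long)
# weight trajectory.
run_session <- function(population, task, trials, policy, rectify, inhibition,
                        update_policy, learning, seed, keep_weights = FALSE) {
  n <- nrow(trials)
  correct <- logical(n)
  p_correct <- numeric(n)
  snap <- function(u) c(u$object_weights, u$scene_weights)
  traj <- if (keep_weights) {
    lapply(population, function(u) {
      m <- matrix(NA_real_, nrow = n + 1, ncol = length(snap(u)),
                  dimnames = list(NULL, names(snap(u))))
      m[1, ] <- snap(u)
      m
    })
  } else NULL

  with_seed(seed, {
    for (t in seq_len(n)) {
      sc <- trials$scene[t]
      offered <- c(trials$offered_1[t], trials$offered_2[t])
      drives <- sc_drive(population, offered, sc, rectify = rectify,
                         inhibition = inhibition)
      probs <- choice_prob(drives, policy)
      ch <- if (stats::runif(1) < probs[[1]]) offered[1] else offered[2]
      vol <- reward_volume_for(task, sc, ch)
      sig <- reward_signal_for(task, vol)
      good <- good_objects(task, sc)
      correct[t] <- ch %in% good
      p_correct[t] <- sum(probs[offered %in% good])
      trials$chosen[t] <- ch
      trials$reward_volume[t] <- vol
      trials$reward_signal[t] <- sig

      if (learning) {
        for (i in seq_along(population)) {
          u <- population[[i]]
          if (update_policy == "chosen") {
            population[[i]] <- apply_update(u, ch,
                                            if (is.na(sc)) NULL else sc,
                                            reward = sig, rectify = rectify,
                                            inhibition = inhibition)
          } else {
            # both offered objects presented: trial response includes both
            # object weights; all presented elements move by the same delta
            exc <- sum(u$object_weights[offered])
            fsi <- 0
            if (!is.na(sc)) {
              exc <- exc + u$scene_weights[[sc]]
              fsi <- u$fsi_input[[sc]]
            }
            act <- if (inhibition == "subtractive") exc - fsi
                   else if (fsi > 0) exc / fsi else exc
            if (rectify) act <- max(act, 0)
            delta <- act * sig * u$learning_rate
            u$object_weights[offered] <- u$object_weights[offered] + delta
            if (!is.na(sc)) u$scene_weights[[sc]] <- u$scene_weights[[sc]] + delta
            population[[i]] <- u
          }
        }
      }
      if (keep_weights) {
        for (i in seq_along(population)) traj[[i]][t + 1, ] <- snap(population[[i]])
      }
    }
  })

  trials$correct <- correct
  trials$p_correct <- p_correct
  weights <- NULL
  if (keep_weights) {
    weights <- do.call(rbind, lapply(seq_along(population), function(i) {
      m <- traj[[i]]
      data.frame(trial = rep(0:n, times = ncol(m)),
                 unit = names(population)[i],
                 element = rep(colnames(m), each = n + 1),
                 weight = as.vector(m),
                 stringsAsFactors = FALSE)
    }))
  }
  list(trials = trials, population = population, weights = weights)
}

#' @export
print.svl <- function(x, ...) {
  n <- nrow(x$trials)
  cat("Scene-gated value-learning fit (", x$condition, " condition, ",
      x$task$preset, ")\n", sep = "")
  cat("  trials: ", n, "   policy: ", x$policy$kind,
      "   inhibition: ", x$inhibition,
      if (x$rectify) "   (rectified)", "\n", sep = "")
  if (n > 0) {
    cat(sprintf("  accuracy: overall %.3f, last 40 trials %.3f\n",
                mean(x$trials$correct),
                mean(utils::tail(x$trials$correct, 40))))
  }
  invisible(x)
}

#' @export
summary.svl <- function(object, bin_size = 20, ...) {
  out <- list(
    fit = object,
    n_trials = nrow(object$trials),
    accuracy = mean(object$trials$correct),
    accuracy_last40 = mean(utils::tail(object$trials$correct, 40)),
    curve = if (nrow(object$trials) > 0) learning_curve(object$trials, bin_size),
    coef = coef(object)
  )
  class(out) <- "summary.svl"
  out
}

#' @export
print.summary.svl <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$curve)) {
    cat("\nLearning curve (bins of", attr(x$curve, "bin_size"), "trials):\n")
    print(x$curve, row.names = FALSE)
  }
  cat("\nFinal synaptic weights:\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Final synaptic weights of a trained agent
#'
#' @param object An [svl()] fit.
#' @param ... Unused.
#' @return Matrix of weights, units in rows, elements (objects then scenes)
#'   in columns.
#' @export
coef.svl <- function(object, ...) {
  t(vapply(object$population,
           function(u) c(u$object_weights, u$scene_weights),
           numeric(length(object$population[[1]]$object_weights) +
                     length(object$population[[1]]$scene_weights))))
}

#' @export
fitted.svl <- function(object, ...) object$trials$p_correct

#' Response residuals of a trained agent
#'
#' The per-trial correctness indicator minus the model's probability of a
#' correct choice on that trial (evaluated with the weights holding at the
#' time of the trial).
#'
#' @param object An [svl()] fit.
#' @param ... Unused.
#' @export
residuals.svl <- function(object, ...) {
  as.numeric(object$trials$correct) - object$trials$p_correct
}

#' Predictions from a trained agent
#'
#' @param object An [svl()] fit.
#' @param newdata Optional `sg_trials` skeleton (columns `scene`,
#'   `offered_1`, `offered_2`). If omitted, `type = "response"` probes the
#'   full object x scene grid.
#' @param type `"response"` (passive-probe response matrix), `"drive"`
#'   (per-trial SC drives), `"prob"` (per-trial probability of choosing
#'   `offered_1`) or `"choice"` (argmax choice).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.svl <- function(object, newdata = NULL,
                        type = c("response", "drive", "prob", "choice"), ...) {
  type <- match.arg(type)
  if (type == "response") {
    return(passive_probe(object$population, rectify = object$rectify,
                         inhibition = object$inhibition))
  }
  if (is.null(newdata)) {
    stop("newdata (trial skeletons) required for type = \"", type, "\"",
         call. = FALSE)
  }
  drives <- t(vapply(seq_len(nrow(newdata)), function(t) {
    sc_drive(object$population,
             c(newdata$offered_1[t], newdata$offered_2[t]),
             newdata$scene[t], rectify = object$rectify,
             inhibition = object$inhibition)
  }, numeric(2)))
  colnames(drives) <- c("offered_1", "offered_2")
  if (type == "drive") return(drives)
  p1 <- vapply(seq_len(nrow(drives)), function(t) {
    choice_prob(c(a = drives[t, 1], b = drives[t, 2]), object$policy)[[1]]
  }, numeric(1))
  if (type == "prob") return(p1)
  ifelse(p1 >= 0.5, newdata$offered_1, newdata$offered_2)
}

#' Simulate evaluation sessions from a trained agent
#'
#' Runs fresh sessions with the trained weights, by default with learning
#' frozen -- the tool for the retention experiments: evaluate the learned
#' behaviour after removing the FSI input (set `fsi_input = 0`), and for the
#' ablation that additionally deletes the learned scene weights
#' (`zero_scene_weights = TRUE`).
#'
#' @param object An [svl()] fit.
#' @param nsim Number of evaluation sessions.
#' @param seed Integer seed.
#' @param n_trials Trials per session; default the fitted task's session
#'   length.
#' @param fsi_input Optional replacement FSI magnitude(s) applied to every
#'   unit (scalar, e.g. 0 for the blockade-after-learning manipulation), or
#'   `NULL` to keep the trained values.
#' @param zero_scene_weights Also reset all scene weights to 0.
#' @param learning Continue learning during evaluation (default `FALSE`).
#' @param sequencing Optional override of the task's scene sequencing for the
#'   evaluation sessions (e.g. `"random"` after block-mode training).
#' @param ... Unused.
#' @return A list of completed `sg_trials` logs, one per simulation, with the
#'   manipulated population in attribute `"population"`.
#' @export
simulate.svl <- function(object, nsim = 1, seed = 1L, n_trials = NULL,
                         fsi_input = NULL, zero_scene_weights = FALSE,
                         learning = FALSE, sequencing = NULL, ...) {
  task <- object$task
  if (!is.null(n_trials)) task$n_trials <- as.integer(n_trials)
  if (!is.null(sequencing)) task$sequencing <- sequencing
  pop <- object$population
  for (i in seq_along(pop)) {
    if (!is.null(fsi_input)) pop[[i]]$fsi_input[] <- fsi_input
    if (zero_scene_weights) pop[[i]]$scene_weights[] <- 0
  }
  out <- lapply(seq_len(nsim), function(k) {
    skel <- generate_trials(task, child_seed(seed, 10L + 2L * k))
    run_session(pop, task, skel, object$policy, object$rectify,
                object$inhibition, object$update_policy, learning = learning,
                seed = child_seed(seed, 11L + 2L * k))$trials
  })
  attr(out, "population") <- pop
  out
}

#' @export
plot.svl <- function(x, bin_size = 20, ...) {
  lc <- learning_curve(x$trials, bin_size)
  graphics::plot(lc$bin, lc$accuracy, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = paste0("trial bin (", bin_size, " trials)"),
                 ylab = "fraction correct",
                 main = paste0("Learning curve (", x$condition, ")"), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(lc)
}

#' Binned learning curve
#'
#' Fraction of correct choices (the currently good object chosen) per bin of
#' consecutive trials. Bins tile the session in order; a final partial bin is
#' kept and its size reported.
#'
#' @param trials A completed trial log with a logical `correct` column.
#' @param bin_size Trials per bin (>= 1).
#' @return Data frame with columns `bin`, `from`, `to`, `n`, `accuracy`;
#'   `bin_size` is carried as an attribute.
#' @export
learning_curve <- function(trials, bin_size = 20) {
  if (nrow(trials) == 0) stop("empty trial log", call. = FALSE)
  if (bin_size < 1) stop("bin_size must be >= 1", call. = FALSE)
  idx <- seq_len(nrow(trials))
  bin <- ceiling(idx / bin_size)
  acc <- tapply(trials$correct, bin, mean)
  n <- tapply(trials$correct, bin, length)
  out <- data.frame(bin = as.integer(names(acc)),
                    from = tapply(idx, bin, min),
                    to = tapply(idx, bin, max),
                    n = as.integer(n),
                    accuracy = as.numeric(acc))
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  out
}

#' Accuracy aligned on scene switches
#'
#' Recodes each trial by its distance from the most recent scene change and
#' averages correctness at each distance. Correctness is always evaluated
#' against the current scene's contingency, including on the switch trial
#' itself, so an agent still choosing by the previous scene scores below
#' chance at position 0. Trials before the first switch are excluded.
#'
#' @param trials A completed trial log with `scene` and `correct` columns.
#' @param max_position Largest distance to report; positions with no data are
#'   returned with `NA` accuracy.
#' @return Data frame with columns `position` (0 = first trial after a scene
#'   change), `n`, `accuracy`.
#' @export
switch_aligned_accuracy <- function(trials, max_position = 19) {
  sc <- trials$scene
  if (all(is.na(sc))) stop("trial log has no scene column to align on", call. = FALSE)
  switches <- which(sc[-1] != sc[-length(sc)]) + 1L
  if (length(switches) == 0) stop("no scene switches in the trial log", call. = FALSE)
  pos <- rep(NA_integer_, length(sc))
  last_switch <- NA_integer_
  for (t in seq_along(sc)) {
    if (t %in% switches) last_switch <- t
    if (!is.na(last_switch)) pos[t] <- t - last_switch
  }
  keep <- !is.na(pos) & pos <= max_position
  acc <- tapply(trials$correct[keep], pos[keep], mean)
  n <- tapply(trials$correct[keep], pos[keep], length)
  all_pos <- 0:max_position
  out <- data.frame(position = all_pos,
                    n = as.integer(n[as.character(all_pos)]),
                    accuracy = as.numeric(acc[as.character(all_pos)]))
  out$n[is.na(out$n)] <- 0L
  out
}

#' Run a multi-seed virtual experiment
#'
#' Scripted end-to-end versions of the four behavioural manipulations:
#'
#' * `"normal"` -- scene-based task, mirrored FSI population.
#' * `"low_fsi_during_learning"` -- FSI scene-selectivity removed while
#'   learning (300-trial sessions by default, the blockade protocol).
#' * `"fsi_removed_after_learning"` -- train under the normal condition, then
#'   set every FSI input to 0 and evaluate with learning frozen (or continued
#'   via `continue_learning`).
#' * `"no_scene"` -- the fixed-value eight-object task (FSI never enters).
#'
#' @param condition Experiment condition (above).
#' @param preset Task preset; defaults to `"two_object_two_scene"` for the
#'   scene conditions and `"no_scene_eight_object"` for `"no_scene"`.
#' @param n_seeds Number of independent agents.
#' @param seed Top-level seed; agent `k` runs with `child_seed(seed, k)`.
#' @param n_trials Learning-session length; defaults: 160 (300 for the
#'   blockade condition).
#' @param n_eval Evaluation trials for `"fsi_removed_after_learning"`.
#' @param continue_learning Keep learning during the post-removal evaluation.
#' @param ... Further arguments passed to [svl()] (policy, rectify,
#'   inhibition, ...).
#' @return An object of class `svl_experiment`: list with the per-seed fits,
#'   per-seed evaluation logs (for the removal condition), and the condition
#'   settings. `summary()` reports accuracy distributions.
#' @export
run_experiment <- function(condition = c("normal", "low_fsi_during_learning",
                                         "fsi_removed_after_learning",
                                         "no_scene"),
                           preset = NULL, n_seeds = 20, seed = 1L,
                           n_trials = NULL, n_eval = 160,
                           continue_learning = FALSE, ...) {
  condition <- match.arg(condition)
  if (is.null(preset)) {
    preset <- if (condition == "no_scene") "no_scene_eight_object"
              else "two_object_two_scene"
  }
  if (condition != "no_scene" && preset == "no_scene_eight_object") {
    stop("scene-based conditions need a scene-based task preset", call. = FALSE)
  }
  if (condition == "no_scene" && preset != "no_scene_eight_object") {
    stop("the no_scene condition needs the no-scene task preset", call. = FALSE)
  }
  if (is.null(n_trials)) {
    n_trials <- if (condition == "low_fsi_during_learning") 300L else 160L
  }
  task <- task_config(preset, n_trials = n_trials)
  fit_condition <- if (condition == "low_fsi_during_learning") "low_fsi" else "normal"

  fits <- lapply(seq_len(n_seeds), function(k) {
    svl(task, condition = fit_condition, seed = child_seed(seed, k),
        keep_weights = FALSE, ...)
  })
  evals <- NULL
  if (condition == "fsi_removed_after_learning") {
    evals <- lapply(seq_len(n_seeds), function(k) {
      simulate(fits[[k]], nsim = 1, seed = child_seed(seed, 1000L + k),
               n_trials = n_eval, fsi_input = 0,
               learning = continue_learning)[[1]]
    })
  }
  structure(list(condition = condition, preset = preset, n_seeds = n_seeds,
                 seed = seed, n_trials = n_trials, n_eval = n_eval,
                 fits = fits, evals = evals),
            class = "svl_experiment")
}

#' @export
print.svl_experiment <- function(x, ...) {
  cat("Virtual experiment:", x$condition, "(", x$n_seeds, "seeds,",
      x$n_trials, "trials )\n")
  acc <- vapply(x$fits, function(f) mean(utils::tail(f$trials$correct, 40)),
                numeric(1))
  cat(sprintf("  last-40-trial accuracy: mean %.3f (sd %.3f)\n",
              mean(acc), stats::sd(acc)))
  if (!is.null(x$evals)) {
    ev <- vapply(x$evals, function(tr) mean(tr$correct), numeric(1))
    cat(sprintf("  post-removal accuracy:  mean %.3f (sd %.3f)\n",
                mean(ev), stats::sd(ev)))
  }
  invisible(x)
}

#' @export
summary.svl_experiment <- function(object, last = 40, ...) {
  acc_last <- vapply(object$fits,
                     function(f) mean(utils::tail(f$trials$correct, last)),
                     numeric(1))
  out <- list(condition = object$condition,
              n_seeds = object$n_seeds,
              accuracy_last = acc_last,
              last = last,
              accuracy_eval = if (!is.null(object$evals)) {
                vapply(object$evals, function(tr) mean(tr$correct), numeric(1))
              })
  class(out) <- "summary.svl_experiment"
  out
}

#' @export
print.summary.svl_experiment <- function(x, ...) {
  cat("Condition:", x$condition, "-", x$n_seeds, "seeds\n")
  cat(sprintf("  last-%d accuracy: mean %.3f, frac > 0.75: %.2f\n",
              x$last, mean(x$accuracy_last), mean(x$accuracy_last > 0.75)))
  if (!is.null(x$accuracy_eval)) {
    cat(sprintf("  evaluation accuracy: mean %.3f\n", mean(x$accuracy_eval)))
  }
  invisible(x)
}
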