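#' Build a task configuration
#'
#' Constructs the declarative description of an object-value task: the scenes,
#' the objects, the scene-dependent reward contingency, and the sequencing of
#' scenes across a session. Three presets cover the behavioural procedures used
#' with the circuit model:
#'
#' * `"two_object_two_scene"` -- two objects (A, B) whose reward values reverse
#'   between two scenes (X, Y): A is good in X and bad in Y, B the opposite.
#' * `"eight_object_two_scene"` -- eight objects in two groups (A1..A4,
#'   B1..B4); group A is good in scene X, group B in scene Y.
#' * `"no_scene_eight_object"` -- eight objects with fixed values (four good,
#'   four bad) and no background scene.
#'
#' A "good" object earns the large reward (0.3 mL by default) and a "bad"
#' object the small reward (0.1 mL). On the model's internal scale the large
#' reward maps to a teaching signal of +1 and the small reward to -0.5; both
#' mappings are configuration fields, not constants.
#'
#' @param preset One of the preset names above.
#' @param ... Overrides for declared fields (`n_trials`, `block_length`,
#'   `sequencing`, `reward_large`, `reward_small`, `reward_signal_large`,
#'   `reward_signal_small`). Unknown fields are an error.
#' @return An object of class `sg_task`: a list with fields `preset`,
#'   `scene_ids`, `object_ids`, `contingency` (data frame with columns
#'   `scene`, `object`, `reward_volume`), `reward_large`, `reward_small`,
#'   `reward_signal_large`, `reward_signal_small`, `sequencing` (one of
#'   `"block"`, `"random"`, `"none"`), `block_length`, `n_trials`, and
#'   `offer_rule` (always `"good_vs_bad"`: each trial offers one currently
#'   good and one currently bad object).
#' @examples
#' task <- task_config("two_object_two_scene")
#' subset(task$contingency, scene == "X")
#' @seealso [generate_trials()], [passive_schedule()]
#' @export
task_config <- function(preset = c("two_object_two_scene",
                                   "eight_object_two_scene",
                                   "no_scene_eight_object"),
                        ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    two_object_two_scene = list(
      scene_ids = c("X", "Y"),
      object_ids = c("A", "B"),
      good_by_scene = list(X = "A", Y = "B"),
      sequencing = "random"
    ),
    eight_object_two_scene = list(
      scene_ids = c("X", "Y"),
      object_ids = c(paste0("A", 1:4), paste0("B", 1:4)),
      good_by_scene = list(X = paste0("A", 1:4), Y = paste0("B", 1:4)),
      sequencing = "block"
    ),
    no_scene_eight_object = list(
      scene_ids = character(0),
      object_ids = c(paste0("G", 1:4), paste0("D", 1:4)),
      good_by_scene = list(none = paste0("G", 1:4)),
      sequencing = "none"
    )
  )
  defaults <- list(
    n_trials = 160L, block_length = 20L,
    reward_large = 0.3, reward_small = 0.1,
    reward_signal_large = 1, reward_signal_small = -0.5,
    sequencing = cfg$sequencing
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown task_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(overrides)] <- overrides

  scenes <- if (length(cfg$scene_ids) > 0) cfg$scene_ids else "none"
  contingency <- do.call(rbind, lapply(scenes, function(sc) {
    good <- cfg$good_by_scene[[sc]]
    data.frame(
      scene = if (identical(sc, "none")) NA_character_ else sc,
      object = cfg$object_ids,
      reward_volume = ifelse(cfg$object_ids %in% good,
                             defaults$reward_large, defaults$reward_small),
      stringsAsFactors = FALSE
    )
  }))
  rownames(contingency) <- NULL

  out <- structure(list(
    preset = preset,
    scene_ids = cfg$scene_ids,
    object_ids = cfg$object_ids,
    contingency = contingency,
    reward_large = defaults$reward_large,
    reward_small = defaults$reward_small,
    reward_signal_large = defaults$reward_signal_large,
    reward_signal_small = defaults$reward_signal_small,
    sequencing = match.arg(defaults$sequencing, c("block", "random", "none")),
    block_length = as.integer(defaults$block_length),
    n_trials = as.integer(defaults$n_trials),
    offer_rule = "good_vs_bad"
  ), class = "sg_task")
  validate_task_config(out)
}

#' Validate a task configuration
#'
#' Checks the structural invariants of an [task_config()] object: every
#' (scene, object) pair maps to exactly one of the two reward volumes, the
#' large reward strictly exceeds the small one (both positive), and in
#' scene-based tasks every object's value label reverses between the two
#' scenes of a pair.
#'
#' @param task An `sg_task` object (or a plain list with the same fields, as
#'   produced by deserialisation).
#' @return The validated `sg_task`, invisibly classed.
#' @export
validate_task_config <- function(task) {
  stopifnot(is.list(task))
  ct <- task$contingency
  if (!all(c("scene", "object", "reward_volume") %in% names(ct))) {
    stop("contingency must have columns scene, object, reward_volume", call. = FALSE)
  }
  if (!(task$reward_large > task$reward_small && task$reward_small > 0)) {
    stop("reward volumes must satisfy reward_large > reward_small > 0", call. = FALSE)
  }
  if (!all(ct$reward_volume %in% c(task$reward_large, task$reward_small))) {
    stop("every contingency entry must equal reward_large or reward_small", call. = FALSE)
  }
  key <- paste(ct$scene, ct$object)
  if (anyDuplicated(key)) {
    stop("contingency maps some (scene, object) pair more than once", call. = FALSE)
  }
  scene_based <- length(task$scene_ids) > 0
  if (scene_based) {
    expected <- length(task$scene_ids) * length(task$object_ids)
    if (nrow(ct) != expected) {
      stop("contingency must cover the full scene x object grid", call. = FALSE)
    }
    # value labels must reverse between the two scenes of a pair
    for (ob in task$object_ids) {
      vols <- ct$reward_volume[ct$object == ob]
      if (length(unique(vols)) != length(vols)) {
        stop("scene-based preset violates the reversal invariant for object ", ob,
             call. = FALSE)
      }
    }
    if (task$sequencing == "none") {
      stop("sequencing \"none\" is incompatible with a scene-based contingency",
           call. = FALSE)
    }
  }
  if (task$n_trials < 0) stop("n_trials must be >= 0", call. = FALSE)
  if (task$block_length < 1) stop("block_length must be >= 1", call. = FALSE)
  structure(task, class = "sg_task")
}

#' @export
print.sg_task <- function(x, ...) {
  cat("Object-value task configuration (", x$preset, ")\n", sep = "")
  cat("  scenes:    ", if (length(x$scene_ids)) paste(x$scene_ids, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  objects:   ", paste(x$object_ids, collapse = ", "), "\n", sep = "")
  cat("  rewards:   ", x$reward_large, "/", x$reward_small, " mL (signals ",
      x$reward_signal_large, "/", x$reward_signal_small, ")\n", sep = "")
  cat("  session:   ", x$n_trials, " trials, sequencing ", x$sequencing,
      if (x$sequencing == "block") paste0(" (block length ", x$block_length, ")"),
      "\n", sep = "")
  invisible(x)
}

# Good objects under a scene (scene may be NA for no-scene tasks).
good_objects <- function(task, scene) {
  ct <- task$contingency
  rows <- if (length(task$scene_ids) == 0 || is.na(scene)) rep(TRUE, nrow(ct))
          else ct$scene == scene
  ct$object[rows & ct$reward_volume == task$reward_large]
}

bad_objects <- function(task, scene) {
  ct <- task$contingency
  rows <- if (length(task$scene_ids) == 0 || is.na(scene)) rep(TRUE, nrow(ct))
          else ct$scene == scene
  ct$object[rows & ct$reward_volume == task$reward_small]
}

# Reward volume for choosing `object` under `scene`.
reward_volume_for <- function(task, scene, object) {
  ct <- task$contingency
  rows <- if (length(task$scene_ids) == 0 || is.na(scene)) ct$object == object
          else ct$scene == scene & ct$object == object
  v <- ct$reward_volume[rows]
  if (length(v) != 1) stop("no contingency entry for (", scene, ", ", object, ")",
                           call. = FALSE)
  v
}

reward_signal_for <- function(task, volume) {
  if (volume == task$reward_large) task$reward_signal_large else task$reward_signal_small
}

#' Generate the trial skeletons of a session
#'
#' Draws the scene sequence and the per-trial object offers for one session.
#' In `"block"` sequencing the scene is constant within consecutive blocks of
#' `block_length` trials and changes at every block boundary, to a scene
#' drawn uniformly among the others (so every session contains scene
#' switches and a 160-trial session has exactly 8 maximal scene runs). In
#' `"random"` sequencing the scene is drawn independently on every trial. Each trial offers one currently good and one
#' currently bad object, drawn uniformly; left/right assignment of the pair to
#' `offered_1`/`offered_2` is randomised.
#'
#' The `chosen`, `reward_volume` and `reward_signal` columns are returned as
#' `NA` and are filled in by an agent (see [svl()]).
#'
#' @param task An [task_config()] object.
#' @param seed Integer seed; the trial list is fully reproducible from
#'   `(task, seed)`.
#' @return A data frame of class `sg_trials` with columns `index`, `block_id`,
#'   `scene`, `offered_1`, `offered_2`, `chosen`, `reward_volume`,
#'   `reward_signal`.
#' @examples
#' trials <- generate_trials(task_config("eight_object_two_scene"), seed = 1)
#' table(rle(trials$scene)$lengths)
#' @export
generate_trials <- function(task, seed) {
  task <- validate_task_config(task)
  n <- task$n_trials
  scene_based <- length(task$scene_ids) > 0
  with_seed(seed, {
    if (scene_based) {
      if (task$sequencing == "block") {
        # the scene changes at every block boundary, to a random other scene:
        # a 160-trial session splits into exactly 8 runs of block_length
        n_blocks <- ceiling(n / task$block_length)
        blocks <- character(n_blocks)
        for (b in seq_len(n_blocks)) {
          pool <- if (b == 1L) task$scene_ids
                  else setdiff(task$scene_ids, blocks[b - 1L])
          blocks[b] <- if (length(pool) == 1L) pool else sample(pool, 1L)
        }
        scenes <- rep(blocks, each = task$block_length)[seq_len(n)]
        block_id <- rep(seq_len(n_blocks), each = task$block_length)[seq_len(n)]
      } else {
        scenes <- sample(task$scene_ids, n, replace = TRUE)
        block_id <- rep(NA_integer_, n)
      }
    } else {
      scenes <- rep(NA_character_, n)
      block_id <- rep(NA_integer_, n)
    }
    offered <- t(vapply(seq_len(n), function(i) {
      gd <- good_objects(task, scenes[i])
      bd <- bad_objects(task, scenes[i])
      pair <- c(sample(gd, 1L), sample(bd, 1L))
      sample(pair)  # randomise position
    }, character(2)))
    out <- data.frame(
      index = seq_len(n),
      block_id = block_id,
      scene = scenes,
      offered_1 = if (n) offered[, 1] else character(0),
      offered_2 = if (n) offered[, 2] else character(0),
      chosen = rep(NA_character_, n),
      reward_volume = rep(NA_real_, n),
      reward_signal = rep(NA_real_, n),
      stringsAsFactors = FALSE
    )
    class(out) <- c("sg_trials", "data.frame")
    out
  })
}

#' Generate a passive-viewing schedule
#'
#' Builds the presentation list of a passive-viewing probe: every
#' (scene, object) combination appears exactly `reps` times, in an order
#' shuffled by `seed`. Objects are presented one at a time on the scene while
#' reward is decoupled from object identity, so the schedule carries no reward
#' column. Sessions with fewer than 7 repetitions per combination are rejected
#' unless `force = TRUE`, because response statistics are unstable below that.
#'
#' @param task An [task_config()] object.
#' @param reps Repetitions per (scene, object) combination; default 7.
#' @param seed Integer seed for the shuffle.
#' @param force Allow `reps < 7`.
#' @return A data frame with columns `order`, `scene`, `object`.
#' @examples
#' sched <- passive_schedule(task_config("eight_object_two_scene"), reps = 7, seed = 1)
#' nrow(sched)  # 2 scenes x 8 objects x 7 reps = 112
#' @export
passive_schedule <- function(task, reps = 7L, seed, force = FALSE) {
  task <- validate_task_config(task)
  if (reps < 7L && !force) {
    stop("reps < 7 gives unstable response estimates; pass force = TRUE to override",
         call. = FALSE)
  }
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  scenes <- if (length(task$scene_ids) > 0) task$scene_ids else NA_character_
  grid <- expand.grid(scene = scenes, object = task$object_ids,
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  with_seed(seed, {
    ord <- sample.int(nrow(grid))
    out <- data.frame(order = seq_len(nrow(grid)),
                      scene = grid$scene[ord],
                      object = grid$object[ord],
                      stringsAsFactors = FALSE)
    out
  })
}

#' Generate a synthetic single-unit recording
#'
#' Produces a synthetic extracellular unit for exercising the classification
#' and response-statistics pipeline: a smooth biphasic spike waveform whose
#' peak-to-trough time equals `duration_us` to within one sampling interval,
#' plus an inhomogeneous-Poisson spike train with rate `baseline_hz` except in
#' the 50--400 ms window after each object onset, where the rate steps to
#' `evoked_hz`. Trials are laid out as scene onset, object onset 800 ms later,
#' and 2 s between scene onsets.
#'
#' @param duration_us Target peak-to-trough duration in microseconds (> 0).
#' @param baseline_hz Baseline firing rate in Hz (>= 0).
#' @param evoked_hz Evoked rate in Hz during the post-object window (>= 0).
#'   Scalar, applied to every object presentation.
#' @param n_events Number of trials (scene + object presentations).
#' @param seed Integer seed.
#' @param sampling_interval_us Waveform sampling interval in microseconds.
#' @param tan Mark the unit as a tonically active neuron (annotation only;
#'   TAN status is an external label, not inferred from the data).
#' @return An object of class `sg_unit`: list with `waveform`,
#'   `sampling_interval_us`, `spike_times` (seconds, strictly increasing),
#'   `scene_onsets`, `object_onsets`, `ground_truth` (one of `"FSI"`, `"MSN"`,
#'   `"TAN_excluded"`, `"unclassified"` under the default 800 us amplifier
#'   profile) and the generating parameters.
#' @examples
#' u <- synthetic_unit(400, baseline_hz = 15, evoked_hz = 45, n_events = 20, seed = 1)
#' peak_trough_duration(u$waveform, u$sampling_interval_us)
#' @export
synthetic_unit <- function(duration_us, baseline_hz, evoked_hz = baseline_hz,
                           n_events = 100L, seed = 1L,
                           sampling_interval_us = 25, tan = FALSE) {
  if (duration_us <= 0) stop("duration_us must be > 0", call. = FALSE)
  if (baseline_hz < 0 || evoked_hz < 0) stop("rates must be >= 0", call. = FALSE)
  waveform <- biphasic_template(duration_us, sampling_interval_us)

  iti <- 2.0            # scene onset every 2 s
  scene_onsets <- seq_len(n_events) * iti
  object_onsets <- scene_onsets + 0.8
  t_end <- if (n_events > 0) max(object_onsets) + 1 else 1

  spikes <- with_seed(seed, {
    # piecewise-constant rate: baseline everywhere, evoked in 50-400 ms
    # post-object windows
    win_start <- object_onsets + 0.05
    win_end <- object_onsets + 0.40
    bounds <- sort(unique(c(0, win_start, win_end, t_end)))
    out <- numeric(0)
    for (i in seq_len(length(bounds) - 1)) {
      a <- bounds[i]; b <- bounds[i + 1]
      in_win <- any(a >= win_start - 1e-12 & b <= win_end + 1e-12)
      rate <- if (in_win) evoked_hz else baseline_hz
      k <- stats::rpois(1, rate * (b - a))
      if (k > 0) out <- c(out, sort(stats::runif(k, a, b)))
    }
    sort(unique(out))
  })

  gt <- if (tan) "TAN_excluded" else {
    cls <- classify_unit(duration_us, baseline_hz,
                         thresholds = classifier_thresholds("long"))
    cls$label
  }
  structure(list(
    waveform = waveform,
    sampling_interval_us = sampling_interval_us,
    spike_times = spikes,
    scene_onsets = scene_onsets,
    object_onsets = object_onsets,
    ground_truth = gt,
    duration_us = duration_us,
    baseline_hz = baseline_hz,
    evoked_hz = evoked_hz,
    tan = tan
  ), class = "sg_unit")
}

# Smooth biphasic spike template: positive Gaussian peak followed by a
# negative Gaussian trough `duration_us` later. The lobes are kept narrow
# relative to their separation so the analytic extrema coincide with the
# sampled ones to within one sample.
biphasic_template <- function(duration_us, sampling_interval_us) {
  sd_us <- duration_us / 4
  t_peak <- 4 * sd_us
  t_trough <- t_peak + duration_us
  t_max <- t_trough + 4 * sd_us
  tt <- seq(0, t_max, by = sampling_interval_us)
  w <- exp(-((tt - t_peak)^2) / (2 * sd_us^2)) -
    0.7 * exp(-((tt - t_trough)^2) / (2 * sd_us^2))
  w
}
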