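#' Construct a model MSN unit
#'
#' One model medium spiny neuron: a vector of scene-selective inhibitory FSI
#' input magnitudes together with its plastic synaptic weights for objects and
#' scenes and the learning-rate coefficient. All quantities are unitless.
#' Weights are initialised at 1 and FSI inputs at (0.6, 1) unless overridden;
#' these are the model's standard "normal condition" values, with the smaller
#' FSI input defining the unit's preferred scene.
#'
#' @param fsi_input Named numeric vector of inhibitory magnitudes, one per
#'   scene (all >= 0), e.g. `c(X = 0.6, Y = 1)`.
#' @param objects Character vector of object labels.
#' @param scenes Character vector of scene labels; defaults to
#'   `names(fsi_input)`.
#' @param object_weights,scene_weights Initial synaptic weights (scalar or
#'   named vector); default 1.
#' @param learning_rate Learning-speed coefficient LS (>= 0); default 0.01.
#' @param unit_id Optional identifier.
#' @return An object of class `msn_unit`.
#' @examples
#' u <- msn_unit(c(X = 0.6, Y = 1), objects = c("A", "B"))
#' msn_response(u, object = "A", scene = "X")  # 1 + 1 - 0.6 = 1.4
#' @export
msn_unit <- function(fsi_input, objects, scenes = names(fsi_input),
                     object_weights = 1, scene_weights = 1,
                     learning_rate = 0.01, unit_id = NULL) {
  if (is.null(names(fsi_input)) && length(scenes) == length(fsi_input)) {
    names(fsi_input) <- scenes
  }
  if (!setequal(names(fsi_input), scenes)) {
    stop("fsi_input must be named with one magnitude per scene", call. = FALSE)
  }
  if (any(fsi_input < 0)) stop("FSI magnitudes must be >= 0", call. = FALSE)
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  ow <- expand_weights(object_weights, objects, "object_weights")
  sw <- expand_weights(scene_weights, scenes, "scene_weights")
  if (!all(is.finite(ow)) || !all(is.finite(sw))) {
    stop("weights must be finite", call. = FALSE)
  }
  structure(list(
    unit_id = if (!is.null(unit_id)) unit_id
              else if (length(fsi_input) > 0) {
                paste0("MSN_", names(which.min(fsi_input[scenes]))[1], "pref")
              } else "MSN",
    fsi_input = fsi_input[scenes],
    object_weights = ow,
    scene_weights = sw,
    learning_rate = learning_rate
  ), class = "msn_unit")
}

expand_weights <- function(w, labels, what) {
  if (length(labels) == 0) return(stats::setNames(numeric(0), character(0)))
  if (length(w) == 1 && is.null(names(w))) {
    return(stats::setNames(rep(as.numeric(w), length(labels)), labels))
  }
  if (!setequal(names(w), labels)) {
    stop(what, " must be a scalar or named with one entry per label", call. = FALSE)
  }
  stats::setNames(as.numeric(w[labels]), labels)
}

#' @export
print.msn_unit <- function(x, ...) {
  cat("Model MSN ", x$unit_id, " (LS = ", x$learning_rate, ")\n", sep = "")
  cat("  FSI input:      ", paste(sprintf("%s=%g", names(x$fsi_input), x$fsi_input),
                                  collapse = "  "), "\n", sep = "")
  cat("  object weights: ", paste(sprintf("%s=%.4g", names(x$object_weights),
                                          x$object_weights), collapse = "  "),
      "\n", sep = "")
  if (length(x$scene_weights)) {
    cat("  scene weights:  ", paste(sprintf("%s=%.4g", names(x$scene_weights),
                                            x$scene_weights), collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' MSN response to a stimulus presentation
#'
#' Evaluates the model MSN's activation to the presentation of at most one
#' object and at most one scene. With subtractive inhibition (the default) the
#' activation is the sum of the presented object and scene synaptic weights
#' minus the FSI input for the presented scene. With divisive inhibition the
#' excitatory sum is instead divided by the FSI input (shunting-style gain
#' control); when no scene is presented there is no FSI pool and the gain
#' is 1. The function is pure: no weights are modified.
#'
#' @param unit An [msn_unit()].
#' @param object Object label or `NULL`.
#' @param scene Scene label or `NULL`.
#' @param rectify If `TRUE`, clamp negative activations to 0 (an MSN
#'   hyperpolarised below threshold fires no spikes). Default `FALSE`: the
#'   model equations are linear.
#' @param inhibition `"subtractive"` (default) or `"divisive"`. The two
#'   readings of the FSI term; see the package vignette for why both are
#'   provided.
#' @return Scalar activation (unitless).
#' @examples
#' u <- msn_unit(c(X = 0.6, Y = 1), objects = c("A", "B"))
#' msn_response(u, "A", "X")                       # 1.4
#' msn_response(u, "A", "X", inhibition = "divisive")  # 2 / 0.6
#' @export
msn_response <- function(unit, object = NULL, scene = NULL, rectify = FALSE,
                         inhibition = c("subtractive", "divisive")) {
  inhibition <- match.arg(inhibition)
  excitation <- 0
  if (!is.null(object) && !is.na(object)) {
    if (!object %in% names(unit$object_weights)) {
      stop("unknown object label: ", object, call. = FALSE)
    }
    excitation <- excitation + unit$object_weights[[object]]
  }
  fsi <- 0
  if (!is.null(scene) && !is.na(scene)) {
    if (!scene %in% names(unit$scene_weights)) {
      stop("unknown scene label: ", scene, call. = FALSE)
    }
    excitation <- excitation + unit$scene_weights[[scene]]
    fsi <- unit$fsi_input[[scene]]
  }
  r <- if (inhibition == "subtractive") {
    excitation - fsi
  } else {
    if (fsi > 0) excitation / fsi else excitation
  }
  if (rectify) max(r, 0) else r
}

#' Apply one reward-gated synaptic update
#'
#' Implements the delta-rule weight change: for each presented element
#' (the object and the scene), the synaptic weight moves by
#' `activation * reward * learning_rate`, where the activation is the MSN
#' response to the presentation computed on the *pre-update* weights. Weights
#' of non-presented elements are untouched. The input unit is not mutated; a
#' new unit is returned.
#'
#' Weights are unclamped and may become negative; pass `floor` to impose a
#' lower bound for exploratory use.
#'
#' @inheritParams msn_response
#' @param reward Reward teaching signal: +1 after a large reward, -0.5 after a
#'   small (or no) reward by default. Other values are accepted (the mapping
#'   is a task-configuration field).
#' @param floor Optional lower bound applied to updated weights.
#' @return The updated `msn_unit`.
#' @examples
#' u <- msn_unit(c(X = 0.6, Y = 1), objects = c("A", "B"))
#' u2 <- apply_update(u, "A", "X", reward = 1)
#' u2$object_weights[["A"]]  # 1 + 1.4 * 1 * 0.01 = 1.014
#' @export
apply_update <- function(unit, object = NULL, scene = NULL, reward,
                         rectify = FALSE,
                         inhibition = c("subtractive", "divisive"),
                         floor = NULL) {
  inhibition <- match.arg(inhibition)
  act <- msn_response(unit, object, scene, rectify = rectify,
                      inhibition = inhibition)
  delta <- act * reward * unit$learning_rate
  out <- unit
  if (!is.null(object) && !is.na(object)) {
    out$object_weights[[object]] <- out$object_weights[[object]] + delta
  }
  if (!is.null(scene) && !is.na(scene)) {
    out$scene_weights[[scene]] <- out$scene_weights[[scene]] + delta
  }
  if (!is.null(floor)) {
    out$object_weights <- pmax(out$object_weights, floor)
    out$scene_weights <- pmax(out$scene_weights, floor)
  }
  out
}

#' Construct an MSN population
#'
#' The default circuit population: two model MSNs with mirrored FSI scene
#' inputs. The scene X-preferring unit receives weak FSI input in scene X and
#' strong in scene Y (0.6, 1); the scene Y-preferring unit the mirror image
#' (1, 0.6). Pass `fsi_input` as a list of named vectors to build other
#' populations (e.g. the low-FSI condition `c(X = 0.5, Y = 0.5)` for both
#' units).
#'
#' @param objects Character vector of object labels.
#' @param scenes Character vector of scene labels (length 2 for the default
#'   mirrored construction).
#' @param fsi_input Either `NULL` (mirrored default), or a list with one named
#'   numeric vector per unit.
#' @param fsi_preferred,fsi_nonpreferred Magnitudes used by the mirrored
#'   default construction; 0.6 and 1.
#' @param ... Passed to [msn_unit()] (weights, learning rate).
#' @return An object of class `msn_population` (a list of `msn_unit`s).
#' @examples
#' pop <- msn_population(objects = c("A", "B"))
#' names(pop)
#' @export
msn_population <- function(objects, scenes = c("X", "Y"), fsi_input = NULL,
                           fsi_preferred = 0.6, fsi_nonpreferred = 1, ...) {
  if (is.null(fsi_input)) {
    if (length(scenes) != 2) {
      stop("the mirrored default population needs exactly two scenes", call. = FALSE)
    }
    fsi_input <- list(
      stats::setNames(c(fsi_preferred, fsi_nonpreferred), scenes),
      stats::setNames(c(fsi_nonpreferred, fsi_preferred), scenes)
    )
  }
  units <- lapply(fsi_input, function(f) {
    msn_unit(f, objects = objects, scenes = scenes, ...)
  })
  ids <- make.unique(vapply(units, function(u) u$unit_id, character(1)), sep = "_")
  for (i in seq_along(units)) units[[i]]$unit_id <- ids[i]
  names(units) <- ids
  structure(units, class = "msn_population")
}

#' @export
print.msn_population <- function(x, ...) {
  cat("MSN population with", length(x), "unit(s)\n")
  for (u in x) print(u)
  invisible(x)
}

#' Probe a population with passive viewing
#'
#' Evaluates every unit's response to every (object, scene) combination, the
#' model analogue of a passive-viewing session. Probing performs no weight
#' updates.
#'
#' @param population An [msn_population()] (or single `msn_unit`).
#' @param objects,scenes Labels to probe; default: the population's own.
#' @inheritParams msn_response
#' @return A 3-d array of class `response_matrix` indexed
#'   `[unit, object, scene]`, with the probe settings in attributes.
#' @examples
#' rm <- passive_probe(msn_population(objects = c("A", "B")))
#' rm["MSN_Xpref", , "X"] - rm["MSN_Xpref", , "Y"]  # FSI asymmetry: 0.4
#' @export
passive_probe <- function(population, objects = NULL, scenes = NULL,
                          rectify = FALSE,
                          inhibition = c("subtractive", "divisive")) {
  inhibition <- match.arg(inhibition)
  if (inherits(population, "msn_unit")) {
    population <- structure(stats::setNames(list(population), population$unit_id),
                            class = "msn_population")
  }
  if (length(population) == 0) stop("population is empty", call. = FALSE)
  if (is.null(objects)) objects <- names(population[[1]]$object_weights)
  if (is.null(scenes)) scenes <- names(population[[1]]$scene_weights)
  use_scenes <- if (length(scenes) == 0) NA_character_ else scenes
  arr <- array(NA_real_,
               dim = c(length(population), length(objects), length(use_scenes)),
               dimnames = list(unit = names(population), object = objects,
                               scene = if (all(is.na(use_scenes))) "none" else use_scenes))
  for (i in seq_along(population)) {
    for (j in seq_along(objects)) {
      for (k in seq_along(use_scenes)) {
        sc <- use_scenes[k]
        arr[i, j, k] <- msn_response(population[[i]], objects[j],
                                     if (is.na(sc)) NULL else sc,
                                     rectify = rectify, inhibition = inhibition)
      }
    }
  }
  structure(arr, class = c("response_matrix", "array"),
            rectify = rectify, inhibition = inhibition)
}

#' Convert a response matrix to long format
#'
#' @param x A `response_matrix` from [passive_probe()].
#' @param ... Unused.
#' @return Data frame with columns `unit`, `object`, `scene`, `activation`.
#' @export
as.data.frame.response_matrix <- function(x, ...) {
  d <- as.data.frame.table(unclass(x), responseName = "activation",
                           stringsAsFactors = FALSE)
  names(d) <- c("unit", "object", "scene", "activation")
  d
}
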