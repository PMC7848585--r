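#' Superior-colliculus drive for offered objects
#'
#' Aggregates MSN population activity into a per-object drive on the saccade
#' map. The striatal output reaches the superior colliculus through a double
#' inhibition (MSN -| SNr -| SC), which is monotone increasing end to end, so
#' the drive is computed as the sum over units of each unit's activation to
#' (object, scene): increasing any unit's activation to an object never
#' decreases that object's drive.
#'
#' @param population An [msn_population()], or a `response_matrix` from
#'   [passive_probe()].
#' @param offered Character vector of offered object labels.
#' @param scene Scene label (or `NULL`/`NA` for the no-scene task).
#' @inheritParams msn_response
#' @return Named numeric vector of drives, one per offered object.
#' @examples
#' pop <- msn_population(objects = c("A", "B"))
#' sc_drive(pop, c("A", "B"), "X")  # symmetric at initial weights
#' @export
sc_drive <- function(population, offered, scene = NULL, rectify = FALSE,
                     inhibition = c("subtractive", "divisive")) {
  inhibition <- match.arg(inhibition)
  if (inherits(population, "response_matrix")) {
    sc <- if (is.null(scene) || is.na(scene)) "none" else scene
    if (!all(offered %in% dimnames(population)$object) ||
        !sc %in% dimnames(population)$scene) {
      stop("response matrix lacks entries for the requested objects/scene",
           call. = FALSE)
    }
    m <- population[, offered, sc, drop = FALSE]
    return(apply(m, 2, sum))
  }
  if (inherits(population, "msn_unit")) population <- list(population)
  drives <- vapply(offered, function(ob) {
    sum(vapply(population, function(u) {
      msn_response(u, ob, if (is.null(scene) || is.na(scene)) NULL else scene,
                   rectify = rectify, inhibition = inhibition)
    }, numeric(1)))
  }, numeric(1))
  if (any(!is.finite(drives))) stop("non-finite drive", call. = FALSE)
  drives
}

#' Construct a choice policy
#'
#' The behavioural read-out layer that converts SC drives into a saccade
#' choice. This layer is not part of the biological circuit model; it is the
#' package's own decision rule. Two kinds are provided: a softmax on the drive
#' difference (`P(o1) = 1 / (1 + exp(-beta * (d1 - d2)))`) and
#' epsilon-greedy argmax.
#'
#' @param kind `"softmax"` or `"argmax_epsilon"`.
#' @param beta Inverse temperature for softmax (> 0). Default 5.
#' @param epsilon Exploration rate for argmax (in `[0, 1]`).
#' @return An object of class `choice_policy`.
#' @export
choice_policy <- function(kind = c("softmax", "argmax_epsilon"), beta = 5,
                          epsilon = 0.1) {
  kind <- match.arg(kind)
  if (kind == "softmax" && beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (kind == "argmax_epsilon" && (epsilon < 0 || epsilon > 1)) {
    stop("epsilon must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, beta = beta, epsilon = epsilon),
            class = "choice_policy")
}

#' Choice probabilities under a policy
#'
#' @param drives Named numeric vector of two finite drives.
#' @param policy A [choice_policy()].
#' @return Named probability vector summing to 1.
#' @export
choice_prob <- function(drives, policy = choice_policy()) {
  if (length(drives) != 2 || any(!is.finite(drives))) {
    stop("drives must be two finite numbers", call. = FALSE)
  }
  p1 <- if (policy$kind == "softmax") {
    1 / (1 + exp(-policy$beta * (drives[[1]] - drives[[2]])))
  } else {
    base <- policy$epsilon / 2
    if (drives[[1]] > drives[[2]]) 1 - base
    else if (drives[[1]] < drives[[2]]) base
    else 0.5
  }
  stats::setNames(c(p1, 1 - p1), names(drives))
}

#' Draw a choice from SC drives
#'
#' @inheritParams choice_prob
#' @return The chosen object label.
#' @examples
#' set.seed(1)
#' choose_object(c(A = 1.2, B = 0.7))
#' @export
choose_object <- function(drives, policy = choice_policy()) {
  p <- choice_prob(drives, policy)
  if (stats::runif(1) < p[[1]]) names(drives)[1] else names(drives)[2]
}

#' Preferred scene of a unit
#'
#' The preferred scene is the scene yielding the larger mean activation across
#' all probed objects. Ties are broken deterministically in favour of the
#' first-declared scene and flagged.
#'
#' @param responses A `response_matrix` from [passive_probe()].
#' @param unit Unit name or index.
#' @return List with `scene`, `means` (per-scene mean activation over
#'   objects), and `tie` (logical).
#' @export
scene_preference <- function(responses, unit) {
  m <- responses[unit, , , drop = FALSE]
  means <- apply(m, 3, mean)
  best <- which.max(means)  # first max on ties
  list(scene = names(means)[best], means = means,
       tie = sum(means == max(means)) > 1)
}

#' Scene-conditional value-coding index
#'
#' The difference between a unit's mean activation to the objects that are
#' good under `scene` and its mean activation to the objects that are bad
#' under that scene. Positive values mean the unit responds more to currently
#' good objects.
#'
#' @param responses A `response_matrix`.
#' @param unit Unit name or index.
#' @param task An [task_config()] supplying the good/bad contingency.
#' @param scene Scene label under which goodness is evaluated.
#' @return Signed scalar.
#' @export
value_coding_index <- function(responses, unit, task, scene) {
  if (length(task$scene_ids) > 0 && !scene %in% task$scene_ids) {
    stop("scene ", scene, " absent from the task contingency", call. = FALSE)
  }
  gd <- good_objects(task, scene)
  bd <- bad_objects(task, scene)
  sc <- if (length(task$scene_ids) == 0) "none" else scene
  mean(responses[unit, gd, sc]) - mean(responses[unit, bd, sc])
}
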