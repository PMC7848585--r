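#' Write / read a task configuration as YAML
#'
#' Serialises an [task_config()] to YAML and back. Reading re-validates the
#' configuration, so a file with, e.g., a contingency violating the
#' scene-reversal invariant is rejected with an informative error.
#'
#' @param task An `sg_task`.
#' @param path File path.
#' @return `write_task_config` returns `path` invisibly; `read_task_config`
#'   returns the validated `sg_task`.
#' @export
write_task_config <- function(task, path) {
  task <- validate_task_config(task)
  lst <- unclass(task)
  lst$contingency <- as.list(as.data.frame(lst$contingency))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  lst <- yaml::read_yaml(path)
  need <- c("preset", "scene_ids", "object_ids", "contingency")
  missing <- setdiff(need, names(lst))
  if (length(missing) > 0) {
    stop("task config ", path, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lst$contingency <- as.data.frame(lst$contingency, stringsAsFactors = FALSE)
  lst$contingency$scene <- as.character(lst$contingency$scene)
  lst$scene_ids <- as.character(unlist(lst$scene_ids))
  lst$object_ids <- as.character(unlist(lst$object_ids))
  lst$n_trials <- as.integer(lst$n_trials)
  lst$block_length <- as.integer(lst$block_length)
  validate_task_config(lst)
}

#' Write / read a trial log as CSV
#'
#' @param trials An `sg_trials` data frame.
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(scene = "character",
                                        offered_1 = "character",
                                        offered_2 = "character",
                                        chosen = "character"))
  class(out) <- c("sg_trials", "data.frame")
  out
}

#' Write a response matrix as long-format CSV
#'
#' @param responses A `response_matrix` from [passive_probe()].
#' @param path File path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' Run a virtual experiment into a directory
#'
#' Executes [run_experiment()] and writes its results as plain-text files:
#' per-seed trial logs (`trials_seed<k>.csv`), per-seed post-manipulation
#' evaluation logs where the condition has them, the final response matrix of
#' the first agent (`responses.csv`), the task configuration
#' (`task.yaml`) and a JSON manifest (`manifest.json`) listing every output
#' file with its MD5 checksum, the seeds, and the package version. Re-running
#' with the same specification and seed reproduces every checksum.
#'
#' @param out_dir Output directory (created if needed).
#' @param condition,preset,n_seeds,seed,... Passed to [run_experiment()].
#' @return The manifest, invisibly.
#' @export
run_to_dir <- function(out_dir, condition = "normal", preset = NULL,
                       n_seeds = 5, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- run_experiment(condition = condition, preset = preset,
                        n_seeds = n_seeds, seed = seed, ...)
  files <- character(0)
  for (k in seq_len(n_seeds)) {
    f <- file.path(out_dir, sprintf("trials_seed%03d.csv", k))
    write_trials(exp$fits[[k]]$trials, f)
    files <- c(files, f)
  }
  if (!is.null(exp$evals)) {
    for (k in seq_len(n_seeds)) {
      f <- file.path(out_dir, sprintf("eval_seed%03d.csv", k))
      write_trials(exp$evals[[k]], f)
      files <- c(files, f)
    }
  }
  f <- file.path(out_dir, "responses.csv")
  write_responses(predict(exp$fits[[1]], type = "response"), f)
  files <- c(files, f)
  f <- file.path(out_dir, "task.yaml")
  write_task_config(exp$fits[[1]]$task, f)
  files <- c(files, f)

  manifest <- list(
    condition = exp$condition,
    preset = exp$preset,
    seed = seed,
    n_seeds = n_seeds,
    package_version = as.character(utils::packageVersion("scenegate")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
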