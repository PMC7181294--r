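#' Word-space size and letter interval for given word/alphabet sizes
#'
#' The word space holds alpha^omega distinct words, from "aa...a" to the
#' last letter repeated omega times. Cost of the method grows with the word
#' space, so sizes above 1e8 are refused unless \code{force = TRUE}.
#'
#' @param omega word length (>= 1).
#' @param alpha alphabet size (2..26).
#' @param force allow word spaces above 1e8.
#' @return List of class \code{"wordspace_info"} with \code{omega},
#'   \code{alpha}, \code{cardinality}, \code{first_word}, \code{last_word}.
#' @export
wordspace_info <- function(omega, alpha, force = FALSE) {
  if (omega < 1) stop("omega must be >= 1")
  if (alpha < 2 || alpha > 26) stop("alpha must be in 2..26")
  card <- as.numeric(alpha)^omega
  if (card > 1e8 && !force)
    stop("word space ", format(card, big.mark = ","),
         " exceeds 1e8; pass force = TRUE to proceed")
  structure(list(omega = as.integer(omega), alpha = as.integer(alpha),
                 cardinality = card,
                 first_word = strrep("a", omega),
                 last_word = strrep(letters[alpha], omega)),
            class = "wordspace_info")
}

#' @export
print.wordspace_info <- function(x, ...) {
  cat(sprintf("omega = %d, alpha = %d: %s words (%s-%s)\n",
              x$omega, x$alpha, format(x$cardinality, big.mark = ",",
                                       scientific = FALSE),
              x$first_word, x$last_word))
  invisible(x)
}

# order-independent fingerprint of a config list, for run logs
config_hash <- function(x) {
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 131 + v[i]) %% 1e9
  sprintf("%09d", h)
}

#' Experiment configuration
#'
#' Validates and normalizes the settings of a full HAR-SR run. Defaults
#' are the standard operating point (concatenation fusion, SAX,
#' omega = 6, alpha = 6, 128-sample window, 50\% overlap, k = 3).
#'
#' @param scenario synthetic scenario name, or \code{NULL} when
#'   \code{dataset} is given.
#' @param dataset path to a long-form CSV read by
#'   \code{\link{read_recordings}}.
#' @param sampling_rate required with \code{dataset}.
#' @param seed integer seed.
#' @param output_dir where \code{\link{run_experiment}} writes artifacts;
#'   \code{NULL} disables writing.
#' @param noise_scale scenario noise multiplier.
#' @param ... passed to \code{\link{harsr_control}}.
#' @return List of class \code{"experiment_config"}.
#' @export
experiment_config <- function(scenario = "separable", dataset = NULL,
                              sampling_rate = NULL, seed = NULL,
                              output_dir = NULL, noise_scale = 1, ...) {
  control <- harsr_control(...)
  if (is.null(dataset) && is.null(scenario))
    stop("config error: give a scenario name or a dataset path")
  if (!is.null(dataset) && is.null(sampling_rate))
    stop("config error: a dataset path needs a sampling_rate")
  wordspace_info(control$symbolic$omega, control$symbolic$alpha)
  structure(list(scenario = scenario, dataset = dataset,
                 sampling_rate = sampling_rate, seed = seed,
                 output_dir = output_dir, noise_scale = noise_scale,
                 control = control),
            class = "experiment_config")
}

#' Run a full HAR-SR experiment
#'
#' Simulates or loads the dataset, runs leave-one-subject-out evaluation
#' with the configured pipeline and, when an output directory is set,
#' persists the report (JSON), pooled confusion matrix (CSV), the feature
#' matrix of a final all-subjects fit (CSV with columns
#' Hs,Q_ref,Q_<class>...,C_ref,C_<class>...,label,subject), the fitted
#' model (JSON) and a run log carrying the seed and a config hash.
#'
#' @param config an \code{\link{experiment_config}}.
#' @return The \code{"harsr_loso"} report, invisibly when writing.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    stop("config error: expected an experiment_config")
  recordings <- if (!is.null(config$dataset))
    read_recordings(config$dataset, config$sampling_rate)
  else
    simulate_scenario(config$scenario, seed = config$seed,
                      noise_scale = config$noise_scale)
  report <- loso(recordings, config$control)
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    write_report(report, dir)
    model <- harsr(recordings, config$control)
    feat <- data.frame(model$features, label = model$labels,
                       subject = model$subjects, check.names = FALSE)
    utils::write.csv(feat, file.path(dir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(labels = model$labels, subjects = model$subjects,
           features = apply(model$features, 1L, identity,
                            simplify = FALSE),
           classes = model$classes,
           references = lapply(model$references$class_refs,
                               function(r) as.list(r$probs)),
           control = unclass_control(config$control)),
      file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(sprintf("seed: %s",
                         if (is.null(config$seed)) "scenario-default"
                         else config$seed),
                 sprintf("config_hash: %s",
                         config_hash(unclass_control(config$control))),
                 sprintf("n_recordings: %d", length(recordings)),
                 sprintf("accuracy: %.6f", report$accuracy),
                 sprintf("macro_f1: %.6f", report$macro_f1)),
               file.path(dir, "run.log"))
    return(invisible(report))
  }
  report
}

unclass_control <- function(control) {
  x <- unclass(control)
  x$symbolic <- unclass(x$symbolic)
  x
}
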