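#' Assemble and validate a session configuration
#'
#' Collects every knob of the pipeline into one validated list. All numeric
#' fields are checked here, before any I/O or computation starts, against
#' the preconditions of the stages that will consume them. Paths may be
#' omitted when a synthetic session is passed directly to [run_pipeline()].
#'
#' @param traces_path,behavior_path input CSVs (see [read_traces()],
#'   [read_behavior()]); ignored when a session object is supplied.
#' @param output_dir directory for pipeline artifacts.
#' @param sampling_rate imaging frame rate (Hz).
#' @param binarization list: `method` ("rise", "threshold", "deconvolved"),
#'   `z_threshold`, `lowpass_cutoff_hz`.
#' @param discretization list: `bin_width_cm`, `direction` (logical, 1D
#'   only), `min_speed_cms`.
#' @param significance list: `n_shuffles`, `alpha`, `tie_mode`; `n_shuffles
#'   = 0` skips the stage.
#' @param bootstrap list: `n_boot`, `sample_fraction`, `level`; `n_boot =
#'   0` skips the stage.
#' @param decoder list: `prior_mode`, `scoring_variant`, `window_s`,
#'   `train_fraction`, `block_s`, `n_trials`.
#' @param seed master seed; every random stage derives its own seed from it.
#' @return A validated list of class `session_config`.
#' @export
session_config <- function(traces_path = NULL, behavior_path = NULL,
                           output_dir = NULL, sampling_rate = 30,
                           binarization = list(), discretization = list(),
                           significance = list(), bootstrap = list(),
                           decoder = list(), seed = 1L) {
  defaults <- list(
    binarization = list(method = "rise", z_threshold = 2, lowpass_cutoff_hz = 2),
    discretization = list(bin_width_cm = 3, direction = FALSE, min_speed_cms = 5),
    significance = list(n_shuffles = 1000, alpha = 0.05, tie_mode = "strict"),
    bootstrap = list(n_boot = 1000, sample_fraction = 0.5, level = 95),
    decoder = list(prior_mode = "uniform", scoring_variant = "log_product",
                   window_s = 0.5, train_fraction = 0.5, block_s = 5,
                   n_trials = 5))
  merge1 <- function(user, def, what) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown)) stop_invalid("unknown %s option(s): %s", what,
                                      paste(unknown, collapse = ", "))
    utils::modifyList(def, user)
  }
  cfg <- list(traces_path = traces_path, behavior_path = behavior_path,
              output_dir = output_dir, sampling_rate = sampling_rate,
              binarization = merge1(binarization, defaults$binarization, "binarization"),
              discretization = merge1(discretization, defaults$discretization, "discretization"),
              significance = merge1(significance, defaults$significance, "significance"),
              bootstrap = merge1(bootstrap, defaults$bootstrap, "bootstrap"),
              decoder = merge1(decoder, defaults$decoder, "decoder"),
              seed = as.integer(seed))
  # validation-first: fail on a bad knob before any file is touched
  check_scalar_number(cfg$sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (!cfg$binarization$method %in% c("rise", "threshold", "deconvolved")) {
    stop_invalid("unknown binarization method '%s'", cfg$binarization$method)
  }
  if (!is.null(cfg$binarization$lowpass_cutoff_hz)) {
    check_scalar_number(cfg$binarization$lowpass_cutoff_hz, "lowpass_cutoff_hz",
                        lower = 0, upper = cfg$sampling_rate / 2,
                        strict_lower = TRUE, strict_upper = TRUE)
  }
  check_scalar_number(cfg$discretization$bin_width_cm, "bin_width_cm",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$discretization$min_speed_cms, "min_speed_cms", lower = 0)
  check_scalar_number(cfg$significance$n_shuffles, "n_shuffles", lower = 0)
  check_scalar_number(cfg$significance$alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(cfg$bootstrap$n_boot, "n_boot", lower = 0)
  if (cfg$bootstrap$n_boot > 0) {
    check_scalar_number(cfg$bootstrap$sample_fraction, "sample_fraction",
                        lower = 0, upper = 1, strict_lower = TRUE)
  }
  if (!cfg$decoder$prior_mode %in% c("uniform", "observed", "unbiased")) {
    stop_invalid("unknown prior_mode '%s'", cfg$decoder$prior_mode)
  }
  if (!cfg$decoder$scoring_variant %in% c("log_product", "log1p")) {
    stop_invalid("unknown scoring_variant '%s'", cfg$decoder$scoring_variant)
  }
  check_scalar_number(cfg$decoder$window_s, "window_s", lower = 0)
  check_scalar_number(cfg$decoder$train_fraction, "train_fraction",
                      lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(cfg$decoder$block_s, "block_s", lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$decoder$n_trials, "n_trials", lower = 1)
  structure(cfg, class = "session_config")
}

#' Run the full analysis pipeline
#'
#' Executes binarize -> discretize -> tune -> significance -> decode ->
#' encode on one session, writes artifacts to `config$output_dir` (CSV +
#' a JSON run report), and returns the report. All randomness flows from
#' `config$seed` through a fixed seed-derivation scheme, so two runs with
#' the same config are identical apart from the wall-clock entry in the
#' report.
#'
#' @param config a [session_config()].
#' @param session optional [simulate_session()] object used instead of
#'   reading `traces_path` / `behavior_path`.
#' @return the run report (list), invisibly; written as `report.json`.
#' @export
run_pipeline <- function(config, session = NULL) {
  stopifnot(inherits(config, "session_config"))
  warn_count <- 0L
  withCallingHandlers({
    if (is.null(session)) {
      if (is.null(config$traces_path) || is.null(config$behavior_path)) {
        stop_invalid("config needs traces_path and behavior_path (or pass a session)")
      }
      traces <- read_traces(config$traces_path, config$sampling_rate)
      track <- read_behavior(config$behavior_path)
      track <- align_behavior_to_frames(track, traces$timestamps)
    } else {
      traces <- session$traces
      track <- session$track
    }
    raster <- switch(config$binarization$method,
      rise = binarize_rise(traces, config$binarization$z_threshold,
                           config$binarization$lowpass_cutoff_hz),
      threshold = binarize_threshold(traces, config$binarization$z_threshold),
      deconvolved = binarize_from_deconvolved(traces$values, traces$sampling_rate))
    stateseq <- if (track$ndim == 1L) {
      discretize_1d(track, config$discretization$bin_width_cm)
    } else {
      discretize_2d(track, config$discretization$bin_width_cm)
    }
    if (isTRUE(config$discretization$direction)) {
      stateseq <- augment_direction(stateseq, track)
    }
    speed <- compute_speed(track)
    stateseq <- exclude_immobility(stateseq, speed,
                                   config$discretization$min_speed_cms)
    tuning <- estimate_tuning(raster, stateseq)
    mi_p <- rep(NA_real_, tuning$n_neurons)
    if (config$significance$n_shuffles > 0) {
      for (k in seq_len(tuning$n_neurons)) {
        dist <- circular_shuffle_statistic(raster$states[k, ], stateseq, "mi",
                                           config$significance$n_shuffles,
                                           seed = derive_seed(config$seed, 100L + k))
        mi_p[k] <- empirical_pvalue(dist$actual, dist$surrogates,
                                    config$significance$tie_mode)
      }
    }
    report_dec <- decoding_report(raster, stateseq,
                                  config$decoder$prior_mode,
                                  config$decoder$scoring_variant,
                                  config$decoder$window_s,
                                  config$decoder$train_fraction,
                                  config$decoder$block_s,
                                  config$decoder$n_trials,
                                  seed = derive_seed(config$seed, 200L))
    recon <- reconstruct_activity(stateseq, tuning)
    report <- list(
      package_version = as.character(utils::packageVersion("caldecode")),
      seed = config$seed,
      parameters = config[c("sampling_rate", "binarization", "discretization",
                            "significance", "decoder")],
      n_neurons = tuning$n_neurons,
      n_frames = ncol(raster$states),
      n_included_frames = tuning$n_included,
      n_states = tuning$M,
      fraction_active = mean(raster$states),
      mi_bits = list(median = stats::median(tuning$mi), max = max(tuning$mi)),
      n_significant_mi = if (config$significance$n_shuffles > 0) {
        sum(mi_p < config$significance$alpha, na.rm = TRUE)
      } else NA,
      decoding = list(agreement = report_dec$agreement,
                      mean_error_cm = report_dec$mean_error_cm,
                      median_error_cm = report_dec$median_error_cm,
                      chance_agreement = 1 / tuning$M,
                      n_trials = report_dec$n_trials),
      warnings = NA_integer_)
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      out <- function(f) file.path(config$output_dir, f)
      utils::write.csv(data.frame(frame = seq_along(stateseq$state),
                                  state = stateseq$state,
                                  included = stateseq$included),
                       out("states.csv"), row.names = FALSE)
      jsonlite::write_json(stateseq$geometry, out("geometry.json"),
                           dataframe = "rows", digits = NA)
      utils::write.csv(tuning$likelihood, out("tuning_likelihood.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(neuron = seq_len(tuning$n_neurons),
                                  marginal = tuning$marginal,
                                  mi_bits = tuning$mi, mi_p_value = mi_p),
                       out("neuron_summary.csv"), row.names = FALSE)
      utils::write.csv(report_dec$confusion, out("confusion.csv"),
                       row.names = FALSE)
      report$warnings <- warn_count
      jsonlite::write_json(c(report, list(timestamp = format(Sys.time()))),
                           out("report.json"), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    report$warnings <- warn_count
    invisible(report)
  }, warning = function(w) {
    warn_count <<- warn_count + 1L
    invokeRestart("muffleWarning")
  })
}
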