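#' Run the full analysis pipeline on simulated cohorts
#'
#' Executes, per experiment (forward, backward, or both): cohort
#' simulation, preprocessing to clean epochs, the behavioural
#' reaction-time analysis, the ERP running-t-test analysis with window
#' selection and topographic p summary, optional per-participant decoding,
#' and questionnaire correlations.  All randomness flows from
#' `config$seed`; identical configurations produce identical bundles.
#'
#' Two preprocessing routes are available: the default epoch-level route
#' (template + 1/f noise epochs, baseline correction, peak-to-peak
#' rejection) and, with `preprocess$use_continuous = TRUE`, the full
#' continuous route (blink-laden raw recordings through filtering, average
#' reference, ICA blink removal, epoching).
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Object of class `result_bundle`: per-experiment results plus a
#'   provenance block (package version, seed, config hash).
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- run_config(unclass(config))
  experiments <- if (cfg$experiment == "both") c("forward", "backward") else
    cfg$experiment
  exp_seeds <- child_seeds(cfg$seed, 2L)
  results <- lapply(experiments, function(exp) {
    k <- match(exp, c("forward", "backward"))
    run_one_experiment(cfg, exp, child_seeds(exp_seeds[k], 4L))
  })
  names(results) <- experiments
  structure(
    list(
      experiments = results,
      provenance = list(
        package_version = as.character(packageVersion("primingEEG")),
        seed = cfg$seed, config_hash = config_hash(unclass(cfg)),
        config = unclass(cfg)
      )
    ),
    class = "result_bundle"
  )
}

run_one_experiment <- function(cfg, experiment, seeds) {
  params <- do.call(sim_params, c(list(experiment = experiment),
                                  cfg$simulate))
  cohort <- simulate_cohort(cfg$n_participants, experiment, params,
                            seed = seeds[1L])

  # --- behaviour ---------------------------------------------------------
  valid <- filter_valid(cohort$log)
  contrasts <- rt_contrast(valid)
  tests <- paired_tests(contrasts$difference, sided = cfg$behaviour$sided)

  # --- EEG ---------------------------------------------------------------
  ep_seeds <- child_seeds(seeds[2L], cfg$n_participants)
  pp <- cfg$preprocess
  epoch_list <- lapply(seq_len(cfg$n_participants), function(i) {
    if (isTRUE(pp$use_continuous)) {
      raw <- simulate_eeg(cohort$schedules[[i]], params, seed = ep_seeds[i])
      preprocess_raw(raw, pp$filter_low, pp$filter_high, pp$ica_threshold,
                     ica_seed = ep_seeds[i], tmin = pp$tmin, tmax = pp$tmax,
                     baseline = pp$baseline,
                     reject_budget_uv = pp$reject_budget_uv)
    } else {
      ep <- simulate_participant_epochs(cohort$schedules[[i]], params,
                                        seed = ep_seeds[i])
      ep <- baseline_correct(ep, pp$baseline)
      reject_peak_to_peak(ep, pp$reject_budget_uv)
    }
  })
  erps <- participant_erps(epoch_list)
  running <- running_ttest(erps, alpha = cfg$erp$alpha)
  selection <- select_longest_window(running)
  topo <- if (!selection$empty) {
    summarize_window(running, selection, method = cfg$erp$summary)
  }
  amplitudes <- lapply(params$effect_spec, function(ef) {
    windowed_amplitude(erps, ef$electrode, ef$window_ms)
  })

  # --- classifier --------------------------------------------------------
  decoding <- NULL
  if (isTRUE(cfg$classify$enabled)) {
    cl_seeds <- child_seeds(seeds[3L], cfg$n_participants)
    decoding <- lapply(seq_len(cfg$n_participants), function(i) {
      classify_participant(
        epoch_list[[i]], seed = cl_seeds[i],
        search = isTRUE(cfg$classify$search),
        n_draws = cfg$classify$n_draws,
        cv_seeds = cfg$classify$cv_seeds,
        train_epochs = cfg$classify$epochs,
        participant = i, experiment = experiment
      )
    })
  }

  # --- questionnaires ----------------------------------------------------
  scores <- simulate_questionnaires(
    cfg$n_participants, cfg$questionnaires$latent_coupling,
    seed = seeds[4L], participant_effects = cohort$effects
  )
  scores_used <- scores[scores$participant %in% contrasts$participant, ]
  correlations <- correlate_questionnaires(
    scores_used, contrasts$difference, "rt_difference"
  )

  list(
    experiment = experiment,
    behaviour = list(contrasts = contrasts, tests = tests,
                     exclusions = attr(valid, "exclusions")),
    erp = list(erps = erps, running = running, selection = selection,
               topo_summary = topo, windowed_amplitudes = amplitudes),
    decoding = decoding,
    questionnaires = list(scores = scores, correlations = correlations),
    n_participants = cfg$n_participants
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> seed %s, config %s\n",
              x$provenance$seed, x$provenance$config_hash))
  for (res in x$experiments) {
    t <- res$behaviour$tests
    sel <- res$erp$selection
    cat(sprintf(
      "  %s: n=%d | RT diff %+.1f ms (W p=%.3g) | window: %s\n",
      res$experiment, res$n_participants,
      mean(res$behaviour$contrasts$difference), t$wilcoxon_p,
      if (sel$empty) "none" else sprintf("%s %.0f-%.0f ms", sel$electrode,
                                         sel$window_ms[1L], sel$window_ms[2L])
    ))
  }
  invisible(x)
}

#' Write the machine-readable report of a result bundle
#'
#' Serializes the numeric results (contrasts, test statistics, window
#' selection, topographic summary, windowed amplitudes, decoding
#' accuracies, correlations, exclusion counts and the provenance block) as
#' JSON.  Identical bundles serialize byte-identically.
#'
#' @param bundle A [run_pipeline()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(bundle, path) {
  report <- list(provenance = bundle$provenance[c("package_version", "seed",
                                                  "config_hash")])
  report$experiments <- lapply(bundle$experiments, function(res) {
    sel <- res$erp$selection
    list(
      experiment = res$experiment,
      behaviour = list(
        contrasts = res$behaviour$contrasts,
        tests = unclass(res$behaviour$tests),
        exclusions = as.list(res$behaviour$exclusions)
      ),
      erp = list(
        selection = sel[c("electrode", "window_ms", "length_ms", "min_p",
                          "min_p_time_ms", "empty")],
        topo_summary = if (!is.null(res$erp$topo_summary)) {
          as.list(unclass_keep(res$erp$topo_summary))
        },
        windowed_amplitudes = lapply(res$erp$windowed_amplitudes, function(a) {
          list(mean = attr(a, "mean"), sd = attr(a, "sd"),
               per_participant = a$amplitude_uv)
        })
      ),
      decoding = if (!is.null(res$decoding)) {
        lapply(res$decoding, function(r) {
          list(participant = r$participant,
               accuracies = as.vector(r$accuracies),
               summary_mean = r$summary_mean,
               summary_median = r$summary_median)
        })
      },
      correlations = res$questionnaires$correlations
    )
  })
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

unclass_keep <- function(x) {
  attributes(x) <- attributes(x)["names"]
  x
}
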