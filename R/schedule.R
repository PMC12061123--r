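#' Build a trial schedule for one priming experiment
#'
#' Constructs the ordered trial list of a forward- or backward-priming
#' session.  A session of `n_trials` trials is split into \code{floor(n/36)}
#' blocks of 36 plus one remainder block (400 trials gives 11 blocks of 36
#' and one block of 4).  Target valences are exactly balanced (half positive,
#' half negative, order permuted by the seed); prime valences are independent
#' fair coin flips, so on average half of the trials are congruent.  A trial
#' is congruent when prime and target share valence.
#'
#' Forward trials run fixation (1200 ms), prime (500 ms), inter-stimulus
#' interval (300 ms), target (up to 2000 ms, terminated by the response),
#' blank (1000 ms).  Backward trials swap prime and target: the prime is
#' only shown after the response to the target, which is the defining
#' property of the backward (retroactive) paradigm.  The nominal onset of
#' each event relative to trial start is stored per trial; the target
#' presentation duration is response-dependent and therefore resolved at
#' simulation time.
#'
#' Schedules regenerate bit-identically from the same seed, and forward and
#' backward schedules built from the same seed carry identical valence
#' sequences (they differ only in event ordering).
#'
#' @param experiment `"forward"` or `"backward"`.
#' @param n_trials Even positive number of trials (default 400).
#' @param seed Integer seed controlling valence draws.
#' @return An object of class `trial_schedule`: a list with `trials` (a
#'   data frame with `index`, `block`, `prime_valence`, `target_valence`,
#'   `congruent`, and nominal event-onset columns in ms), `experiment`,
#'   `n_trials`, `seed`, and `timing` (the fixed event durations in ms).
#' @examples
#' sch <- make_schedule("forward", 400, seed = 1)
#' table(sch$trials$block)
#' mean(sch$trials$congruent)
#' @export
make_schedule <- function(experiment = c("forward", "backward"),
                          n_trials = 400, seed = 1L) {
  experiment <- match.arg(experiment)
  stopifnot(is.numeric(n_trials), length(n_trials) == 1L, n_trials > 0)
  n_trials <- as.integer(n_trials)
  if (n_trials %% 2L != 0L) {
    stop("n_trials must be even: target valences are exactly balanced")
  }

  n_full <- n_trials %/% 36L
  sizes <- c(rep(36L, n_full), if (n_trials %% 36L) n_trials %% 36L)
  block <- rep(seq_along(sizes), times = sizes)

  valences <- c("pos", "neg")
  drawn <- with_seed(seed, {
    target <- sample(rep(valences, each = n_trials %/% 2L))
    prime <- valences[rbinom(n_trials, 1L, 0.5) + 1L]
    list(target = target, prime = prime)
  })

  timing <- list(
    fixation_ms = 1200, prime_ms = 500, isi_ms = 300,
    target_max_ms = 2000, blank_ms = 1000
  )
  # Nominal onsets relative to trial start; events after the response-limited
  # target presentation are nominal at the maximal target duration.
  if (experiment == "forward") {
    onsets <- c(fixation_on = 0, prime_on = 1200, isi_on = 1700,
                target_on = 2000, blank_on = 4000)
  } else {
    onsets <- c(fixation_on = 0, target_on = 1200, isi_on = 3200,
                prime_on = 3500, blank_on = 4000)
  }

  trials <- data.frame(
    index = seq_len(n_trials),
    block = block,
    prime_valence = drawn$prime,
    target_valence = drawn$target,
    congruent = drawn$prime == drawn$target,
    stringsAsFactors = FALSE
  )
  for (nm in names(onsets)) trials[[nm]] <- onsets[[nm]]

  structure(
    list(trials = trials, experiment = experiment, n_trials = n_trials,
         seed = as.integer(seed), timing = timing),
    class = "trial_schedule"
  )
}

#' @export
print.trial_schedule <- function(x, ...) {
  sizes <- as.integer(table(x$trials$block))
  cat(sprintf(
    "<trial_schedule> %s priming, %d trials in %d blocks (%s), seed %d\n",
    x$experiment, x$n_trials, length(sizes),
    paste(sizes, collapse = "/"), x$seed
  ))
  cat(sprintf("  congruent: %d (%.1f%%)\n", sum(x$trials$congruent),
              100 * mean(x$trials$congruent)))
  invisible(x)
}
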