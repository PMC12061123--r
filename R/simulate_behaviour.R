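#' Simulate the behavioural log of one participant
#'
#' Draws per-trial reaction times and valence responses for a schedule.
#' Reaction times follow a shifted lognormal whose median is
#' `rt_base - rt_delta/2` on congruent and `rt_base + rt_delta/2` on
#' incongruent trials; with `rt_sigma = 0` the reaction times are exactly
#' those medians.  Responses are wrong with probability `error_rate`
#' (independent of condition), and trials whose drawn reaction time exceeds
#' the 2000 ms response deadline are flagged as timeouts with no recorded
#' response.
#'
#' @param schedule A [make_schedule()] object.
#' @param params A [sim_params()] object (uses the `rt_*` and `error_rate`
#'   fields).
#' @param seed Integer seed.
#' @return Data frame with one row per trial: `trial`, `block`,
#'   `experiment`, `prime_valence`, `target_valence`, `congruent`, `rt_ms`,
#'   `response`, `correct`, `timeout`.
#' @examples
#' log <- simulate_rt(make_schedule("forward", 40), sim_params(), seed = 2)
#' head(log)
#' @export
simulate_rt <- function(schedule, params = sim_params(), seed = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (params$rt_sigma < 0) stop("rt_sigma must be non-negative")
  stopifnot(params$rt_base > 0)
  tr <- schedule$trials
  n <- nrow(tr)
  cond <- ifelse(tr$congruent, -params$rt_delta / 2, +params$rt_delta / 2)
  out <- with_seed(seed, {
    noise <- rlnorm(n, meanlog = log(params$rt_shift), sdlog = params$rt_sigma)
    rt <- params$rt_base - params$rt_shift + cond + noise
    wrong <- runif(n) < params$error_rate
    list(rt = rt, wrong = wrong)
  })
  flip <- c(pos = "neg", neg = "pos")
  response <- ifelse(out$wrong, flip[tr$target_valence], tr$target_valence)
  timeout <- out$rt > 2000
  response[timeout] <- NA_character_
  data.frame(
    trial = tr$index, block = tr$block, experiment = schedule$experiment,
    prime_valence = tr$prime_valence, target_valence = tr$target_valence,
    congruent = tr$congruent, rt_ms = out$rt, response = response,
    correct = !is.na(response) & response == tr$target_valence,
    timeout = timeout, stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of participants
#'
#' Generates one schedule and behavioural log per participant.  Each
#' participant's congruency effect is drawn as
#' `rt_delta + rt_delta_sd * e_i` with standardized effects
#' `e_i ~ N(0, 1)`; the `e_i` are returned so that questionnaire scores can
#' be coupled to the realized behavioural effect (see
#' [simulate_questionnaires()]).
#'
#' @param n_participants Cohort size.
#' @param experiment `"forward"` or `"backward"`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed; all participant-level seeds derive from it.
#' @return List with `log` (row-bound behavioural logs with a `participant`
#'   column), `schedules` (list), `effects` (standardized per-participant
#'   effect deviations), `deltas` (realized congruency shifts in ms) and
#'   `seeds`.
#' @export
simulate_cohort <- function(n_participants = 31, experiment = "forward",
                            params = sim_params(), seed = 1L) {
  stopifnot(n_participants >= 1)
  seeds <- child_seeds(seed, 2L * n_participants)
  effects <- with_seed(seeds[1L], rnorm(n_participants))
  deltas <- params$rt_delta + params$rt_delta_sd * effects
  schedules <- vector("list", n_participants)
  logs <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    s_sched <- seeds[2L * i - 1L]
    s_rt <- seeds[2L * i]
    schedules[[i]] <- make_schedule(experiment, seed = s_sched)
    p_i <- params
    p_i$rt_delta <- deltas[i]
    logs[[i]] <- cbind(participant = i,
                       simulate_rt(schedules[[i]], p_i, seed = s_rt))
  }
  list(log = do.call(rbind, logs), schedules = schedules,
       effects = effects, deltas = deltas, seeds = seeds)
}

#' Simulate questionnaire scores
#'
#' Draws, per participant, mindfulness (FMI-14: presence and acceptance
#' subscales of 7 four-point items each, plus their sum), impulsivity
#' (BIS-11: 30 four-point items, sum in 30--120) and exceptional-experience
#' scores (PExE-II: four factors of five 5-level Likert items each).
#'
#' A latent trait can couple the FMI sum to the participants' realized
#' behavioural congruency effects: with `latent_coupling = rho` and
#' `participant_effects` set to the standardized effects returned by
#' [simulate_cohort()], the population correlation between `fmi_sum` and the
#' per-participant reaction-time difference equals `rho`.  The two FMI
#' subscales are built as orthogonal mixtures of the latent trait so their
#' sum carries the full coupling without ordinal attenuation.
#'
#' @param n Number of participants.
#' @param latent_coupling Correlation in `[-1, 1]` between the FMI sum and
#'   the behavioural effect.
#' @param seed Integer seed.
#' @param participant_effects Optional standardized effect deviations
#'   (length `n`); drawn internally when `NULL`.
#' @return Data frame with `participant`, `fmi_presence`, `fmi_accept`,
#'   `fmi_sum`, `bis_sum` and `pexe_f1` .. `pexe_f4`.
#' @export
simulate_questionnaires <- function(n, latent_coupling = 0, seed = 1L,
                                    participant_effects = NULL) {
  stopifnot(n >= 1)
  if (abs(latent_coupling) > 1) stop("|latent_coupling| must not exceed 1")
  with_seed(seed, {
    e <- participant_effects %||% rnorm(n)
    stopifnot(length(e) == n)
    latent <- latent_coupling * e + sqrt(1 - latent_coupling^2) * rnorm(n)
    eta <- rnorm(n)
    # presence + accept is proportional to the latent trait by construction
    presence <- clamp_int(17.5 + 3 * (latent + eta) / sqrt(2), 7L, 28L)
    accept <- clamp_int(17.5 + 3 * (latent - eta) / sqrt(2), 7L, 28L)
    bis <- ordinal_sum(n, n_items = 30L, levels = 4L)
    pexe <- replicate(4L, ordinal_sum(n, n_items = 5L, levels = 5L))
    data.frame(
      participant = seq_len(n),
      fmi_presence = presence, fmi_accept = accept,
      fmi_sum = presence + accept,
      bis_sum = bis,
      pexe_f1 = pexe[, 1L], pexe_f2 = pexe[, 2L],
      pexe_f3 = pexe[, 3L], pexe_f4 = pexe[, 4L]
    )
  })
}

clamp_int <- function(x, lo, hi) pmin(pmax(as.integer(round(x)), lo), hi)

# Sum of n_items ordinal items (1..levels) with a person-level trait giving
# realistic within-scale consistency.
ordinal_sum <- function(n, n_items, levels) {
  trait <- rnorm(n)
  items <- matrix(rnorm(n * n_items), n, n_items) * sqrt(0.5) +
    trait * sqrt(0.5)
  cuts <- stats::qnorm(seq_len(levels - 1L) / levels)
  scored <- matrix(findInterval(items, cuts) + 1L, n, n_items)
  as.integer(rowSums(scored))
}
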