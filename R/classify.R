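#' Extract the decoding tensor from an epoch set
#'
#' Slices the trials x channels x time window used for single-trial
#' decoding (default 400--700 ms after target onset, half-open at the
#' upper edge: `[0.400, 0.700)` in sample terms, giving 300 samples at
#' 1000 Hz and 75 at 250 Hz) and attaches numeric labels (1 = congruent,
#' 0 = incongruent).
#'
#' @param epochs An [epoch_set()].
#' @param window `c(start, end)` in seconds, half-open.
#' @return List with `x` (array trials x channels x samples) and `y`
#'   (numeric labels).
#' @export
extract_decoding_tensor <- function(epochs, window = c(0.400, 0.700)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (window[1L] < min(epochs$times) - 1e-9 ||
      window[2L] > max(epochs$times) + 1 / epochs$sfreq + 1e-9) {
    stop("decoding window lies outside the epoch span")
  }
  sel <- which(epochs$times >= window[1L] - 1e-9 &
                 epochs$times < window[2L] - 1e-9)
  if (!length(sel)) stop("decoding window contains no samples at this rate")
  list(
    x = epochs$data[, , sel, drop = FALSE],
    y = as.numeric(epochs$labels == "congruent")
  )
}

#' Balance classes by seeded subsampling
#'
#' Randomly subsamples the majority class down to the minority count so
#' that congruent and incongruent trials enter training and evaluation in
#' equal numbers.
#'
#' @param y Numeric or logical labels (1/TRUE = congruent).
#' @param seed Integer seed for the subsample.
#' @return Sorted integer indices of retained trials (equal class counts).
#' @export
balance_classes <- function(y, seed = 1L) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (!length(pos) || !length(neg)) {
    stop("both classes must be present to balance")
  }
  m <- min(length(pos), length(neg))
  with_seed(seed, {
    sort(c(sample(pos, m), sample(neg, m)))
  })
}

# Per-class fold assignment: shuffle each class, drop the remainder beyond
# a multiple of n_folds (logged via attribute), deal consecutive chunks to
# folds so every fold is exactly 50/50.
make_cv_folds <- function(y, n_folds = 4L, seed = 1L) {
  with_seed(seed, {
    fold <- rep(NA_integer_, length(y))
    dropped <- integer()
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      m <- (length(idx) %/% n_folds) * n_folds
      if (m < n_folds) stop("fewer than ", n_folds, " trials in a class")
      dropped <- c(dropped, idx[seq_len(length(idx) - m) + m])
      keep <- idx[seq_len(m)]
      fold[keep] <- rep(seq_len(n_folds), each = m %/% n_folds)
    }
    attr(fold, "dropped") <- sort(dropped)
    fold
  })
}

# Standardize per channel with training-fold statistics only.
channel_standardize <- function(x, stats = NULL) {
  d <- dim(x)
  if (is.null(stats)) {
    m <- apply(x, 2L, mean)
    s <- apply(x, 2L, stats::sd)
    s[s == 0] <- 1
    stats <- list(mean = m, sd = s)
  }
  ctr <- aperm(array(stats$mean, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  scl <- aperm(array(stats$sd, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  list(x = (x - ctr) / scl, stats = stats)
}

#' Cross-validated training and evaluation of the decoding network
#'
#' The per-participant decoding protocol: balanced trials are split into 4
#' folds (each fold 50% congruent / 50% incongruent by construction); for
#' each fold a fresh network is trained on the remaining 75% and evaluated
#' on the held-out 25% (prediction threshold 0.5).  The whole procedure
#' runs once per cross-validation seed (default three seeds), so the
#' report carries exactly `n_folds * length(cv_seeds)` = 12 accuracies.
#' Per seed the four fold accuracies are averaged; the final summary is
#' the mean of all twelve, with the median reported alongside.
#'
#' Channel standardization uses training-fold statistics only, so no
#' held-out trial influences the model that scores it.
#'
#' @param x Array trials x channels x time (balanced classes).
#' @param y Numeric labels (1 = congruent), equal class counts.
#' @param spec A [net_spec()].
#' @param cv_seeds Integer seeds; each controls fold assignment, weight
#'   initialization, shuffling and dropout of one repetition.
#' @param n_folds Number of folds (4 in the protocol).
#' @param epochs Optional override of `spec$epochs`.
#' @param participant,experiment Identifiers carried into the report.
#' @return Object of class `accuracy_report`: `accuracies` (folds x seeds
#'   matrix), `summary_mean`, `summary_median`, `per_seed_mean`, `spec`,
#'   `cv_seeds`, `n_dropped`, `participant`, `experiment`.
#' @export
train_eval_cv <- function(x, y, spec = net_spec(),
                          cv_seeds = c(101L, 102L, 103L), n_folds = 4L,
                          epochs = NULL, participant = NA, experiment = NA) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1L] == length(y))
  if (sum(y == 1) < n_folds || sum(y == 0) < n_folds) {
    stop("need at least ", n_folds, " trials per class")
  }
  acc <- matrix(NA_real_, n_folds, length(cv_seeds))
  n_dropped <- 0L
  for (s in seq_along(cv_seeds)) {
    seed <- cv_seeds[s]
    fold <- make_cv_folds(y, n_folds, seed)
    n_dropped <- max(n_dropped, length(attr(fold, "dropped")))
    sub_seeds <- child_seeds(seed, 2L * n_folds)
    for (f in seq_len(n_folds)) {
      tr <- which(!is.na(fold) & fold != f)
      te <- which(!is.na(fold) & fold == f)
      std <- channel_standardize(x[tr, , , drop = FALSE])
      xte <- channel_standardize(x[te, , , drop = FALSE], std$stats)$x
      net <- build_net(spec, dim(x)[2L], dim(x)[3L],
                       seed = sub_seeds[2L * f - 1L])
      net <- train_net(net, std$x, y[tr], seed = sub_seeds[2L * f],
                       epochs = epochs)
      pred <- predict_net(net, xte) > 0.5
      acc[f, s] <- mean(pred == (y[te] == 1))
    }
  }
  structure(
    list(
      accuracies = acc, summary_mean = mean(acc),
      summary_median = median(acc), per_seed_mean = colMeans(acc),
      spec = spec, cv_seeds = cv_seeds, n_folds = n_folds,
      n_dropped = n_dropped, participant = participant,
      experiment = experiment
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> participant %s (%s): %d accuracies, mean %.3f, median %.3f\n",
    as.character(x$participant), as.character(x$experiment),
    length(x$accuracies), x$summary_mean, x$summary_median
  ))
  invisible(x)
}

#' Random hyperparameter search
#'
#' Draws `n_draws` specifications uniformly (seeded) from the
#' cross-product search space (activation x filters x optimizer x learning
#' rate x loss), evaluates each with the full cross-validation protocol,
#' and returns the specification with the best summary accuracy along with
#' the complete leaderboard.
#'
#' @param x,y Balanced decoding tensor and labels.
#' @param n_draws Number of random draws (10 in the protocol).
#' @param seed Seed of the draw sequence.
#' @param cv_seeds,n_folds,epochs Passed to [train_eval_cv()].
#' @return List with `best_spec`, `best_report`, and `leaderboard` (one
#'   row per draw, sorted by summary accuracy, original draw order in
#'   `draw`).
#' @export
random_search <- function(x, y, n_draws = 10L, seed = 1L,
                          cv_seeds = c(101L, 102L, 103L), n_folds = 4L,
                          epochs = NULL) {
  if (n_draws < 1L) stop("n_draws must be at least 1")
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      list(activation = sample(NET_ACTIVATIONS, 1L),
           n_filters = sample(NET_FILTERS, 1L),
           optimizer = sample(NET_OPTIMIZERS, 1L),
           learning_rate = sample(NET_LEARNING_RATES, 1L),
           loss = sample(NET_LOSSES, 1L))
    })
  })
  reports <- vector("list", n_draws)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    spec <- suppressMessages(do.call(net_spec, draws[[i]]))
    reports[[i]] <- train_eval_cv(x, y, spec, cv_seeds, n_folds, epochs)
    rows[[i]] <- data.frame(
      draw = i, activation = spec$activation, n_filters = spec$n_filters,
      optimizer = spec$optimizer, learning_rate = spec$learning_rate,
      loss = spec$loss, summary_mean = reports[[i]]$summary_mean,
      summary_median = reports[[i]]$summary_median,
      stringsAsFactors = FALSE
    )
  }
  leaderboard <- do.call(rbind, rows)
  leaderboard <- leaderboard[order(-leaderboard$summary_mean,
                                   leaderboard$draw), ]
  rownames(leaderboard) <- NULL
  best <- leaderboard$draw[1L]
  list(best_spec = reports[[best]]$spec, best_report = reports[[best]],
       leaderboard = leaderboard)
}

#' Decode one participant end to end
#'
#' Balances classes, extracts the 400--700 ms decoding window and runs the
#' cross-validation protocol (optionally preceded by the random
#' hyperparameter search).
#'
#' @param epochs An [epoch_set()] for one participant.
#' @param spec A [net_spec()]; ignored when `search = TRUE`.
#' @param seed Seed for balancing (and the search draws).
#' @param search Run [random_search()] first?
#' @param n_draws,cv_seeds,train_epochs Protocol controls.
#' @param window Decoding window, seconds.
#' @param participant,experiment Identifiers for the report.
#' @return An `accuracy_report` (with the leaderboard attached as
#'   attribute `"search"` when `search = TRUE`).
#' @export
classify_participant <- function(epochs, spec = net_spec(), seed = 1L,
                                 search = FALSE, n_draws = 10L,
                                 cv_seeds = c(101L, 102L, 103L),
                                 train_epochs = NULL,
                                 window = c(0.400, 0.700),
                                 participant = NA, experiment = NA) {
  tens <- extract_decoding_tensor(epochs, window)
  keep <- balance_classes(tens$y, seed)
  x <- tens$x[keep, , , drop = FALSE]
  y <- tens$y[keep]
  if (search) {
    rs <- random_search(x, y, n_draws, seed, cv_seeds, epochs = train_epochs)
    rep <- rs$best_report
    rep$participant <- participant
    rep$experiment <- experiment
    attr(rep, "search") <- rs$leaderboard
    rep
  } else {
    train_eval_cv(x, y, spec, cv_seeds, epochs = train_epochs,
                  participant = participant, experiment = experiment)
  }
}
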