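#' Per-participant and grand-mean event-related potentials
#'
#' Averages each participant's epochs per condition (congruent /
#' incongruent), then across participants to grand means with standard
#' errors, and forms difference traces (congruent minus incongruent) per
#' participant and on the grand mean.  Participants missing a condition are
#' excluded and logged.
#'
#' @param epoch_list List of [epoch_set()] objects, one per participant,
#'   on identical time/channel grids.
#' @return Object of class `erp_set`: arrays `cond_mean_congruent` and
#'   `cond_mean_incongruent` (participants x channels x time), `diff`
#'   (their difference), grand means and SEMs per condition and for the
#'   difference, `times`, `channel_names`, `n`, and `excluded`.
#' @export
participant_erps <- function(epoch_list) {
  stopifnot(length(epoch_list) >= 1L)
  ref <- epoch_list[[1L]]
  usable <- vapply(epoch_list, function(ep) {
    all(c("congruent", "incongruent") %in% ep$labels)
  }, logical(1L))
  excluded <- which(!usable)
  eps <- epoch_list[usable]
  n <- length(eps)
  if (!n) stop("no participant has both conditions")
  nc <- length(ref$channel_names)
  nt <- length(ref$times)
  cong <- array(0, c(n, nc, nt))
  incg <- array(0, c(n, nc, nt))
  for (i in seq_len(n)) {
    ep <- eps[[i]]
    stopifnot(length(ep$times) == nt, length(ep$channel_names) == nc)
    cong[i, , ] <- cond_mean(ep, "congruent")
    incg[i, , ] <- cond_mean(ep, "incongruent")
  }
  diffs <- cong - incg
  sem <- function(a) {
    if (n > 1L) sqrt(apply(a, c(2L, 3L), stats::var) / n) else
      array(NA_real_, c(nc, nt))
  }
  structure(
    list(
      cond_mean_congruent = cong, cond_mean_incongruent = incg,
      diff = diffs,
      grand_congruent = colMeans(cong), grand_incongruent = colMeans(incg),
      grand_diff = colMeans(diffs),
      sem_congruent = sem(cong), sem_incongruent = sem(incg),
      sem_diff = sem(diffs),
      times = ref$times, channel_names = ref$channel_names,
      n = n, excluded = excluded
    ),
    class = "erp_set"
  )
}

cond_mean <- function(ep, label) {
  sel <- ep$labels == label
  colMeans(ep$data[sel, , , drop = FALSE])
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf(
    "<erp_set> %d participants, %d channels, %d timepoints (%.0f..%.0f ms)\n",
    x$n, length(x$channel_names), length(x$times),
    1000 * min(x$times), 1000 * max(x$times)
  ))
  invisible(x)
}

#' Running paired t-test over electrodes and timepoints
#'
#' At every (channel, timepoint) cell, tests the per-participant condition
#' difference against zero with a paired t test (two-sided, as no direction
#' is assumed for the ERP contrast) and computes the pointwise Cohen's d.
#' No multiple-testing correction is applied -- the procedure is an
#' exploratory device for locating spatio-temporal regions of interest,
#' and the `corrected = FALSE` flag is carried in the result.  Cells with
#' zero variance across participants yield `NA` (or t = 0, p = 1 when all
#' differences are exactly zero).
#'
#' @param erps An [participant_erps()] object (n >= 3).
#' @param alpha Significance level carried into window selection.
#' @return Object of class `running_test` with matrices `t`, `p`, `d`
#'   (channels x time), plus `alpha`, `n`, `times`, `channel_names`,
#'   `corrected`.
#' @export
running_ttest <- function(erps, alpha = 0.05) {
  stopifnot(inherits(erps, "erp_set"))
  n <- erps$n
  if (n < 3L) stop("running t-test needs at least 3 participants")
  d <- erps$diff
  m <- colMeans(d)
  ss <- colSums(d^2) - n * m^2
  s <- sqrt(pmax(ss, 0) / (n - 1))
  tmat <- m / (s / sqrt(n))
  pmat <- 2 * pt(-abs(tmat), df = n - 1)
  dmat <- m / s
  zero_all <- s == 0 & m == 0
  tmat[zero_all] <- 0
  pmat[zero_all] <- 1
  dmat[zero_all] <- 0
  undef <- s == 0 & m != 0
  tmat[undef] <- NA_real_
  pmat[undef] <- NA_real_
  dmat[undef] <- NA_real_
  dimnames(tmat) <- dimnames(pmat) <- dimnames(dmat) <-
    list(erps$channel_names, NULL)
  structure(
    list(t = tmat, p = pmat, d = dmat, alpha = alpha, n = n,
         times = erps$times, channel_names = erps$channel_names,
         corrected = FALSE),
    class = "running_test"
  )
}

#' Select the longest sub-alpha window across all electrodes
#'
#' Finds, over every electrode, the longest contiguous run of timepoints
#' with p below `alpha`; run length is measured in milliseconds so the
#' selection is sampling-rate invariant.  Undefined p-values break runs.
#' Ties are resolved by earlier window onset, then montage order, and the
#' applied tie-break is recorded.  If no cell is below alpha the selection
#' is empty (no error).
#'
#' @param result A [running_ttest()] object.
#' @param alpha Threshold (defaults to the one stored in `result`).
#' @return Object of class `window_selection`: `electrode`, `window_ms`
#'   `(start, end)`, `length_ms`, `min_p`, `min_p_time_ms`, `empty`,
#'   `tie_break`, and `per_electrode` (longest run per electrode, for
#'   side-by-side reporting).
#' @export
select_longest_window <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "running_test"))
  times_ms <- result$times * 1000
  dt_ms <- 1000 / diff_sfreq(result$times)
  per <- lapply(seq_along(result$channel_names), function(ch) {
    below <- result$p[ch, ] < alpha
    below[is.na(below)] <- FALSE
    r <- rle(below)
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    lens <- r$lengths[runs]
    best <- runs[order(-lens, starts[runs])][1L]
    i1 <- starts[best]
    i2 <- ends[best]
    data.frame(
      electrode = result$channel_names[ch], start_ms = times_ms[i1],
      end_ms = times_ms[i2],
      length_ms = (i2 - i1 + 1L) * dt_ms,
      stringsAsFactors = FALSE
    )
  })
  per_tab <- do.call(rbind, per)
  if (is.null(per_tab)) {
    return(structure(
      list(electrode = NA_character_, window_ms = c(NA_real_, NA_real_),
           length_ms = 0, min_p = NA_real_, min_p_time_ms = NA_real_,
           empty = TRUE, tie_break = NA_character_, per_electrode = NULL,
           alpha = alpha),
      class = "window_selection"
    ))
  }
  ord <- order(-per_tab$length_ms, per_tab$start_ms,
               match(per_tab$electrode, result$channel_names))
  top <- per_tab[ord[1L], ]
  ties <- sum(per_tab$length_ms == top$length_ms)
  tie_break <- if (ties > 1L) "earlier onset, then montage order" else "none"
  ch <- match(top$electrode, result$channel_names)
  sel <- which(times_ms >= top$start_ms - 1e-9 & times_ms <= top$end_ms + 1e-9)
  pin <- result$p[ch, sel]
  imin <- sel[which.min(pin)]
  structure(
    list(electrode = top$electrode,
         window_ms = c(top$start_ms, top$end_ms),
         length_ms = top$length_ms,
         min_p = result$p[ch, imin], min_p_time_ms = times_ms[imin],
         empty = FALSE, tie_break = tie_break, per_electrode = per_tab,
         alpha = alpha),
    class = "window_selection"
  )
}

diff_sfreq <- function(times) {
  1 / stats::median(diff(times))
}

#' @export
print.window_selection <- function(x, ...) {
  if (x$empty) {
    cat("<window_selection> empty (no sub-alpha timepoint)\n")
  } else {
    cat(sprintf(
      "<window_selection> %s, %.0f-%.0f ms (%.0f ms), min p = %.3g at %.0f ms\n",
      x$electrode, x$window_ms[1L], x$window_ms[2L], x$length_ms,
      x$min_p, x$min_p_time_ms
    ))
  }
  invisible(x)
}

#' Topographic p summary around the minimum-p timepoint
#'
#' Locates the minimum p-value time within the selected window (on the
#' selected electrode) and summarizes, for every electrode, the p-values
#' from 10 ms before to 10 ms after that time with their median (the mean
#' is available as an option), capping the result at 0.05.  These are the
#' per-electrode values behind a capped topographic significance map; the
#' spatial rendering itself is out of scope.
#'
#' @param result A [running_ttest()] object.
#' @param selection A non-empty [select_longest_window()] selection.
#' @param method `"median"` or `"mean"`.
#' @param half_width_ms Neighbourhood half-width, ms.
#' @param cap Upper cap applied to the summaries.
#' @return Named numeric vector (one value per electrode, all `<= cap`),
#'   with attributes `method`, `t_star_ms` and `clipped` (whether the
#'   neighbourhood had to be clipped to the epoch span).
#' @export
summarize_window <- function(result, selection, method = c("median", "mean"),
                             half_width_ms = 10, cap = 0.05) {
  stopifnot(inherits(result, "running_test"),
            inherits(selection, "window_selection"))
  if (selection$empty) stop("cannot summarize an empty window selection")
  method <- match.arg(method)
  times_ms <- result$times * 1000
  t_star <- selection$min_p_time_ms
  sel <- which(times_ms >= t_star - half_width_ms - 1e-9 &
                 times_ms <= t_star + half_width_ms + 1e-9)
  clipped <- (t_star - half_width_ms < min(times_ms) - 1e-9) ||
    (t_star + half_width_ms > max(times_ms) + 1e-9)
  fun <- if (method == "median") median else mean
  vals <- apply(result$p[, sel, drop = FALSE], 1L,
                function(p) fun(p, na.rm = TRUE))
  out <- pmin(vals, cap)
  names(out) <- result$channel_names
  attr(out, "method") <- method
  attr(out, "t_star_ms") <- t_star
  attr(out, "clipped") <- clipped
  out
}

#' Windowed difference-trace amplitude per participant
#'
#' Averages each participant's difference trace (congruent minus
#' incongruent) at one electrode over a time window (inclusive bounds on
#' the sampling grid, the same convention used when injecting synthetic
#' effects), and reports the cohort mean and standard deviation.
#'
#' @param erps An [participant_erps()] object.
#' @param electrode Electrode label.
#' @param window_ms `c(start, end)` in ms after target onset.
#' @return Data frame `participant`, `amplitude_uv`, with attributes
#'   `mean` and `sd`.
#' @export
windowed_amplitude <- function(erps, electrode, window_ms) {
  stopifnot(inherits(erps, "erp_set"))
  ch <- match(electrode, erps$channel_names)
  if (is.na(ch)) stop("unknown electrode label: ", electrode)
  if (window_ms[1L] < min(erps$times) * 1000 - 1e-9 ||
      window_ms[2L] > max(erps$times) * 1000 + 1e-9) {
    stop("window lies outside the epoch span")
  }
  sel <- window_sample_idx(erps$times, window_ms)
  amp <- rowMeans(erps$diff[, ch, sel, drop = FALSE], dims = 1L)
  out <- data.frame(participant = seq_len(erps$n), amplitude_uv = amp)
  attr(out, "mean") <- mean(amp)
  attr(out, "sd") <- sd(amp)
  out
}
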