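#' Write a recording in BrainVision format
#'
#' Writes the header (`.vhdr`), marker (`.vmrk`) and binary data (`.eeg`)
#' triplet.  Data are stored as IEEE float32, multiplexed (all channels per
#' sample), resolution 1 uV.  Events become standard `Stimulus` markers
#' with descriptions `S  1` (congruent) and `S  2` (incongruent), in
#' temporal order.
#'
#' @param raw A [raw_recording()].
#' @param basepath Path without extension; the three files are written as
#'   `basepath.vhdr/.vmrk/.eeg`.
#' @return `basepath`, invisibly.
#' @export
write_brainvision <- function(raw, basepath) {
  stopifnot(inherits(raw, "raw_recording"))
  base <- basename(basepath)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(raw$data)),
    sprintf("SamplingInterval=%g", 1e6 / raw$sfreq),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_along(raw$channel_names),
            raw$channel_names)
  )
  writeLines(hdr, paste0(basepath, ".vhdr"))

  code <- ifelse(raw$events$condition == "congruent", 1L, 2L)
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    if (nrow(raw$events)) {
      sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
              seq_len(nrow(raw$events)) + 1L, code, raw$events$sample)
    }
  )
  writeLines(mrk, paste0(basepath, ".vmrk"))

  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(raw$data), con, size = 4L, endian = "little")
  invisible(basepath)
}

#' Read a continuous recording
#'
#' Reads a BrainVision triplet written by [write_brainvision()] (or any
#' float32 multiplexed BrainVision set with `Stimulus` markers).  Trial
#' indices are reconstructed from marker order; conditions from the
#' `S  1`/`S  2` codes.  A missing marker file yields an empty event list;
#' an inconsistent header is a parse error.  EDF is not supported.
#'
#' @param path Path to the `.vhdr` file (or basepath without extension).
#' @param format `"brainvision"`.
#' @return A [raw_recording()].
#' @export
read_raw <- function(path, format = c("brainvision", "edf")) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("EDF is not supported by this build; use BrainVision ",
         "(.vhdr/.vmrk/.eeg)")
  }
  base <- sub("\\.vhdr$", "", path)
  vhdr <- paste0(base, ".vhdr")
  if (!file.exists(vhdr)) stop("header file not found: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("missing header field: ", key)
    sub(paste0("^", key, "="), "", hit[1L])
  }
  if (get_field("DataFormat") != "BINARY" ||
      get_field("DataOrientation") != "MULTIPLEXED" ||
      get_field("BinaryFormat") != "IEEE_FLOAT_32") {
    stop("unsupported BrainVision variant (need BINARY multiplexed ",
         "IEEE_FLOAT_32)")
  }
  n_chan <- as.integer(get_field("NumberOfChannels"))
  sfreq <- 1e6 / as.numeric(get_field("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[[`, character(1L), 1L)
  if (length(ch_names) != n_chan) {
    stop("channel count mismatch: header announces ", n_chan,
         " channels but lists ", length(ch_names))
  }

  eeg_path <- file.path(dirname(vhdr), get_field("DataFile"))
  n_floats <- file.size(eeg_path) / 4L
  con <- file(eeg_path, "rb")
  vals <- readBin(con, numeric(), n = n_floats, size = 4L, endian = "little")
  close(con)
  if (length(vals) %% n_chan != 0L) {
    stop("data file length is not a multiple of the channel count")
  }
  data <- matrix(vals, nrow = n_chan)

  vmrk <- file.path(dirname(vhdr), sub("\\.eeg$", ".vmrk",
                                       get_field("DataFile")))
  events <- empty_events()
  if (file.exists(vmrk)) {
    mlines <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk, warn = FALSE),
                   value = TRUE)
    if (length(mlines)) {
      parts <- strsplit(sub("^Mk[0-9]+=Stimulus,", "", mlines), ",")
      codes <- as.integer(sub("^S\\s*", "", vapply(parts, `[[`,
                                                   character(1L), 1L)))
      samples <- as.integer(vapply(parts, `[[`, character(1L), 2L))
      events <- data.frame(
        sample = samples, trial = seq_along(samples),
        condition = ifelse(codes == 1L, "congruent", "incongruent"),
        stringsAsFactors = FALSE
      )
    }
  }
  raw_recording(data, sfreq, ch_names, events, chain = "read_raw")
}

RUN_CONFIG_KEYS <- c("experiment", "n_participants", "n_trials", "seed",
                     "simulate", "preprocess", "behaviour", "erp",
                     "classify", "questionnaires")

#' Build and validate a pipeline run configuration
#'
#' Accepts a named list, or the path of a YAML/JSON file, and fills
#' defaults for every stage.  Unknown top-level keys are rejected so typos
#' cannot silently disable a stage.
#'
#' @param x Named list, path to a `.yaml`/`.yml`/`.json` file, or `NULL`
#'   for all defaults.
#' @return Object of class `run_config`.
#' @export
run_config <- function(x = NULL) {
  if (is.character(x)) {
    x <- if (grepl("\\.ya?ml$", x)) yaml::read_yaml(x) else
      jsonlite::read_json(x, simplifyVector = TRUE)
  }
  x <- x %||% list()
  unknown <- setdiff(names(x), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- list(
    experiment = x$experiment %||% "forward",
    n_participants = x$n_participants %||% 31L,
    n_trials = x$n_trials %||% 400L,
    seed = x$seed %||% 1L,
    simulate = x$simulate %||% list(),
    preprocess = utils::modifyList(
      list(use_continuous = FALSE, filter_low = 0.1, filter_high = 30,
           ica_threshold = 0.5, reject_budget_uv = 200,
           tmin = -0.1, tmax = 1.0, baseline = c(-0.06, 0.04)),
      x$preprocess %||% list()
    ),
    behaviour = utils::modifyList(
      list(sided = "one", alpha = 0.05), x$behaviour %||% list()
    ),
    erp = utils::modifyList(
      list(alpha = 0.05, summary = "median"), x$erp %||% list()
    ),
    classify = utils::modifyList(
      list(enabled = FALSE, epochs = 20L, search = FALSE, n_draws = 10L,
           cv_seeds = c(101L, 102L, 103L)),
      x$classify %||% list()
    ),
    questionnaires = utils::modifyList(
      list(latent_coupling = 0), x$questionnaires %||% list()
    )
  )
  stopifnot(cfg$experiment %in% c("forward", "backward", "both"))
  structure(cfg, class = "run_config")
}

# Small stable polynomial hash of a deparsed object, for provenance blocks.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
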