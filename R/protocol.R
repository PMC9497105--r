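protocol_kinds <- c("capsaicin", "mustard_oil", "menthol", "high_k",
                    "sensitizer", "temperature", "mech_step",
                    "voltage_step", "current_step")

#' Stimulus protocols
#'
#' A stimulus protocol is an ordered, non-overlapping set of epochs that
#' segments a recording into baseline and stimulus windows. Epochs carry an
#' onset and duration in seconds, a stimulus kind and a magnitude with units
#' (e.g. capsaicin concentration in nM, bath temperature in degrees C,
#' probe indentation in um).
#'
#' @param epochs A data frame with columns `onset_s`, `duration_s`, `kind`,
#'   `magnitude`, `magnitude_units`.
#' @return A tibble of class `noci_protocol`, sorted by onset.
#' @export
stimulus_protocol <- function(epochs) {
  epochs <- tibble::as_tibble(epochs)
  needed <- c("onset_s", "duration_s", "kind", "magnitude", "magnitude_units")
  missing <- setdiff(needed, names(epochs))
  if (length(missing) > 0) {
    rlang::abort(paste0("Protocol is missing columns: ",
                        paste(missing, collapse = ", ")),
                 class = "nociphys_format_error")
  }
  bad_kind <- setdiff(unique(epochs$kind), protocol_kinds)
  if (length(bad_kind) > 0) {
    rlang::abort(paste0("Unknown epoch kind(s): ",
                        paste(bad_kind, collapse = ", ")),
                 class = "nociphys_format_error")
  }
  epochs <- dplyr::arrange(epochs, .data$onset_s)
  if (nrow(epochs) > 1) {
    ends <- epochs$onset_s + epochs$duration_s
    if (any(epochs$onset_s[-1] < ends[-nrow(epochs)] - 1e-9)) {
      rlang::abort("Protocol epochs must not overlap.",
                   class = "nociphys_format_error")
    }
  }
  class(epochs) <- c("noci_protocol", class(epochs))
  epochs
}

as_protocol <- function(x) {
  if (inherits(x, "noci_protocol")) x else stimulus_protocol(x)
}

#' @rdname stimulus_protocol
#' @param path JSON file: an array of epoch objects with keys `onset_s`,
#'   `duration_s`, `kind`, `magnitude`, `magnitude_units`.
#' @export
read_protocol <- function(path) {
  stimulus_protocol(jsonlite::fromJSON(path))
}

#' @rdname stimulus_protocol
#' @param protocol A protocol to write.
#' @export
write_protocol <- function(protocol, path) {
  df <- as.data.frame(tibble::as_tibble(as_protocol(protocol)))
  jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Canonical sensitization protocol
#'
#' The TRPV1 sensitization paradigm: five 1-min challenges with a low
#' capsaicin dose, spaced by 5-min washes, then a 5-min incubation with an
#' inflammatory mediator (NGF, PMA, serotonin or bradykinin), a sixth
#' capsaicin pulse, optionally a final high-dose (1 uM) capsaicin pulse,
#' and a terminal high-K depolarization to identify all viable neurons.
#' The sensitization statistic compares the peak after incubation (pulse 6)
#' with the second peak before it (pulse 4).
#'
#' @param caps_nm Capsaicin concentration for the repeated pulses (nM).
#' @param pulse_s Pulse duration (s). @param wash_s Washout duration (s).
#' @param sensitizer_s Incubation duration (s).
#' @param include_high_dose Append a final 1 uM capsaicin challenge.
#' @return A [stimulus_protocol()].
#' @export
sensitization_protocol <- function(caps_nm = 100, pulse_s = 60, wash_s = 300,
                                   sensitizer_s = 300,
                                   include_high_dose = FALSE) {
  t <- 60  # pre-stimulus baseline for F0
  rows <- list()
  for (i in 1:5) {
    rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = pulse_s,
                                     kind = "capsaicin", magnitude = caps_nm,
                                     magnitude_units = "nM")
    t <- t + pulse_s + wash_s
  }
  rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = sensitizer_s,
                                   kind = "sensitizer", magnitude = 1,
                                   magnitude_units = "dose")
  t <- t + sensitizer_s
  rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = pulse_s,
                                   kind = "capsaicin", magnitude = caps_nm,
                                   magnitude_units = "nM")
  t <- t + pulse_s + wash_s
  if (include_high_dose) {
    rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = pulse_s,
                                     kind = "capsaicin", magnitude = 1000,
                                     magnitude_units = "nM")
    t <- t + pulse_s + wash_s
  }
  rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = 60,
                                   kind = "high_k", magnitude = 100,
                                   magnitude_units = "mM")
  stimulus_protocol(dplyr::bind_rows(rows))
}

#' Agonist screening protocol
#'
#' Single challenges with capsaicin (TRPV1), mustard oil (TRPA1) and
#' optionally menthol (TRPM8), each followed by a wash, and a terminal
#' high-K depolarization.
#'
#' @param agonists Character vector of agonist epoch kinds to include.
#' @param pulse_s,wash_s Pulse and washout durations (s).
#' @return A [stimulus_protocol()].
#' @export
agonist_protocol <- function(agonists = c("capsaicin", "mustard_oil"),
                             pulse_s = 60, wash_s = 300) {
  mags <- c(capsaicin = 1000, mustard_oil = 200000, menthol = 500000)
  t <- 60
  rows <- list()
  for (a in agonists) {
    rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = pulse_s,
                                     kind = a, magnitude = unname(mags[[a]]),
                                     magnitude_units = "nM")
    t <- t + pulse_s + wash_s
  }
  rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = 60,
                                   kind = "high_k", magnitude = 100,
                                   magnitude_units = "mM")
  stimulus_protocol(dplyr::bind_rows(rows))
}

#' Temperature-step protocol
#'
#' Increasing bath-temperature challenges of 25 s duration separated by
#' 5-min room-temperature intervals, followed by a capsaicin challenge
#' (TRPV1 check) and a terminal high-K depolarization.
#'
#' @param temps_c Temperatures of the successive steps (degrees C).
#' @param step_s Step duration (s). @param interval_s Inter-step interval (s).
#' @param include_capsaicin Append a 1 uM capsaicin challenge.
#' @return A [stimulus_protocol()].
#' @export
temperature_protocol <- function(temps_c = seq(35, 43, by = 2), step_s = 25,
                                 interval_s = 300,
                                 include_capsaicin = TRUE) {
  t <- 60
  rows <- list()
  for (temp in temps_c) {
    rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = step_s,
                                     kind = "temperature", magnitude = temp,
                                     magnitude_units = "degC")
    t <- t + step_s + interval_s
  }
  if (include_capsaicin) {
    rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = 60,
                                     kind = "capsaicin", magnitude = 1000,
                                     magnitude_units = "nM")
    t <- t + 60 + interval_s
  }
  rows[[length(rows) + 1]] <- list(onset_s = t, duration_s = 60,
                                   kind = "high_k", magnitude = 100,
                                   magnitude_units = "mM")
  stimulus_protocol(dplyr::bind_rows(rows))
}

protocol_duration <- function(protocol, tail_s = 60) {
  protocol <- as_protocol(protocol)
  max(protocol$onset_s + protocol$duration_s) + tail_s
}

#' Read and write genes-by-samples count matrices
#'
#' Counts are stored as TSV with gene identifiers in the first column and a
#' header row of sample identifiers. Entries must be nonnegative.
#'
#' @param path TSV file path.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_counts(m)
  m
}

#' @rdname read_counts
#' @param counts A counts matrix.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)) ||
      is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    rlang::abort("Counts need unique gene rownames and sample colnames.",
                 class = "nociphys_format_error")
  }
  if (any(counts < 0)) {
    rlang::abort("Counts must be nonnegative.",
                 class = "nociphys_format_error")
  }
  invisible(counts)
}
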