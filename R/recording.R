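#' Construct an SEEG recording object
#'
#' A recording bundles a channels-by-samples signal matrix (microvolts) with
#' its sampling rate, channel labels, optional expert good/bad labels and
#' free-form metadata. Signals are kept in the referential (monopolar)
#' montage as recorded; no re-referencing is ever applied, because bad
#' channels are an instrumental property of the recorded montage.
#'
#' @param signals Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of channel names, one per row,
#'   e.g. `"a7"` (shaft `a`, contact 7).
#' @param labels Optional character vector in `c("good", "bad")`, one per
#'   channel (expert annotation).
#' @param meta Optional named list of provenance (subject id, run id,
#'   center/group tag, phenotype tags, ...).
#' @return An object of class `seeg_recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(400), 4), fs = 200,
#'                  channel_labels = c("a1", "a2", "a3", "b1"))
#' rec
recording <- function(signals, fs, channel_labels, labels = NULL, meta = list()) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    abort("`signals` must be a numeric channels x samples matrix.")
  }
  if (nrow(signals) < 1L) abort("A recording needs at least one channel.")
  if (ncol(signals) < 2L) abort("Every channel needs at least 2 samples.")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive sampling rate in Hz.")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(signals)) {
    abort(sprintf(
      "Got %d channel labels for %d signal rows.",
      length(channel_labels), nrow(signals)
    ))
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(signals)) {
      abort("`labels`, when present, needs one entry per channel.")
    }
    bad_lab <- setdiff(unique(labels), c("good", "bad"))
    if (length(bad_lab)) {
      abort(sprintf("Unknown class label(s): %s", toString(bad_lab)))
    }
  }
  structure(
    list(
      signals = signals, fs = as.numeric(fs),
      channel_labels = channel_labels, labels = labels,
      meta = meta
    ),
    class = "seeg_recording"
  )
}

#' @export
print.seeg_recording <- function(x, ...) {
  dur <- ncol(x$signals) / x$fs
  cat(sprintf(
    "<seeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
    nrow(x$signals), ncol(x$signals), dur, x$fs
  ))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d good, %d bad\n",
                sum(x$labels == "good"), sum(x$labels == "bad")))
  }
  if (length(x$meta)) {
    cat("  meta:", toString(names(x$meta)), "\n")
  }
  invisible(x)
}

#' Parse SEEG channel labels into shaft and contact
#'
#' SEEG channels are conventionally named by electrode shaft letter(s) plus
#' the contact index along the shaft, e.g. `"a7"` is contact 7 of shaft `a`.
#' A prime/apostrophe after the letters (`"a'7"`) distinguishes the
#' contralateral shaft of a bilateral pair and is kept as part of the shaft
#' name. Parsing is case-insensitive on the shaft. Labels that do not match
#' (reference electrodes, ECG leads, ...) are returned with `ok = FALSE`;
#' such channels get empty neighborhoods downstream rather than aborting the
#' run.
#'
#' @param labels Character vector of channel labels.
#' @return A tibble with columns `label`, `shaft` (lower-cased), `contact`
#'   (integer) and `ok` (logical; `FALSE` rows have `NA` shaft/contact).
#' @export
#' @examples
#' parse_channel_labels(c("a7", "f11", "A'3", "EKG"))
parse_channel_labels <- function(labels) {
  labels <- as.character(labels)
  m <- regmatches(labels, regexec("^([A-Za-z]+'?)\\s?([0-9]+)$", labels))
  shaft <- vapply(m, function(g) if (length(g) == 3L) tolower(g[[2L]]) else NA_character_, "")
  contact <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[[3L]]) else NA_integer_, 1L)
  ok <- !is.na(shaft) & !is.na(contact) & contact >= 1L
  shaft[!ok] <- NA_character_
  contact[!ok] <- NA_integer_
  tibble::tibble(label = labels, shaft = shaft, contact = contact, ok = ok)
}

#' Build same-shaft channel neighborhoods
#'
#' For every channel, the neighborhood is the set of other channels on the
#' same electrode shaft whose contact index differs by at most
#' `max_distance` contacts. All per-channel feature normalizations
#' (correlation, variance, amplitude, gradient) are computed against this
#' neighborhood, which makes the features local and robust to regional
#' amplitude differences across the brain. Missing contacts do not extend
#' the window: distance is counted on nominal contact indices. Channels with
#' unparseable labels get an empty neighborhood.
#'
#' @param recording A [recording()].
#' @param max_distance Maximum contact-index distance (default 5).
#' @return A tibble with one row per channel: `channel` (row index),
#'   `label`, `shaft`, `contact`, `ok`, and a list-column `neighbors` of
#'   neighbor row indices (ordered by contact). Carries `max_distance` as an
#'   attribute.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(10 * 50), 10), fs = 100,
#'                  channel_labels = paste0("a", 1:10))
#' build_neighborhoods(rec)$neighbors[[6]]
build_neighborhoods <- function(recording, max_distance = 5L) {
  stopifnot(inherits(recording, "seeg_recording"))
  if (!is.numeric(max_distance) || max_distance < 1L) {
    abort("`max_distance` must be a positive number of contacts.")
  }
  addr <- parse_channel_labels(recording$channel_labels)
  n <- nrow(addr)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    if (!addr$ok[[i]]) {
      neighbors[[i]] <- integer(0)
      next
    }
    same <- which(
      addr$ok & addr$shaft == addr$shaft[[i]] &
        abs(addr$contact - addr$contact[[i]]) <= max_distance
    )
    same <- setdiff(same, i)
    neighbors[[i]] <- same[order(addr$contact[same])]
  }
  out <- dplyr::mutate(addr, channel = dplyr::row_number(), .before = 1)
  out$neighbors <- neighbors
  attr(out, "max_distance") <- as.integer(max_distance)
  out
}
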