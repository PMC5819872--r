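#' Read an SEEG recording from disk
#'
#' Two containers are supported. `"edf"` is the European Data Format
#' (16-bit, continuous); the package ships its own minimal EDF codec, and
#' signals are converted to microvolts when the header declares `uV`, `mV`
#' or `V`. `"fixture"` is the package-native container — an RDS-serialized
#' recording object — which stores doubles bit-exactly and keeps good/bad
#' class labels and metadata; it is the format the simulator writes and the
#' tests round-trip. `"auto"` picks by file extension (`.edf` vs `.rds`).
#'
#' @param path File to read.
#' @param format One of `"auto"`, `"edf"`, `"fixture"`.
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "fixture")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      edf = "edf",
      rds = "fixture",
      abort(sprintf("Cannot infer format from extension '.%s'; pass `format`.", ext))
    )
  }
  switch(format, edf = read_edf(path), fixture = read_fixture(path))
}

#' Write an SEEG recording to disk
#'
#' @inheritParams read_recording
#' @param recording A [recording()].
#' @return `path`, invisibly.
#' @details EDF quantizes each channel to 16 bits over its physical range
#'   and stores whole one-second data records (a trailing partial second is
#'   padded by repeating the last sample), so the EDF round trip is exact
#'   only up to quantization; the fixture round trip is bit-exact and also
#'   preserves class labels and metadata, which EDF cannot carry.
#' @export
write_recording <- function(recording, path, format = c("auto", "edf", "fixture")) {
  stopifnot(inherits(recording, "seeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      edf = "edf",
      rds = "fixture",
      abort(sprintf("Cannot infer format from extension '.%s'; pass `format`.", ext))
    )
  }
  switch(format,
    edf = write_edf(recording, path),
    fixture = write_fixture(recording, path)
  )
  invisible(path)
}

FIXTURE_VERSION <- 1L

write_fixture <- function(recording, path) {
  obj <- unclass(recording)
  obj$container <- list(kind = "badchan-fixture", version = FIXTURE_VERSION)
  saveRDS(obj, path)
  path
}

read_fixture <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("Not a readable fixture file: %s (%s)", path, conditionMessage(e)))
  })
  if (!is.list(obj) || !identical(obj$container$kind, "badchan-fixture")) {
    abort(sprintf("File %s is not a badchan fixture recording.", path))
  }
  recording(obj$signals, obj$fs, obj$channel_labels, labels = obj$labels,
            meta = obj$meta %||% list())
}

# --- minimal EDF codec ------------------------------------------------------
# Continuous EDF: 256-byte fixed header, 256 bytes per signal, then data
# records of little-endian int16 samples. One-second records.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(recording, path) {
  sig <- recording$signals
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) {
    abort("EDF export requires an integer sampling rate (one-second records).")
  }
  fs <- as.integer(round(fs))
  ns <- nrow(sig)
  n_rec <- as.integer(ceiling(ncol(sig) / fs))
  total <- n_rec * fs
  if (total > ncol(sig)) {          # pad trailing partial second
    pad <- sig[, ncol(sig), drop = FALSE][, rep(1L, total - ncol(sig)), drop = FALSE]
    sig <- cbind(sig, pad)
  }
  pmin <- apply(sig, 1L, min)
  pmax <- apply(sig, 1L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (ns + 1L), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  ), con, eos = NULL)
  writeChar(paste0(
    paste(edf_pad(recording$channel_labels, 16), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep("uV", ns), 8), collapse = ""),
    paste(edf_pad(formatC(pmin, digits = 6, format = "g"), 8), collapse = ""),
    paste(edf_pad(formatC(pmax, digits = 6, format = "g"), 8), collapse = ""),
    paste(edf_pad(rep(dmin, ns), 8), collapse = ""),
    paste(edf_pad(rep(dmax, ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep(fs, ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 32), collapse = "")
  ), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(round((sig[, idx, drop = FALSE] - pmin) * scale + dmin))
    storage.mode(block) <- "integer"
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  path
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (length(version) == 0L || !nzchar(version)) {
    abort(sprintf("%s: empty EDF header.", path))
  }
  rd(80); rd(80); rd(8); rd(8)                    # ids, date, time
  rd(8); rd(44)                                    # header bytes, reserved
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1L) abort(sprintf("%s: EDF header declares no signals.", path))
  if (is.na(rec_dur) || rec_dur <= 0) abort(sprintf("%s: missing record duration (no sampling rate).", path))

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  if (!any(nzchar(labels))) abort(sprintf("%s: EDF file lacks channel names.", path))
  vapply(seq_len(ns), function(i) rd(80), "")
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1L) {
    abort(sprintf("%s: ragged per-signal sample counts are not supported.", path))
  }
  spr1 <- spr[[1L]]
  fs <- spr1 / rec_dur

  keep <- labels != "EDF Annotations"
  out <- matrix(NA_real_, sum(keep), n_rec * spr1)
  scale <- (pmax - pmin) / (dmax - dmin)
  # microvolt conversion by declared physical dimension
  unit_gain <- vapply(dims, function(d) {
    switch(tolower(d), uv = 1, "µv" = 1, mv = 1e3, v = 1e6, 1)
  }, 1)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr1, size = 2L,
                   endian = "little", signed = TRUE)
    if (length(raw) < ns * spr1) abort(sprintf("%s: truncated EDF data record %d.", path, r))
    block <- matrix(raw, nrow = spr1, ncol = ns)
    phys <- t(block) * scale - dmin * scale + pmin
    out[, ((r - 1L) * spr1 + 1L):(r * spr1)] <- (phys * unit_gain)[keep, , drop = FALSE]
  }
  recording(out, fs, labels[keep], meta = list(source = path, format = "edf"))
}

#' Write a feature table (and its degeneracy flags) to CSV
#'
#' Writes one row per channel with the fixed feature column order and, when
#' present, the class column. Per-cell degeneracy flags are written to a
#' sibling file `<path-sans-ext>_flags.csv`.
#'
#' @param features A feature table from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  cols <- intersect(c("channel", "label", FEATURE_COLUMNS, "class"), names(features))
  write.csv(features[cols], path, row.names = FALSE)
  flags <- feature_flags(features)
  if (!is.null(flags)) {
    fp <- paste0(tools::file_path_sans_ext(path), "_flags.csv")
    write.csv(flags, fp, row.names = FALSE)
  }
  invisible(path)
}
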