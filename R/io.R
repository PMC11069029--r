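# File interchange: BrainVision triplets for continuous recordings,
# JSON for stimulus specifications and ground truth, format-0 MIDI
# rendering of melodies, and native serialization for epochs/TFR objects.

#' Write a recording as a BrainVision triplet
#'
#' Emits `<basename>.vhdr` (INI header), `<basename>.vmrk` (markers:
#' `New Segment` plus one `Stimulus` marker per event), and
#' `<basename>.eeg` (IEEE float32, multiplexed, microvolts).
#'
#' @param recording an `eeg_recording`.
#' @param basename output path without extension.
#' @return invisibly, the three file paths.
#' @export
write_brainvision <- function(recording, basename) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  stem <- basename(basename)
  nch <- nrow(recording$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / recording$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), recording$channels))
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (!is.null(recording$events) && nrow(recording$events)) {
    ev <- recording$events
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                        seq_len(nrow(ev)) + 1L,
                        ev$run * 100 + ev$trial %% 100, ev$sample))
  }
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$data), con, size = 4, endian = "little")
  invisible(c(vhdr = vhdr, vmrk = vmrk, eeg = eeg))
}

parse_ini <- function(lines) {
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nchar(section)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Supports multiplexed and vectorized orientations with IEEE float32 or
#' signed 16-bit samples (with per-channel resolution scaling), and
#' recovers `Stimulus` markers as events.
#'
#' @param vhdr path to the `.vhdr` header.
#' @param montage optional montage; defaults to matching labels against
#'   [montage_1020()].
#' @return an `eeg_recording`.
#' @export
read_brainvision <- function(vhdr, montage = NULL) {
  ini <- parse_ini(readLines(vhdr, warn = FALSE, encoding = "UTF-8"))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  nch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  dirn <- dirname(vhdr)
  chinfo <- ini[["Channel Infos"]]
  labels <- character(nch); resol <- rep(1, nch)
  for (i in seq_len(nch)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",")[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nchar(parts[3])) resol[i] <- as.numeric(parts[3])
  }
  fmt <- toupper(bi$BinaryFormat %||% "IEEE_FLOAT_32")
  datafile <- file.path(dirn, ci$DataFile)
  sz <- file.info(datafile)$size
  con <- file(datafile, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                   endian = "little")
  } else stop_param("unsupported BinaryFormat: ", fmt)
  nsamp <- length(raw) %/% nch
  orient <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (orient == "MULTIPLEXED") {
    dat <- matrix(raw[seq_len(nch * nsamp)], nrow = nch)
  } else {
    dat <- t(matrix(raw[seq_len(nch * nsamp)], ncol = nch))
  }
  dat <- dat * resol
  events <- NULL
  if (!is.null(ci$MarkerFile)) {
    mpath <- file.path(dirn, ci$MarkerFile)
    if (file.exists(mpath)) {
      mini <- parse_ini(readLines(mpath, warn = FALSE, encoding = "UTF-8"))
      mks <- mini[["Marker Infos"]]
      rows <- lapply(mks, function(v) {
        parts <- strsplit(v, ",")[[1]]
        if (trimws(parts[1]) != "Stimulus") return(NULL)
        code <- as.integer(gsub("[^0-9]", "", parts[2]))
        data.frame(sample = as.integer(parts[3]),
                   run = code %/% 100, trial = code %% 100)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (length(rows)) events <- do.call(rbind, rows)
    }
  }
  if (is.null(montage)) {
    known <- intersect(labels, montage_1020()$label)
    montage <- montage_1020()
  }
  eeg_recording(dat, labels, fs, events = events, montage = montage)
}

#' Serialize a stimulus specification to JSON
#'
#' @param spec a `melody_spec` or `figure_spec`.
#' @param path output path.
#' @export
write_stimulus_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Render a melody to a standard MIDI file (format 0)
#'
#' Single-track MIDI with the melody's tempo; the chord event is rendered
#' as a major triad on the melody note.
#'
#' @param melody a `melody_spec`.
#' @param path output `.mid` path.
#' @param velocity note velocity (default 80).
#' @export
write_midi <- function(melody, path, velocity = 80L) {
  ticks_per_beat <- 480L
  usec_per_beat <- round(60e6 / melody$tempo_bpm)
  vlq <- function(x) {
    out <- as.raw(x %% 128L)
    x <- x %/% 128L
    while (x > 0) {
      out <- c(as.raw(128L + x %% 128L), out)
      x <- x %/% 128L
    }
    out
  }
  be <- function(x, n) as.raw(rev((x %/% 256^(0:(n - 1))) %% 256))
  notes <- melody$notes
  midi_num <- round(69 + 12 * log2(notes$freq_hz / 440))
  evts <- list(c(as.raw(0x00), as.raw(0xFF), as.raw(0x51), as.raw(0x03),
                 be(usec_per_beat, 3)))
  beat_ms <- 60000 / melody$tempo_bpm
  cursor <- 0
  for (i in seq_len(nrow(notes))) {
    on_t <- round(notes$onset_ms[i] / beat_ms * ticks_per_beat)
    off_t <- round((notes$onset_ms[i] + notes$duration_ms[i]) / beat_ms *
                     ticks_per_beat)
    pitches <- midi_num[i]
    if (notes$is_chord[i]) pitches <- c(pitches, pitches + 4L, pitches + 7L)
    for (p in pitches) {
      evts[[length(evts) + 1]] <- c(vlq(on_t - cursor), as.raw(0x90),
                                    as.raw(p), as.raw(velocity))
      cursor <- on_t
    }
    for (p in pitches) {
      evts[[length(evts) + 1]] <- c(vlq(off_t - cursor), as.raw(0x80),
                                    as.raw(p), as.raw(0L))
      cursor <- off_t
    }
  }
  evts[[length(evts) + 1]] <- c(as.raw(0x00), as.raw(0xFF), as.raw(0x2F),
                                as.raw(0x00))
  track <- do.call(c, evts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), be(6, 4), be(0, 2), be(1, 2),
             be(ticks_per_beat, 2),
             charToRaw("MTrk"), be(length(track), 4), track), con)
  invisible(path)
}

#' Save / load epochs or TFR objects
#'
#' Native serialization with a format tag; the documented layout (data
#' array, axes, channels, masks, log) is preserved verbatim.
#' @param x an `eeg_epochs` or `eeg_tfr`.
#' @param path output path (`.rds`).
#' @export
save_eeg_object <- function(x, path) {
  saveRDS(list(format = class(x)[1], payload = x), path)
  invisible(path)
}

#' @rdname save_eeg_object
#' @export
load_eeg_object <- function(path) {
  obj <- readRDS(path)
  obj$payload
}
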