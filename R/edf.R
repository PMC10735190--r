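#' @title EDF input/output and tabular persistence
#' @name edf-io
#' @description
#' Minimal reader and writer for EDF (European Data Format), the 16-bit
#' binary container the source recordings ship in, plus CSV persistence for
#' subject manifests and feature tables. No EDF library is available in the
#' supported environment, so the format is implemented directly: a 256-byte
#' fixed header, 256 bytes of per-signal header fields, then data records
#' of little-endian 16-bit samples mapped linearly between the declared
#' digital and physical ranges.
NULL

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Physical units are microvolt; each channel's physical range is its data
#' range, so quantization error is at most half of range/65535.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  data <- rec$data
  ns <- nrow(data)
  n <- ncol(data)
  fs <- rec$fs
  if (n %% fs == 0) {
    spr <- fs; n_rec <- n %/% fs; rec_dur <- 1
  } else {
    spr <- n; n_rec <- 1L; rec_dur <- n / fs
  }
  pmin <- apply(data, 1, min); pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$subject_id, 80),
    .edf_pad(paste("cogload", rec$condition), 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_num(rec_dur, 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(rec$channel_labels, .edf_pad, "", width = 16),
    rep(.edf_pad("", 80), ns),
    rep(.edf_pad("uV", 8), ns),
    vapply(pmin, .edf_num, "", width = 8),
    vapply(pmax, .edf_num, "", width = 8),
    rep(.edf_pad(dmin, 8), ns),
    rep(.edf_pad(dmax, 8), ns),
    rep(.edf_pad("", 80), ns),
    rep(.edf_pad(spr, 8), ns),
    rep(.edf_pad("", 32), ns))
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)
  # digital conversion uses the header values as re-parsed, so the round
  # trip is limited by quantization only, not by header truncation
  pmin2 <- as.numeric(vapply(pmin, .edf_num, "", width = 8))
  pmax2 <- as.numeric(vapply(pmax, .edf_num, "", width = 8))
  gain <- (dmax - dmin) / (pmax2 - pmin2)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, cols] - pmin2[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Low-level reader returning every signal as stored. Use
#' [read_recording()] to get the canonical 19-channel montage.
#'
#' @param path EDF file path.
#' @return List with `labels`, `fs` (per signal), `units`, and `data`
#'   (signals x samples matrix, physical units).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(k) readChar(con, k, useBytes = TRUE)
  version <- trimws(rd(8))
  if (!identical(version, "0")) stop("not an EDF file (bad version field): ",
                                     path, call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: ", path, call. = FALSE)
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- trimws(fld(16))
  fld(80)
  units <- trimws(fld(8))
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  data <- matrix(NA_real_, nrow = ns, ncol = n_rec * max(spr))
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     signed = TRUE, endian = "little")
      cols <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      data[ch, cols] <- pmin[ch] + (dig - dmin[ch]) * gain[ch]
    }
  }
  list(labels = labels, fs = spr / rec_dur, units = units, data = data)
}

# Common modern-to-classic temporal alias map.
.label_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

.match_montage <- function(file_labels, montage, use_aliases = FALSE) {
  clean <- trimws(sub("^EEG[ .-]*", "", file_labels, ignore.case = TRUE))
  if (use_aliases) {
    hit <- toupper(clean) %in% names(.label_aliases)
    clean[hit] <- .label_aliases[toupper(clean)[hit]]
  }
  idx <- match(toupper(montage), toupper(clean))
  if (anyNA(idx)) {
    stop("channel missing from EDF file: ",
         paste(montage[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Read a recording as the canonical 19-channel montage
#'
#' Selects the montage channels (dropping reference, ECG and stimulus
#' signals) and returns them in canonical order. Labels are matched after
#' trimming an optional "EEG" prefix, case-insensitively; the modern
#' temporal labels (T7/T8/P7/P8) are mapped to the classic T3/T4/T5/T6 only
#' when `use_aliases = TRUE`.
#'
#' @param path EDF file path.
#' @param montage Channel labels wanted, in order (default [montage_1020()]).
#' @param subject_id,condition Metadata for the returned recording; by
#'   default parsed from a `<subject>_<condition>.edf` file name.
#' @param use_aliases Apply the T7/T3-style alias map (default `FALSE`).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, montage = montage_1020(),
                           subject_id = NULL, condition = NULL,
                           use_aliases = FALSE) {
  raw <- read_edf(path)
  idx <- .match_montage(raw$labels, montage, use_aliases)
  fs <- unique(raw$fs[idx])
  if (length(fs) != 1L)
    stop("montage channels have differing sampling rates", call. = FALSE)
  base <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  parts <- strsplit(base, "_")[[1]]
  if (is.null(subject_id)) subject_id <- parts[1]
  if (is.null(condition) && length(parts) > 1) condition <- parts[2]
  data <- raw$data[idx, , drop = FALSE]
  if (!all(is.finite(data))) stop("non-finite samples in ", path, call. = FALSE)
  rownames(data) <- montage
  structure(list(subject_id = subject_id, condition = condition,
                 fs = fs, channel_labels = montage, data = data),
            class = "eeg_recording")
}

#' Load a subject manifest
#'
#' @param path CSV with columns `subject_id` and `X` (problems completed
#'   per minute). A `group` column, if absent, is derived by the threshold
#'   rule `X <= threshold -> "BAD"`.
#' @param threshold Performance threshold (default 10).
#' @return Data frame with `subject_id`, `X`, `group`.
#' @export
load_manifest <- function(path, threshold = 10) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty manifest: ", path, call. = FALSE)
  if (!all(c("subject_id", "X") %in% names(df)))
    stop("manifest must have subject_id and X columns", call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest", call. = FALSE)
  x <- suppressWarnings(as.numeric(df$X))
  if (anyNA(x)) stop("non-numeric X in manifest", call. = FALSE)
  if (any(x <= 0)) stop("X must be positive", call. = FALSE)
  df$X <- x
  if (is.null(df$group)) df$group <- ifelse(x <= threshold, "BAD", "GOOD")
  df[, c("subject_id", "X", "group",
         intersect("skill", names(df))), drop = FALSE]
}

#' Persist and reload feature tables
#'
#' The feature table holds one row per subject-condition with the 570
#' feature columns named `<channel>.imf<k>.<feature>` in the canonical
#' channel-major layout. The round trip is lossless to numeric precision.
#'
#' @param features Data frame from [extract_cohort_features()].
#' @param path CSV path.
#' @return `path` invisibly (`write_features`); the feature data frame
#'   (`read_features`).
#' @export
write_features <- function(features, path) {
  .check_feature_table(features)
  num <- features[, feature_layout(), drop = FALSE]
  out <- cbind(features[, c("subject_id", "condition"), drop = FALSE],
               as.data.frame(lapply(num, function(v) sprintf("%.17g", v)),
                             check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_feature_table(df)
  for (nm in feature_layout()) df[[nm]] <- as.numeric(df[[nm]])
  df
}

.check_feature_table <- function(df) {
  need <- c("subject_id", "condition", feature_layout())
  if (!identical(intersect(need, names(df)), need) ||
      length(setdiff(names(df), need)) > 0L)
    stop("feature table header/shape mismatch: expected subject_id, ",
         "condition and the 570 canonical feature columns", call. = FALSE)
  invisible(df)
}
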