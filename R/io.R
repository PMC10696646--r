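# WFDB-dialect record and annotation I/O, and the 15-label beat vocabulary.
#
# Records are .hea/.dat/.atr triplets as used by the MIT-BIH Arrhythmia
# Database: a text header, interleaved binary samples (format 16 or the packed
# 12-bit format 212), and the MIT binary annotation format (16-bit words of
# code << 10 | time-delta, with SKIP/AUX escape codes). Annotation sample
# indices are 0-based throughout the package.

#' Ordered 15-symbol beat vocabulary
#'
#' Returns the fixed class vocabulary used everywhere in the package: the 14
#' beat classes (normal, bundle branch blocks, ventricular and atrial
#' ectopics, fusions, escapes, unclassifiable) followed by `"Z"`, the single
#' symbol that all non-beat annotations are grouped into. The position of a
#' symbol in this vector, counted from 0, is its class index; `"N"` is class 0
#' and `"Z"` is class 14.
#'
#' @return Character vector of length 15.
#' @export
#' @examples
#' class_labels()
class_labels <- function() {
  c("N", "L", "R", "V", "A", "f", "F", "j", "a", "E", "J", "Q", "e", "S", "Z")
}

# cached annotation code table (code, symbol, is_beat, grouped)
.ann_env <- new.env(parent = emptyenv())

annotation_codes <- function() {
  if (is.null(.ann_env$tab)) {
    path <- system.file("extdata", "annotation_groups.txt", package = "ecgbeats")
    tab <- read.delim(path, comment.char = "#", header = FALSE,
                      col.names = c("code", "symbol", "is_beat", "grouped"),
                      colClasses = c("integer", "character", "integer", "character"),
                      quote = "")
    .ann_env$tab <- tab
  }
  .ann_env$tab
}

#' Group a raw annotation symbol into the 15-label vocabulary
#'
#' Beat symbols that belong to the 14 named beat classes pass through
#' unchanged; beat symbols outside that set (for example `"/"`, a paced beat)
#' map to `"Q"` (unclassifiable beat); every non-beat symbol maps to `"Z"`.
#' The function is total: any character yields exactly one of the 15 labels,
#' and it is idempotent on its own output.
#'
#' @param raw_symbol Character vector of single-character annotation symbols.
#' @param is_beat Optional logical vector; whether each symbol marks a beat.
#'   When missing, the standard WFDB beat flag for the symbol is looked up
#'   (unknown symbols are treated as non-beats).
#' @return Character vector of grouped symbols, each one of [class_labels()].
#' @export
#' @examples
#' group_symbol("N")  # "N"
#' group_symbol("+")  # rhythm change marker -> "Z"
#' group_symbol("/")  # paced beat, not a named class -> "Q"
group_symbol <- function(raw_symbol, is_beat = NULL) {
  tab <- annotation_codes()
  beats <- setdiff(class_labels(), "Z")
  if (is.null(is_beat)) {
    is_beat <- tab$is_beat[match(raw_symbol, tab$symbol)] == 1L
    is_beat[is.na(is_beat)] <- raw_symbol[is.na(is_beat)] %in% beats
  }
  is_beat <- rep_len(as.logical(is_beat), length(raw_symbol))
  out <- ifelse(!is_beat, "Z", ifelse(raw_symbol %in% beats, raw_symbol, "Q"))
  as.character(out)
}

#' Construct an ECG record object
#'
#' @param record_id Record name (used as the file stem on disk).
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling frequency in Hz (> 0).
#' @param channel_names Character vector, one name per channel.
#' @param annotations Data frame with columns `sample_index` (0-based integer
#'   position), `symbol` (grouped label), and optionally `raw_symbol`.
#' @param units Character scalar describing the amplitude units.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signal, fs, channel_names = NULL,
                       annotations = NULL, units = "mV") {
  signal <- as.matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop("channel_names length must equal the number of channels")
  if (is.null(annotations))
    annotations <- data.frame(sample_index = integer(), symbol = character(),
                              raw_symbol = character())
  if (is.null(annotations$raw_symbol)) annotations$raw_symbol <- annotations$symbol
  n <- ncol(signal)
  if (nrow(annotations) > 0 &&
      (any(annotations$sample_index < 0) || any(annotations$sample_index >= n)))
    stop("annotation sample_index out of range [0, n_samples): record '",
         record_id, "' has ", n, " samples")
  structure(list(record_id = as.character(record_id), signal = signal,
                 fs = fs, channel_names = as.character(channel_names),
                 annotations = annotations, units = units),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'>  %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  ann <- x$annotations
  cat(sprintf("  annotations: %d", nrow(ann)))
  if (nrow(ann) > 0) {
    tb <- sort(table(ann$symbol), decreasing = TRUE)
    cat("  (", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

n_samples <- function(record) ncol(record$signal)

# ---------------------------------------------------------------------------
# header

parse_header <- function(hea_path) {
  if (!file.exists(hea_path))
    stop("header file not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("corrupt header (empty): ", hea_path)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) stop("corrupt header line in ", hea_path)
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp))
    stop("corrupt header fields in ", hea_path)
  if (length(lines) < 1L + nsig)
    stop("header declares ", nsig, " signals but has too few lines: ", hea_path)
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2L) stop("corrupt signal line in ", hea_path)
    gain_spec <- if (length(f) >= 3L) f[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_spec)))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec)) else 0
    units <- if (grepl("/", gain_spec)) sub(".*/", "", gain_spec) else "adu"
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else NA_character_
    list(file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
         gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = baseline, units = units, desc = desc)
  })
  list(record = top[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

# ---------------------------------------------------------------------------
# signal data

read_dat <- function(dat_path, format, nsig, nsamp) {
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  total <- nsig * nsamp
  if (format == 16L) {
    v <- readBin(raw, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  } else if (format == 212L) {
    nb <- ceiling(total / 2) * 3L
    b <- as.integer(raw[seq_len(min(nb, length(raw)))])
    npair <- length(b) %/% 3L
    b0 <- b[3L * seq_len(npair) - 2L]
    b1 <- b[3L * seq_len(npair) - 1L]
    b2 <- b[3L * seq_len(npair)]
    s1 <- bitwAnd(b1, 15L) * 256L + b0
    s2 <- bitwAnd(b1, 240L) * 16L + b2
    v <- as.vector(rbind(s1, s2))
    v <- ifelse(v > 2047L, v - 4096L, v)  # 12-bit two's complement
    v <- v[seq_len(total)]
  } else {
    stop("unsupported signal format ", format, " in ", dat_path)
  }
  if (length(v) < total) stop("signal file too short: ", dat_path)
  matrix(v[seq_len(total)], nrow = nsig)  # interleaved: channel varies fastest
}

write_dat <- function(dat_path, adc) {
  v <- as.integer(round(as.vector(adc)))  # interleaved channel-major
  v <- pmax(pmin(v, 32767L), -32768L)
  writeBin(v, dat_path, size = 2L, endian = "little")
  invisible(v)
}

# ---------------------------------------------------------------------------
# MIT annotation format

SKIP_CODE <- 59L
AUX_CODE <- 63L
PSEUDO_CODES <- c(59L, 60L, 61L, 62L, 63L)

read_atr <- function(atr_path) {
  raw <- readBin(atr_path, "raw", n = file.info(atr_path)$size)
  nb <- length(raw)
  b <- as.integer(raw)
  tab <- annotation_codes()
  idx <- integer(0); sym <- character(0)
  t_cur <- 0; i <- 1L
  while (i + 1L <= nb) {
    word <- b[i] + 256L * b[i + 1L]
    i <- i + 2L
    code <- word %/% 1024L
    delta <- word %% 1024L
    if (word == 0L) break
    if (code == SKIP_CODE) {
      if (i + 3L > nb) stop("truncated SKIP in ", atr_path)
      hi <- b[i] + 256L * b[i + 1L]
      lo <- b[i + 2L] + 256L * b[i + 3L]
      i <- i + 4L
      t_cur <- t_cur + hi * 65536 + lo
    } else if (code == AUX_CODE) {
      nbytes <- delta + delta %% 2L  # padded to even
      i <- i + nbytes
    } else if (code %in% PSEUDO_CODES) {
      # NUM/SUB/CHN modifiers: parsed and ignored
    } else {
      t_cur <- t_cur + delta
      s <- tab$symbol[match(code, tab$code)]
      idx <- c(idx, t_cur)
      sym <- c(sym, if (is.na(s)) "Q" else s)
    }
  }
  data.frame(sample_index = as.integer(idx), raw_symbol = sym)
}

write_atr <- function(atr_path, sample_index, raw_symbol) {
  tab <- annotation_codes()
  o <- order(sample_index)
  sample_index <- sample_index[o]; raw_symbol <- raw_symbol[o]
  code <- tab$code[match(raw_symbol, tab$symbol)]
  code[is.na(code)] <- 13L  # unknown symbol -> UNKNOWN beat code
  con <- file(atr_path, "wb")
  on.exit(close(con))
  put_word <- function(w) writeBin(as.integer(w), con, size = 2L, endian = "little")
  t_prev <- 0
  for (k in seq_along(sample_index)) {
    delta <- sample_index[k] - t_prev
    if (delta > 1023) {
      put_word(SKIP_CODE * 1024L)
      put_word(delta %/% 65536)
      put_word(delta %% 65536)
      delta <- 0
    }
    put_word(code[k] * 1024L + delta)
    t_prev <- sample_index[k]
  }
  put_word(0L)
  invisible(atr_path)
}

# ---------------------------------------------------------------------------

#' Read a WFDB-dialect ECG record
#'
#' Reads a `.hea` header, the binary signal file it names (format 16 or 212),
#' and, if present, a binary annotation file in the MIT format. Samples are
#' returned in physical units (`(adc - baseline) / gain`). Raw annotation
#' symbols are preserved in the `raw_symbol` column; the `symbol` column holds
#' the grouped 15-class label (see [group_symbol()]).
#'
#' @param path Record path without extension (e.g. `"dir/rec01"`).
#' @param annotation_extension Extension of the annotation file (default
#'   `"atr"`); set to `NA` to skip annotations.
#' @return An [ecg_record()] object.
#' @export
read_record <- function(path, annotation_extension = "atr") {
  hdr <- parse_header(paste0(path, ".hea"))
  dat_path <- file.path(dirname(path), hdr$signals[[1]]$file)
  fmt <- hdr$signals[[1]]$format
  adc <- read_dat(dat_path, fmt, hdr$nsig, hdr$nsamp)
  sig <- adc
  for (k in seq_len(hdr$nsig))
    sig[k, ] <- (adc[k, ] - hdr$signals[[k]]$baseline) / hdr$signals[[k]]$gain
  ch <- vapply(hdr$signals, function(s)
    if (is.na(s$desc)) "" else s$desc, character(1))
  ch[!nzchar(ch)] <- paste0("ch", which(!nzchar(ch)))
  ann <- NULL
  if (!is.na(annotation_extension)) {
    atr_path <- paste0(path, ".", annotation_extension)
    if (file.exists(atr_path)) {
      a <- read_atr(atr_path)
      if (nrow(a) > 0 && any(a$sample_index >= hdr$nsamp))
        stop("annotation index beyond signal length in ", atr_path)
      ann <- data.frame(sample_index = a$sample_index,
                        symbol = group_symbol(a$raw_symbol),
                        raw_symbol = a$raw_symbol)
    }
  }
  ecg_record(hdr$record, sig, hdr$fs, channel_names = ch, annotations = ann,
             units = hdr$signals[[1]]$units)
}

#' Write an ECG record in the WFDB dialect
#'
#' Emits `<id>.hea`, `<id>.dat` (format 16, interleaved 16-bit little-endian)
#' and, when the record carries annotations, `<id>.atr` in the MIT annotation
#' format. Physical sample values are quantized with the given gain
#' (`adc = round(value * gain)`), so the round trip through [read_record()]
#' reproduces each sample to within half an ADC step (`0.5 / gain`).
#'
#' @param record An [ecg_record()] object.
#' @param dir Output directory (created if needed).
#' @param gain ADC units per physical unit (default 200, the MIT-BIH value).
#' @return The record path (without extension), invisibly.
#' @export
write_record <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, record$record_id)
  adc <- round(record$signal * gain)
  adc <- pmax(pmin(adc, 32767), -32768)
  nsig <- nrow(adc); nsamp <- ncol(adc)
  chks <- apply(adc, 1, function(v) {
    s <- sum(v) %% 65536
    if (s > 32767) s - 65536 else s
  })
  lines <- c(
    sprintf("%s %d %g %d", record$record_id, nsig, record$fs, nsamp),
    sprintf("%s.dat 16 %g(0)/%s 16 0 %d %d 0 %s",
            record$record_id, gain, record$units,
            as.integer(adc[, 1]), as.integer(chks), record$channel_names))
  writeLines(lines, paste0(stem, ".hea"))
  write_dat(paste0(stem, ".dat"), adc)
  if (nrow(record$annotations) > 0)
    write_atr(paste0(stem, ".atr"), record$annotations$sample_index,
              record$annotations$raw_symbol)
  invisible(stem)
}
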