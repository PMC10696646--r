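# Beat-window extraction and signal-to-image encoding.
#
# A beat window is n consecutive samples centered on an annotated sample x:
# it covers stream positions [x - n/2, x + n/2). Windows that would overrun
# either end of the record are discarded. Each window is encoded as an n x h
# binary raster with exactly one lit pixel per column, the row chosen by
# floor quantization r = floor((w_c - min) / d * h) with d = max - min,
# clamped to [0, h-1]. Row 0 is the minimum-amplitude row; the raster is kept
# "upside down" relative to a plotted trace, matching how image coordinates
# are consumed by the network.

#' Construct a beat window
#'
#' @param samples Numeric vector of exactly `n` samples.
#' @param label Grouped class symbol.
#' @param record_id Source record name.
#' @param center_index 0-based sample position of the annotation.
#' @param skew_offset Integer shift applied when the window was re-cut
#'   (0 for aligned windows).
#' @return An object of class `beat_window`.
#' @export
beat_window <- function(samples, label, record_id = "", center_index = NA_integer_,
                        skew_offset = 0L) {
  structure(list(samples = as.numeric(samples), label = label,
                 record_id = record_id, center_index = as.integer(center_index),
                 skew_offset = as.integer(skew_offset)),
            class = "beat_window")
}

#' Extract fixed-length beat windows around annotations
#'
#' One window is produced per annotation whose full span
#' `[center - n/2, center + n/2)` lies inside the record; annotations too
#' close to either boundary are discarded, and the next annotated sample is
#' used instead. Non-beat (`"Z"`) annotations also produce windows: `"Z"` is
#' one of the 15 classes.
#'
#' @param record An [ecg_record()].
#' @param n Window length in samples (even, >= 2); also the image width.
#' @param channel 1-based channel to analyze (default 1).
#' @return List of [beat_window()] objects (possibly empty).
#' @export
extract_windows <- function(record, n, channel = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (n < 2 || n %% 2 != 0) stop("n must be even and >= 2")
  if (channel < 1 || channel > nrow(record$signal)) stop("invalid channel")
  ann <- record$annotations
  if (nrow(ann) == 0) return(list())
  half <- n %/% 2L
  ns <- n_samples(record)
  keep <- ann$sample_index - half >= 0 & ann$sample_index + half <= ns
  sig <- record$signal[channel, ]
  lapply(which(keep), function(k) {
    x <- ann$sample_index[k]
    beat_window(sig[(x - half + 1L):(x + half)], ann$symbol[k],
                record$record_id, x, 0L)
  })
}

#' Randomly skew a beat window
#'
#' Re-cuts the window at `center_index + offset` where the offset is drawn
#' uniformly from the integers in `[-floor(n/4), +floor(n/4)]`, emulating an
#' imperfectly centered beat detector. If the shifted window would overrun
#' the record the offset is redrawn (up to `max_retries` times), then falls
#' back to 0.
#'
#' @param window A [beat_window()] produced from `record`.
#' @param record The source [ecg_record()].
#' @param channel 1-based channel (must match the extraction channel).
#' @param max_retries Bounded redraws at record boundaries.
#' @return A [beat_window()] with `skew_offset` recorded. Uses the R RNG:
#'   seed with [set.seed()] for reproducibility.
#' @export
apply_skew <- function(window, record, channel = 1L, max_retries = 10L) {
  n <- length(window$samples)
  half <- n %/% 2L
  m <- n %/% 4L
  ns <- n_samples(record)
  off <- 0L
  for (i in seq_len(max_retries)) {
    cand <- sample.int(2L * m + 1L, 1L) - m - 1L  # uniform on [-m, m]
    ctr <- window$center_index + cand
    if (ctr - half >= 0 && ctr + half <= ns) { off <- cand; break }
  }
  ctr <- window$center_index + off
  sig <- record$signal[channel, ]
  beat_window(sig[(ctr - half + 1L):(ctr + half)], window$label,
              window$record_id, window$center_index, off)
}

#' Construct a beat image object
#'
#' @param grid Integer matrix `h` rows x `n` columns with values 0 or 255 and
#'   exactly one 255 per column; row 1 of the matrix is quantization row 0.
#' @param limits Length-2 numeric `(min_limit, max_limit)` used for
#'   quantization.
#' @return An object of class `beat_image` with fields `grid`, `width`,
#'   `height`, `limits`.
#' @export
beat_image <- function(grid, limits) {
  structure(list(grid = grid, width = ncol(grid), height = nrow(grid),
                 limits = as.numeric(limits)),
            class = "beat_image")
}

#' @export
print.beat_image <- function(x, ...) {
  cat(sprintf("<beat_image> %d x %d (width x height), limits [%g, %g]\n",
              x$width, x$height, x$limits[1], x$limits[2]))
  invisible(x)
}

#' Convert a signal window to a binary beat image
#'
#' Each of the `n` samples becomes one image column with a single lit pixel
#' (value 255) at row `floor((value - min_limit) / d * h)` where
#' `d = max_limit - min_limit`; rows are clamped to `[0, h-1]` so a sample at
#' (or beyond) the maximum limit lights row `h - 1`. For the five-sample
#' sequence `c(300, 325, 600, 100, 300)` with limits `c(0, 700)` and `h = 5`
#' the lit pixels are (0,2), (1,2), (2,4), (3,0), (4,2) in (column, row)
#' coordinates.
#'
#' @param samples Numeric vector of window samples.
#' @param min_limit,max_limit Quantization limits; `max_limit > min_limit`.
#' @param h Image height in pixels (>= 1).
#' @return A [beat_image()].
#' @export
signal_to_image <- function(samples, min_limit, max_limit, h) {
  if (!is.numeric(h) || h < 1) stop("h must be >= 1")
  d <- max_limit - min_limit
  if (!is.finite(d) || d <= 0) stop("max_limit must exceed min_limit")
  r <- floor((samples - min_limit) / d * h)
  r <- pmax(pmin(r, h - 1), 0)
  grid <- matrix(0L, nrow = h, ncol = length(samples))
  grid[cbind(r + 1L, seq_along(samples))] <- 255L
  beat_image(grid, c(min_limit, max_limit))
}

#' Lit-pixel rows of a beat image
#'
#' @param image A [beat_image()].
#' @return Integer vector of the 0-based lit row per column.
#' @export
lit_rows <- function(image) {
  apply(image$grid, 2, function(col) which(col != 0L)[1]) - 1L
}

#' Decode a beat image back to an approximate signal
#'
#' Inverts the quantization of [signal_to_image()] up to resolution: each
#' column's lit row `r` is decoded to the cell midpoint
#' `min_limit + (r + 0.5) * d / h`, so an in-range signal round-trips with
#' per-sample error at most `d / h`.
#'
#' @param image A [beat_image()].
#' @return Numeric vector of length `image$width`.
#' @export
image_to_signal <- function(image) {
  d <- diff(image$limits)
  image$limits[1] + (lit_rows(image) + 0.5) * d / image$height
}

#' Build an image dataset from annotated records
#'
#' Extracts beat windows from every record, optionally skews each window by a
#' random shift of up to a quarter window, converts windows to binary images,
#' shuffles the pooled collection with the given seed, and splits it into
#' training and testing partitions.
#'
#' @param records A single [ecg_record()] or a list of them.
#' @param n Window length / image width.
#' @param h Image height.
#' @param skewed Logical; cut windows at a random offset in `[-n/4, n/4]`
#'   instead of exactly on the annotation.
#' @param limits Length-2 quantization limits, or `NULL` to use the global
#'   min/max of each record's analyzed channel.
#' @param split_fraction Fraction of windows assigned to training (default 0.9).
#' @param channel 1-based channel to analyze.
#' @param seed Integer seed controlling skew draws and the shuffle.
#' @return List with elements `train` and `test`, each a list with `images`
#'   (list of [beat_image()]), `y` (integer 0-based class indices per
#'   [class_labels()]), and `meta` (data frame: record_id, center_index,
#'   skew_offset, label).
#' @export
build_dataset <- function(records, n, h, skewed = FALSE, limits = NULL,
                          split_fraction = 0.9, channel = 1L, seed = 1L) {
  if (inherits(records, "ecg_record")) records <- list(records)
  set.seed(seed)
  labels <- class_labels()
  images <- list(); meta <- list()
  for (rec in records) {
    wins <- extract_windows(rec, n, channel)
    if (length(wins) == 0) next
    lim <- if (is.null(limits))
      range(rec$signal[channel, ]) else as.numeric(limits)
    for (w in wins) {
      if (skewed) w <- apply_skew(w, rec, channel)
      images[[length(images) + 1L]] <-
        signal_to_image(w$samples, lim[1], lim[2], h)
      meta[[length(meta) + 1L]] <-
        data.frame(record_id = w$record_id, center_index = w$center_index,
                   skew_offset = w$skew_offset, label = w$label)
    }
  }
  if (length(images) == 0)
    stop("no usable windows: every annotation was discarded or absent")
  meta <- do.call(rbind, meta)
  y <- match(meta$label, labels) - 1L
  if (anyNA(y)) stop("label outside the 15-symbol vocabulary")
  perm <- sample.int(length(images))
  n_train <- floor(split_fraction * length(images))
  tr <- perm[seq_len(n_train)]
  te <- perm[setdiff(seq_along(perm), seq_len(n_train))]
  part <- function(ix) {
    m <- meta[ix, , drop = FALSE]
    rownames(m) <- NULL
    list(images = images[ix], y = y[ix], meta = m)
  }
  list(train = part(tr), test = part(te))
}

#' Write an image dataset as PNG files plus a CSV manifest
#'
#' Each image is written as an 8-bit grayscale PNG (`h` rows x `n` columns);
#' the manifest records `file, record_id, center_index, skew_offset, label,
#' class_index, split` one row per image.
#'
#' @param dataset A dataset from [build_dataset()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (split in c("train", "test")) {
    part <- dataset[[split]]
    for (k in seq_along(part$images)) {
      img <- part$images[[k]]
      fname <- sprintf("%s_%05d.png", split, k)
      png::writePNG(img$grid / 255, file.path(dir, fname))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(file = fname), part$meta[k, , drop = FALSE],
        data.frame(class_index = part$y[k], split = split,
                   min_limit = img$limits[1], max_limit = img$limits[2]))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir Directory containing PNGs and `manifest.csv`.
#' @return A dataset list shaped like the output of [build_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       colClasses = c(label = "character"))
  part <- function(split) {
    m <- manifest[manifest$split == split, , drop = FALSE]
    images <- lapply(seq_len(nrow(m)), function(k) {
      g <- png::readPNG(file.path(dir, m$file[k]))
      beat_image(matrix(as.integer(round(g * 255)), nrow = nrow(g)),
                 c(m$min_limit[k], m$max_limit[k]))
    })
    meta <- m[, c("record_id", "center_index", "skew_offset", "label")]
    rownames(meta) <- NULL
    list(images = images, y = m$class_index, meta = meta)
  }
  list(train = part("train"), test = part("test"))
}
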