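# Synthetic annotated ECG: beats are sums of Gaussian bumps (P/QRS/T-like
# components), concatenated at randomized RR intervals with additive Gaussian
# noise and sinusoidal baseline wander. Each beat's annotation is placed at
# the argmax of its clean rendered segment, so annotations sit exactly on the
# R-peak by construction — the alignment guarantee the center-check tests
# rely on. No physiological realism is claimed beyond class-distinct shapes.

#' Construct a beat template
#'
#' @param label Grouped class symbol for beats rendered from this template.
#' @param waves Data frame with columns `amp` (amplitude, arbitrary units),
#'   `center` (offset from the template midpoint, seconds) and `width`
#'   (Gaussian standard deviation, seconds); one row per component wave.
#' @param duration Template duration in seconds (> 0).
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(label, waves, duration = 0.6) {
  stopifnot(duration > 0, nrow(waves) >= 1,
            all(c("amp", "center", "width") %in% names(waves)))
  structure(list(label = label, waves = waves, duration = duration),
            class = "beat_template")
}

#' Built-in beat morphologies
#'
#' Two well-separated presets: `"N"`, a narrow tall QRS with small P and T
#' waves, and `"V"`, a wide high-amplitude complex without a P wave —
#' emulating a normal beat versus a ventricular ectopic at the level of
#' gross morphology.
#'
#' @param labels Which presets to return (subset of `c("N", "V")`).
#' @return Named list of [beat_template()] objects.
#' @export
preset_templates <- function(labels = c("N", "V")) {
  all <- list(
    N = beat_template("N", data.frame(
      amp = c(0.12, -0.15, 1.0, -0.2, 0.25),
      center = c(-0.18, -0.035, 0, 0.035, 0.22),
      width = c(0.025, 0.01, 0.012, 0.012, 0.04))),
    V = beat_template("V", data.frame(
      amp = c(1.15, -0.45),
      center = c(0, 0.12),
      width = c(0.055, 0.05))))
  stopifnot(all(labels %in% names(all)))
  all[labels]
}

#' Render a beat template at a sampling frequency
#'
#' Samples the sum of the template's Gaussian components over
#' `[-duration/2, duration/2)`.
#'
#' @param template A [beat_template()].
#' @param fs Sampling frequency in Hz.
#' @return Numeric vector with attribute `peak` giving the 0-based index of
#'   its maximum (lowest index on ties), used for annotation placement.
#' @export
render_beat <- function(template, fs) {
  len <- round(template$duration * fs)
  t <- (seq_len(len) - 1) / fs - template$duration / 2
  v <- rep(0, len)
  for (k in seq_len(nrow(template$waves))) {
    w <- template$waves[k, ]
    v <- v + w$amp * exp(-0.5 * ((t - w$center) / w$width)^2)
  }
  attr(v, "peak") <- which.max(v) - 1L
  v
}

#' Synthesis configuration
#'
#' @param fs Sampling frequency in Hz (default 360).
#' @param duration Record duration in seconds.
#' @param templates Named list of [beat_template()]s (default
#'   [preset_templates()]).
#' @param probs Per-template probabilities (default uniform; must sum to 1).
#' @param rr_mean,rr_sd Mean and standard deviation of the RR interval in
#'   seconds; intervals are drawn from a normal truncated below at
#'   `0.6 * rr_mean` so consecutive beats cannot collide.
#' @param noise_sd Additive Gaussian noise standard deviation (amplitude
#'   units).
#' @param wander_amp,wander_freq Sinusoidal baseline wander amplitude and
#'   frequency (Hz).
#' @param n_channels Number of channels (channel 2+ are attenuated copies
#'   with independent noise).
#' @param seed Integer seed; the whole record is reproducible from it.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(fs = 360, duration = 30,
                             templates = preset_templates(),
                             probs = NULL, rr_mean = 0.8, rr_sd = 0.05,
                             noise_sd = 0.03, wander_amp = 0.05,
                             wander_freq = 0.33, n_channels = 2L, seed = 1L) {
  if (is.null(probs)) probs <- rep(1 / length(templates), length(templates))
  stopifnot(fs > 0, duration > 0, length(probs) == length(templates),
            abs(sum(probs) - 1) < 1e-8)
  structure(list(fs = fs, duration = duration, templates = templates,
                 probs = probs, rr_mean = rr_mean, rr_sd = rr_sd,
                 noise_sd = noise_sd, wander_amp = wander_amp,
                 wander_freq = wander_freq, n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

#' Generate a synthetic annotated ECG record
#'
#' Draws beat labels and RR intervals, renders each beat from its template,
#' adds noise and baseline wander, and annotates every beat at the argmax of
#' its clean rendered segment.
#'
#' @param config A [synthesis_config()].
#' @param record_id Record name.
#' @return An [ecg_record()] with one beat annotation per rendered beat.
#' @export
generate_record <- function(config, record_id = "synth") {
  stopifnot(inherits(config, "synthesis_config"))
  set.seed(config$seed)
  fs <- config$fs
  ns <- round(config$duration * fs)
  tmpl <- config$templates
  max_len <- max(vapply(tmpl, function(tp) round(tp$duration * fs), numeric(1)))
  if (ns < max_len + fs * config$rr_mean)
    stop("duration too short for a single beat at the configured RR interval")
  clean <- rep(0, ns)
  idx <- integer(0); lab <- character(0)
  pos <- config$rr_mean  # time of the first beat center, seconds
  while (TRUE) {
    k <- sample.int(length(tmpl), 1L, prob = config$probs)
    tp <- tmpl[[k]]
    seg <- render_beat(tp, fs)
    start <- round(pos * fs) - round(length(seg) / 2)  # 0-based segment start
    if (start < 0) start <- 0
    if (start + length(seg) > ns) break
    rng <- start + seq_along(seg)  # 1-based sample range
    clean[rng] <- clean[rng] + seg
    idx <- c(idx, start + attr(seg, "peak"))
    lab <- c(lab, tp$label)
    rr <- stats::rnorm(1, config$rr_mean, config$rr_sd)
    rr <- max(rr, 0.6 * config$rr_mean)
    pos <- pos + rr
  }
  if (length(idx) == 0) stop("duration too short for a single beat")
  tt <- (seq_len(ns) - 1) / fs
  wander <- config$wander_amp * sin(2 * pi * config$wander_freq * tt)
  sig <- matrix(0, nrow = config$n_channels, ncol = ns)
  for (ch in seq_len(config$n_channels)) {
    scale <- if (ch == 1) 1 else 0.7^(ch - 1)
    sig[ch, ] <- scale * (clean + wander) + stats::rnorm(ns, 0, config$noise_sd)
  }
  ann <- data.frame(sample_index = as.integer(idx), symbol = group_symbol(lab),
                    raw_symbol = lab)
  ecg_record(record_id, sig, fs,
             channel_names = paste0("SYN", seq_len(config$n_channels)),
             annotations = ann, units = "mV")
}
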