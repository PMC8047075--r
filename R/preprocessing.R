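#' Zero-phase 1-8 Hz Chebyshev type-II band-pass
#'
#' Band-passes every channel between `passband` Hz with a Chebyshev
#' type-II design meeting `rs` dB stop-band attenuation outside `stopband`
#' and at most `rp` dB pass-band ripple, applied forward-backward
#' (zero phase). The band-pass is realized as a minimum-order high-pass /
#' low-pass cascade, which is numerically far better conditioned than a
#' single high-order transfer-function band-pass. Blocks are filtered
#' independently, since they are discontinuous recordings.
#'
#' @param recording an [eeg_recording()] with sample rate >= 64 Hz.
#' @param passband pass-band edges in Hz, default `c(1, 8)`.
#' @param stopband stop-band edges in Hz, default `c(0.5, 9)`.
#' @param rp maximum pass-band ripple in dB.
#' @param rs minimum stop-band attenuation in dB.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_1_8 <- function(recording, passband = c(1, 8), stopband = c(0.5, 9),
                         rp = 1, rs = 80) {
  fs <- recording$sample_rate_hz
  if (fs < 64) stop("design infeasible: sample rate must be >= 64 Hz")
  flt <- design_bandpass(fs, passband, stopband, rp, rs)
  out <- recording$data
  for (b in seq_len(n_blocks(recording))) {
    idx <- block_idx(recording, b)
    for (ch in seq_len(nrow(out))) {
      out[ch, idx] <- sos_filtfilt(flt, out[ch, idx])
    }
  }
  recording$data <- out
  recording
}

# Chebyshev type-II analog low-pass prototype in zero-pole-gain form
# (stop-band edge at 1 rad/s, attenuation rs dB, unit DC gain).
cheb2_prototype <- function(n, rs) {
  eps <- 1 / sqrt(10^(rs / 10) - 1)
  mu <- asinh(1 / eps) / n
  theta <- (2 * seq_len(n) - 1) * pi / (2 * n)
  p <- 1 / complex(real = -sinh(mu) * sin(theta),
                   imaginary = cosh(mu) * cos(theta))
  z <- 1i / cos(theta[abs(cos(theta)) > 1e-12])
  g <- Re(prod(-p) / prod(-z))
  list(z = z, p = p, g = g)
}

# Minimum even order for a Chebyshev filter meeting Rp dB pass-band ripple
# at Wp and Rs dB attenuation at Ws (normalized digital edges, prewarped).
cheb2_order <- function(Wp, Ws, Rp, Rs) {
  wp <- tan(pi * Wp / 2); ws <- tan(pi * Ws / 2)
  ratio <- max(ws / wp, wp / ws)
  n <- ceiling(acosh(sqrt((10^(Rs / 10) - 1) / (10^(Rp / 10) - 1))) /
                 acosh(ratio))
  n + n %% 2   # even order pairs cleanly into biquads
}

# digital zero-pole-gain -> second-order sections (L x 6 matrix b0 b1 b2 a0 a1 a2)
zpg_to_sos <- function(zpg) {
  pair_up <- function(v) {
    v <- v[order(-abs(Im(v)), Re(v))]
    up <- v[Im(v) > 1e-9]
    list(pairs = up, real = sort(Re(v[abs(Im(v)) <= 1e-9])))
  }
  ps <- pair_up(zpg$p); zs <- pair_up(zpg$z)
  stopifnot(length(ps$real) %% 2 == 0, length(zs$real) %% 2 == 0)
  # complex pole pairs nearest the unit circle first; match each with the
  # zero pair closest in angle
  pp <- ps$pairs[order(-Mod(ps$pairs))]
  zz <- zs$pairs
  n_sec <- length(pp)
  sos <- matrix(0, n_sec, 6)
  for (i in seq_len(n_sec)) {
    p <- pp[i]
    j <- which.min(abs(Arg(zz) - Arg(p)))
    z <- zz[j]; zz <- zz[-j]
    sos[i, ] <- c(1, -2 * Re(z), Mod(z)^2, 1, -2 * Re(p), Mod(p)^2)
  }
  gsec <- abs(zpg$g)^(1 / n_sec)
  sgn <- sign(Re(zpg$g))
  sos[, 1:3] <- sos[, 1:3] * gsec
  sos[1, 1:3] <- sos[1, 1:3] * sgn
  sos
}

# Design one Chebyshev II digital filter (zpg + SOS) for a pass/stop edge
# pair; `type` "high" or "low".
design_cheb2 <- function(fs, f_pass, f_stop, rp, rs, type) {
  nyq <- fs / 2
  n <- cheb2_order(f_pass / nyq, f_stop / nyq, rp, rs)
  proto <- cheb2_prototype(n, rs)
  W <- tan(pi * (f_stop / nyq) / 2)   # prewarped stop-band edge
  s <- signal::sftrans(proto$z, proto$p, proto$g, W, stop = (type == "high"))
  d <- signal::bilinear(s$zero, s$pole, s$gain, T = 2)
  zpg_to_sos(list(z = d$zero, p = d$pole, g = d$gain))
}

# Minimum-order Chebyshev II high-pass + low-pass cascade meeting the
# printed attenuation/ripple specification at sample rate fs.
design_bandpass <- function(fs, passband, stopband, rp, rs) {
  nyq <- fs / 2
  if (stopband[2] >= nyq) stop("design infeasible: upper stop-band at or above Nyquist")
  rbind(design_cheb2(fs, passband[1], stopband[1], rp, rs, "high"),
        design_cheb2(fs, passband[2], stopband[2], rp, rs, "low"))
}

# zero-phase (forward-backward) filtering through a cascade of biquads
sos_filtfilt <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    flt <- signal::Arma(b = sos[i, 1:3], a = sos[i, 4:6])
    x <- signal::filtfilt(flt, x)
  }
  x
}

# cascade magnitude response at frequencies f (Hz)
sos_response <- function(sos, f, fs) {
  zi <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    h <- h * (sos[i, 1] + sos[i, 2] * zi + sos[i, 3] * zi^2) /
      (sos[i, 4] + sos[i, 5] * zi + sos[i, 6] * zi^2)
  }
  abs(h)
}

#' Z-score every channel of a recording
#'
#' Per channel over the whole recording: subtract the mean, divide by the
#' standard deviation. Controls for between-subject differences in overall
#' signal amplitude (skull thickness, electrode impedance) before
#' cross-validated regression.
#'
#' @param recording an [eeg_recording()].
#' @return The z-scored [eeg_recording()].
#' @export
zscore_eeg <- function(recording) {
  s <- apply(recording$data, 1, sd)
  flat <- s == 0 | !is.finite(s)
  if (any(flat)) {
    stop("zero-variance channel(s): ",
         paste(recording$channel_labels[flat], collapse = ", "))
  }
  recording$data <- (recording$data - rowMeans(recording$data)) / s
  recording
}

#' Region-of-interest specification
#'
#' @param name ROI name (e.g. `"frontal"`, `"parietal"`).
#' @param members character vector of channel labels.
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(name, members) {
  if (length(members) == 0) stop("ROI must have at least one member channel")
  structure(list(name = name, members = unique(members)), class = "roi_spec")
}

#' Default frontal and parietal ROIs
#'
#' Configurable defaults: a fronto-central cluster around Fz and a
#' centro-parietal cluster around Pz, where responses to lexical-semantic
#' features typically peak. Electrode membership is a configuration
#' choice, not a fixed property -- override freely.
#'
#' @return A named list of two [roi_spec()] objects.
#' @export
default_rois <- function() {
  list(frontal = roi_spec("frontal", c("F3", "Fz", "F4", "FC1", "FC2")),
       parietal = roi_spec("parietal", c("P3", "Pz", "P4", "PO3", "PO4")))
}

#' Average values over an ROI's member channels
#'
#' @param values numeric vector (one value per channel) or matrix/array
#'   whose FIRST dimension indexes channels.
#' @param roi a [roi_spec()].
#' @param channel_labels labels naming the channel dimension of `values`.
#' @return `values` with the channel dimension collapsed by arithmetic
#'   mean over the ROI members.
#' @export
roi_average <- function(values, roi, channel_labels) {
  miss <- setdiff(roi$members, channel_labels)
  if (length(miss)) {
    stop("unknown channel(s) in ROI '", roi$name, "': ",
         paste(miss, collapse = ", "))
  }
  sel <- match(roi$members, channel_labels)
  if (is.null(dim(values))) return(mean(values[sel]))
  if (length(dim(values)) == 2) return(colMeans(values[sel, , drop = FALSE]))
  apply(values, seq_along(dim(values))[-1],
        function(v) mean(v[sel]))
}

#' Half-gain hearing-loss compensation profile
#'
#' Computes the per-frequency amplification gain A(f) that compensates
#' half the hearing loss above a 20 dB HL floor:
#' `A(f) = 0.5 * (T(f) - 20)` when the detection threshold `T(f)` exceeds
#' 20 dB HL, and 0 otherwise. Half-gain amplification restores audibility
#' while avoiding loudness-recruitment discomfort.
#'
#' @param thresholds data frame with columns `frequency_hz` and
#'   `threshold_db_hl` (finite).
#' @return The input with a `gain_db` column appended.
#' @export
half_gain_profile <- function(thresholds) {
  t_f <- thresholds$threshold_db_hl
  if (any(!is.finite(t_f))) stop("thresholds must be finite")
  thresholds$gain_db <- ifelse(t_f > 20, 0.5 * (t_f - 20), 0)
  thresholds
}
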