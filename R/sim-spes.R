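#' Simulate a SPES recording from a planted effective network
#'
#' Builds a multichannel time series (uV) plus an event list realizing the
#' single pulse electrical stimulation protocol: for every adjacent
#' stimulation pair, `n_pulses` monophasic pulses at 0.2 Hz. Channels
#' connected in the planted effective network to either stimulated contact
#' carry an evoked deflection — a damped half-sine of ~20 ms width — of the
#' configured amplitude peaking at the configured latency (negative polarity
#' for ECoG; random but channel-consistent polarity for sEEG). Every channel
#' receives a brief stimulus artifact spike at the pulse time and additive
#' white Gaussian noise.
#'
#' @param truth A `synthetic_truth` from [simulate_truth_networks()].
#' @param electrodes Electrode tibble used to build the truth.
#' @param config A [sim_config()]; `fs` must be at least 512 Hz.
#' @return An object of class `spes_recording`: list with `signal` (samples
#'   x channels matrix, uV), `fs`, `channels`, `events` (tibble: `onset_s`,
#'   `sample`, `site`, `anode`, `cathode`, `current_ma`), `modality`.
#' @export
simulate_spes_recording <- function(truth, electrodes, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  if (config$fs < 512) stop("SPES simulation requires fs >= 512 Hz.", call. = FALSE)
  fs <- config$fs
  channels <- electrodes$label[electrodes$included]
  n_ch <- length(channels)
  pairs <- truth$pairs
  np <- nrow(pairs)
  ec <- unclass(truth$ec_true)

  pulse_times <- 2 + (seq_len(np * config$n_pulses) - 1) * config$inter_pulse_s
  pair_of_pulse <- rep(seq_len(np), each = config$n_pulses)
  total_s <- max(pulse_times) + 2.5
  n_samp <- ceiling(total_s * fs)

  # damped half-sine deflection, unit peak amplitude
  width_s <- 0.020
  n_shape <- round(2 * width_s * fs)
  u <- seq_len(n_shape) / fs
  shape <- sin(pi * u / width_s) * exp(-u / width_s)
  shape[u > width_s] <- 0
  shape <- shape / max(abs(shape))

  # 1 ms stimulus artifact at t = 0
  n_art <- max(1, round(0.001 * fs))

  sig <- withr::with_seed(config$seed + 2L, {
    s <- if (config$noise_sd_uv > 0) {
      matrix(stats::rnorm(n_samp * n_ch, sd = config$noise_sd_uv), n_samp, n_ch)
    } else {
      matrix(0, n_samp, n_ch)
    }
    colnames(s) <- channels
    # per-channel response polarity: ECoG always negative, sEEG fixed per channel
    polarity <- if (config$modality == "ECoG") {
      rep(-1, n_ch)
    } else {
      sample(c(-1, 1), n_ch, replace = TRUE)
    }
    lat_off <- round(config$latency_ms / 1000 * fs) - which.max(abs(shape)) + 1
    for (k in seq_along(pulse_times)) {
      t0 <- round(pulse_times[k] * fs) + 1  # 1-based stimulus sample
      p <- pair_of_pulse[k]
      a <- pairs$anode[p]; b <- pairs$cathode[p]
      # artifact spike on all channels, larger on the stimulated contacts
      art_idx <- t0:min(t0 + n_art - 1, n_samp)
      s[art_idx, ] <- s[art_idx, ] + 500
      s[art_idx, c(a, b)] <- s[art_idx, c(a, b)] + 2000
      resp <- channels[(ec[a, channels] | ec[b, channels]) & !(channels %in% c(a, b))]
      for (ch in resp) {
        idx <- t0 + lat_off + seq_along(shape) - 1
        ok <- idx >= 1 & idx <= n_samp
        s[idx[ok], ch] <- s[idx[ok], ch] +
          polarity[match(ch, channels)] * config$amplitude_uv * shape[ok]
      }
    }
    s
  })

  current <- if (config$modality == "ECoG") 8 else 2
  events <- tibble::tibble(
    onset_s = pulse_times,
    sample = round(pulse_times * fs) + 1L,
    site = pairs$site[pair_of_pulse],
    anode = pairs$anode[pair_of_pulse],
    cathode = pairs$cathode[pair_of_pulse],
    current_ma = current
  )
  structure(list(signal = sig, fs = fs, channels = channels,
                 events = events, modality = config$modality),
            class = "spes_recording")
}

#' @export
print.spes_recording <- function(x, ...) {
  cat(sprintf("<spes_recording> %d channels (%s), %.1f s at %g Hz, %d stimuli over %d pairs\n",
              length(x$channels), x$modality, nrow(x$signal) / x$fs, x$fs,
              nrow(x$events), length(unique(x$events$site))))
  invisible(x)
}
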