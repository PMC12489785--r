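#' Epoch a SPES recording around each stimulus
#'
#' Cuts the recording into per-pulse epochs time-locked to the stimulus,
#' spanning `window` seconds around it as a half-open sample interval
#' (`[round(w1*fs), round(w2*fs))` relative to the stimulus sample). Epochs
#' that would run past either end of the recording are dropped and reported.
#' The two channels of the stimulated pair are marked non-analyzable for
#' their own trials (stimulation saturates them).
#'
#' @param recording A `spes_recording` ([simulate_spes_recording()] or
#'   [read_brainvision()] plus events).
#' @param window Numeric c(start, end) in seconds relative to the stimulus
#'   (default c(-2, 2)).
#' @return An object of class `spes_epochs`: `trials` tibble (`pair_id`,
#'   `site`, `anode`, `cathode`, `n_epochs`), `data` list of arrays
#'   (samples x channels x pulses), sample `times` (s, relative to the
#'   stimulus), `fs`, `channels`, `modality`, and `n_dropped`.
#' @export
epoch_trials <- function(recording, window = c(-2, 2)) {
  stopifnot(inherits(recording, "spes_recording"), length(window) == 2,
            window[1] < window[2])
  fs <- recording$fs
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1)
  ev <- recording$events
  stopifnot(all(c("sample", "site", "anode", "cathode") %in% names(ev)))
  if (is.unsorted(ev$sample)) stop("Events must be sorted by onset.", call. = FALSE)
  missing_ch <- setdiff(unique(c(ev$anode, ev$cathode)), recording$channels)
  if (length(missing_ch) > 0) {
    stop(sprintf("Stimulated contacts not among channels: %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  n_samp <- nrow(recording$signal)
  sites <- unique(ev$site)
  n_dropped <- 0L
  data <- vector("list", length(sites))
  trials <- tibble::tibble(pair_id = seq_along(sites), site = sites,
                           anode = NA_character_, cathode = NA_character_,
                           n_epochs = 0L)
  for (i in seq_along(sites)) {
    evi <- ev[ev$site == sites[i], , drop = FALSE]
    trials$anode[i] <- evi$anode[1]
    trials$cathode[i] <- evi$cathode[1]
    epochs <- list()
    for (s0 in evi$sample) {
      idx <- s0 + rel
      if (idx[1] < 1 || idx[length(idx)] > n_samp) { n_dropped <- n_dropped + 1L; next }
      epochs[[length(epochs) + 1]] <- recording$signal[idx, , drop = FALSE]
    }
    if (length(epochs) == 0) {
      stop(sprintf("All epochs dropped for stimulus pair %s.", sites[i]), call. = FALSE)
    }
    data[[i]] <- array(unlist(epochs, use.names = FALSE),
                       dim = c(length(rel), ncol(recording$signal), length(epochs)),
                       dimnames = list(NULL, recording$channels, NULL))
    trials$n_epochs[i] <- length(epochs)
  }
  if (n_dropped > 0) {
    message(sprintf("Dropped %d epoch(s) too close to the recording edge.", n_dropped))
  }
  structure(list(trials = trials, data = data, times = rel / fs, fs = fs,
                 channels = recording$channels, modality = recording$modality,
                 n_dropped = n_dropped),
            class = "spes_epochs")
}

#' Re-reference epochs to low-variance channels
#'
#' Within each trial, the non-stimulated channels are ranked by their signal
#' variance over the trial's epochs; the per-sample median of the
#' `max(1, round(fraction * n))` lowest-variance channels is subtracted from
#' every channel. This removes channel-common signal (drift, reference
#' artifacts) without letting high-amplitude evoked responses leak into the
#' reference.
#'
#' @param epochs A `spes_epochs` from [epoch_trials()].
#' @param fraction Fraction of analyzable channels used as reference
#'   (default 0.10).
#' @return The `spes_epochs` object with re-referenced data.
#' @export
rereference_epochs <- function(epochs, fraction = 0.10) {
  stopifnot(inherits(epochs, "spes_epochs"), fraction > 0, fraction <= 1)
  for (i in seq_len(nrow(epochs$trials))) {
    arr <- epochs$data[[i]]
    stim <- c(epochs$trials$anode[i], epochs$trials$cathode[i])
    analyzable <- setdiff(epochs$channels, stim)
    if (length(analyzable) < 2) {
      stop("Re-referencing requires at least 2 analyzable channels.", call. = FALSE)
    }
    v <- apply(arr[, analyzable, , drop = FALSE], 2,
               function(m) stats::var(as.vector(m)))
    n_ref <- max(1L, round(fraction * length(analyzable)))
    ref_ch <- analyzable[order(v)][seq_len(n_ref)]
    for (k in seq_len(dim(arr)[3])) {
      ref <- apply(arr[, ref_ch, k, drop = FALSE], 1, stats::median)
      arr[, , k] <- arr[, , k] - ref
    }
    epochs$data[[i]] <- arr
  }
  epochs
}

#' Average epochs into evoked response potentials
#'
#' Pointwise mean of the epochs of each (stimulus pair, channel), followed
#' by subtraction of the baseline median of the averaged trace; the baseline
#' SD is computed on the averaged, baseline-corrected trace. The baseline
#' window ends 0.1 s before the stimulus as a guard against artifact bleed.
#'
#' @param epochs A `spes_epochs` (typically re-referenced).
#' @param baseline Numeric c(start, end) of the baseline window in seconds
#'   relative to the stimulus (default c(-2, -0.1)).
#' @return A tibble of class `erp_set` with one row per (stimulus pair,
#'   channel): `site`, `anode`, `cathode`, `channel`, `waveform` (list
#'   column, baseline-corrected averaged trace), `baseline_median` (of the
#'   raw averaged trace), `baseline_sd`, `n_epochs`, `analyzable`.
#'   Sample times, sampling rate and modality ride along as attributes.
#' @export
average_erp <- function(epochs, baseline = c(-2, -0.1)) {
  stopifnot(inherits(epochs, "spes_epochs"), length(baseline) == 2,
            baseline[1] < baseline[2])
  bl_idx <- which(epochs$times >= baseline[1] & epochs$times <= baseline[2])
  if (length(bl_idx) < 2) stop("Baseline window contains fewer than 2 samples.", call. = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(epochs$trials)), function(i) {
    arr <- epochs$data[[i]]
    avg <- apply(arr, c(1, 2), mean)  # samples x channels
    stim <- c(epochs$trials$anode[i], epochs$trials$cathode[i])
    bl_med <- apply(avg[bl_idx, , drop = FALSE], 2, stats::median)
    corrected <- sweep(avg, 2, bl_med)
    bl_sd <- apply(corrected[bl_idx, , drop = FALSE], 2, stats::sd)
    tibble::tibble(
      site = epochs$trials$site[i],
      anode = epochs$trials$anode[i],
      cathode = epochs$trials$cathode[i],
      channel = epochs$channels,
      waveform = purrr::map(seq_along(epochs$channels), ~ corrected[, .x]),
      baseline_median = unname(bl_med),
      baseline_sd = unname(bl_sd),
      n_epochs = epochs$trials$n_epochs[i],
      analyzable = !(epochs$channels %in% stim)
    )
  })
  structure(rows, times = epochs$times, fs = epochs$fs,
            modality = epochs$modality, baseline = baseline,
            class = c("erp_set", class(rows)))
}

#' Detect cortico-cortical evoked potentials in averaged ERPs
#'
#' Searches each analyzable ERP for its extremum in the post-stimulus window
#' (9-100 ms by default): the most negative sample for ECoG (CCEPs present
#' as negative sharp potentials on grids), the largest-magnitude sample of
#' either polarity for sEEG. The response is a CCEP when its magnitude
#' strictly exceeds `k` times the baseline SD, with k = 2.6 for ECoG and
#' k = 3.5 for sEEG. Latency, amplitude and z-score are reported for every
#' ERP regardless of detection. A zero baseline SD (noiseless traces) is
#' flagged via `sd_zero`; the threshold inequality then reduces to "any
#' nonzero deflection".
#'
#' @param erps An `erp_set` from [average_erp()].
#' @param modality `"ECoG"` or `"sEEG"`; defaults to the ERP set's modality.
#' @param window_ms Detection window in ms after the stimulus (default
#'   c(9, 100)).
#' @param k Detection threshold in baseline SDs; defaults to 2.6 (ECoG) or
#'   3.5 (sEEG).
#' @return A tibble with one row per analyzable (stimulus pair, channel):
#'   `site`, `anode`, `cathode`, `channel`, `detected`, `latency_ms`,
#'   `amplitude_uv`, `z`, `sd_zero`.
#' @export
detect_ccep <- function(erps, modality = NULL, window_ms = c(9, 100), k = NULL) {
  stopifnot(inherits(erps, "erp_set"))
  modality <- modality %||% attr(erps, "modality")
  modality <- match.arg(modality, c("ECoG", "sEEG"))
  k <- k %||% if (modality == "ECoG") 2.6 else 3.5
  stopifnot(k > 0, length(window_ms) == 2, window_ms[1] < window_ms[2])
  times_ms <- attr(erps, "times") * 1000
  win <- which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
  if (length(win) == 0) stop("Detection window contains no samples.", call. = FALSE)
  det <- erps[erps$analyzable, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(nrow(det)), function(r) {
    w <- det$waveform[[r]][win]
    if (modality == "ECoG") {
      i <- which.min(w)
      amp <- w[i]
      extremum_ok <- amp < 0
    } else {
      i <- which.max(abs(w))
      amp <- w[i]
      extremum_ok <- TRUE
    }
    sd0 <- det$baseline_sd[r]
    z <- if (sd0 > 0) abs(amp) / sd0 else if (abs(amp) > 0) Inf else 0
    tibble::tibble(
      detected = extremum_ok && abs(amp) > k * sd0,
      latency_ms = times_ms[win[i]],
      amplitude_uv = amp,
      z = z,
      sd_zero = sd0 == 0
    )
  })
  dplyr::bind_cols(
    det[, c("site", "anode", "cathode", "channel")],
    res
  )
}

#' Build the bi-directional effective network from CCEP detections
#'
#' For every detected CCEP on channel c under stimulation of pair (a, b),
#' undirected edges a-c and b-c are added: the response cannot be attributed
#' to one contact of the pair, and symmetrization makes the effective
#' network comparable to the (undirected) structural network. Detections on
#' channels outside `nodes` are ignored with a warning.
#'
#' @param detections Detection tibble from [detect_ccep()].
#' @param nodes Character vector of included node labels (fixes node order).
#' @return A [binary_network()].
#' @export
build_effective_network <- function(detections, nodes) {
  stopifnot(is.character(nodes), length(nodes) >= 2)
  hits <- detections[detections$detected, , drop = FALSE]
  outside <- unique(hits$channel[!(hits$channel %in% nodes)])
  if (length(outside) > 0) {
    warning(sprintf("Ignoring detections on excluded channel(s): %s",
                    paste(outside, collapse = ", ")), call. = FALSE)
    hits <- hits[hits$channel %in% nodes, , drop = FALSE]
  }
  edges <- dplyr::bind_rows(
    tibble::tibble(from = hits$anode, to = hits$channel),
    tibble::tibble(from = hits$cathode, to = hits$channel)
  )
  edges <- edges[edges$from %in% nodes, , drop = FALSE]
  network_from_edges(edges, nodes)
}
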