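ramp_recording <- function(fs = 2048, n_ch = 3, dur_s = 14) {
  n <- fs * dur_s
  sig <- matrix(rep(seq_len(n), n_ch), n, n_ch,
                dimnames = list(NULL, c("a", "b", "c")))
  events <- tibble::tibble(onset_s = 10, sample = 10L * fs + 1L,
                           site = "a-b", anode = "a", cathode = "b",
                           current_ma = 8)
  structure(list(signal = sig, fs = fs, channels = c("a", "b", "c"),
                 events = events, modality = "ECoG"),
            class = "spes_recording")
}

test_that("epochs are half-open sample windows time-locked to the stimulus", {
  rec <- ramp_recording()
  ep <- epoch_trials(rec)
  arr <- ep$data[[1]]
  expect_equal(dim(arr), c(4 * 2048, 3, 1))
  # event at t = 10 s, fs = 2048: 0-based samples [16384, 24576)
  expect_equal(unname(arr[1, "c", 1]), 16385)        # 1-based value of the ramp
  expect_equal(unname(arr[dim(arr)[1], "c", 1]), 24576)
  expect_equal(ep$times[1], -2)
  # constant signal -> constant epochs
  rec2 <- ramp_recording(); rec2$signal[] <- 7
  expect_true(all(epoch_trials(rec2)$data[[1]] == 7))
})

test_that("epochs too close to the recording edge are dropped and reported", {
  rec <- ramp_recording()
  rec$events <- dplyr::bind_rows(
    rec$events,
    tibble::tibble(onset_s = 13.5, sample = as.integer(13.5 * 2048) + 1L,
                   site = "a-b", anode = "a", cathode = "b", current_ma = 8))
  expect_message(ep <- epoch_trials(rec), "Dropped 1 epoch")
  expect_equal(ep$trials$n_epochs, 1L)
})

test_that("ten pulses per pair give ten epochs", {
  cfg <- sim_config("sEEG", n_shafts = 1, contacts_per_shaft = 4, fs = 512,
                    noise_sd_uv = 1, seed = 2)
  tr <- simulate_truth_networks(cfg)
  rec <- simulate_spes_recording(tr, simulate_electrodes(cfg), cfg)
  ep <- epoch_trials(rec)
  expect_true(all(ep$trials$n_epochs == 10L))
})

test_that("re-referencing removes channel-common drift and keeps zeros at zero", {
  fs <- 512
  n <- fs * 14
  drift <- 3 * sin(2 * pi * 0.2 * seq_len(n) / fs)
  n_ch <- 20
  sig <- matrix(drift, n, n_ch)  # identical drift on all channels
  colnames(sig) <- sprintf("c%02d", 1:n_ch)
  events <- tibble::tibble(onset_s = 10, sample = 10L * fs + 1L,
                           site = "c01-c02", anode = "c01", cathode = "c02",
                           current_ma = 2)
  rec <- structure(list(signal = sig, fs = fs, channels = colnames(sig),
                        events = events, modality = "sEEG"),
                   class = "spes_recording")
  ep <- rereference_epochs(epoch_trials(rec))
  expect_true(all(abs(ep$data[[1]]) < 1e-10))
  # 18 analyzable channels -> round(1.8) = 2 reference channels
  sig0 <- sig; sig0[] <- 0
  rec0 <- rec; rec0$signal <- sig0
  ep0 <- rereference_epochs(epoch_trials(rec0))
  expect_true(all(ep0$data[[1]] == 0))
})

test_that("ERP averaging subtracts the baseline median and reports baseline SD", {
  fs <- 512
  rel <- seq(-2 * fs, 2 * fs - 1)
  wave <- ifelse(rel >= 0, -40, 5)  # step with a nonzero baseline
  arr <- array(rep(wave, 10), dim = c(length(rel), 1, 10),
               dimnames = list(NULL, "c1", NULL))
  epochs <- structure(list(
    trials = tibble::tibble(pair_id = 1L, site = "x-y", anode = "x",
                            cathode = "y", n_epochs = 10L),
    data = list(arr), times = rel / fs, fs = fs,
    channels = "c1", modality = "ECoG", n_dropped = 0L
  ), class = "spes_epochs")
  erp <- average_erp(epochs)
  expect_equal(erp$baseline_median, 5)
  expect_equal(erp$waveform[[1]][1], 0)       # corrected baseline
  expect_equal(erp$baseline_sd, 0)
  # +1 and -1 epochs cancel
  arr2 <- array(c(rep(1, length(rel)), rep(-1, length(rel))),
                dim = c(length(rel), 1, 2), dimnames = list(NULL, "c1", NULL))
  epochs$data <- list(arr2); epochs$trials$n_epochs <- 2L
  expect_true(all(average_erp(epochs)$waveform[[1]] == 0))
})

test_that("averaging ten noisy epochs shrinks the baseline SD by sqrt(10)", {
  fs <- 512
  rel <- seq(-2 * fs, 2 * fs - 1)
  sigma <- 8
  sds <- withr::with_seed(5, {
    replicate(30, {
      arr <- array(stats::rnorm(length(rel) * 10, sd = sigma),
                   dim = c(length(rel), 1, 10), dimnames = list(NULL, "c1", NULL))
      epochs <- structure(list(
        trials = tibble::tibble(pair_id = 1L, site = "x-y", anode = "x",
                                cathode = "y", n_epochs = 10L),
        data = list(arr), times = rel / fs, fs = fs,
        channels = "c1", modality = "ECoG", n_dropped = 0L
      ), class = "spes_epochs")
      average_erp(epochs)$baseline_sd
    })
  })
  expect_equal(mean(sds), sigma / sqrt(10), tolerance = 0.05)
})

make_erp_row <- function(waveform, fs, baseline_sd, modality = "ECoG") {
  rel <- seq(-2 * fs, 2 * fs - 1)
  stopifnot(length(waveform) == length(rel))
  rows <- tibble::tibble(
    site = "x-y", anode = "x", cathode = "y", channel = "c1",
    waveform = list(waveform), baseline_median = 0,
    baseline_sd = baseline_sd, n_epochs = 10L, analyzable = TRUE
  )
  structure(rows, times = rel / fs, fs = fs, modality = modality,
            baseline = c(-2, -0.1), class = c("erp_set", class(rows)))
}

test_that("CCEP detection applies modality thresholds, polarity and latency window", {
  fs <- 2048
  rel <- seq(-2 * fs, 2 * fs - 1)
  trough_at <- function(lat_ms, amp) {
    w <- numeric(length(rel))
    w[which.min(abs(rel / fs - lat_ms / 1000))] <- amp
    w
  }
  # ECoG: trough -6 uV on baseline SD 2 -> z = 3 >= 2.6: detected
  d1 <- detect_ccep(make_erp_row(trough_at(40, -6), fs, 2, "ECoG"))
  expect_true(d1$detected)
  expect_equal(d1$z, 3)
  expect_equal(d1$latency_ms, 40, tolerance = 1)
  # same trace under sEEG thresholds: z = 3 < 3.5: not detected
  d2 <- detect_ccep(make_erp_row(trough_at(40, -6), fs, 2, "sEEG"))
  expect_false(d2$detected)
  # ECoG ignores positive deflections regardless of size
  d3 <- detect_ccep(make_erp_row(trough_at(40, 20), fs, 2, "ECoG"))
  expect_false(d3$detected)
  # sEEG accepts either polarity
  d4 <- detect_ccep(make_erp_row(trough_at(40, 20), fs, 2, "sEEG"))
  expect_true(d4$detected)
  # deflection at 150 ms lies outside the 9-100 ms window
  d5 <- detect_ccep(make_erp_row(trough_at(150, -50), fs, 2, "ECoG"))
  expect_false(d5$detected)
  # zero baseline SD: literal inequality, flagged
  d6 <- detect_ccep(make_erp_row(trough_at(40, -6), fs, 0, "ECoG"))
  expect_true(d6$detected)
  expect_true(d6$sd_zero)
})

test_that("detection is monotone in response amplitude", {
  fs <- 512
  rel <- seq(-2 * fs, 2 * fs - 1)
  base <- numeric(length(rel))
  i <- which.min(abs(rel / fs - 0.04))
  zs <- vapply(c(1, 3, 6, 12), function(a) {
    w <- base; w[i] <- -a
    detect_ccep(make_erp_row(w, fs, 2, "ECoG"))$z
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("the effective network draws edges from both stimulated contacts", {
  det <- tibble::tibble(site = "a-b", anode = "a", cathode = "b",
                        channel = "c", detected = TRUE, latency_ms = 30,
                        amplitude_uv = -20, z = 5, sd_zero = FALSE)
  net <- build_effective_network(det, c("a", "b", "c", "d"))
  expect_true(net["a", "c"] && net["b", "c"])
  expect_equal(sum(net["c", ]), 2)  # EC degree of the responding channel
  expect_equal(sum(net) / 2, 2)
  # no detections -> empty network
  net0 <- build_effective_network(det[det$z > 10, ], c("a", "b", "c"))
  expect_equal(sum(net0), 0)
  # detections on excluded channels are ignored with a warning
  det2 <- det; det2$channel <- "zz"
  expect_warning(net2 <- build_effective_network(det2, c("a", "b", "c")),
                 "excluded channel")
  expect_equal(sum(net2), 0)
})

test_that("high-SNR synthetic recordings recover every planted effective edge", {
  cfg <- sim_config("sEEG", n_shafts = 2, contacts_per_shaft = 8, fs = 512,
                    amplitude_uv = 200, noise_sd_uv = 5, seed = 12)
  el <- simulate_electrodes(cfg)
  tr <- simulate_truth_networks(cfg, el)
  rec <- simulate_spes_recording(tr, el, cfg)
  ep <- rereference_epochs(epoch_trials(rec))
  det <- detect_ccep(average_erp(ep))
  net <- build_effective_network(det, el$label)
  expect_true(all(unclass(net)[unclass(tr$ec_true)]))  # sensitivity 1
})
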