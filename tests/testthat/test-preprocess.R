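# hand-built recording helper: arbitrary data matrix on a montage
make_rec <- function(data, mont, fs = 256, events = NULL) {
  rownames(data) <- mont$channels$name
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), from = character(0),
                         to = character(0))
  structure(list(data = data, fs = fs, channels = mont$channels$name,
                 montage = mont, events = events, gain = 1),
            class = "eeg_recording")
}

test_that("mastoid-average re-referencing removes common mode", {
  mont <- montage("biosemi16")
  n_ch <- nrow(mont$channels)
  set.seed(1)
  # mastoids already zero: unchanged
  d <- matrix(rnorm(n_ch * 100), n_ch, 100)
  d[match(c("M1", "M2"), mont$channels$name), ] <- 0
  rec <- make_rec(d, mont)
  expect_equal(rereference(rec)$data, rec$data)
  # constant offset on all channels vanishes
  rec2 <- make_rec(matrix(7.5, n_ch, 50), mont)
  expect_true(all(rereference(rec2)$data == 0))
  # random data: output mastoid average identically zero
  rec3 <- make_rec(matrix(rnorm(n_ch * 200), n_ch, 200), mont)
  out <- rereference(rec3)
  mast <- colMeans(out$data[mont$mastoids, ])
  expect_lt(max(abs(mast)), 1e-12)
  # missing mastoids
  rec4 <- rec3
  rec4$channels <- setdiff(rec4$channels, "M1")
  rec4$data <- rec4$data[rec4$channels, ]
  expect_error(rereference(rec4), "mastoid")
})

test_that("band-limiting passes 10 Hz, removes DC, and stops 100 Hz", {
  mont <- montage("biosemi16")
  fs <- 512
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  mid <- seq(round(20 * fs), round(40 * fs))
  x10 <- sin(2 * pi * 10 * t)
  x100 <- sin(2 * pi * 100 * t)
  d <- matrix(0, nrow(mont$channels), length(t))
  d[1, ] <- x10
  d[2, ] <- x100
  d[3, ] <- 1          # pure DC
  rec <- bandpass(make_rec(d, mont, fs = fs))
  ratio10 <- max(abs(rec$data[1, mid]))
  expect_gt(ratio10, 0.95)
  expect_lt(ratio10, 1.05)
  att100 <- 20 * log10(max(abs(rec$data[2, mid])))
  expect_lt(att100, -20)
  expect_lt(max(abs(rec$data[3, mid])), 0.01)
  expect_error(bandpass(make_rec(d, mont, fs = fs), high = 300), "Nyquist")
})

test_that("posterior channels are dropped and bad channels interpolated", {
  mont32 <- montage("biosemi32")
  n_ch <- nrow(mont32$channels)
  set.seed(2)
  rec <- make_rec(matrix(rnorm(n_ch * 100), n_ch, 100), mont32)
  out <- drop_and_interpolate(rec)
  expect_equal(length(rec$channels) - length(out$channels), 12)  # 10 + mastoids
  expect_false(any(c("O1", "Oz", "O2", "P3", "Pz", "P4",
                     "PO3", "PO4", "P7", "P8") %in% out$channels))
  kept <- intersect(rec$channels, out$channels)
  expect_equal(out$data[kept, ], rec$data[kept, ])
  # constant field: interpolated channel equals the constant
  rec2 <- make_rec(matrix(3.25, n_ch, 10), mont32)
  out2 <- drop_and_interpolate(rec2, bad_channels = "C3")
  expect_equal(unname(out2$data["C3", ]), rep(3.25, 10))
  expect_error(drop_and_interpolate(rec, bad_channels = "XX"), "montage")
})

test_that("epoching subtracts the baseline exactly and rejects on threshold", {
  mont <- montage("biosemi16")
  fs <- 256
  model <- data.frame(from = "a", to = "i", amplitude_uv = 5)
  set.seed(3)
  onsets <- cumsum(runif(100, 0.6, 0.7))
  events <- data.frame(onset_s = onsets, from = "a", to = "i")
  nm <- noise_model(pink_rms = 5, white_rms = 0.5, blink_rate = 0)
  rec <- simulate_recording(events, model, mont, noise = nm, fs = fs, seed = 8)
  ep <- epoch_and_reject(rec, threshold = 150)
  expect_equal(sum(ep$retained), 100L)                    # clean recording
  # window spans -100..+350 ms up to sample quantization
  expect_lt(max(abs(range(ep$times) - c(-0.100, 0.350))), 0.5 / fs)
  # baseline contract: pre-stimulus mean is zero to machine precision
  base <- apply(ep$data[, ep$times < 0, ], c(1, 3), mean)
  expect_lt(max(abs(base)), 1e-9)
  # plant one 200 uV blink inside epoch 17 only: exactly that epoch rejected
  rec2 <- rec
  i0 <- round((onsets[17] + 0.1) * fs)
  rec2$data["Fp1", i0:(i0 + 10)] <- rec2$data["Fp1", i0:(i0 + 10)] + 200
  ep2 <- epoch_and_reject(rec2, threshold = 150)
  expect_identical(which(!ep2$retained), 17L)
  # all epochs rejected is an error, not silence
  rec3 <- rec
  # oscillation (a constant would be removed by the baseline subtraction)
  rec3$data[1, ] <- 1e4 * sin(2 * pi * 7 * seq_len(ncol(rec3$data)) / fs)
  expect_error(epoch_and_reject(rec3, threshold = 150), "empty|retained")
})

test_that("subject inclusion applies the 1800-trial cutoff to event counts", {
  expect_false(include_subjects(1500))
  expect_true(include_subjects(1800))
  expect_equal(include_subjects(c(s1 = 2879, s2 = 1500, s3 = 1799)),
               c(s1 = TRUE, s2 = FALSE, s3 = FALSE))
})

test_that("re-reference and filtering commute on linear data", {
  mont <- montage("biosemi16")
  fs <- 256
  n_ch <- nrow(mont$channels)
  set.seed(9)
  d <- matrix(rnorm(n_ch * fs * 20), n_ch, fs * 20)
  events <- data.frame(onset_s = seq(2, 18, by = 0.5), from = "a", to = "i")
  rec <- make_rec(d, mont, fs = fs, events = events)
  a <- epoch_and_reject(bandpass(rereference(rec)), threshold = NULL)
  b <- epoch_and_reject(rereference(bandpass(rec)), threshold = NULL)
  # floating-point only: the 0.1 Hz high-pass amplifies round-off a little
  expect_lt(max(abs(a$data - b$data)), 1e-5)
})
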