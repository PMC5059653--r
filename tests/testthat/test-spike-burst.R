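# spike detection, overlap windows, burst segmentation, ISI analytics

test_that("spikes are upward crossings of multiples of 2*pi", {
  t <- seq(0, 3, by = 0.001)
  traj <- constructed_traj(t, 2 * pi * t)      # 0 -> 6*pi over 3 ms
  sp <- detect_spikes(traj)
  expect_length(sp, 3)
  expect_equal(as.numeric(sp), c(1, 2, 3), tolerance = 1e-9)

  flat <- constructed_traj(t, rep(1.5, length(t)))
  expect_length(detect_spikes(flat), 0)
})

test_that("hysteresis counts a dip-and-recross once, a full retreat twice", {
  # rise through 2*pi, dip 0.4 rad back below it, re-cross: one spike
  th <- c(seq(0, 6.4, length.out = 65), seq(6.4, 6.0, length.out = 5),
          seq(6.0, 6.5, length.out = 6))
  t <- seq_along(th) * 0.01
  expect_length(detect_spikes(constructed_traj(t, th)), 1)
  # same but continuing to 4*pi after arming below 3*pi: second spike
  th2 <- c(th, seq(6.5, 13, length.out = 66))
  t2 <- seq_along(th2) * 0.01
  expect_length(detect_spikes(constructed_traj(t2, th2)), 2)
})

test_that("steady overlap windows match the closed-form roots", {
  w <- overlap_windows(default_set, 35, c(0, 6 * 2 * pi / 0.0503586))
  pv <- eval_params(default_set, 35)
  width <- (2 * pi - 2 * acos((pv$b - 1) / (2 * pv$A))) / pv$Omega
  expect_equal(attr(w, "delta"), width, tolerance = 1e-6)
  expect_equal(attr(w, "delta"), 22.54, tolerance = 1e-3)
  # one window per modulation cycle
  expect_equal(nrow(w), 6)
  expect_equal(diff(w$start), rep(2 * pi / pv$Omega, 5), tolerance = 1e-9)
})

test_that("overlap windows handle the always/never limits", {
  always <- linear_param_set(2.2, 0, 0.5, 0, 0.05, 0)   # b - 1 > 2A
  w1 <- overlap_windows(always, 20, c(0, 100))
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(0, 100))

  never <- linear_param_set(0.3, 0, 0.2, 0, 0.05, 0)    # b - 1 < -2A
  expect_equal(nrow(overlap_windows(never, 20, c(0, 100))), 0)
})

test_that("closed-form and sign-change-scan windows agree below dt", {
  cfg <- simulation_config(dt = 0.01, t_end = 600)
  traj <- simulate_steady(default_set, 35, cfg)
  w_closed <- overlap_windows(traj)                     # closed form
  w_scan <- coldburst:::overlap_windows_scan(traj, default_set)
  keep <- w_scan$start > 0 & w_scan$end < 600           # unclipped windows
  expect_equal(nrow(w_closed[w_closed$start > 0 & w_closed$end < 600, ]),
               sum(keep))
  expect_lt(max(abs(w_scan$width[keep] -
                    w_closed$width[seq_len(sum(keep))])), 0.01)
  expect_lt(abs(attr(w_scan, "delta") - attr(w_closed, "delta")), 0.01)
})

test_that("burst segmentation assigns spikes and derives SB/BP", {
  sp <- spike_train(c(10, 12, 14, 130, 132), span = c(0, 200))
  w <- structure(data.frame(start = c(5, 125), end = c(20, 140),
                            width = c(15, 15)),
                 class = c("overlap_windows", "data.frame"))
  b <- segment_bursts(sp, w)
  expect_equal(b$SB, c(3L, 2L))
  expect_equal(b$BP, 118)
  expect_equal(b$BP_time, (14 + 132) / 2)
  expect_equal(b$SB_time, c(14, 132))

  empty <- segment_bursts(spike_train(numeric(0), c(0, 10)), w)
  expect_equal(nrow(empty$bursts), 0)
  expect_length(empty$BP, 0)
})

test_that("stray spikes warn and attach to the nearest window", {
  sp <- spike_train(c(10, 60, 130), span = c(0, 200))
  w <- structure(data.frame(start = c(5, 125), end = c(20, 140),
                            width = c(15, 15)),
                 class = c("overlap_windows", "data.frame"))
  expect_warning(b <- segment_bursts(sp, w), "nearest")
  expect_equal(b$SB, c(2L, 1L))   # 60 ms spike joins the first window
})

test_that("steady bursting at 35 degC has one burst per modulation cycle", {
  st <- steady_burst_stats(default_set, 35)
  pv <- eval_params(default_set, 35)
  expect_equal(mean(st$bursts$BP), 2 * pi / pv$Omega, tolerance = 1e-3)
  # every detected spike lies inside a dilated overlap window
  for (Te in c(15, 25, 40)) {
    stT <- steady_burst_stats(default_set, Te)
    w <- stT$windows
    inside <- vapply(as.numeric(stT$spikes), function(s)
      any(s >= w$start - 2 & s <= w$end + 2), logical(1))
    expect_true(all(inside))
  }
})

test_that("SB is monotone nonincreasing across the steady sweep", {
  sb <- vapply(seq(15, 40, by = 5), function(Te)
    steady_burst_stats(default_set, Te)$mean_SB, numeric(1))
  expect_true(all(diff(sb) <= 0))
  expect_gt(sb[1], sb[6])
})

test_that("ISI histogram conserves counts and bins uniformly", {
  h <- isi_histogram(spike_train(c(0, 2, 4, 10)), bin_width = 2)
  expect_equal(h$isi, c(2, 2, 6))
  expect_equal(sum(h$counts), 3)
  expect_equal(h$bin_edges, c(0, 2, 4, 6))
  expect_equal(h$counts, c(2L, 0L, 1L))

  expect_length(isi_histogram(spike_train(5))$counts, 0)
  expect_length(isi_histogram(spike_train(numeric(0), c(0, 1)))$counts, 0)
  expect_error(isi_histogram(spike_train(c(0, 1)), bin_width = 0))

  # counts always sum to spikes - 1 on simulated trains
  st <- steady_burst_stats(default_set, 25)
  h2 <- isi_histogram(st$spikes)
  expect_equal(sum(h2$counts), length(st$spikes) - 1L)
})

test_that("large ISIs mark the warm regime but not the cold one", {
  warm <- steady_burst_stats(default_set, 40)
  cold <- steady_burst_stats(default_set, 15)
  period_warm <- 2 * pi / eval_params(default_set, 40)$Omega
  period_cold <- 2 * pi / eval_params(default_set, 15)$Omega
  expect_gt(max(warm$isi), 0.95 * period_warm)  # beating/skipping intervals
  expect_lt(max(cold$isi), 0.9 * period_cold)
})

test_that("ISI clusters split on the single-linkage gap", {
  sp <- spike_train(c(0, 2, 4.05, 6, 20, 34.2))
  # ISIs: 2, 2.05, 1.95, 14, 14.2 -> clusters {~2}, {~14.1}
  cl <- isi_clusters(sp, gap = 1)
  expect_length(cl, 2)
  expect_equal(cl, c(2, 14.1), tolerance = 1e-2)
  expect_length(isi_clusters(spike_train(3)), 0)
})

test_that("spike and burst tables round-trip as TSV", {
  sp <- spike_train(c(1.25, 3.5, 9), span = c(0, 10))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_spike_times(sp, p)
  back <- read_spike_times(p)
  expect_equal(as.numeric(back), as.numeric(sp), tolerance = 1e-6)

  w <- structure(data.frame(start = 0, end = 10, width = 10),
                 class = c("overlap_windows", "data.frame"))
  b <- segment_bursts(sp, w)
  write_burst_summary(b, p)
  expect_equal(readLines(p)[1], "onset\toffset\tcount\tlast_spike")
  write_isi_histogram(isi_histogram(sp), p)
  expect_equal(readLines(p)[1], "bin_left\tbin_right\tcount")
  expect_error(spike_train(c(2, 1)), "increasing")
})
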