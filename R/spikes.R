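#' Spike trains
#'
#' A spike train is a strictly increasing vector of spike times (ms)
#' together with the time span it was observed on.
#'
#' @param times numeric vector of spike times, ms, strictly increasing.
#' @param span length-2 numeric, observation window (ms).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, span = range(times, 0)) {
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0))
    stop("spike_train: times must be strictly increasing", call. = FALSE)
  if (length(times) &&
      (min(times) < span[1] - 1e-9 || max(times) > span[2] + 1e-9))
    stop("spike_train: times outside span", call. = FALSE)
  structure(times, span = as.numeric(span), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes on [%.4g, %.4g] ms\n",
              length(x), attr(x, "span")[1], attr(x, "span")[2]))
  invisible(x)
}

#' Detect spikes from a phase trajectory
#'
#' A spike is an upward crossing of the unwrapped phase `theta` through a
#' multiple of `2*pi` (one full rotation = one action potential).  The
#' crossing time is linearly interpolated between samples.  A hysteresis
#' rule makes detection robust against grazing dynamics near fixed
#' points: after a threshold is crossed, the next threshold only arms
#' once `theta` is at least `pi` below it, so a trajectory that dips back
#' below a just-crossed multiple of `2*pi` and re-crosses it is counted
#' once.
#'
#' @param traj a `trajectory` from [simulate_steady()] /
#'   [simulate_transition()], or any data frame with columns `t` and
#'   `theta` (unwrapped radians).
#' @return A [spike_train()] (possibly empty).
#' @export
detect_spikes <- function(traj) {
  t <- traj$t
  th <- traj$theta
  n <- length(t)
  if (n < 2L) return(spike_train(numeric(0), span = c(0, 0)))
  two_pi <- 2 * pi
  thr <- two_pi * (floor(th[1] / two_pi) + 1)
  armed <- th[1] <= thr - pi
  times <- numeric(0)
  for (i in 2:n) {
    if (!armed && th[i] <= thr - pi) armed <- TRUE
    while (armed && th[i] >= thr) {
      frac <- if (th[i] == th[i - 1]) 1 else (thr - th[i - 1]) /
        (th[i] - th[i - 1])
      frac <- min(max(frac, 0), 1)
      times <- c(times, t[i - 1] + frac * (t[i] - t[i - 1]))
      thr <- thr + two_pi
      armed <- th[i] <= thr - pi
    }
  }
  # numerically coincident crossings cannot occur on a strictly
  # increasing grid, but guard against ties from interpolation round-off
  if (length(times) > 1L) times <- times[c(TRUE, diff(times) > 0)]
  spike_train(times, span = range(t))
}

new_overlap_windows <- function(start, end, span) {
  df <- data.frame(start = start, end = end, width = end - start)
  structure(df, span = span, delta = if (nrow(df)) max(df$width) else 0,
            class = c("overlap_windows", "data.frame"))
}

#' Burst (overlap) windows where f1 exceeds f2
#'
#' A burst is in progress while `f1 > f2`, i.e. while
#' `b - 1 - 2*A*cos(phi) > 0`.  For a steady parameter set the window
#' edges are the closed-form roots `cos(phi) = (b - 1)/(2*A)` mapped to
#' time through `phi = Omega*t`; for a trajectory (e.g. a transient run)
#' the sign changes of the recorded `f1 - f2` are located by linear
#' interpolation.  The attribute `delta` holds the maximum window width,
#' the quantity the mean spikes-per-burst is proportional to.
#'
#' @param x a parameter set (then give `Teff` and `span`) or a
#'   `trajectory`.
#' @param ... passed to methods.
#' @return A data frame of class `overlap_windows` with columns `start`,
#'   `end`, `width` (ms) and attributes `span`, `delta`.  May have zero
#'   rows.
#' @export
overlap_windows <- function(x, ...) UseMethod("overlap_windows")

#' @rdname overlap_windows
#' @param Teff steady effective temperature, degC.
#' @param span length-2 numeric time window, ms.
#' @export
overlap_windows.param_set <- function(x, Teff, span, ...) {
  stopifnot(is.numeric(span), length(span) == 2L, span[2] > span[1])
  pv <- eval_params(x, Teff)
  b <- pv$b; A <- pv$A; Om <- abs(pv$Omega)  # cos is even in Omega*t
  if (A <= 0 || Om == 0) {
    always <- (b - 1 - 2 * A * cos(0)) > 0 || (A > 0 && (b - 1) / (2 * A) >= 1)
    if (A == 0) always <- b - 1 > 0
    return(if (always) new_overlap_windows(span[1], span[2], span)
           else new_overlap_windows(numeric(0), numeric(0), span))
  }
  thr <- (b - 1) / (2 * A)
  if (thr >= 1) return(new_overlap_windows(span[1], span[2], span))
  if (thr <= -1) return(new_overlap_windows(numeric(0), numeric(0), span))
  cang <- acos(thr)                     # window: phi in (cang, 2*pi - cang)
  period <- 2 * pi / Om
  k <- seq(floor(span[1] / period) - 1, ceiling(span[2] / period) + 1)
  start <- (cang + 2 * pi * k) / Om
  end <- (2 * pi - cang + 2 * pi * k) / Om
  keep <- end > span[1] & start < span[2]
  start <- pmax(start[keep], span[1])
  end <- pmin(end[keep], span[2])
  new_overlap_windows(start, end, span)
}

#' @rdname overlap_windows
#' @export
overlap_windows.trajectory <- function(x, ...) {
  pset <- attr(x, "pset")
  if (attr(x, "kind") == "steady" && !is.null(pset))
    return(overlap_windows(pset, x$Teff[1], range(x$t)))
  overlap_windows_scan(x, pset)
}

# numerical sign-change scan of f1 - f2 along a trajectory
overlap_windows_scan <- function(traj, pset) {
  if (is.null(pset)) stop("trajectory lacks its parameter set", call. = FALSE)
  pv <- eval_params(pset, traj$Teff)
  g <- pv$b - 1 - 2 * pv$A * cos(traj$phi)
  t <- traj$t
  pos <- g > 0
  n <- length(t)
  span <- range(t)
  if (!any(pos)) return(new_overlap_windows(numeric(0), numeric(0), span))
  r <- rle(pos)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  iw <- which(r$values)
  cross <- function(i, j) {
    # root of g between samples i < j (g[i], g[j] opposite signs)
    t[i] + (0 - g[i]) / (g[j] - g[i]) * (t[j] - t[i])
  }
  start <- end <- numeric(length(iw))
  for (m in seq_along(iw)) {
    i0 <- starts_i[iw[m]]; i1 <- ends_i[iw[m]]
    start[m] <- if (i0 == 1L) t[1] else cross(i0 - 1L, i0)
    end[m] <- if (i1 == n) t[n] else cross(i1, i1 + 1L)
  }
  new_overlap_windows(start, end, span)
}

#' Segment spikes into bursts
#'
#' Spikes are assigned to overlap windows dilated by `dilate` ms on each
#' side (a rotation begun just inside a window completes just after it);
#' windows that catch no spikes are dropped.  Spikes falling outside all
#' dilated windows raise a warning and are assigned to the nearest
#' window.  Per-burst records carry onset/offset (the undilated window),
#' spike count and last spike time.  The derived series are `SB` (spikes
#' per burst, reported at the burst's last spike) and `BP` (burst period
#' = time between consecutive bursts' last spikes, reported at the
#' midtime of the pair).
#'
#' @param spikes a [spike_train()].
#' @param windows an [overlap_windows()] result.
#' @param dilate window dilation, ms; default 2.
#' @return An object of class `burst_summary`: a list with `bursts` (data
#'   frame `onset`, `offset`, `spike_count`, `last_spike`), `SB`,
#'   `SB_time`, `BP`, `BP_time`.
#' @export
segment_bursts <- function(spikes, windows, dilate = 2) {
  stopifnot(inherits(windows, "data.frame"))
  nw <- nrow(windows)
  if (length(spikes) == 0L || nw == 0L) {
    bursts <- data.frame(onset = numeric(0), offset = numeric(0),
                         spike_count = integer(0), last_spike = numeric(0))
    return(structure(list(bursts = bursts, SB = integer(0),
                          SB_time = numeric(0), BP = numeric(0),
                          BP_time = numeric(0)),
                     class = "burst_summary"))
  }
  lo <- windows$start - dilate
  hi <- windows$end + dilate
  assign_idx <- integer(length(spikes))
  outside <- FALSE
  for (i in seq_along(spikes)) {
    s <- unclass(spikes)[i]
    inw <- which(s >= lo & s <= hi)
    if (length(inw)) {
      assign_idx[i] <- inw[1]
    } else {
      outside <- TRUE
      d <- pmax(lo - s, 0) + pmax(s - hi, 0)
      assign_idx[i] <- which.min(d)
    }
  }
  if (outside)
    warning("segment_bursts: spike(s) outside all dilated windows; ",
            "assigned to the nearest window", call. = FALSE)
  keep <- sort(unique(assign_idx))
  bursts <- do.call(rbind, lapply(keep, function(k) {
    s <- unclass(spikes)[assign_idx == k]
    data.frame(onset = windows$start[k], offset = windows$end[k],
               spike_count = length(s), last_spike = max(s))
  }))
  o <- order(bursts$onset)
  bursts <- bursts[o, , drop = FALSE]
  rownames(bursts) <- NULL
  ls <- bursts$last_spike
  BP <- diff(ls)
  structure(list(bursts = bursts,
                 SB = bursts$spike_count, SB_time = ls,
                 BP = BP,
                 BP_time = if (length(BP)) (ls[-length(ls)] + ls[-1]) / 2
                           else numeric(0)),
            class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  cat(sprintf("<burst_summary> %d bursts; mean SB = %.3g; mean BP = %.4g ms\n",
              nrow(x$bursts),
              if (length(x$SB)) mean(x$SB) else NA,
              if (length(x$BP)) mean(x$BP) else NA))
  print(utils::head(x$bursts, 6L))
  if (nrow(x$bursts) > 6L) cat("...\n")
  invisible(x)
}

#' Interspike-interval histogram
#'
#' ISIs are the consecutive differences of the spike times; the histogram
#' uses uniform bins of width `bin_width` covering `[0, max(ISI)]` with
#' left-open, right-closed bins, so the counts always sum to the number
#' of intervals.  Fewer than two spikes give an empty histogram.
#'
#' @param spikes a [spike_train()] (or numeric spike times).
#' @param bin_width bin width, ms; default 2.
#' @return An object of class `isi_histogram`: list with `bin_edges`,
#'   `counts` and the raw `isi` vector.
#' @export
isi_histogram <- function(spikes, bin_width = 2) {
  stopifnot(is.numeric(bin_width), bin_width > 0)
  s <- as.numeric(spikes)
  if (length(s) < 2L)
    return(structure(list(bin_edges = numeric(0), counts = integer(0),
                          isi = numeric(0), bin_width = bin_width),
                     class = "isi_histogram"))
  isi <- diff(s)
  edges <- seq(0, bin_width * ceiling(max(isi) / bin_width), by = bin_width)
  if (length(edges) < 2L) edges <- c(0, bin_width)
  counts <- tabulate(findInterval(isi, edges, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = as.integer(counts), isi = isi,
                 bin_width = bin_width),
            class = "isi_histogram")
}

#' @export
print.isi_histogram <- function(x, ...) {
  cat(sprintf("<isi_histogram> %d intervals, %d bins of %.3g ms\n",
              length(x$isi), length(x$counts), x$bin_width))
  invisible(x)
}

#' Cluster centres of the interspike intervals
#'
#' Summarises the multivalued ISI-versus-temperature picture: ISIs are
#' grouped by single linkage with a gap threshold (consecutive sorted
#' intervals more than `gap` ms apart start a new cluster) and each
#' cluster is reported by its mean.
#'
#' @param spikes a [spike_train()] or numeric spike times.
#' @param gap single-linkage gap threshold, ms; default 1.
#' @return Numeric vector of cluster centres (ms), possibly empty.
#' @export
isi_clusters <- function(spikes, gap = 1) {
  s <- as.numeric(spikes)
  if (length(s) < 2L) return(numeric(0))
  isi <- sort(diff(s))
  grp <- cumsum(c(1, diff(isi) > gap))
  as.numeric(tapply(isi, grp, mean))
}

#' Steady-state burst statistics at one temperature
#'
#' Convenience wrapper: simulates a steady run (six modulation periods by
#' default), discards the first modulation period as transient, then
#' detects spikes, forms closed-form overlap windows and segments bursts.
#'
#' @param pset a parameter set.
#' @param Teff steady effective temperature, degC.
#' @param cfg a [simulation_config()]; `t_end = NULL` gives six periods.
#' @param burnin portion discarded at the start, ms; `NULL` (default)
#'   discards one modulation period.
#' @return A list with `spikes`, `windows`, `bursts`, `mean_SB`,
#'   `mean_BP`, `isi` and the `trajectory`.
#' @export
steady_burst_stats <- function(pset, Teff, cfg = simulation_config(),
                               burnin = NULL) {
  traj <- simulate_steady(pset, Teff, cfg)
  if (is.null(burnin)) {
    Om <- abs(eval_params(pset, Teff)$Omega)
    burnin <- if (Om > 0) 2 * pi / Om else 0
  }
  keep <- traj$t >= burnin
  sub <- as.data.frame(traj)[keep, c("t", "theta"), drop = FALSE]
  spikes <- detect_spikes(sub)
  windows <- overlap_windows(pset, Teff, range(sub$t))
  bursts <- segment_bursts(spikes, windows)
  list(spikes = spikes, windows = windows, bursts = bursts,
       mean_SB = if (length(bursts$SB)) mean(bursts$SB) else NA_real_,
       mean_BP = if (length(bursts$BP)) mean(bursts$BP) else NA_real_,
       isi = diff(as.numeric(spikes)),
       trajectory = traj)
}

# ---- plain-text IO ------------------------------------------------------

#' Spike, burst and histogram tables as TSV
#'
#' Spike-time tables are a single column `t_ms`; burst summaries have
#' columns `onset`, `offset`, `count`, `last_spike`; histograms have
#' `bin_left`, `bin_right`, `count`.
#'
#' @param spikes,summary,h objects to write.
#' @param path file path.
#' @return The writers return `path` invisibly; `read_spike_times()`
#'   returns a [spike_train()].
#' @export
write_spike_times <- function(spikes, path) {
  writeLines(c("t_ms", sprintf("%.6f", as.numeric(spikes))), path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path) {
  lines <- readLines(path)
  if (length(lines) && identical(trimws(lines[1]), "t_ms"))
    lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  spike_train(as.numeric(lines))
}

#' @rdname write_spike_times
#' @export
write_burst_summary <- function(summary, path) {
  b <- summary$bursts
  lines <- c("onset\toffset\tcount\tlast_spike",
             sprintf("%.6f\t%.6f\t%d\t%.6f",
                     b$onset, b$offset, b$spike_count, b$last_spike))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
write_isi_histogram <- function(h, path) {
  n <- length(h$counts)
  lines <- c("bin_left\tbin_right\tcount",
             if (n) sprintf("%.6f\t%.6f\t%d",
                            h$bin_edges[-(n + 1)], h$bin_edges[-1],
                            h$counts))
  writeLines(lines, path)
  invisible(path)
}
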