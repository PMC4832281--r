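#' Calcium trace container
#'
#' A calcium signature is a sampled time course of cytosolic free Ca2+:
#' strictly increasing times in seconds, non-negative concentrations in uM.
#'
#' @param time_s Numeric vector of times (s), strictly increasing.
#' @param ca_um Numeric vector of concentrations (uM), non-negative.
#' @return A data frame of class `ca_trace` with columns `time_s`, `ca_um`.
#' @export
ca_trace <- function(time_s, ca_um) {
  if (length(time_s) != length(ca_um))
    stop("time and concentration vectors must have equal length")
  if (length(time_s) == 0) stop("empty trace")
  if (any(!is.finite(time_s)) || any(!is.finite(ca_um)))
    stop("non-finite values in trace")
  bad <- which(diff(time_s) <= 0)
  if (length(bad))
    stop("times must be strictly increasing; first violation at row ",
         bad[1] + 1L)
  neg <- which(ca_um < 0)
  if (length(neg))
    stop("negative concentration at row ", neg[1])
  tr <- data.frame(time_s = as.numeric(time_s), ca_um = as.numeric(ca_um))
  class(tr) <- c("ca_trace", "data.frame")
  tr
}

#' Dwell times of a square-wave signature from its average
#'
#' A square-wave (piecewise) signature spends `t_max` seconds per period at
#' its maximum and `t_min` at its minimum, and its time average `A` fixes
#' that split: `A = (t_max * ca_max + t_min * ca_min) / T` with
#' `T = t_max + t_min`.
#'
#' @param a Average Ca2+ concentration over one period (uM).
#' @param ca_max,ca_min High/low concentration levels (uM).
#' @param period Oscillation period `T` (s).
#' @return Named numeric vector `c(t_max, t_min)` in seconds.
#' @examples
#' dwell_times(0.16, 0.52, 0.10, 40)  # t_max = 40 * 0.06 / 0.42
#' @export
dwell_times <- function(a, ca_max, ca_min, period) {
  stopifnot(period > 0)
  if (ca_min > ca_max) stop("ca_min must not exceed ca_max")
  if (ca_min == ca_max) {
    if (a != ca_max)
      stop("degenerate levels ca_min = ca_max require a equal to them")
    return(c(t_max = period, t_min = 0))
  }
  if (a < ca_min || a > ca_max)
    stop("average must lie within [ca_min, ca_max]")
  t_max <- period * (a - ca_min) / (ca_max - ca_min)
  c(t_max = t_max, t_min = period - t_max)
}

#' Construct a square-wave (piecewise) calcium signature
#'
#' Rebuilds a signature from its summary parameters: the average, maximum
#' and minimum concentrations fix the per-period dwell times (see
#' [dwell_times()]), and `duration / period` complete cycles are laid out
#' from `onset`. Within each cycle the low phase comes first, so a spike
#' develops after stimulation onset rather than the trace beginning
#' mid-spike. Before onset and after `onset + duration` the trace sits at
#' `baseline`.
#'
#' Each switch is sampled twice, at `t` and `t - 1e-9` s, so that linear
#' interpolation of the samples reproduces the square wave; the trace also
#' carries a `segments` attribute (exact constant levels between switches)
#' used by [simulate_binding()] for discontinuity-aware integration.
#'
#' @inheritParams dwell_times
#' @param duration Signature duration (s); truncated to whole cycles with a
#'   warning if not an integer multiple of `period`.
#' @param onset Signature start time (s).
#' @param baseline Pre/post-signature level (uM); defaults to `ca_min`.
#' @param t_end Trace end time (s); defaults to `onset + duration`.
#' @param dt Sample spacing (s).
#' @return A [ca_trace()] with attributes `segments` and `n_spikes`.
#' @examples
#' tr <- piecewise_signature(0.16, 0.52, 0.10, period = 40, duration = 400)
#' attr(tr, "n_spikes")  # 10
#' @export
piecewise_signature <- function(a, ca_max, ca_min, period, duration,
                                onset = 0, baseline = ca_min,
                                t_end = onset + duration, dt = 0.1) {
  stopifnot(duration >= 0, baseline >= 0, dt > 0)
  n_spikes <- duration / period
  if (abs(n_spikes - round(n_spikes)) > 1e-9) {
    n_spikes <- floor(n_spikes)
    warning(sprintf(
      "duration %g s is not a multiple of period %g s; truncating to %d complete cycles",
      duration, period, n_spikes))
    duration <- n_spikes * period
  } else n_spikes <- round(n_spikes)
  dw <- dwell_times(a, ca_max, ca_min, period)
  # the trace must end on the baseline: values beyond the trace end are
  # held constant, so a trace ending mid-spike would hold Ca high forever
  t_end <- max(t_end, onset + duration + dt)

  seg <- data.frame(t0 = numeric(0), t1 = numeric(0), ca = numeric(0))
  add_seg <- function(t0, t1, ca) {
    if (t1 > t0)
      seg <<- rbind(seg, data.frame(t0 = t0, t1 = t1, ca = ca))
  }
  if (onset > 0) add_seg(0, onset, baseline)
  if (n_spikes > 0) {
    for (k in seq_len(n_spikes) - 1L) {
      cyc <- onset + k * period
      add_seg(cyc, cyc + dw["t_min"], ca_min)            # low phase first
      add_seg(cyc + dw["t_min"], cyc + period, ca_max)
    }
  }
  add_seg(onset + duration, t_end, baseline)
  # merge adjacent segments at equal level so switch bookkeeping is minimal
  keep <- c(TRUE, abs(diff(seg$ca)) > 0)
  if (any(!keep)) {
    grp <- cumsum(keep)
    seg <- data.frame(t0 = tapply(seg$t0, grp, min),
                      t1 = tapply(seg$t1, grp, max),
                      ca = tapply(seg$ca, grp, function(z) z[1]))
  }
  rownames(seg) <- NULL

  times <- numeric(0); vals <- numeric(0)
  for (k in seq_len(nrow(seg))) {
    tt <- unique(c(seq(seg$t0[k], seg$t1[k], by = dt), seg$t1[k]))
    if (k < nrow(seg)) tt[length(tt)] <- tt[length(tt)] - 1e-9
    times <- c(times, tt)
    vals <- c(vals, rep(seg$ca[k], length(tt)))
  }
  tr <- ca_trace(times, vals)
  attr(tr, "segments") <- seg
  attr(tr, "n_spikes") <- n_spikes
  attr(tr, "spec") <- list(a = a, ca_max = ca_max, ca_min = ca_min,
                           period = period, duration = duration,
                           onset = onset, baseline = baseline)
  tr
}

#' Generate smooth synthetic calcium signatures
#'
#' Stand-ins for the three experimentally observed signature classes:
#' an oscillatory spike train (smooth sin^2 spikes of given peak, resting
#' level, period and count), a single transient (fast rise, exponential
#' return to baseline), and a prolonged elevation (saturating rise to a
#' plateau held for a duration, then exponential return). Optional Gaussian
#' measurement noise is reproducible through `seed`; the generator is a
#' pure function of its parameters and seed.
#'
#' @param class `"oscillatory"`, `"transient"`, or `"prolonged"`.
#' @param peak Peak (oscillatory/transient) or plateau (prolonged) level, uM.
#' @param baseline Resting level (uM).
#' @param period Oscillation period (s; oscillatory).
#' @param n_spikes Number of spikes (oscillatory).
#' @param rise_s Rise time constant (s; transient/prolonged).
#' @param decay_s Decay time constant (s; transient/prolonged).
#' @param duration Plateau duration (s; prolonged).
#' @param onset Signature start (s).
#' @param t_end Trace end (s); default covers the signature plus recovery.
#' @param dt Sample spacing (s).
#' @param noise_sd Gaussian noise standard deviation (uM).
#' @param seed Integer seed used only for the noise draw.
#' @return A [ca_trace()].
#' @export
synthetic_signature <- function(class = c("oscillatory", "transient",
                                          "prolonged"),
                                peak = 0.52, baseline = 0.10, period = 40,
                                n_spikes = 10, rise_s = 10, decay_s = 60,
                                duration = 300, onset = 0, t_end = NULL,
                                dt = 0.1, noise_sd = 0, seed = NULL) {
  class <- match.arg(class)
  stopifnot(peak > 0, baseline >= 0, period > 0, n_spikes >= 1,
            rise_s > 0, decay_s > 0, duration > 0, noise_sd >= 0)
  if (is.null(t_end))
    t_end <- onset + switch(class,
      oscillatory = n_spikes * period,
      transient = rise_s + 8 * decay_s,
      prolonged = rise_s * 6 + duration + 8 * decay_s)
  tt <- seq(0, t_end, by = dt)
  s <- tt - onset
  v <- switch(class,
    oscillatory = {
      phase <- s %% period
      active <- s >= 0 & s < n_spikes * period & phase < period / 2
      val <- rep(baseline, length(tt))
      val[active] <- baseline +
        (peak - baseline) * sin(pi * phase[active] / (period / 2))^2
      val
    },
    transient = {
      val <- rep(baseline, length(tt))
      ris <- s >= 0 & s < rise_s
      val[ris] <- baseline + (peak - baseline) * s[ris] / rise_s
      dec <- s >= rise_s
      val[dec] <- baseline + (peak - baseline) * exp(-(s[dec] - rise_s) / decay_s)
      val
    },
    prolonged = {
      val <- rep(baseline, length(tt))
      up <- s >= 0 & s < rise_s * 6 + duration
      val[up] <- baseline + (peak - baseline) * (1 - exp(-s[up] / rise_s))
      hold_end <- rise_s * 6 + duration
      dec <- s >= hold_end
      lev <- baseline + (peak - baseline) * (1 - exp(-hold_end / rise_s))
      val[dec] <- baseline + (lev - baseline) * exp(-(s[dec] - hold_end) / decay_s)
      val
    })
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    v <- pmax(v + stats::rnorm(length(v), 0, noise_sd), 0)
  }
  ca_trace(tt, v)
}

#' Read / write calcium traces as delimited text
#'
#' Two columns, `time_s` and `ca_um`, tab-delimited with a header row.
#' Values are written with enough digits for an exact round trip (1e-12 or
#' better). On read, a header row is detected automatically; malformed rows,
#' non-monotone times and negative concentrations are rejected with the
#' offending row number.
#'
#' @param file Path.
#' @param trace A [ca_trace()].
#' @return `read_trace` returns a [ca_trace()]; `write_trace` returns the
#'   file path invisibly.
#' @export
read_trace <- function(file) {
  if (!file.exists(file)) stop("trace file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trace file: ", file)
  first <- strsplit(trimws(lines[1]), "[\t, ]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) lines[-1] else lines
  if (!length(body)) stop("trace file has a header but no data rows: ", file)
  parts <- strsplit(trimws(body), "[\t, ]+")
  nc <- lengths(parts)
  if (any(nc != 2))
    stop("malformed row ", which(nc != 2)[1] + has_header,
         " in ", file, ": expected 2 columns, found ", nc[nc != 2][1])
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 2,
                               byrow = TRUE))
  bad <- which(rowSums(is.na(m)) > 0)
  if (length(bad))
    stop("non-numeric value at row ", bad[1] + has_header, " in ", file)
  tryCatch(ca_trace(m[, 1], m[, 2]),
           error = function(e) stop("invalid trace in ", file, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, file) {
  stopifnot(inherits(trace, "ca_trace"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("time_s\tca_um", con)
  writeLines(sprintf("%.17g\t%.17g", trace$time_s, trace$ca_um), con)
  invisible(file)
}
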