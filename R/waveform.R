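#' Define a pulse protocol
#'
#' A protocol is the clinical specification of the pulse train: number of
#' pulses (periods), energized length per period, repetition frequency, and
#' the applied-voltage amplitude given as a voltage-to-distance (V/D) ratio
#' together with the electrode gap used to convert it to volts. Monopolar
#' square trains and bipolar H-FIRE bursts (symmetric or asymmetric
#' positive-delay-negative phases) are supported.
#'
#' @param n_pulses number of pulse periods (>= 1).
#' @param t_on energized time per period (s); must be < 1/frequency. For
#'   H-FIRE this is the burst's energized window.
#' @param frequency pulse repetition frequency (Hz).
#' @param v_per_m voltage-to-distance ratio in V/m (SI; configs accept V/cm
#'   and convert by x100).
#' @param gap electrode gap D (m); applied voltage is `v_per_m * gap`.
#' @param waveform `"monopolar"`, `"hfire-symmetric"` or `"hfire-asymmetric"`.
#' @param hfire for H-FIRE kinds: list with `pos`, `delay`, `neg` phase
#'   widths (s), `energized` window per burst (s), and optional `neg_scale`
#'   (negative-phase amplitude as a fraction of the positive, default 1).
#' @return An `ep_protocol` object.
#' @export
pulse_protocol <- function(n_pulses, t_on, frequency, v_per_m, gap,
                           waveform = c("monopolar", "hfire-symmetric", "hfire-asymmetric"),
                           hfire = NULL) {
  waveform <- match.arg(waveform)
  if (n_pulses < 1) stop("invalid protocol: n_pulses must be >= 1", call. = FALSE)
  if (t_on <= 0 || frequency <= 0 || gap <= 0) {
    stop("invalid protocol: t_on, frequency and gap must be positive", call. = FALSE)
  }
  if (t_on >= 1 / frequency) {
    stop("invalid protocol: t_on must be shorter than the pulse period 1/frequency",
         call. = FALSE)
  }
  if (startsWith(waveform, "hfire")) {
    if (is.null(hfire)) stop("invalid protocol: hfire timing parameters required", call. = FALSE)
    if (is.null(hfire$neg_scale)) hfire$neg_scale <- 1
    if (waveform == "hfire-symmetric") hfire$neg <- hfire$pos
    with(hfire, {
      if (pos <= 0 || neg <= 0 || delay < 0 || energized <= 0)
        stop("invalid protocol: hfire phase widths must be positive", call. = FALSE)
      if (pos + delay + neg > energized)
        stop("invalid protocol: one hfire cycle exceeds the energized window", call. = FALSE)
    })
    if (hfire$energized > t_on + 1e-15) {
      stop("invalid protocol: hfire energized window exceeds t_on", call. = FALSE)
    }
  }
  structure(list(n_pulses = as.integer(n_pulses), t_on = t_on,
                 frequency = frequency, v_per_m = v_per_m, gap = gap,
                 voltage = v_per_m * gap, waveform = waveform, hfire = hfire),
            class = "ep_protocol")
}

new_waveform <- function(segments, duration) {
  # segments: data.frame(t0, t1, width, v, stage) tiling [0, duration];
  # `width` is the exact specified segment length (t1 - t0 up to rounding),
  # so signed volt-second sums cancel exactly for symmetric bursts
  stopifnot(all(abs(segments$t1[-nrow(segments)] - segments$t0[-1]) < 1e-15))
  structure(list(segments = segments, duration = duration), class = "ep_waveform")
}

#' @export
print.ep_waveform <- function(x, ...) {
  cat(sprintf("<ep_waveform> %d segments over %g s, |V|max = %g V\n",
              nrow(x$segments), x$duration, max(abs(x$segments$v))))
  invisible(x)
}

#' Build the applied-voltage schedule of a monopolar pulse train
#'
#' `n_pulses` square segments of amplitude `V = (V/D) * gap`, each lasting
#' `t_on` and starting at `k/frequency`; zero during every OFF remainder.
#'
#' @param protocol an [pulse_protocol()] with `waveform = "monopolar"`.
#' @return An `ep_waveform`: piecewise-constant segments `(t0, t1, v, stage)`
#'   tiling `[0, n_pulses/frequency]`.
#' @export
build_monopolar <- function(protocol) {
  stopifnot(inherits(protocol, "ep_protocol"))
  if (protocol$waveform != "monopolar") {
    stop("invalid protocol: build_monopolar needs a monopolar waveform kind", call. = FALSE)
  }
  period <- 1 / protocol$frequency
  k <- seq_len(protocol$n_pulses) - 1
  seg <- data.frame(
    t0 = as.vector(rbind(k * period, k * period + protocol$t_on)),
    t1 = as.vector(rbind(k * period + protocol$t_on, (k + 1) * period)),
    width = rep(c(protocol$t_on, period - protocol$t_on), protocol$n_pulses),
    v = rep(c(protocol$voltage, 0), protocol$n_pulses),
    stage = rep(c("ON", "OFF"), protocol$n_pulses),
    stringsAsFactors = FALSE
  )
  new_waveform(seg, protocol$n_pulses * period)
}

# one burst's intra-ON segments, relative to the burst start
hfire_burst_segments <- function(hf, voltage) {
  cyc <- hf$pos + hf$delay + hf$neg + hf$delay
  n_cyc <- floor(hf$energized / cyc + 1e-12)
  if (n_cyc < 1) stop("invalid protocol: energized window shorter than one hfire cycle",
                      call. = FALSE)
  t0 <- 0; out <- vector("list", n_cyc)
  for (c in seq_len(n_cyc)) {
    out[[c]] <- data.frame(
      t0 = t0 + cumsum(c(0, hf$pos, hf$delay, hf$neg)),
      t1 = t0 + cumsum(c(hf$pos, hf$delay, hf$neg, hf$delay)),
      width = c(hf$pos, hf$delay, hf$neg, hf$delay),
      v = c(voltage, 0, -voltage * hf$neg_scale, 0),
      stage = "ON", stringsAsFactors = FALSE)
    t0 <- t0 + cyc
  }
  do.call(rbind, out)
}

#' Build the applied-voltage schedule of an H-FIRE burst train
#'
#' Each period carries one burst: complete (positive phase, inter-phase
#' delay, negative phase, delay) cycles repeated to fill the energized
#' window, both polarities at magnitude `V` (negative phase scaled by
#' `hfire$neg_scale`, default 1), then zero until the next period. Delays
#' inside a burst are part of the energized (ON) stage.
#'
#' @param protocol an [pulse_protocol()] with an `hfire-*` waveform kind.
#' @return An `ep_waveform`.
#' @export
build_hfire <- function(protocol) {
  stopifnot(inherits(protocol, "ep_protocol"))
  if (!startsWith(protocol$waveform, "hfire")) {
    stop("invalid protocol: build_hfire needs an hfire waveform kind", call. = FALSE)
  }
  period <- 1 / protocol$frequency
  burst <- hfire_burst_segments(protocol$hfire, protocol$voltage)
  burst_len <- burst$t1[nrow(burst)]
  out <- vector("list", protocol$n_pulses)
  for (p in seq_len(protocol$n_pulses)) {
    off <- (p - 1) * period
    b <- burst
    b$t0 <- b$t0 + off; b$t1 <- b$t1 + off
    out[[p]] <- rbind(b, data.frame(t0 = off + burst_len, t1 = off + period,
                                    width = period - burst_len, v = 0,
                                    stage = "OFF", stringsAsFactors = FALSE))
  }
  new_waveform(do.call(rbind, out), protocol$n_pulses * period)
}

#' Build the waveform matching a protocol's kind
#' @param protocol an `ep_protocol`.
#' @return An `ep_waveform`.
#' @export
build_waveform <- function(protocol) {
  if (protocol$waveform == "monopolar") build_monopolar(protocol) else build_hfire(protocol)
}

segment_index_at <- function(w, t) {
  if (any(t < 0 | t > w$duration + 1e-15)) {
    stop("range error: t outside [0, duration]", call. = FALSE)
  }
  # left-closed right-open intervals; t == duration resolves to the last segment
  i <- findInterval(t, w$segments$t0, left.open = FALSE)
  pmax(i, 1L)
}

#' Applied voltage at a time point
#'
#' Segments are left-closed right-open, so a boundary instant resolves to
#' the later segment; `t = duration` returns the final segment's value.
#'
#' @param w an `ep_waveform`.
#' @param t time(s) in `[0, duration]` (s); vectorized.
#' @return voltage(s) (V).
#' @export
voltage_at <- function(w, t) {
  w$segments$v[segment_index_at(w, t)]
}

#' Stage (ON/OFF) at a time point
#'
#' ON during any energized window, including the zero-voltage inter-phase
#' delays inside an H-FIRE burst; OFF during the rest of each period.
#'
#' @param w an `ep_waveform`.
#' @param t time(s) in `[0, duration]` (s); vectorized.
#' @return character vector of `"ON"` / `"OFF"`.
#' @export
stage_at <- function(w, t) {
  w$segments$stage[segment_index_at(w, t)]
}

#' Export a waveform as a CSV time series
#'
#' Writes the segment breakpoints as step samples `(time_s, voltage_V)`,
#' two rows per segment, so a step plot reproduces the schedule exactly.
#'
#' @param w an `ep_waveform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  s <- w$segments
  df <- data.frame(time_s = as.vector(rbind(s$t0, s$t1)),
                   voltage_V = rep(s$v, each = 2))
  write_timeseries_csv(df, path)
}
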