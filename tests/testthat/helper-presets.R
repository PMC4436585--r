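# shared fixtures built in code

# short acquisition settings keep simulated families light while preserving
# the 100 kHz / 3 kHz structure of the recordings
short_step_protocol <- function(v_start = -115, v_end = 175, dv = 20)
  make_step_protocol(-60, v_start, v_end, dv, pre_ms = 10, step_ms = 50,
                     tail_ms = 25, sampling_kHz = 100)

default_line <- function() calibration_line(0.5, -2.0, 5, 8)

# independent trapezoidal-integration oracle for charge measurements
trapz_charge_pC <- function(sweep, time_ms, window_ms, baseline) {
  idx <- which(time_ms >= window_ms[1] & time_ms < window_ms[2])
  x <- time_ms[idx]; y <- sweep[idx] - baseline
  abs(sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)) / 1000
}
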