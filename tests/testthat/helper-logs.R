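# Shared fixtures, all built in code.

# minimal events frame for a log running [0, t_end]
base_events <- function(t_end, handover = NULL, extra = NULL) {
  ev <- data.frame(kind = c("arrest_recognized", "rosc"),
                   time = c(0, t_end), detail = "")
  if (!is.null(handover))
    ev <- rbind(ev, data.frame(kind = "handover", time = handover,
                               detail = ""))
  if (!is.null(extra)) ev <- rbind(ev, extra)
  ev
}

# metronomic compressions over [from, to] at `rate` per minute
metronome <- function(from, to, rate = 117) {
  seq(from, to, by = 60 / rate)
}

# a log compressing continuously except over the given silent spans
log_with_silences <- function(t_end, silences = list(), rate = 120,
                              handover = NULL, extra = NULL) {
  cp <- metronome(0, t_end, rate)
  for (s in silences) cp <- cp[cp < s[1] | cp >= s[2]]
  event_log("fixture", cp, base_events(t_end, handover, extra))
}

expect_close <- function(x, y, tol = 1e-9) {
  expect_true(abs(x - y) <= tol,
              label = sprintf("|%g - %g| <= %g", x, y, tol))
}
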