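# Whole-hour helpers. POSIXct is kept (trunc() would return POSIXlt).

.floor_hour <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 3600) * 3600, origin = "1970-01-01",
             tz = "UTC")
}

# Round to the nearest whole hour, half-up (xx:30:00 rounds to the next hour).
.round_hour_half_up <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 3600 + 0.5) * 3600, origin = "1970-01-01",
             tz = "UTC")
}
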