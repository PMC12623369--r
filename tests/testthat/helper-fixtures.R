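# Fixtures built in code: tiny recordings and reduced synthetic specs.

two_region_map <- function(chs) {
  stats::setNames(rep(c("S1", "RFA"), length.out = length(chs)), chs)
}

# Recording from explicit channel vectors (named list) at rate fs.
make_rec <- function(..., fs = 1000, region = NULL) {
  cols <- list(...)
  data <- do.call(cbind, cols)
  colnames(data) <- names(cols)
  if (is.null(region)) region <- two_region_map(names(cols))
  lfp_recording(data, fs, region = region)
}

sine <- function(freq, dur_s, fs = 1000, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (1:(dur_s * fs)) / fs + phase)
}

# Small quiet session spec: no line noise, few channels.
quiet_spec <- function(duration_s = 130, n_s1 = 1, n_rfa = 1, ...) {
  session_spec(duration_s = duration_s, n_s1 = n_s1, n_rfa = n_rfa,
               line_noise = 0, ...)
}

# Hand-built hypnogram on the 1-s epoch grid.
make_hyp <- function(labels, start = 1) {
  structure(list(epoch_time = seq_along(labels) + start - 1,
                 label = factor(labels,
                                levels = c("WK", "SWS", "REM", "UNSCORED"))),
            class = "hypnogram")
}

# The line filter takes ~2 s to design; share one instance per test run.
line_filter_1k <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- design_line_filter(1000)
    cache
  }
})
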