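# One fully calibrated default bundle shared across test files (calibration
# is deterministic, so caching is safe).
cached_models <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- mgus_models()
    m
  }
})

# Bundle with a custom progression model but the default calibration
# otherwise (recalibrating incidence for every p would couple the tests).
with_progression <- function(models, prog) {
  models$progression <- prog
  models
}

# Bundle whose incidence is identically zero (no MGUS ever).
zero_incidence_models <- function() {
  m <- cached_models()
  m$incidence <- incidence_model(k = c(low = 0, high = 0))
  m
}
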