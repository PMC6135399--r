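# Shared fixtures, built in code.

# A constant-temperature weather table.
make_weather <- function(n, tmean = 20, tmin = tmean - 5, tmax = tmean + 5,
                         start = as.Date("2020-01-01"), ...) {
  data.frame(date = start + seq_len(n) - 1L, tmin = tmin, tmax = tmax,
             tmean = tmean, ...)
}

# A well-behaved rise-and-fall double-logistic coefficient set (growth
# inflection 300, senescence inflection 800) used by generic model tests.
# All six entries are non-zero so relative-error recovery checks are
# meaningful for every parameter.
cf_rise <- dl_coef(2, 32, 0.02, 300, 0.03, 800)

# Relative difference helper.
rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), .Machine$double.eps)
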