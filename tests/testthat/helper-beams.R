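# Shared beam fixtures, built in code.

# CT-like beam: 80 kV tungsten spectrum behind 7 mm Al (inherent + bowtie
# centre). Broad; the quadratic fit estimand differs from the continuous
# half-kerma thickness by ~12% for this beam (see the methods vignette).
ct_beam_80 <- function() apply_filter(generate_spectrum(80), "al", 7)

# Cu-hardened beam on which the quadratic log-attenuation model holds to
# <1%, so fitted HVL and narrow-beam HVL estimate the same quantity.
hardened_beam <- function() apply_filter(ct_beam_80(), "cu", 0.5)

# Monoenergetic spectrum helper.
mono_beam <- function(energy_kev)
  xray_spectrum(energy_kev, 1, tube_voltage_kv = energy_kev)

pipe_thicknesses <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6)

# An attenuation_series whose mean log-exposure follows exp(c0+c1 t+c2 t^2)
# exactly (replicated identically).
exact_quadratic_series <- function(c0, c1, c2,
                                   thicknesses = pipe_thicknesses,
                                   replicates = 3) {
  attenuation_series(
    thicknesses,
    lapply(thicknesses, function(t)
      rep(exp(c0 + c1 * t + c2 * t^2), replicates)),
    method = "copper_pipe", strict = FALSE)
}
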