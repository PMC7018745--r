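# Shared fixtures, built in code at load time.

sham <- gating_preset("sham")
pni <- gating_preset("pni")

# default in-vivo dose-response truths (benzodiazepine-site drug "a",
# KCC2 enhancer "b")
hill_a_true <- hill_params(y0 = 6, ymax = 31.2, h = 1, ec50 = 0.43)
hill_b_true <- hill_params(y0 = 6, ymax = 22.9, h = 1, ec50 = 29.4)
doses_a <- c(0, 0.05, 0.15, 0.43, 1.1, 3.3, 10, 20)
doses_b <- c(0, 5, 15, 29.4, 60, 100, 150)

calibrated_model <- function() {
  cal <- calibrate_anion_constants()
  list(params = cal$params, residuals = cal$residuals,
       effect = calibrate_effect())
}

expect_close <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
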