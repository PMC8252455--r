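# shared fixtures: the bundled study inputs and a calibrated model-1 PBPK spec
thy <- thy1773_inputs()

model1_spec <- function() {
  build_model(thy$compound, clint_mode = "model1_no_esf", vd_target = 0.405)
}

# study sampling schedule (h) for single-dose animal PK
animal_times <- c(5 / 60, 0.25, 0.5, 1, 2, 4, 8, 12, 24)

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
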