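# Shared fixtures, built in code.

test_params <- function(...) cea_parameters(...)

test_lt <- function(...) gompertz_life_table(...)

# Tiny hand-made life table: ages 41..43, death certain at 43.
toy_lt <- function(q = c(0.1, 0.2, 1.0), cvd_fatality = 0.1) {
  life_table(tibble::tibble(
    age = seq(41, length.out = length(q)),
    q_all = q,
    cvd_fatality = cvd_fatality
  ))
}
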