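# Shared fixtures, built once per test run.  Small grids keep the unit tests
# fast; the acceptance tests build the full 400-location grid themselves.

grid100 <- generate_grid(100, 7.5, seed = 1)
grid400 <- generate_grid(400, 7.5, seed = 1)

default_field <- ctelm:::default_visibility_field()

# mean fixation duration helper (standard exclusions)
mid_durations <- function(st) {
  f <- st$fixations
  nf <- stats::ave(f$trial, f$trial, FUN = length)
  f$duration[f$fix_index > 1 & f$fix_index < nf]
}
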