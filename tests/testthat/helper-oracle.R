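# Independent direct evaluation of the plume equations, written as a plain
# scalar transliteration (explicit loops, no shared code with the package)
# for use as an oracle.

oracle_vertical <- function(h, delta_z, l, n_max) {
  p <- 2 * exp(-h^2 / (2 * delta_z^2))
  if (n_max >= 1) {
    for (n in 1:n_max) {
      p <- p + exp(-(n * l - h)^2 / (2 * delta_z^2))
      p <- p + exp(-(n * l + h)^2 / (2 * delta_z^2))
    }
  }
  p
}

oracle_concentration <- function(E, y, mu, delta_y, delta_z, h, l, n_max) {
  E / (2 * pi * mu * delta_y * delta_z) *
    exp(-y^2 / (2 * delta_y^2)) *
    oracle_vertical(h, delta_z, l, n_max)
}

oracle_average <- function(E, mu, delta_y, delta_z, h, l, n_max, offsets = 1:3) {
  total <- 0
  for (y in offsets) {
    total <- total + oracle_concentration(E, y, mu, delta_y, delta_z, h, l, n_max)
  }
  total / length(offsets)
}

# small noise-free scenario shared by several tests
quiet_config <- function(...) {
  scenario_config(noise_sd = 0, ...)
}
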