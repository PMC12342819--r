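# Shared fixtures: simple constant-index materials alongside the defaults,
# and small stacks used by several solver tests.

fixture_materials <- function() {
  c(default_materials(),
    list(glass = material_dispersion("glass", "constant", c(n = 1.5, k = 0)),
         absglass = material_dispersion("absglass", "constant",
                                        c(n = 1.6, k = 0.05)),
         hi = material_dispersion("hi", "constant", c(n = 1.7428, k = 0)),
         lo = material_dispersion("lo", "constant", c(n = 1.55556, k = 0))))
}

# lossless quarter-wave-like bilayer stack (5 periods)
fixture_bilayer_stack <- function(mats = fixture_materials(),
                                  d1 = 186, d2 = 30, n = 5) {
  layer_stack(rep(c(d1, d2), n), material = rep(c("hi", "lo"), n),
              materials = mats, exit = "lo")
}

# closed-form Fresnel intensity coefficients, air -> n2
fresnel_R <- function(n2, theta_deg, pol) {
  s0 <- sin(theta_deg * pi / 180); c0 <- cos(theta_deg * pi / 180)
  c2 <- sqrt(1 - (s0 / n2)^2)
  if (pol == "s") ((c0 - n2 * c2) / (c0 + n2 * c2))^2
  else ((n2 * c0 - c2) / (n2 * c0 + c2))^2
}
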