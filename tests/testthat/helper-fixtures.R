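# Shared fixtures and independent oracles.

# Small single-vessel scene: one straight horizontal vessel crossing a
# 40 x 60 image.
single_vessel_scene <- function(true_so2 = 0.7, diameter_um = 100,
                                noise = noise_spec("none"), seed = 1L,
                                scatter = list(mode = "linear",
                                               g0 = 0.08, g1 = 2e-4),
                                hb_mol_l = 2.3e-3,
                                path_length_scale = 1) {
  v <- vessel_spec("vein", "temporal", rbind(c(20, 6), c(20, 55)),
                   diameter_um, true_so2, hb_mol_l = hb_mol_l,
                   path_length_scale = path_length_scale)
  scene_spec(40, 60, vessels = v, noise = noise, seed = seed,
             scatter = scatter)
}

# Closed-form forward OD of a vessel: L*c*(s*eps_oxy + (1-s)*eps_deoxy)
# + g(lambda). Independent of compute_od()'s image-based path.
analytic_od <- function(vessel_row, wl, extinction = hb_extinction(),
                        scatter = list(mode = "linear",
                                       g0 = 0.08, g1 = 2e-4)) {
  eps <- resample_extinction(extinction, wl)
  l_cm <- vessel_row$path_length_scale * vessel_row$diameter_um * 1e-4
  s <- vessel_row$true_so2
  g <- switch(scatter$mode,
              none = 0,
              linear = scatter$g0 + scatter$g1 * (wl - 575),
              powerlaw = scatter$g0 * (wl / 550)^(-scatter$b))
  l_cm * vessel_row$hb_mol_l *
    (s * eps$eps_oxy + (1 - s) * eps$eps_deoxy) + g
}

# Brute-force normal-equations least squares: solve (X'X) b = X'y.
normal_equations_fit <- function(x, y) {
  as.vector(solve(t(x) %*% x, t(x) %*% y))
}

# Closed-form paired t-test.
closed_form_paired_t <- function(pre, post) {
  d <- pre - post
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

default_grid <- make_band_grid()
hb_table <- hb_extinction()
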