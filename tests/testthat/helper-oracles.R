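# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the finite-volume solver below discretises the
# spherically symmetric steady diffusion equation directly, with no use of
# the 1/r closed form it is used to check.

# Steady-state spherical diffusion around a cell of radius r_cell_um with a
# surface source of strength q_fmol_d (negative = sink), outer Dirichlet
# C(r_out) = bulk_uM far away. Finite-volume on a log grid; interface fluxes
# F = -D * 4 pi r_mid^2 * dC/dr. Solved with the Thomas algorithm.
# Returns conc (uM) on the requested r_eval_um grid (linear interpolation).
fdSphericalSteadyState <- function(q_fmol_d, d_m2_s, r_cell_um, bulk_uM,
                                   r_eval_um, n = 4000,
                                   r_out_factor = 1e4) {
  r <- exp(seq(log(r_cell_um * 1e-6), log(r_cell_um * 1e-6 * r_out_factor),
               length.out = n))                      # m
  q <- q_fmol_d * 1e-15 / 86400                      # mol/s
  rmid <- sqrt(r[-n] * r[-1])                        # interface radii
  g <- d_m2_s * 4 * pi * rmid^2 / diff(r)            # interface conductances

  # Tridiagonal system: interior nodes balance interface fluxes; node 1
  # receives the surface source; node n is pinned to the bulk value.
  a <- b <- cc <- dd <- numeric(n)
  b[1] <- -g[1]; cc[1] <- g[1]; dd[1] <- -q
  for (i in 2:(n - 1)) {
    a[i] <- g[i - 1]
    b[i] <- -(g[i - 1] + g[i])
    cc[i] <- g[i]
    dd[i] <- 0
  }
  a[n] <- 0; b[n] <- 1; dd[n] <- bulk_uM * 1e-3      # mol/m^3

  # Thomas sweep
  for (i in 2:n) {
    w <- a[i] / b[i - 1]
    b[i] <- b[i] - w * cc[i - 1]
    dd[i] <- dd[i] - w * dd[i - 1]
  }
  x <- numeric(n)
  x[n] <- dd[n] / b[n]
  for (i in (n - 1):1) x[i] <- (dd[i] - cc[i] * x[i + 1]) / b[i]

  conc_uM <- x / 1e-3
  stats::approx(r * 1e6, conc_uM, xout = r_eval_um, rule = 2)$y
}

# Closed-form density of Monod growth at fixed resource concentrations.
monodExponential <- function(b0, mu_max_doc, km_doc, doc,
                             mu_max_n = 0, km_n = 1, no3 = 0,
                             mortality = 0, t) {
  mu <- mu_max_doc * doc / (km_doc + doc) + mu_max_n * no3 / (km_n + no3) -
    mortality
  b0 * exp(mu * t)
}

# Total moles (nmol) of a solute in all wells of a run at one time index.
totalMoles <- function(series, what, ti) {
  w <- wellsOf(series)
  conc <- wellMatrix(series, what)[ti, w$id]
  sum(conc * w$volume_ul) / 1e3   # uM * ul = 1e-3 nmol
}

# Geometric mean by group, with a floor.
geoMeanBy <- function(values, groups, floor = 1) {
  vapply(split(pmax(values, floor), groups),
         function(v) exp(mean(log(v))), numeric(1))
}
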