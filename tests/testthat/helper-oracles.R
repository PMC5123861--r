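# Independent oracles used across test files. These re-derive quantities by
# brute force or closed form, never through the code paths they check.

# Exponential-fit oracle: grid over log10(k) with exact linear least squares
# for (F0, A) at each k; returns the minimum RSS over the grid.
grid_rss_exponential <- function(t, F, log10k = seq(-3, 4, by = 0.01)) {
  min(vapply(10^log10k, function(k) {
    X <- cbind(1, exp(-k * t))
    sum(stats::lsfit(X, F, intercept = FALSE)$residuals^2)
  }, 1.0))
}

# Mass-action bisection oracle: bound concentration solved from
# B (K + n P - B)(...) without the quadratic formula.
bisect_bound <- function(n, K_d, P, L, tol = 1e-16) {
  f <- function(B) (n * P - B) * (L - B) - K_d * B
  lo <- 0; hi <- min(n * P, L)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(hi, 1e-30)) break
  }
  (lo + hi) / 2
}

# Build a planted-pose docking problem on the toy domain: returns the
# structure, restraints consistent with pose (tilt, azimuth, z) at zero
# noise, and the planted depths.
planted_docking_problem <- function(tilt, azimuth, z, range_A = 0.1,
                                    sites = c(4L, 10L, 16L, 22L),
                                    geometry_seed = 3, label_offset = 7) {
  dom <- make_toy_domain(geometry_seed = geometry_seed)
  R <- c2membrane:::rot_y(tilt) %*% c2membrane:::rot_z(azimuth)
  pts <- t(vapply(sites, function(r) label_site_position(dom, r, label_offset),
                  numeric(3)))
  ctr <- colMeans(pts)
  depths <- drop(sweep(pts, 2, ctr) %*% R[3, ]) + z
  list(structure = dom,
       restraints = plane_restraints(sites, depths, range_A),
       depths = depths, sites = sites)
}

# Synthetic HSQC base peak list spanning the C2B polybasic region.
base_hsqc_peaks <- function(residues = 300:340) {
  data.frame(residue = residues,
             dH_ppm = 8 + 0.4 * sin(residues),
             dN_ppm = 118 + 4 * cos(residues))
}

make_identity_pose <- function() {
  structure(list(rotation = diag(3), z_offset = 0, centroid = c(0, 0, 0)),
            class = "docking_result")
}
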