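test_that("pseudo-nitroxide label geometry is a fixed Cbeta extension", {
  dom <- make_toy_domain(geometry_seed = 2)
  ca <- c2membrane:::get_atom(dom, 5L, "CA")
  cb <- c2membrane:::get_atom(dom, 5L, "CB")
  expect_equal(label_site_position(dom, 5L, offset_len = 0), cb)
  p <- label_site_position(dom, 5L, offset_len = 7)
  expect_equal(sqrt(sum((p - cb)^2)), 7, tolerance = 1e-12)
  ## collinearity of CA, CB and the label point
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  expect_lt(sqrt(sum(cross(cb - ca, p - cb)^2)), 1e-9)

  noCB <- structure_model(data.frame(residue = c(1L, 1L, 2L),
                                     atom = c("CA", "CB", "CA"),
                                     x = c(0, 1, 3), y = 0, z = 0))
  expect_error(label_site_position(noCB, 2L), class = "missing_atom")
})

test_that("a single restraint is solved exactly by translation", {
  one <- structure_model(data.frame(residue = c(1L, 1L), atom = c("CA", "CB"),
                                    x = c(0, 1.5), y = 0, z = 0))
  expect_warning(
    res <- dock_to_plane(one, plane_restraints(1L, -5.4, 0.5)),
    class = "translation_only")
  expect_equal(res$residuals, 0)
  expect_equal(res$objective, 0)
})

test_that("planted poses are recovered within 2 degrees and 0.2 Angstrom", {
  for (pose in list(c(35, 120, -2), c(80, 300, 4), c(10, 45, 0))) {
    prob <- planted_docking_problem(pose[1], pose[2], pose[3], range_A = 0.1)
    res <- dock_to_plane(prob$structure, prob$restraints)
    expect_equal(res$objective, 0, tolerance = 1e-10)
    expect_lt(abs(res$tilt_deg - pose[1]), 2)
     achieved <- apply_pose(res$label_points, res)[, 3]
    expect_true(all(abs(achieved - prob$depths) < 0.2))
    ## grid-oracle dominance on every run
    expect_lte(res$objective, res$grid_min + 1e-12)
  }
})

test_that("docking is equivariant under pre-rotation of the input", {
  prob <- planted_docking_problem(50, 200, -3, range_A = 0.1)
  res0 <- dock_to_plane(prob$structure, prob$restraints)

  R0 <- c2membrane:::rot_y(25) %*% c2membrane:::rot_z(70)
  a <- prob$structure$atoms
  xyz <- as.matrix(a[c("x", "y", "z")]) %*% t(R0)
  rot_struct <- structure_model(data.frame(residue = a$residue, atom = a$atom,
                                           x = xyz[, 1], y = xyz[, 2],
                                           z = xyz[, 3]))
  res1 <- dock_to_plane(rot_struct, prob$restraints)
  expect_equal(res1$objective, res0$objective, tolerance = 1e-6)
  d0 <- sort(apply_pose(res0$label_points, res0)[, 3])
  d1 <- sort(apply_pose(res1$label_points, res1)[, 3])
  expect_equal(d1, d0, tolerance = 0.15)
})

test_that("per-residue depth report transforms correctly", {
  dom <- make_toy_domain(geometry_seed = 4)
  ident <- make_identity_pose()
  ca <- dom$atoms[dom$atoms$atom == "CA", ]
  expect_equal(report_depths(dom, ident)$depth_A, ca$z)

  flip <- structure(list(rotation = c2membrane:::rot_y(180), z_offset = 0,
                         centroid = c(0, 0, 0)), class = "docking_result")
  expect_equal(report_depths(dom, flip)$depth_A, -ca$z, tolerance = 1e-12)

  ## restrained-site label depths recompute from the pose geometry
  prob <- planted_docking_problem(40, 90, 1, range_A = 0.1)
  res <- dock_to_plane(prob$structure, prob$restraints)
  pts <- t(vapply(prob$sites, function(r)
    label_site_position(prob$structure, r), numeric(3)))
  lab_z <- apply_pose(pts, res)[, 3]
  expect_equal(lab_z, prob$depths, tolerance = 0.2)
})

test_that("measured depth restraints dock with the aqueous-side site placed", {
  ## three sites from the 20% PtdSer condition of the depth table, mapped
  ## onto a synthetic domain with restraint ranges from the calibration
  tab <- spin_label_depths()
  cal <- fit_calibration(data.frame(phi = tab$phi, distance_A = tab$distance_A))
  ps20 <- tab[tab$composition == "20% PtdSer" & tab$site %in% c(304, 329, 368), ]
  rng <- pmax(depth_from_phi(ps20$phi, cal, ps20$phi_err)$x_err, 0.5)
  dom <- make_toy_domain(n_residues = 30, geometry_seed = 11)
  sites <- c(3L, 15L, 27L)
  restr <- plane_restraints(sites, ps20$distance_A, rng)
  res <- dock_to_plane(dom, restr)
  expect_lte(res$objective, res$grid_min + 1e-12)
  achieved <- apply_pose(res$label_points, res)[, 3]
  i329 <- which(ps20$site == 329)
  expect_lt(abs(achieved[i329] - (-5.4)), rng[i329] + 0.1)
  expect_lt(achieved[i329], 0)  # polybasic-patch site stays on the aqueous side
})

test_that("degenerate poses are reported sorted by tilt", {
  prob <- planted_docking_problem(30, 60, -1, range_A = 2)  # wide flat bottoms
  res <- dock_to_plane(prob$structure, prob$restraints)
  poses <- res$degenerate_poses
  expect_true(all(diff(poses$tilt) >= 0))
  expect_true(all(poses$objective <= res$objective + 1e-3))
  ## rotation stays proper
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(res$rotation), diag(3), tolerance = 1e-9)
})
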