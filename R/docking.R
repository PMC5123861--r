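#' Rigid protein structure as an atom table
#'
#' Minimal coordinate container for rigid-body membrane docking: one row per
#' atom with residue number, atom name and Cartesian coordinates in
#' Angstroms.
#'
#' @param atoms Data frame with columns `residue` (integer), `atom`
#'   (character, e.g. `"CA"`, `"CB"`), `x`, `y`, `z`.
#' @param chain Optional chain identifier kept as metadata.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, chain = "A") {
  req <- c("residue", "atom", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms))) {
    cm_stop("`atoms` must be a data frame with residue, atom, x, y, z",
            "invalid_structure")
  }
  if (anyDuplicated(atoms[c("residue", "atom")])) {
    cm_stop("duplicate (residue, atom) keys", "invalid_structure")
  }
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (any(!is.finite(xyz))) {
    cm_stop("coordinates must be finite", "invalid_structure")
  }
  atoms$residue <- as.integer(atoms$residue)
  structure(list(atoms = atoms, chain = chain), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues\n",
              nrow(x$atoms), length(unique(x$atoms$residue))))
  invisible(x)
}

get_atom <- function(structure, residue, atom) {
  a <- structure$atoms
  i <- which(a$residue == residue & a$atom == atom)
  if (length(i) != 1L) {
    cm_stop(sprintf(
      "residue %d has no %s atom%s", residue, atom,
      if (atom == "CB") " (glycine? supply mutation-aware coordinates)" else ""),
      "missing_atom")
  }
  as.numeric(a[i, c("x", "y", "z")])
}

#' Pseudo-nitroxide label position for a spin-labelled site
#'
#' Geometric surrogate for the nitroxide ring of an R1 spin-label side
#' chain: the point `offset_len` Angstroms beyond the Cbeta atom along the
#' Calpha-to-Cbeta direction. This fixed-offset construction replaces full
#' rotamer modelling and is the dominant systematic approximation of the
#' docking module.
#'
#' @param structure A [structure_model()].
#' @param residue Residue number carrying the label.
#' @param offset_len Label reach beyond Cbeta in Angstroms (default 7.0, a
#'   typical nitroxide extension).
#' @return Numeric xyz vector.
#' @export
label_site_position <- function(structure, residue, offset_len = 7.0) {
  stopifnot(inherits(structure, "structure_model"))
  stopifnot_scalar_pos(offset_len, "offset_len", strict = FALSE)
  ca <- get_atom(structure, residue, "CA")
  cb <- get_atom(structure, residue, "CB")
  u <- cb - ca
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) cm_stop("degenerate CA-CB geometry", "invalid_structure")
  cb + offset_len * u / nu
}

#' Point-to-plane depth restraints
#'
#' @param residue Residue numbers of the labelled sites.
#' @param target_A Target signed distances of each label point to the
#'   phosphate plane (Angstrom; positive = hydrocarbon side).
#' @param range_A Flat-bottom half-widths (Angstrom, > 0), typically the
#'   uncertainty in label position.
#' @return Data frame of class `plane_restraints`.
#' @export
plane_restraints <- function(residue, target_A, range_A) {
  if (length(range_A) == 1L) range_A <- rep(range_A, length(residue))
  if (length(residue) != length(target_A) ||
      length(residue) != length(range_A)) {
    cm_stop("restraint columns must have equal length", "invalid_restraints")
  }
  if (any(range_A <= 0)) cm_stop("`range_A` must be > 0", "invalid_restraints")
  structure(data.frame(residue = as.integer(residue),
                       target_A = as.numeric(target_A),
                       range_A = as.numeric(range_A)),
            class = c("plane_restraints", "data.frame"))
}

rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, sin(r), 0, 1, 0, -sin(r), 0, cos(r)), 3, 3)
}
rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), -sin(r), 0, sin(r), cos(r), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

## flat-bottom harmonic: zero inside +-range of target, quadratic outside
restraint_objective <- function(depths, target, range) {
  sum(pmax(0, abs(depths - target) - range)^2)
}

#' Dock a rigid domain onto the membrane plane from depth restraints
#'
#' Finds the rigid-body pose of a domain relative to the fixed membrane
#' plane z = 0 (+z = hydrocarbon side) that minimises a flat-bottom harmonic
#' penalty on the signed distances of pseudo-nitroxide label points to the
#' plane. Only the three observable degrees of freedom are searched — tilt
#' theta (rotation about the lab y axis), body azimuth psi (pre-rotation
#' about the body z axis) and the vertical offset z — since rotation about
#' the membrane normal and in-plane translation do not change any
#' point-to-plane distance. A coarse grid (5 deg x 5 deg x 0.5 A by
#' default) is scanned exhaustively, the best nodes are refined by
#' Nelder-Mead, and every pose scoring within `tol` of the minimum is
#' reported as degenerate (sorted by tilt; no silent selection).
#'
#' @param structure A [structure_model()].
#' @param restraints A [plane_restraints()] table (>= 2 rows; a single
#'   restraint triggers translation-only mode with a warning).
#' @param label_offset Label reach passed to [label_site_position()].
#' @param grid Named list of grid steps: `tilt` and `azimuth` in degrees,
#'   `z` in Angstroms.
#' @param tol Objective tolerance within which poses count as degenerate.
#' @param axis Body-frame reference axis whose angle to the membrane normal
#'   is reported as the tilt (default the body z axis).
#' @return An object of class `docking_result`: `rotation` (3x3 proper
#'   rotation applied about the label-point centroid), `z_offset`,
#'   `tilt_deg`, `residuals` (achieved minus target depth per restraint),
#'   `violations` (excess beyond each flat-bottom range), `objective`,
#'   `degenerate_poses` (data frame), `grid_min` (best coarse-grid
#'   objective), plus the centroid and label points needed to re-apply the
#'   pose.
#' @export
dock_to_plane <- function(structure, restraints, label_offset = 7.0,
                          grid = list(tilt = 5, azimuth = 5, z = 0.5),
                          tol = 1e-3, axis = c(0, 0, 1)) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(restraints, "plane_restraints"))
  pts <- t(vapply(restraints$residue, function(r)
    label_site_position(structure, r, label_offset), numeric(3)))
  centroid <- colMeans(pts)
  P <- sweep(pts, 2, centroid)
  tgt <- restraints$target_A
  rng <- restraints$range_A
  n_r <- nrow(restraints)
  axis <- axis / sqrt(sum(axis^2))

  if (n_r == 1L) {
    cm_warn("single restraint: translation-only docking (orientation unresolved)",
            "translation_only")
    z <- tgt[1] - P[1, 3]
    return(structure(
      list(rotation = diag(3), z_offset = z,
           tilt_deg = acos(min(1, max(-1, axis[3]))) * 180 / pi,
           residuals = 0, violations = 0, objective = 0,
           degenerate_poses = data.frame(tilt = NA_real_, azimuth = NA_real_,
                                         z = z, objective = 0),
           grid_min = 0, centroid = centroid, label_points = pts,
           restraints = restraints, converged = TRUE),
      class = "docking_result"))
  }

  thetas <- seq(0, 180, by = grid$tilt)
  psis <- seq(0, 360 - grid$azimuth, by = grid$azimuth)
  obj_of <- function(theta, psi, z) {
    R <- rot_y(theta) %*% rot_z(psi)
    restraint_objective(P %*% R[3, ] + z, tgt, rng)
  }

  nodes <- vector("list", length(thetas) * length(psis))
  k <- 0L
  for (th in thetas) {
    Ry3 <- rot_y(th)
    for (ps in psis) {
      R3 <- (Ry3 %*% rot_z(ps))[3, ]
      pz <- drop(P %*% R3)
      d <- tgt - pz
      zg <- seq(min(d) - 1, max(d) + 1, by = grid$z)
      ## residual matrix: length(zg) x n_r
      resid <- abs(outer(zg, d, function(z, dd) z - dd)) -
        matrix(rng, length(zg), n_r, byrow = TRUE)
      ov <- rowSums(pmax(resid, 0)^2)
      j <- which.min(ov)
      k <- k + 1L
      nodes[[k]] <- c(th, ps, zg[j], ov[j])
    }
  }
  nodes <- do.call(rbind, nodes)
  colnames(nodes) <- c("tilt", "azimuth", "z", "objective")
  grid_min <- min(nodes[, "objective"])

  ## refine the most promising nodes
  ord <- order(nodes[, "objective"])
  cand <- unique(c(ord[seq_len(min(12L, nrow(nodes)))],
                   which(nodes[, "objective"] <= grid_min + tol)))
  refined <- lapply(cand, function(i) {
    st <- nodes[i, 1:3]
    o <- tryCatch(
      stats::optim(st, function(p) obj_of(p[1], p[2], p[3]),
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(o)) list(par = st, value = nodes[i, "objective"],
                         convergence = 1L)
    else o
  })
  vals <- vapply(refined, function(o) o$value, 1.0)
  best_i <- which.min(vals)
  best <- refined[[best_i]]
  converged <- best$value <= grid_min + 1e-12 || isTRUE(best$convergence == 0)
  if (!converged) {
    cm_warn("refinement did not converge; best grid pose returned",
            "refinement_failed")
    bi <- which.min(nodes[, "objective"])
    best <- list(par = nodes[bi, 1:3], value = nodes[bi, "objective"])
  }

  ## collect degenerate poses from refined + grid candidates
  pose_rows <- lapply(refined, function(o)
    data.frame(tilt = o$par[1] %% 360, azimuth = o$par[2] %% 360,
               z = o$par[3], objective = o$value))
  poses <- rbind(do.call(rbind, pose_rows),
                 as.data.frame(nodes)[, c("tilt", "azimuth", "z", "objective")])
  poses <- poses[poses$objective <= best$value + tol, , drop = FALSE]
  ## dedupe by the achieved depth signature (poses differing only through
  ## unobservable DOF give identical depths)
  sig <- vapply(seq_len(nrow(poses)), function(i) {
    R <- rot_y(poses$tilt[i]) %*% rot_z(poses$azimuth[i])
    paste(round(P %*% R[3, ] + poses$z[i], 2), collapse = "|")
  }, "")
  poses <- poses[!duplicated(sig), , drop = FALSE]
  poses <- poses[order(poses$tilt), , drop = FALSE]
  rownames(poses) <- NULL

  theta <- best$par[1]; psi <- best$par[2]; z <- best$par[3]
  R <- rot_y(theta) %*% rot_z(psi)
  depths <- drop(P %*% R[3, ]) + z
  tilt <- acos(min(1, max(-1, drop(R %*% axis)[3]))) * 180 / pi
  structure(
    list(rotation = R, z_offset = z, tilt_deg = tilt,
         residuals = depths - tgt,
         violations = pmax(0, abs(depths - tgt) - rng),
         objective = best$value, degenerate_poses = poses,
         grid_min = grid_min, centroid = centroid, label_points = pts,
         restraints = restraints, converged = converged),
    class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf(
    "Docking: tilt %.1f deg, z offset %.2f A, objective %.3g (%d degenerate pose%s)\n",
    x$tilt_deg, x$z_offset, x$objective, nrow(x$degenerate_poses),
    if (nrow(x$degenerate_poses) == 1) "" else "s"))
  invisible(x)
}

#' Apply a docked pose to a set of points
#'
#' Rotates points about the pose's label-point centroid and applies the
#' vertical offset, returning lab-frame coordinates with the membrane plane
#' at z = 0.
#'
#' @param points Matrix (n x 3) of body-frame coordinates.
#' @param result A [dock_to_plane()] result.
#' @return Matrix (n x 3) of lab-frame coordinates.
#' @export
apply_pose <- function(points, result) {
  stopifnot(inherits(result, "docking_result"))
  pts <- sweep(as.matrix(points), 2, result$centroid)
  out <- pts %*% t(result$rotation)
  out[, 3] <- out[, 3] + result$z_offset
  out
}

#' Per-residue membrane depths under a docked pose
#'
#' Signed z coordinate (Angstrom; positive = hydrocarbon side of the
#' phosphate plane) of every Calpha atom under the fitted pose.
#'
#' @param structure A [structure_model()].
#' @param result A [dock_to_plane()] result for that structure.
#' @return Data frame with columns `residue` and `depth_A`.
#' @export
report_depths <- function(structure, result) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  ca <- a[a$atom == "CA", ]
  lab <- apply_pose(as.matrix(ca[c("x", "y", "z")]), result)
  data.frame(residue = ca$residue, depth_A = lab[, 3])
}
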