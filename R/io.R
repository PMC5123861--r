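#' Read a schema-validated CSV table
#'
#' Strict reader for the package's CSV dialects (comma-separated, dot
#' decimal, header required, UTF-8). Header matching is case-insensitive;
#' every schema column must be present and convert cleanly to its declared
#' type, and errors name the offending row and column.
#'
#' @param path File path.
#' @param schema Named character vector mapping column name to type
#'   (`"numeric"`, `"integer"`, `"character"`).
#' @return Data frame with the schema columns, in schema order.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) {
    cm_stop(sprintf("file not found: %s", path), "schema_error")
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  names(raw) <- tolower(names(raw))
  want <- tolower(names(schema))
  missing <- setdiff(want, names(raw))
  if (length(missing)) {
    cm_stop(sprintf("%s: missing column(s): %s", path,
                    paste(missing, collapse = ", ")), "schema_error")
  }
  if (nrow(raw) == 0L) {
    cm_stop(sprintf("%s: file has a header but no data rows", path),
            "schema_error")
  }
  out <- raw[want]
  for (j in seq_along(schema)) {
    type <- schema[[j]]; col <- want[j]
    if (type == "character") next
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]) & nzchar(trimws(out[[col]])))
    if (any(is.na(v)) ) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      cm_stop(sprintf("%s: non-numeric value '%s' at row %d, column '%s'",
                      path, out[[col]][row], row, col), "schema_error")
    }
    out[[col]] <- if (type == "integer") as.integer(v) else v
  }
  names(out) <- names(schema)
  out
}

#' Write a data frame in the package CSV dialect
#'
#' @param x Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records with bio3d and returns the package's rigid
#' [structure_model()]. Multi-model files default to the first model;
#' `model` selects another.
#'
#' @param path PDB file path.
#' @param model Model number for multi-model files (default 1).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, model = 1) {
  if (!file.exists(path)) {
    cm_stop(sprintf("file not found: %s", path), "schema_error")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) cm_stop("no ATOM records found", "invalid_structure")
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    cm_stop(sprintf("model %d requested; file has %d model(s)", model,
                    n_models), "invalid_structure")
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  keep <- which(pdb$atom$type == "ATOM")
  structure_model(data.frame(
    residue = at$resno, atom = at$elety,
    x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3]),
    chain = at$chain[1])
}

#' Write a structure (optionally docked) to a PDB file
#'
#' Writes the atoms of a [structure_model()] as standard fixed-width ATOM
#' records via bio3d. When a [dock_to_plane()] result is supplied the pose
#' is applied first and the membrane plane z = 0 is recorded in a REMARK.
#'
#' @param structure A [structure_model()].
#' @param path Output path.
#' @param pose Optional `docking_result` to apply before writing.
#' @return The path, invisibly.
#' @export
write_structure <- function(structure, path, pose = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  xyz <- as.matrix(a[c("x", "y", "z")])
  if (!is.null(pose)) xyz <- apply_pose(xyz, pose)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = a$residue, resid = rep("ALA", nrow(a)),
                   elety = a$atom, chain = rep(structure$chain %||% "A", nrow(a)))
  if (!is.null(pose)) {
    lines <- readLines(path)
    writeLines(c(
      "REMARK 999 MEMBRANE PLANE Z=0; +Z = HYDROCARBON SIDE OF PHOSPHATE PLANE",
      sprintf("REMARK 999 POSE TILT %.2f DEG, Z OFFSET %.2f A",
              pose$tilt_deg, pose$z_offset),
      lines), path)
  }
  invisible(path)
}

#' Validated pipeline configuration
#'
#' Bundles stage selection, the RNG seed, the output directory and the
#' physical defaults shared across stages; every default is validated
#' before any stage runs.
#'
#' @param stages Character vector from `c("kinetics", "itc", "partition",
#'   "epr", "csp", "dock")`; may be empty (no-op pipeline).
#' @param seed Integer RNG seed.
#' @param out_dir Output directory (created if needed at run time).
#' @param temperature Kelvin.
#' @param accessible_fraction Outer-leaflet lipid fraction, (0, 1].
#' @param lipids_per_vesicle Phospholipids per vesicle.
#' @param alpha 15N CSP weight.
#' @param label_offset Spin-label reach, Angstrom.
#' @param params Named list of per-stage parameter overrides.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stages = c("kinetics", "itc", "partition", "epr",
                                  "csp", "dock"),
                       seed = 1, out_dir = tempfile("c2membrane-"),
                       temperature = 298.15, accessible_fraction = 0.5,
                       lipids_per_vesicle = 90000, alpha = 0.2,
                       label_offset = 7.0, params = list()) {
  known <- c("kinetics", "itc", "partition", "epr", "csp", "dock")
  if (length(stages) && !all(stages %in% known)) {
    cm_stop(sprintf("unknown stage(s): %s",
                    paste(setdiff(stages, known), collapse = ", ")),
            "invalid_config")
  }
  stopifnot_scalar_pos(temperature, "temperature")
  stopifnot_scalar_pos(lipids_per_vesicle, "lipids_per_vesicle")
  if (accessible_fraction <= 0 || accessible_fraction > 1) {
    cm_stop("`accessible_fraction` must be in (0, 1]", "invalid_config")
  }
  stopifnot_scalar_pos(alpha, "alpha", strict = FALSE)
  stopifnot_scalar_pos(label_offset, "label_offset", strict = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(stages = stages, seed = as.integer(seed), out_dir = out_dir,
                 temperature = temperature,
                 accessible_fraction = accessible_fraction,
                 lipids_per_vesicle = lipids_per_vesicle, alpha = alpha,
                 label_offset = label_offset, params = params),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the simulate-and-analyse pipeline
#'
#' Executes the selected stages end to end on seeded synthetic data:
#' each stage simulates its input class with known ground truth, runs the
#' corresponding fitter, and records the recovered parameters with
#' uncertainties next to the truth. Reports are written as JSON plus tidy
#' CSVs under `config$out_dir` and are byte-reproducible for a fixed
#' (config, seed).
#'
#' @param config A [run_config()].
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!length(config$stages)) {
    message("run_pipeline: no stages selected; nothing to do")
    return(invisible(list()))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed)
  sd <- config$seed

  if ("kinetics" %in% config$stages) {
    comp <- lipid_composition(c(PtdChol = 0.88, PtdSer = 0.10, PtdInsP2 = 0.02),
                              lipids_per_vesicle = config$lipids_per_vesicle,
                              accessible_fraction = config$accessible_fraction)
    v <- vesicle_concentration(seq(30e-6, 270e-6, length.out = 6), comp)
    truth <- list(k_on = 1e11, k_off = 20)
    traces <- simulate_stopped_flow(truth$k_on, truth$k_off, v,
                                    noise = noise_model(0.005, sd + 1))
    fits <- lapply(traces, fit_monoexponential)
    ser <- kinetic_series(v, vapply(fits, `[[`, 1.0, "k_obs"),
                          vapply(fits, function(f) f$se[["k_obs"]], 1.0))
    rl <- fit_rate_law(ser)
    report$kinetics <- list(
      truth = truth,
      fit = list(k_on = rl$k_on, k_off = rl$k_off, K_d = rl$K_d,
                 se = as.list(rl$se)))
    write_table(data.frame(vesicle_M = ser$v, k_obs = ser$k_obs,
                           k_obs_se = ser$k_obs_se),
                file.path(config$out_dir, "kinetics_kobs.csv"))
  }

  if ("itc" %in% config$stages) {
    prot <- titration_protocol(1.4e-3, 50e-6, 1e-3, rep(10e-6, 25),
                               config$temperature)
    truth <- list(n = 1, K_d = 14e-6, dH = -30)
    sigma <- 0.02 * max(abs(predict_heats(truth$n, truth$K_d, truth$dH,
                                          prot)$q))
    sim <- simulate_itc(truth$n, truth$K_d, truth$dH, prot,
                        noise_model(sigma, sd + 2))
    fit <- fit_isotherm(sim, prot)
    report$itc <- list(truth = truth,
                       fit = list(n = fit$n, K_d = fit$K_d, dH = fit$dH,
                                  dG = fit$dG, minus_TdS = fit$minus_TdS,
                                  se = as.list(fit$se), c_value = fit$c_value))
    write_table(data.frame(injection = seq_along(sim$q),
                           molar_ratio = sim$molar_ratio, heat_kJ = sim$q),
                file.path(config$out_dir, "itc_heats.csv"))
  }

  if ("partition" %in% config$stages) {
    truth <- list(K = 2.2e4)
    L <- 10^seq(-6, -2.5, length.out = 12)
    sim <- simulate_sedimentation(truth$K, L, noise_model(0.02, sd + 3))
    fit <- fit_partition(sim)
    report$partition <- list(
      truth = truth,
      fit = list(K = fit$K, se = fit$se, half_binding_L = fit$half_binding_L))
    write_table(data.frame(lipid_M = sim$L, f_b = sim$f_b),
                file.path(config$out_dir, "partition_fb.csv"))
  }

  if ("epr" %in% config$stages) {
    truth <- c(N2 = 2, O2 = 12, NiEDDA = 5)
    curves <- simulate_power_saturation(truth, noise = noise_model(0.004, sd + 4))
    fits <- lapply(curves, fit_saturation)
    ph <- vapply(fits, `[[`, 1.0, "P_half")
    dp <- depth_parameter(ph[["O2"]], ph[["NiEDDA"]], ph[["N2"]])
    cal <- fit_calibration(spin_label_depths())
    x <- depth_from_phi(dp$phi, cal)
    report$epr <- list(truth = as.list(truth), P_half = as.list(ph),
                       phi = dp$phi, depth_A = x$x)
  }

  if ("csp" %in% config$stages) {
    base <- data.frame(residue = 300:340,
                       dH_ppm = 8 + 0.4 * sin(300:340),
                       dN_ppm = 118 + 4 * cos(300:340))
    planted <- list("325" = c(0.12, 0.8), "326" = c(0.15, 1.0),
                    "327" = c(0.13, 0.9))
    sim <- simulate_hsqc_shifts(base, planted, noise_model(0.002, sd + 5))
    prof <- csp_profile(sim$reference, sim$titrated, config$alpha)
    top <- rank_perturbed(prof)
    report$csp <- list(planted = names(planted), top = top$residue)
    write_table(prof[c("residue", "dH", "dN", "csp")],
                file.path(config$out_dir, "csp_profile.csv"))
  }

  if ("dock" %in% config$stages) {
    dom <- make_toy_domain(geometry_seed = sd + 6)
    sites <- c(4L, 10L, 16L, 22L)
    truth <- list(tilt = 35, azimuth = 120, z = -2)
    R <- rot_y(truth$tilt) %*% rot_z(truth$azimuth)
    pts <- t(vapply(sites, function(r)
      label_site_position(dom, r, config$label_offset), numeric(3)))
    ctr <- colMeans(pts)
    depths <- drop(sweep(pts, 2, ctr) %*% R[3, ]) + truth$z
    res <- dock_to_plane(dom, plane_restraints(sites, depths, 0.5),
                         label_offset = config$label_offset)
    report$dock <- list(truth = truth,
                        fit = list(tilt_deg = res$tilt_deg,
                                   z_offset = res$z_offset,
                                   objective = res$objective))
    write_structure(dom, file.path(config$out_dir, "docked_domain.pdb"),
                    pose = res)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
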