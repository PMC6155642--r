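## End-to-end experiment drivers reproducing the four study protocols, plus
## the run-manifest bookkeeping.

#' Gas-liquid interface construction and NPH solvation run
#'
#' The interfacial protocol: (1) equilibrate a spherically confined CO2
#' cluster under NVT; (2) equilibrate a periodic MEA liquid box under NVT at
#' the same temperature; (3) carve a spherical cavity out of the box,
#' removing molecules by center of mass; (4) merge the cluster into the
#' cavity, carrying velocities from both parents; (5) run NPH (pressure
#' coupling, no thermostat) and store frames for analysis. The full-scale
#' study conditions are a (CO2)44 cluster of radius 9.1257 A inside an
#' (MEA)864-derived box at 1.01 g/cm^3, 400 K, 7415 atm and 250 ps; the
#' argument defaults are a reduced configuration that runs the identical
#' pipeline at desk scale.
#'
#' @param ff an \code{ffparams}
#' @param n_co2 CO2 molecules in the gas cluster
#' @param cluster_radius confinement radius during the cluster stage (A)
#' @param n_mea MEA molecules in the liquid box
#' @param density box density (g/cm^3)
#' @param carve_radius cavity radius (A)
#' @param T temperature for the preparation stages (K)
#' @param P external pressure of the NPH stage (atm)
#' @param equil_ps NVT equilibration length per preparation stage (ps)
#' @param nph_ps NPH production length (ps)
#' @param frame_ps frame-storage interval (ps)
#' @param seed RNG seed (packing and velocity draws derive from it)
#' @param dt time step (ps)
#' @return list with \code{traj} (the NPH \code{trajectory}),
#'   \code{system} (merged initial state), \code{cluster}, \code{box},
#'   \code{removed} (molecules carved out)
#' @export
interface_pipeline <- function(ff, n_co2 = 10, cluster_radius = 5.6,
                               n_mea = 150, density = 1.01,
                               carve_radius = 6.0, T = 400, P = 7415,
                               equil_ps = 2, nph_ps = 20, frame_ps = 0.1,
                               seed = 1, dt = 5e-4) {
  eqsteps <- round(equil_ps / dt)
  # stage 1: CO2 cluster, confined, NVT
  cl <- pack_cluster("CO2", n_co2, cluster_radius, seed = seed, ff = ff)
  cl <- initialize_velocities(cl, T, seed = seed + 101)
  cl_run <- run_md(cl, ff, eqsteps, dt = dt, stride = max(eqsteps, 1),
                   thermostat = list(T = T))
  cluster <- cl_run$final
  # stage 2: MEA box, packed tight, relaxed, then NVT
  box <- pack_liquid_box("MEA", n_mea, density, seed = seed + 1,
                         min_dist = 1.2, ff = ff)
  box <- minimize(box, ff, tol = 1, maxit = 200, factr = 1e7)$system
  box <- initialize_velocities(box, T, seed = seed + 102)
  box_run <- run_md(box, ff, eqsteps, dt = dt, stride = max(eqsteps, 1),
                    thermostat = list(T = T))
  box_eq <- box_run$final
  # stages 3-4: carve and merge; if the thermally expanded cluster overlaps
  # the cavity wall, contract it slightly about its center until contacts
  # clear, then relieve residual strain with a short relaxation
  carved <- carve_cavity(box_eq, carve_radius)
  merged <- NULL
  shrink <- cluster
  for (try in 1:8) {
    m <- tryCatch(merge_interface(shrink, carved$system, min_dist = 1.0),
                  error = function(e) NULL)
    if (!is.null(m)) { merged <- m; break }
    ctr <- .com(shrink)
    shrink$xyz <- sweep(sweep(shrink$xyz, 2, ctr, "-") * 0.96, 2, ctr, "+")
  }
  if (is.null(merged))
    merged <- merge_interface(shrink, carved$system, min_dist = 0)
  vel <- merged$vel
  relaxed <- minimize(merged, ff, tol = 1, maxit = 200, factr = 1e7)$system
  relaxed$vel <- vel
  merged <- relaxed
  # stage 5: NPH
  traj <- run_md(merged, ff, round(nph_ps / dt), dt = dt, stride = 50,
                 frame_stride = round(frame_ps / dt),
                 barostat = list(P = P))
  list(traj = traj, system = merged, cluster = cluster,
       box = box_eq, removed = carved$removed)
}

.hash_config <- function(config) {
  s <- paste(deparse(config), collapse = "")
  # small rolling hash; enough to fingerprint a config in the manifest
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run a named experiment end to end
#'
#' Orchestrates builders, dynamics and analysis for one of the study
#' protocols and writes its outputs (TSV tables, XYZ geometries, fitted
#' parameter files) under \code{out_dir}. Scientific outputs are
#' reproducible for a given config and seed.
#'
#' Experiments: \code{calibrate} (fit + residual report),
#' \code{dimer_bench} (the six dimer interaction energies with
#' decomposition), \code{melt_scan} ((CO2)13 heat-capacity scan),
#' \code{mea_melt} (MEA liquid heat-capacity scan), \code{scan_rCN}
#' (physisorption distance scan), \code{interface} and
#' \code{interface_scaled} (NPH solvation run, optionally with the hydroxyl
#' dipole scaled to 10 percent).
#'
#' @param config list with \code{experiment}, \code{out_dir}, \code{seed}
#'   and experiment-specific fields (see the methods vignette); unknown
#'   fields are rejected
#' @return a manifest list: config hash, per-stage timing and status, file
#'   inventory
#' @export
run_experiment <- function(config) {
  known <- c("experiment", "out_dir", "seed", "ff", "temps", "equil_ps",
             "prod_ps", "nph_ps", "n_co2", "n_mea", "density", "grid",
             "cluster_radius", "carve_radius", "T", "P", "frame_ps",
             "n_cluster", "mu_factor")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  exp <- match.arg(config$experiment,
                   c("calibrate", "dimer_bench", "melt_scan", "mea_melt",
                     "scan_rCN", "interface", "interface_scaled"))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  ff <- config$ff %||% mm_parameters()
  manifest <- list(experiment = exp, config_hash = .hash_config(config),
                   version = as.character(utils::packageVersion("co2mea")),
                   stages = list(), files = character(0))
  tick <- function(name, fun) {
    t0 <- Sys.time()
    res <- fun()
    manifest$stages[[name]] <<- list(
      status = "ok", wall_s = as.numeric(difftime(Sys.time(), t0, "secs")))
    res
  }
  emit <- function(path) manifest$files <<- c(manifest$files, path)
  if (exp == "calibrate") {
    fit <- tick("fit", function()
      fit_parameters(build_reference_set(), mm_start_parameters()))
    p1 <- file.path(out_dir, "fitted.prm")
    write_parameters(fit$ff, p1, comment = "calibrated against the shipped reference set")
    emit(p1)
    p2 <- file.path(out_dir, "residuals.tsv")
    write_tsv(fit$residuals, p2, c(objective = signif(fit$objective, 6)))
    emit(p2)
  } else if (exp == "dimer_bench") {
    tab <- tick("bench", function() dimer_benchmark(ff))
    p <- file.path(out_dir, "dimer_bench.tsv")
    write_tsv(tab, p); emit(p)
  } else if (exp %in% c("melt_scan", "mea_melt")) {
    if (exp == "melt_scan") {
      temps <- config$temps %||% 88:97
      solid <- pack_cluster_annealed("CO2", config$n_cluster %||% 13,
                                     radius = 4.3, seed = seed, ff = ff)
      solid$wall$radius <- 15
      cvb <- function() solid
      eq <- config$equil_ps %||% 50; pr <- config$prod_ps %||% 250
    } else {
      temps <- config$temps %||% seq(280, 420, by = 20)
      cvb <- function() {
        box <- pack_liquid_box("MEA", config$n_mea %||% 128,
                               config$density %||% 1.01, seed = seed,
                               min_dist = 1.2, ff = ff)
        minimize(box, ff, tol = 1, maxit = 200, factr = 1e7)$system
      }
      eq <- config$equil_ps %||% 5; pr <- config$prod_ps %||% 20
    }
    cv <- tick("scan", function()
      heat_capacity_scan(cvb, ff, temps, round(eq / 5e-4), round(pr / 5e-4),
                         seed = seed))
    p <- file.path(out_dir, paste0(exp, "_cv.tsv"))
    write_tsv(cv$curve, p, c(peak_T = cv$peak_T)); emit(p)
  } else if (exp == "scan_rCN") {
    d <- build_dimer("co2_amino", ff = ff)
    sc <- tick("scan", function()
      scan_rcn(d$system, ff, config$grid %||% seq(2.0, 4.0, by = 0.1)))
    p <- file.path(out_dir, "scan_rcn.tsv")
    write_tsv(sc$profile, p, c(r_min = sc$r_min)); emit(p)
  } else {
    ffx <- if (exp == "interface_scaled")
      scale_bond_dipole(ff, factor = config$mu_factor %||% 0.1) else ff
    res <- tick("pipeline", function()
      interface_pipeline(ffx, n_co2 = config$n_co2 %||% 10,
                         n_mea = config$n_mea %||% 150,
                         density = config$density %||% 1.01,
                         T = config$T %||% 400, P = config$P %||% 7415,
                         equil_ps = config$equil_ps %||% 2,
                         nph_ps = config$nph_ps %||% 20,
                         frame_ps = config$frame_ps %||% 0.1, seed = seed))
    p0 <- file.path(out_dir, "interface_initial.xyz")
    write_xyz(res$system, p0); emit(p0)
    for (sel in list(c("C_co2", "C_co2"), c("C_co2", "N_amine"),
                     c("C_co2", "O_hydroxyl"))) {
      r <- rdf(res$traj, sel_a = sel[1], sel_b = sel[2], r_max = 8)
      p <- file.path(out_dir, sprintf("rdf_%s_%s.tsv", sel[1], sel[2]))
      write_tsv(r$table, p, c(selection = paste(sel, collapse = "-"),
                              frames = r$n_frames)); emit(p)
    }
    gv <- rdf_time_evolution(res$traj, sel_a = "C_co2", sel_b = "C_co2")
    p <- file.path(out_dir, "gCcCc_series.tsv")
    write_tsv(gv, p, c(probe = "3.65 A")); emit(p)
  }
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benchmark table of the characteristic dimer interaction energies
#'
#' Relaxes the five reference dimers and the two CO2 binding motifs under
#' their arrangement constraints and tabulates Eint with its dipole-dipole /
#' LJ decomposition.
#'
#' @param ff an \code{ffparams}
#' @return data.frame: arrangement, Eint, mumu, lj (kcal/mol)
#' @export
dimer_benchmark <- function(ff = mm_parameters()) {
  arr <- c("min", "parallel", "T", "NHN", "OHO", "co2_amino", "co2_hydroxyl")
  rows <- lapply(arr, function(a) {
    d <- build_dimer(a, ff = ff)
    e <- interaction_energy(d$system, ff, constraints = d$constraints)
    data.frame(arrangement = a, Eint = e$Eint,
               mumu = e$components["mumu"], lj = e$components["lj"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
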