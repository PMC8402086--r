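#' Simulation scenario
#'
#' Bundles geometry, fluid, actuation, perfusion and the transported
#' species into one run definition. For chip runs the species list holds
#' exactly oxygen and glucose.
#'
#' @param geometry \code{chip_geometry}
#' @param fluid \code{fluid_properties}
#' @param actuation \code{acoustic_actuation}
#' @param perfusion \code{perfusion_spec}
#' @param species named list of \code{species_spec} (oxygen, glucose)
#' @param label scenario label
#' @return object of class \code{scenario}
#' @export
scenario <- function(geometry = chip_geometry(), fluid = fluid_properties(),
                     actuation = acoustic_actuation(),
                     perfusion = perfusion_spec(),
                     species = list(oxygen = oxygen_spec(),
                                    glucose = glucose_spec()),
                     label = NULL) {
  if (is.null(label)) {
    label <- sprintf("d0=%.2gnm_Q=%g", actuation$d0 * 1e9, perfusion$Q)
  }
  out <- list(geometry = geometry, fluid = fluid, actuation = actuation,
              perfusion = perfusion, species = species, label = label)
  class(out) <- "scenario"
  out
}

#' Cartesian scenario sweep
#'
#' Expands a base scenario over actuation amplitudes and flow rates, with
#' optional overrides (currently \code{low_glucose = TRUE} replaces the
#' inlet glucose concentration by 1 mM, the low-glucose culture-medium
#' variant).
#'
#' @param base a \code{scenario}
#' @param d0_values_nm actuation amplitudes (nm), may include 0
#' @param Q_values flow rates (uL/min)
#' @param overrides list; supported: \code{low_glucose}
#' @return list of \code{scenario}s (empty if either value set is empty)
#' @export
make_scenario_sweep <- function(base, d0_values_nm, Q_values,
                                overrides = list()) {
  stopifnot(all(d0_values_nm >= 0), all(Q_values >= 0))
  out <- list()
  for (Q in Q_values) for (d0 in d0_values_nm) {
    sc <- base
    sc$actuation <- acoustic_actuation(
      f = base$actuation$f, d0 = d0 * 1e-9,
      actuated_boundary = base$actuation$actuated_boundary)
    sc$perfusion <- perfusion_spec(Q = Q)
    if (isTRUE(overrides$low_glucose)) {
      sc$species$glucose <- glucose_spec(c0 = 1)
      sc$label <- sprintf("d0=%.2gnm_Q=%g_lowGl", d0, Q)
    } else {
      sc$label <- sprintf("d0=%.2gnm_Q=%g", d0, Q)
    }
    out[[length(out) + 1]] <- sc
  }
  out
}

#' Create a run cache
#'
#' Meshes and acoustic solves are shared across the scenarios of a sweep
#' (the acoustic field is linear in the actuation amplitude, so one solve
#' per mesh and frequency serves every amplitude).
#'
#' @return an environment used as cache by \code{\link{run_case}}
#' @export
new_run_cache <- function() new.env(parent = emptyenv())

chip_wall_tags <- c("channel_walls", "well_walls", "actuated_wall",
                    "spheroid_interface")

geom_key <- function(geometry, mspec) {
  paste(c(unlist(geometry[c("channel_length", "channel_height", "well_width",
                            "well_height", "spheroid_diameter",
                            "well_center_x", "out_of_plane_depth")]),
          geometry$spheroid_center,
          mspec$n_bl, mspec$bl_total_um, mspec$h_well_um, mspec$h_channel_um,
          mspec$growth), collapse = "|")
}

#' Run one chip scenario end to end
#'
#' Executes the staged solution sequence: mesh, first-order acoustics,
#' streaming representation, combined mean flow, species transport (oxygen
#' then glucose), zone classification and the scenario report. The
#' acoustic stage short-circuits to zero fields when the actuation
#' amplitude is zero.
#'
#' Streaming representation: \code{"slip_velocity"} (default) solves the
#' damped bulk Helmholtz problem with resonance tracking (see
#' \code{\link{tracked_acoustics}}) and imposes the Rayleigh limiting
#' velocity on the walls; \code{"body_force"} solves the full thermoviscous
#' system and forces the mean flow with the second-order stresses, which
#' requires the boundary-layer-resolved mesh and is used for the
#' validation cavity.
#'
#' @param sc a \code{scenario}
#' @param mspec a \code{mesh_spec}; the default desk-scale resolution is
#'   \code{mesh_spec(n_boundary_layers = 3, bl_total_um = 5,
#'   h_well_um = 15, h_channel_um = 40, growth_rate = 1.6)}
#' @param streaming_mode "slip_velocity" or "body_force"
#' @param track_resonance operate at the cavity resonance nearest the
#'   nominal drive frequency (the physical operating point of the
#'   transducer); FALSE actuates at the nominal frequency as-is
#' @param cache environment from \code{\link{new_run_cache}} or NULL
#' @param keep_fields return the full field objects (mesh, flow,
#'   concentrations) besides the report row
#' @return list with \code{report} (named list, one row of the sweep
#'   table), \code{log} (stage diagnostics), and optionally the fields
#' @export
run_case <- function(sc, mspec = desk_mesh_spec(),
                     streaming_mode = c("slip_velocity", "body_force"),
                     track_resonance = TRUE, cache = NULL,
                     keep_fields = FALSE) {
  streaming_mode <- match.arg(streaming_mode)
  if (is.null(cache)) cache <- new_run_cache()
  om_nom <- sc$actuation$omega
  delta <- viscous_penetration_depth(sc$fluid, om_nom)
  key <- geom_key(sc$geometry, mspec)
  mk <- paste0("mesh|", key)
  if (is.null(cache[[mk]])) {
    dom <- build_chip_geometry(sc$geometry)
    mesh <- generate_mesh(dom, mspec, delta)
    cache[[mk]] <- list(mesh = mesh, med = submesh(mesh, 1L))
  }
  mesh <- cache[[mk]]$mesh; med <- cache[[mk]]$med
  # acoustic stage (linear in d0: cached at 1 nm reference amplitude)
  d0 <- sc$actuation$d0
  slip <- NULL; forcing <- NULL
  f_res <- NA_real_; inv_Q <- NA_real_
  if (d0 > 0) {
    if (streaming_mode == "slip_velocity") {
      ak <- paste0("helm|", key, "|", sc$actuation$f, "|", track_resonance)
      if (is.null(cache[[ak]])) {
        act_ref <- acoustic_actuation(f = sc$actuation$f, d0 = 1e-9,
                                      actuated_boundary = sc$actuation$actuated_boundary)
        cache[[ak]] <- tracked_acoustics(med, sc$fluid, act_ref,
                                         chip_wall_tags,
                                         track = track_resonance)
      }
      tr <- cache[[ak]]
      fo <- tr$fo
      s <- d0 / fo$d0
      fo$p1 <- fo$p1 * s; fo$rho1 <- fo$rho1 * s; fo$V1 <- fo$V1 * s
      fo$d0 <- d0
      f_res <- tr$f_res; inv_Q <- tr$inv_Q
      slip <- slip_velocity(fo, chip_wall_tags)
    } else {
      fo <- solve_first_order(med, sc$fluid, sc$actuation)
      forcing <- assemble_streaming_forcing(fo, sc$fluid)
      f_res <- sc$actuation$f
    }
  } else {
    fo <- zero_first_order(med, om_nom, 0, streaming_mode)
  }
  flow <- solve_mean_flow(med, sc$fluid, forcing = forcing,
                          perfusion = sc$perfusion, slip = slip)
  vel_full <- matrix(0, nrow(mesh$nodes), 2)
  vel_full[attr(med, "node_map"), ] <- flow$vel_p1
  conc <- lapply(sc$species, function(sp) solve_species(mesh, vel_full, sp))
  zm <- classify_zones(conc$oxygen, conc$glucose)
  zf <- zone_fractions(zm)
  ws <- wall_shear_stress(flow)
  lf <- lift_force(flow)
  fr <- zf$fractions
  report <- list(
    scenario = sc$label, label = sc$label,
    Q_uLmin = sc$perfusion$Q, d0_nm = d0 * 1e9,
    avg_O2_mM = average_concentration(conc$oxygen),
    avg_Gl_mM = average_concentration(conc$glucose),
    nec_O2_pct = fr$oxygen[["necrotic"]],
    qui_O2_pct = fr$oxygen[["quiescent"]],
    pro_O2_pct = fr$oxygen[["proliferating"]],
    nec_Gl_pct = fr$glucose[["necrotic"]],
    qui_Gl_pct = fr$glucose[["quiescent"]],
    pro_Gl_pct = fr$glucose[["proliferating"]],
    nec_comb_pct = fr$combined[["necrotic"]],
    qui_comb_pct = fr$combined[["quiescent"]],
    pro_comb_pct = fr$combined[["proliferating"]],
    tau_max_dyn_cm2 = ws$tau_max_dyn_cm2,
    lift_N = lf$lift_N)
  log <- list(label = sc$label, n_elements = n_elements(mesh),
              n_elements_medium = n_elements(med),
              streaming_mode = streaming_mode,
              f_nominal = sc$actuation$f, f_res = f_res, inv_Q = inv_Q,
              delta = delta,
              flow_iterations = flow$iterations,
              species_iterations = vapply(conc, function(x) x$iterations, 0L),
              net_weight_N = lf$net_weight_N)
  out <- list(report = report, log = log)
  if (keep_fields) {
    out$mesh <- mesh; out$flow <- flow; out$first_order <- fo
    out$concentrations <- conc; out$zones <- zm; out$slip <- slip
  }
  out
}

#' Default desk-scale mesh resolution for chip runs
#'
#' 15 um elements in the well and around the spheroid, 40 um in the
#' channel, three graded near-wall layers within 5 um. Chosen so that a
#' full scenario (acoustics, mean flow, two species) solves in tens of
#' seconds while zone fractions change by less than about one percentage
#' point under refinement (see the mesh convergence study).
#'
#' @return a \code{mesh_spec}
#' @export
desk_mesh_spec <- function() {
  mesh_spec(n_boundary_layers = 3, bl_total_um = 5, h_well_um = 15,
            h_channel_um = 40, growth_rate = 1.6)
}

#' Run a list of scenarios and collect the sweep table
#'
#' @param scenarios list of \code{scenario}
#' @param ... passed to \code{\link{run_case}}
#' @param cache shared run cache (created if NULL)
#' @return list with \code{table} (data frame, one row per scenario) and
#'   \code{logs}
#' @export
run_sweep <- function(scenarios, ..., cache = NULL) {
  if (is.null(cache)) cache <- new_run_cache()
  res <- lapply(scenarios, run_case, cache = cache, ...)
  tab <- do.call(rbind, lapply(res, function(r) {
    as.data.frame(r$report, stringsAsFactors = FALSE)
  }))
  list(table = tab, logs = lapply(res, `[[`, "log"))
}

#' Mesh convergence study
#'
#' Reruns a scenario on successively refined meshes (interior sizes scaled
#' by \code{factors}), tracking the maximum spheroid shear stress and the
#' spheroid-average oxygen concentration, and flags the first level whose
#' change from the previous one is below 1 percent for the concentration
#' and 3 percent for the shear stress.
#'
#' @param sc a \code{scenario}
#' @param factors decreasing mesh-size multipliers (>= 3 values), applied
#'   to the interior sizes of \code{base_spec}
#' @param base_spec starting \code{mesh_spec}
#' @param ... passed to \code{\link{run_case}}
#' @return data frame with elements, tau_max, avg_O2 and successive
#'   relative changes; attribute \code{converged_level}
#' @export
mesh_convergence_study <- function(sc, factors = c(1.5, 1, 0.67),
                                   base_spec = desk_mesh_spec(), ...) {
  if (length(factors) < 3) stop("at least 3 refinement levels required")
  if (any(diff(factors) >= 0)) stop("factors must be strictly decreasing")
  rows <- lapply(factors, function(f) {
    ms <- mesh_spec(n_boundary_layers = base_spec$n_bl,
                    bl_total_um = base_spec$bl_total_um,
                    h_well_um = base_spec$h_well_um * f,
                    h_channel_um = base_spec$h_channel_um * f,
                    growth_rate = base_spec$growth)
    r <- run_case(sc, mspec = ms, ...)
    data.frame(factor = f, elements = r$log$n_elements,
               tau_max = r$report$tau_max_dyn_cm2,
               avg_O2 = r$report$avg_O2_mM,
               pro_O2_pct = r$report$pro_O2_pct,
               nec_O2_pct = r$report$nec_O2_pct)
  })
  tab <- do.call(rbind, rows)
  tab$d_tau <- c(NA, abs(diff(tab$tau_max)) / utils::head(tab$tau_max, -1))
  tab$d_O2 <- c(NA, abs(diff(tab$avg_O2)) / utils::head(tab$avg_O2, -1))
  tab$d_pro_pp <- c(NA, abs(diff(tab$pro_O2_pct)))
  conv <- which(tab$d_O2 < 0.01 & tab$d_tau < 0.03)
  attr(tab, "converged_level") <- if (length(conv)) conv[1] else NA_integer_
  if (nrow(tab) >= 3 && any(diff(abs(diff(tab$avg_O2))) > 0)) {
    warning("avg O2 changes are not monotonically decreasing under refinement")
  }
  tab
}

## ---- configuration files ----------------------------------------------

#' Write a scenario (plus run options) to a YAML config
#' @param sc a \code{scenario}
#' @param path output path (.yaml or .json)
#' @param run_options optional list (mesh spec, streaming mode, ...)
#' @export
write_scenario_config <- function(sc, path, run_options = list()) {
  cfg <- list(
    label = sc$label,
    geometry_um = sc$geometry[c("channel_length", "channel_height",
                                "well_width", "well_height",
                                "spheroid_diameter", "well_center_x",
                                "out_of_plane_depth")],
    spheroid_center_um = as.numeric(sc$geometry$spheroid_center),
    fluid = sc$fluid[c("rho0", "mu", "muB", "Cp", "alpha0", "beta0", "ca",
                       "T0", "k_thermal")],
    actuation = list(f_MHz = sc$actuation$f / 1e6,
                     d0_nm = sc$actuation$d0 * 1e9),
    perfusion = list(Q_uLmin = sc$perfusion$Q),
    species = lapply(sc$species, function(s) {
      s[c("D_medium", "D_spheroid", "S", "Vmax", "Km", "c0_inlet",
          "necrotic_threshold", "quiescent_threshold")]
    }),
    run_options = run_options)
  if (grepl("[.]json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(cfg)
}

#' Read a scenario from a YAML/JSON config
#' @param path config path
#' @return a \code{scenario}; run options (if any) in attribute
#'   \code{run_options}
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  g <- cfg$geometry_um
  geom <- chip_geometry(channel_length = g$channel_length,
                        channel_height = g$channel_height,
                        well_width = g$well_width,
                        well_height = g$well_height,
                        spheroid_diameter = g$spheroid_diameter,
                        well_center_x = g$well_center_x,
                        spheroid_center = as.numeric(cfg$spheroid_center_um),
                        out_of_plane_depth = g$out_of_plane_depth)
  fl <- do.call(fluid_properties, cfg$fluid)
  species <- lapply(names(cfg$species), function(nm) {
    do.call(species_spec, c(list(name = nm), cfg$species[[nm]]))
  })
  names(species) <- names(cfg$species)
  sc <- scenario(geometry = geom, fluid = fl,
                 actuation = acoustic_actuation(f = cfg$actuation$f_MHz * 1e6,
                                                d0 = cfg$actuation$d0_nm * 1e-9),
                 perfusion = perfusion_spec(Q = cfg$perfusion$Q_uLmin),
                 species = species, label = cfg$label)
  attr(sc, "run_options") <- cfg$run_options
  sc
}

## ---- field export ------------------------------------------------------

#' Export a mesh with nodal fields as ASCII VTU
#'
#' Minimal unstructured-grid writer for inspection in ParaView-class
#' viewers; complex fields are written as real/imaginary pairs.
#'
#' @param mesh a \code{fem_mesh}
#' @param path output .vtu path
#' @param point_data named list of nodal vectors (real or complex)
#' @export
write_mesh_vtu <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n,
    '" NumberOfCells="', m, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(mesh$tri[, 1] - 1, mesh$tri[, 2] - 1, mesh$tri[, 3] - 1), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * 3), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(5L, m)), con)
  w('</DataArray></Cells>')
  expand <- list()
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.complex(v)) {
      expand[[paste0(nm, "_re")]] <- Re(v)
      expand[[paste0(nm, "_im")]] <- Im(v)
    } else expand[[nm]] <- v
  }
  w('<PointData>')
  for (nm in names(expand)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    writeLines(paste(expand[[nm]]), con)
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
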