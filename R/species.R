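#' Transported species specification
#'
#' Diffusivities in medium and aggregate tissue, solubility (partition)
#' coefficient of the aggregate relative to the medium, Michaelis-Menten
#' consumption parameters and the lethal/growth concentration thresholds.
#' Concentration units are mM (= mol/m3), so all parameters combine
#' consistently with SI lengths and times.
#'
#' @param name species name
#' @param D_medium,D_spheroid diffusivities (m2/s)
#' @param S partition coefficient (aggregate vs medium)
#' @param Vmax maximum consumption rate (mM/s)
#' @param Km Michaelis-Menten constant (mM)
#' @param c0_inlet inlet concentration (mM)
#' @param necrotic_threshold,quiescent_threshold zone thresholds (mM)
#' @return object of class \code{species_spec}
#' @export
species_spec <- function(name, D_medium, D_spheroid, S, Vmax, Km, c0_inlet,
                         necrotic_threshold, quiescent_threshold) {
  vals <- c(D_medium = D_medium, D_spheroid = D_spheroid, S = S,
            Vmax = Vmax, Km = Km, c0_inlet = c0_inlet,
            necrotic_threshold = necrotic_threshold,
            quiescent_threshold = quiescent_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all species parameters must be positive and finite")
  }
  if (!(necrotic_threshold < quiescent_threshold &&
        quiescent_threshold < c0_inlet)) {
    stop("thresholds must satisfy necrotic < quiescent < c0_inlet")
  }
  out <- as.list(vals)
  out$name <- name
  class(out) <- "species_spec"
  out
}

#' Oxygen with standard culture-medium parameters
#' @return \code{species_spec}
#' @export
oxygen_spec <- function() {
  species_spec("oxygen", D_medium = 2.6e-9, D_spheroid = 1.83e-9, S = 4.81,
               Vmax = 0.0203, Km = 0.00463, c0_inlet = 0.2,
               necrotic_threshold = 0.002644, quiescent_threshold = 0.01322)
}

#' Glucose with standard (or low-glucose) culture-medium parameters
#' @param c0 inlet concentration in mM; 5 for standard DMEM-like medium,
#'   1 for the low-glucose variant
#' @return \code{species_spec}
#' @export
glucose_spec <- function(c0 = 5) {
  species_spec("glucose", D_medium = 9.27e-10, D_spheroid = 2.7e-10, S = 1,
               Vmax = 0.01076, Km = 0.04, c0_inlet = c0,
               necrotic_threshold = 0.2, quiescent_threshold = 0.5)
}

#' Michaelis-Menten consumption rate
#'
#' Saturating uptake \eqn{R = V_{max} c / (c + K_m)}, applied as a sink in
#' the spheroid tissue. Negative concentrations (possible as transient
#' Newton undershoot) are clamped to zero with a warning.
#'
#' @param c concentration (mM)
#' @param Vmax maximum rate (mM/s)
#' @param Km half-saturation constant (mM)
#' @return rate (mM/s)
#' @export
michaelis_menten_rate <- function(c, Vmax, Km) {
  if (any(c < 0)) {
    warning("negative concentration clamped to 0 in Michaelis-Menten rate")
    c <- pmax(c, 0)
  }
  Vmax * c / (c + Km)
}

#' Discrete realization of the solubility-jump interface coupling
#'
#' The concentration jump \eqn{c_{agg} = S\,c_{med}} with diffusive-flux
#' continuity is realized by the substituted variable
#' \eqn{u = c / S_{dom}} (\eqn{S_{dom}=1} in the medium, \eqn{S} in the
#' aggregate), which is continuous across the interface; flux continuity
#' becomes conservation of \eqn{(D\,S_{dom})\nabla u}, the natural
#' interface condition of the weighted weak form.
#'
#' @param spec a \code{species_spec}
#' @return list with per-region scaling \code{S_region} and effective
#'   diffusivity \code{D_eff} (medium, spheroid)
#' @export
interface_coupling_transform <- function(spec) {
  if (spec$S <= 0) stop("partition coefficient S must be positive")
  list(S_region = c(medium = 1, spheroid = spec$S),
       D_eff = c(medium = spec$D_medium,
                 spheroid = spec$D_spheroid * spec$S))
}

#' Solve steady species transport with Michaelis-Menten consumption
#'
#' Advection-diffusion in the medium, diffusion + saturating consumption in
#' the spheroid, coupled through the solubility jump (see
#' \code{\link{interface_coupling_transform}}). Inlet Dirichlet
#' concentration, zero diffusive flux at the outlet, no-flux walls. The
#' nonlinearity is handled by damped Newton iteration with a mass-lumped
#' reaction term; convergence on relative residual 1e-3 with an absolute
#' 1e-9 safeguard.
#'
#' @param mesh full \code{fem_mesh} (medium + spheroid regions)
#' @param vel n x 2 nodal velocity (m/s) on the full mesh (zero inside the
#'   spheroid); NULL for pure diffusion
#' @param spec \code{species_spec}
#' @param dirichlet optional named list \code{list(tag = value)} overriding
#'   the default inlet condition (used by oracle sub-problems)
#' @param tol relative residual tolerance
#' @param max_iter Newton cap
#' @param stabilization "auto" enables streamline diffusion when the
#'   maximum cell Peclet number exceeds 2 (acoustically stirred runs);
#'   "none" is plain Galerkin (adequate for perfusion-only transport);
#'   "streamline" forces it on
#' @return object of class \code{concentration_field} with the continuous
#'   variable \code{u} and the physical concentrations
#' @export
solve_species <- function(mesh, vel, spec, dirichlet = NULL,
                          tol = 1e-3, max_iter = 50,
                          stabilization = c("auto", "none", "streamline")) {
  stabilization <- match.arg(stabilization)
  n <- nrow(mesh$nodes)
  ict <- interface_coupling_transform(spec)
  in_sph <- mesh$region == 2L
  D_el <- ifelse(in_sph, ict$D_eff[["spheroid"]], ict$D_eff[["medium"]])
  K <- p1_stiffness(mesh, D_el)
  Cv <- if (!is.null(vel)) p1_convection(mesh, vel, elems = !in_sph) else
    sp(1, 1, 0, n)
  if (!is.null(vel) && stabilization != "none") {
    g <- mesh_geom(mesh)
    vc <- sqrt(rowMeans(matrix(vel[mesh$tri, 1], ncol = 3))^2 +
               rowMeans(matrix(vel[mesh$tri, 2], ncol = 3))^2)
    pe_max <- max(vc * sqrt(2 * g$A) / (2 * D_el))
    if (stabilization == "streamline" || pe_max > 2) {
      Cv <- Cv + p1_streamline_diffusion(mesh, vel, D_el, elems = !in_sph)
    }
  }
  A_sph <- lumped_area(mesh, elems = in_sph)
  S <- spec$S; Vmax <- spec$Vmax; Km <- spec$Km
  if (is.null(dirichlet)) {
    dirichlet <- if ("inlet" %in% mesh$btag) list(inlet = spec$c0_inlet)
    else list()
  }
  didx <- integer(0); dval <- numeric(0)
  for (tg in names(dirichlet)) {
    nds <- nodes_on_tags(mesh, tg)
    didx <- c(didx, nds); dval <- c(dval, rep(dirichlet[[tg]], length(nds)))
  }
  keep <- !duplicated(didx)
  didx <- didx[keep]; dval <- dval[keep]
  L <- K + Cv
  u <- rep(if (length(dval)) max(dval) else spec$c0_inlet, n)
  u[didx] <- dval
  mask <- rep(1, n); mask[didx] <- 0
  # Michaelis-Menten sink with a C1 linear extension below c = 0 (rate
  # slope Vmax/Km continued), so transient Newton undershoots see a smooth
  # restoring term instead of a kink.
  mm_ext <- function(c) ifelse(c >= 0, Vmax * c / (c + Km), Vmax / Km * c)
  mm_ext_d <- function(c) ifelse(c >= 0, Vmax * Km / (c + Km)^2, Vmax / Km)
  # residual scale: total consumption at saturation (units mM m2/s)
  res_scale <- max(sqrt(sum((A_sph * Vmax)^2)), 1e-300)
  for (it in seq_len(max_iter)) {
    cs <- S * u
    Fres <- (as.vector(L %*% u) + A_sph * mm_ext(cs)) * mask
    rn <- sqrt(sum(Fres^2))
    if (rn <= tol * res_scale) break
    J <- L + Matrix::Diagonal(n, A_sph * mm_ext_d(cs) * S)
    bd <- apply_dirichlet(J, -Fres, didx, numeric(length(didx)))
    du <- sp_solve(bd$A, bd$b)
    # damping: halve the step while it fails to reduce the residual
    lam <- 1
    repeat {
      u_try <- u + lam * du
      F_t <- (as.vector(L %*% u_try) + A_sph * mm_ext(S * u_try)) * mask
      if (sqrt(sum(F_t^2)) <= (1 - 0.25 * lam) * rn || lam < 1 / 16) break
      lam <- lam / 2
    }
    u <- u + lam * du
    if (max(abs(lam * du)) <= 1e-9) break  # absolute 1e-9 mM safeguard
  }
  if (it == max_iter && rn > tol * res_scale) {
    stop(sprintf("species transport did not converge: residual %.3g (rel %.3g)",
                 rn, rn / res_scale))
  }
  cmax <- if (length(dval)) max(dval) else spec$c0_inlet
  # gross bound violations abort; small discretization overshoots are
  # reported via attributes and checked by the property suite
  if (any(u < -1e-2 * cmax) || any(u > cmax * (1 + 1e-2))) {
    stop(sprintf(
      "maximum principle grossly violated: range [%.3g, %.3g] mM",
      min(u), max(u)))
  }
  out <- list(mesh = mesh, u = u, spec = spec,
              c_medium = u, c_spheroid = S * u, iterations = it)
  class(out) <- "concentration_field"
  out
}

#' Area-weighted average concentration over a region
#'
#' @param conc a \code{concentration_field}
#' @param region "spheroid" (default; uses the aggregate-side concentration
#'   \eqn{S u}) or "medium"
#' @return mean concentration (mM)
#' @export
average_concentration <- function(conc, region = "spheroid") {
  mesh <- conc$mesh
  rid <- match(region, c("medium", "spheroid"))
  sel <- mesh$region == rid
  if (!any(sel)) stop("empty region: ", region)
  g <- mesh_geom(mesh)
  vals <- if (region == "spheroid") conc$c_spheroid else conc$c_medium
  vm <- matrix(vals[mesh$tri[sel, ]], ncol = 3)
  sum(g$A[sel] * rowMeans(vm)) / sum(g$A[sel])
}

#' Global species conservation residual
#'
#' At steady state the net convective + diffusive influx across the open
#' boundaries balances the total Michaelis-Menten consumption inside the
#' spheroid. Returns the imbalance relative to the total consumption.
#'
#' @param conc a \code{concentration_field}
#' @param vel nodal velocity used in the solve
#' @return list with \code{consumption}, \code{net_influx} (mM m2/s per
#'   unit depth) and \code{rel_imbalance}
#' @export
species_conservation <- function(conc, vel) {
  mesh <- conc$mesh
  in_sph <- mesh$region == 2L
  A_sph <- lumped_area(mesh, elems = in_sph)
  cs <- pmax(conc$spec$S * conc$u, 0)
  consumption <- sum(A_sph * conc$spec$Vmax * cs / (cs + conc$spec$Km))
  # weak-form boundary flux: residual of the interior equations against the
  # constant-one test function restricted to non-Dirichlet nodes equals the
  # boundary influx; evaluate flux through inlet/outlet directly instead.
  influx <- 0
  for (tg in intersect(unique(mesh$btag), c("inlet", "outlet"))) {
    eo <- edge_owner(mesh, tg)
    if (!nrow(eo$edge)) next
    g <- mesh_geom(mesh)
    for (k in seq_len(nrow(eo$edge))) {
      e <- eo$elem[k]
      a <- eo$edge[k, 1]; b <- eo$edge[k, 2]
      pa <- mesh$nodes[a, ]; pb <- mesh$nodes[b, ]
      tv <- pb - pa; len <- sqrt(sum(tv^2)); tv <- tv / len
      nor <- c(tv[2], -tv[1])
      other <- setdiff(mesh$tri[e, ], c(a, b))
      mid <- (pa + pb) / 2
      if (sum((mesh$nodes[other, ] - mid) * nor) > 0) nor <- -nor
      cmid <- mean(conc$u[c(a, b)])
      vmid <- colMeans(vel[c(a, b), , drop = FALSE])
      gradc <- c(sum(conc$u[mesh$tri[e, ]] * g$gx[e, ]),
                 sum(conc$u[mesh$tri[e, ]] * g$gy[e, ]))
      D <- conc$spec$D_medium
      flux_out <- (cmid * sum(vmid * nor) - D * sum(gradc * nor)) * len
      influx <- influx - flux_out
    }
  }
  list(consumption = consumption, net_influx = influx,
       rel_imbalance = abs(influx - consumption) / max(consumption, 1e-300))
}
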