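#' Perfusion specification
#'
#' @param Q volumetric flow rate in uL/min (>= 0)
#' @param inlet_profile only "parabolic" (fully developed plane Poiseuille)
#' @param outlet_pressure gauge pressure at the outlet (Pa)
#' @return object of class \code{perfusion_spec}
#' @export
perfusion_spec <- function(Q = 1, inlet_profile = "parabolic",
                           outlet_pressure = 0) {
  stopifnot(Q >= 0, inlet_profile == "parabolic")
  out <- list(Q = Q, inlet_profile = inlet_profile,
              outlet_pressure = outlet_pressure)
  class(out) <- "perfusion_spec"
  out
}

uL_min_to_m3_s <- function(Q) Q * 1e-9 / 60

#' Fully developed inlet velocity profile
#'
#' Plane-Poiseuille parabola across the channel height with mean velocity
#' \eqn{U = Q / (H\, d)}, where \eqn{d} is the out-of-plane depth used to
#' interpret the volumetric flow rate in 2D; the peak velocity is
#' \eqn{1.5\,U}.
#'
#' @param Q flow rate (uL/min)
#' @param geometry a \code{chip_geometry}
#' @return function of y (metres, 0 at the channel floor) giving the axial
#'   velocity (m/s); carries attributes \code{U_mean} and \code{U_peak}
#' @export
inlet_profile <- function(Q, geometry) {
  stopifnot(Q >= 0)
  H <- geometry$channel_height * 1e-6
  depth <- geometry$out_of_plane_depth * 1e-6
  if (depth <= 0) stop("out_of_plane_depth must be positive")
  U <- uL_min_to_m3_s(Q) / (H * depth)
  f <- function(y) 6 * U * y * (H - y) / H^2
  attr(f, "U_mean") <- U
  attr(f, "U_peak") <- 1.5 * U
  f
}

#' Solve the steady time-averaged mean flow
#'
#' Incompressible Navier-Stokes (Taylor-Hood P2/P1) for the combined
#' perfusion + acoustic-streaming mean flow. The streaming enters either as
#' the second-order body force and mass source ("body_force" mode) or as a
#' Rayleigh limiting velocity imposed tangentially on the walls
#' ("slip_velocity" mode). Perfusion and streaming are solved together in a
#' single system; the convective term is retained via Picard iteration
#' (negligible at chip Reynolds numbers but kept for fidelity).
#'
#' Boundary conditions: parabolic inlet, stress-free outlet (p ~ 0),
#' no-slip (or slip) on all walls including the spheroid interface. For a
#' closed domain (no inlet/outlet) the pressure is gauged by a zero-mean
#' constraint.
#'
#' @param mesh medium-region \code{fem_mesh} (flow never enters the
#'   spheroid)
#' @param fluid \code{fluid_properties}
#' @param forcing output of \code{\link{assemble_streaming_forcing}}, or
#'   NULL
#' @param perfusion \code{perfusion_spec}, or NULL for a closed cavity
#' @param slip n x 2 wall slip-velocity matrix from
#'   \code{\link{slip_velocity}}, or NULL
#' @param tol nonlinear relative-update tolerance (default 1e-6)
#' @param max_iter Picard iteration cap
#' @return object of class \code{mean_flow_field}: P2 nodal velocity
#'   (\code{ux}, \code{uy}), P1 pressure \code{p}, and vertex-restricted
#'   velocity \code{vel_p1}
#' @export
solve_mean_flow <- function(mesh, fluid, forcing = NULL, perfusion = NULL,
                            slip = NULL, tol = 1e-6, max_iter = 25) {
  p2 <- p2_connect(mesh)
  n <- nrow(mesh$nodes); n2 <- p2$n_p2
  mu <- fluid$mu; rho0 <- fluid$rho0
  A <- p2_operator(mesh, "stiffness", coef = mu)
  Dx <- p2_div_block(mesh, "x")
  Dy <- p2_div_block(mesh, "y")
  has_io <- any(mesh$btag %in% c("inlet", "outlet"))
  fx <- numeric(n2); fy <- numeric(n2); g <- numeric(n)
  if (!is.null(forcing)) {
    fx <- p2_load(mesh, forcing$body_force[, 1])
    fy <- p2_load(mesh, forcing$body_force[, 2])
    g <- p1_load(mesh, forcing$mass_source / rho0)
  }
  # Dirichlet values on P2 boundary nodes
  wall_tags <- setdiff(unique(mesh$btag), c("inlet", "outlet"))
  bidx <- integer(0); bux <- numeric(0); buy <- numeric(0)
  wall_p2 <- p2_nodes_on_tags(mesh, wall_tags)
  if (length(wall_p2)) {
    sv <- matrix(0, n2, 2)
    if (!is.null(slip)) {
      sv[1:n, ] <- slip
      sv[(n + 1):n2, ] <- p2_midedge_average(mesh, slip)
    }
    bidx <- wall_p2; bux <- sv[wall_p2, 1]; buy <- sv[wall_p2, 2]
  }
  if (has_io && !is.null(perfusion)) {
    prof <- inlet_profile(perfusion$Q, mesh$domain$geometry)
    in_p2 <- p2_nodes_on_tags(mesh, "inlet")
    yy <- p2$coords[in_p2, 2]
    keep <- !(in_p2 %in% bidx)  # wall corners keep wall values
    bidx <- c(bidx, in_p2[keep])
    bux <- c(bux, prof(yy[keep]))
    buy <- c(buy, numeric(sum(keep)))
  }
  ux <- numeric(n2); uy <- numeric(n2)
  ux[bidx] <- bux; uy[bidx] <- buy
  closed <- !has_io
  ap <- lumped_area(mesh)  # int p dx with P1 shapes (lumped)
  ndof <- 2 * n2 + n + closed
  for (iter in seq_len(max_iter)) {
    C <- p2_operator(mesh, "convection", coef = rho0, vel = cbind(ux, uy))
    Auu <- A + C
    Zn2n2 <- sp(1, 1, 0, n2)
    rows <- list(
      cbind(Auu, Zn2n2, -Matrix::t(Dx)),
      cbind(Zn2n2, Auu, -Matrix::t(Dy)),
      cbind(Dx, Dy, sp(1, 1, 0, n, n)))
    S <- do.call(rbind, rows)
    rhs <- c(fx, fy, g)
    if (closed) {
      S <- rbind(cbind(S, c(numeric(2 * n2), ap)),
                 c(numeric(2 * n2), ap, 0))
      rhs <- c(rhs, 0)
    }
    bd <- apply_dirichlet(S, rhs, c(bidx, n2 + bidx), c(bux, buy))
    sol <- sp_solve(bd$A, bd$b)
    ux_new <- sol[1:n2]; uy_new <- sol[(n2 + 1):(2 * n2)]
    dv <- sqrt(sum((ux_new - ux)^2 + (uy_new - uy)^2))
    sc <- sqrt(sum(ux_new^2 + uy_new^2))
    ux <- ux_new; uy <- uy_new
    p <- sol[(2 * n2 + 1):(2 * n2 + n)]
    if (sc == 0 || dv <= tol * sc) break
  }
  if (iter == max_iter && sc > 0 && dv > tol * sc) {
    Umax <- max(sqrt(ux^2 + uy^2))
    Lc <- max(mesh$nodes[, 1]) - min(mesh$nodes[, 1])
    stop(sprintf("mean flow did not converge (Re ~ %.3g)",
                 rho0 * Umax * Lc / mu))
  }
  out <- list(mesh = mesh, p2 = p2, ux = ux, uy = uy, p = p,
              vel_p1 = cbind(ux[1:n], uy[1:n]),
              fluid = fluid, iterations = iter)
  class(out) <- "mean_flow_field"
  out
}

# Average of a vertex-valued field onto P2 mid-edge nodes.
p2_midedge_average <- function(mesh, vals) {
  p2 <- p2_connect(mesh)
  tri <- mesh$tri
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  uk <- unique(key)
  first <- match(uk, key)
  if (is.matrix(vals)) {
    (vals[ed[first, 1], , drop = FALSE] + vals[ed[first, 2], , drop = FALSE]) / 2
  } else {
    (vals[ed[first, 1]] + vals[ed[first, 2]]) / 2
  }
}

#' Volume flux through a tagged boundary
#'
#' Integral of the outward normal velocity over the tagged boundary (per
#' unit out-of-plane depth, m2/s). Used for mass-conservation checks:
#' inlet + outlet flux must balance the integrated continuity source.
#'
#' @param flow a \code{mean_flow_field}
#' @param tag boundary tag
#' @return net outward flux (m2/s)
#' @export
flow_flux <- function(flow, tag) {
  mesh <- flow$mesh
  eo <- edge_owner(mesh, tag)
  if (!nrow(eo$edge)) return(0)
  out <- 0
  for (k in seq_len(nrow(eo$edge))) {
    a <- eo$edge[k, 1]; b <- eo$edge[k, 2]
    pa <- mesh$nodes[a, ]; pb <- mesh$nodes[b, ]
    tv <- pb - pa; len <- sqrt(sum(tv^2)); tv <- tv / len
    nor <- c(tv[2], -tv[1])
    e <- eo$elem[k]
    other <- setdiff(mesh$tri[e, ], c(a, b))
    mid <- (pa + pb) / 2
    if (sum((mesh$nodes[other, ] - mid) * nor) > 0) nor <- -nor
    # Simpson rule with the P2 mid-edge value
    p2 <- flow$p2
    loc <- eo$local[k]
    midn <- p2$t2[e, 3 + loc]
    un <- c(sum(flow$vel_p1[a, ] * nor),
            flow$ux[midn] * nor[1] + flow$uy[midn] * nor[2],
            sum(flow$vel_p1[b, ] * nor))
    out <- out + len * sum(un * c(1, 4, 1)) / 6
  }
  out
}

# Map boundary edges (of given tags) to their owning triangle and local
# edge; returns data frame-ish list.
edge_owner <- function(mesh, tags) {
  ed <- boundary_edges(mesh, tags)
  tri <- mesh$tri
  all_ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(all_ed[, 1], all_ed[, 2]), pmax(all_ed[, 1], all_ed[, 2]))
  bkey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  pos <- match(bkey, key)
  m <- nrow(tri)
  list(edge = ed, elem = ((pos - 1) %% m) + 1, local = ((pos - 1) %/% m) + 1)
}

# Stress evaluation on tagged boundary edges of a mean flow: returns
# midpoints, outward normals (pointing out of the flow domain), edge
# lengths, traction vectors and tangential traction magnitude.
boundary_traction <- function(flow, tags) {
  mesh <- flow$mesh
  eo <- edge_owner(mesh, tags)
  ne <- nrow(eo$edge)
  g <- mesh_geom(mesh)
  p2 <- flow$p2
  mu <- flow$fluid$mu
  out_mid <- matrix(0, ne, 2); out_n <- matrix(0, ne, 2)
  out_len <- numeric(ne); out_tr <- matrix(0, ne, 2); out_tau <- numeric(ne)
  # local edges: 1 = (v1,v2), 2 = (v2,v3), 3 = (v3,v1)
  lam_mid <- rbind(c(.5, .5, 0), c(0, .5, .5), c(.5, 0, .5))
  for (k in seq_len(ne)) {
    e <- eo$elem[k]; le <- eo$local[k]
    lam <- lam_mid[le, ]
    s <- p2_shape(lam)
    gx <- s$dN %*% g$gx[e, ]; gy <- s$dN %*% g$gy[e, ]
    dofs <- p2$t2[e, ]
    dudx <- sum(gx * flow$ux[dofs]); dudy <- sum(gy * flow$ux[dofs])
    dvdx <- sum(gx * flow$uy[dofs]); dvdy <- sum(gy * flow$uy[dofs])
    pmid <- sum(lam * flow$p[mesh$tri[e, ]])
    a <- eo$edge[k, 1]; b <- eo$edge[k, 2]
    pa <- mesh$nodes[a, ]; pb <- mesh$nodes[b, ]
    tv <- pb - pa; len <- sqrt(sum(tv^2)); tv <- tv / len
    nor <- c(tv[2], -tv[1])
    # orient outward: away from the element's third vertex
    other <- setdiff(mesh$tri[e, ], c(a, b))
    mid <- (pa + pb) / 2
    if (sum((mesh$nodes[other, ] - mid) * nor) > 0) nor <- -nor
    sxx <- -pmid + 2 * mu * dudx
    syy <- -pmid + 2 * mu * dvdy
    sxy <- mu * (dudy + dvdx)
    tr <- c(sxx * nor[1] + sxy * nor[2], sxy * nor[1] + syy * nor[2])
    tt <- tr - sum(tr * nor) * nor
    out_mid[k, ] <- mid; out_n[k, ] <- nor; out_len[k] <- len
    out_tr[k, ] <- tr; out_tau[k] <- sqrt(sum(tt^2))
  }
  list(mid = out_mid, normal = out_n, len = out_len,
       traction = out_tr, tau = out_tau)
}

#' Wall shear stress on the spheroid surface
#'
#' Tangential traction magnitude along the spheroid interface and its
#' maximum, reported in dyne/cm2 (1 Pa = 10 dyne/cm2). The biological
#' safety bound for cultured cells is 0.5 dyne/cm2.
#'
#' @param flow a \code{mean_flow_field}
#' @param interface boundary tag (default "spheroid_interface")
#' @return list with the per-edge profile (\code{mid}, \code{tau_Pa}) and
#'   \code{tau_max_dyn_cm2}
#' @export
wall_shear_stress <- function(flow, interface = "spheroid_interface") {
  bt <- boundary_traction(flow, interface)
  list(mid = bt$mid, tau_Pa = bt$tau,
       tau_max_dyn_cm2 = if (length(bt$tau)) max(bt$tau) * 10 else 0)
}

#' Hydrodynamic lift force on the spheroid
#'
#' Vertical component of the surface-integrated mean-flow traction
#' (pressure + viscous) over the spheroid interface, multiplied by the
#' out-of-plane depth. Compared against the net submerged weight
#' \eqn{(\rho_{sph}-\rho_0) g (\pi/6) d^3} computed with the configured
#' spheroid density.
#'
#' @param flow a \code{mean_flow_field}
#' @param interface boundary tag
#' @param depth out-of-plane depth (m); default from the mesh domain
#' @param rho_spheroid spheroid density (kg/m3), default 1050 (typical
#'   tissue)
#' @return list with \code{lift_N} and \code{net_weight_N}
#' @export
lift_force <- function(flow, interface = "spheroid_interface",
                       depth = flow$mesh$domain$depth,
                       rho_spheroid = 1050) {
  bt <- boundary_traction(flow, interface)
  # traction uses the outward normal of the flow domain (pointing into the
  # spheroid); force on the spheroid flips the sign
  lift <- -sum(bt$traction[, 2] * bt$len) * depth
  d <- 2 * flow$mesh$domain$sph_r
  w <- (rho_spheroid - flow$fluid$rho0) * 9.81 * pi / 6 * d^3
  list(lift_N = lift, net_weight_N = w)
}
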