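# Independent small-scale oracles and the rectangular-cavity streaming
# benchmark used to certify each physics stage before full chip runs.

#' 1D radial Michaelis-Menten diffusion oracle
#'
#' Dense finite-difference solution of steady diffusion with saturating
#' consumption in a radially symmetric aggregate:
#' \deqn{\frac{1}{r^g}\partial_r (r^g D c') = V_{max} c/(c+K_m)}
#' with \eqn{g = 2} (sphere, default) or \eqn{g = 1} (cylinder, matching a
#' 2D disk), surface condition \eqn{c(R) = S\,c_{surf}} and symmetry at the
#' centre. Used as an independent check of the 2D transport solver and for
#' the zero-order-kinetics closed form.
#'
#' @param spec a \code{species_spec}
#' @param R_um aggregate radius (um)
#' @param c_surface_medium medium-side surface concentration (mM)
#' @param n_points number of radial intervals (>= 1000 for oracle use)
#' @param geometry "sphere" or "cylinder"
#' @return list with \code{r} (m), \code{c} (mM, aggregate side),
#'   \code{necrotic_radius}, \code{quiescent_radius} (m)
#' @export
radial_mm_oracle <- function(spec, R_um, c_surface_medium, n_points = 2000,
                             geometry = c("sphere", "cylinder")) {
  geometry <- match.arg(geometry)
  g <- if (geometry == "sphere") 2 else 1
  R <- R_um * 1e-6
  n <- n_points
  h <- R / n
  r <- seq(0, R, length.out = n + 1)
  D <- spec$D_spheroid
  Vmax <- spec$Vmax; Km <- spec$Km
  cR <- spec$S * c_surface_medium
  rp <- (r[-(n + 1)] + h / 2)^g  # r_{i+1/2}^g for i = 0..n-1
  mm <- function(c) ifelse(c >= 0, Vmax * c / (c + Km), Vmax / Km * c)
  mmd <- function(c) ifelse(c >= 0, Vmax * Km / (c + Km)^2, Vmax / Km)
  # unknowns c_0..c_{n-1}; c_n = cR fixed
  cvec <- rep(cR, n)
  converged <- FALSE
  for (it in 1:60) {
    cfull <- c(cvec, cR)
    res <- numeric(n)
    # centre: 2(g+1) D (c1 - c0)/h^2 = mm(c0)
    res[1] <- 2 * (g + 1) * D * (cfull[2] - cfull[1]) / h^2 - mm(cfull[1])
    i <- 2:n
    res[i] <- D / (r[i]^g * h^2) *
      (rp[i] * (cfull[i + 1] - cfull[i]) - rp[i - 1] * (cfull[i] - cfull[i - 1])) -
      mm(cfull[i])
    if (max(abs(res)) < 1e-9 * Vmax) { converged <- TRUE; break }
    # tridiagonal Jacobian
    dl <- numeric(n - 1); dd <- numeric(n); du <- numeric(n - 1)
    dd[1] <- -2 * (g + 1) * D / h^2 - mmd(cfull[1])
    du[1] <- 2 * (g + 1) * D / h^2
    dd[i] <- -D * (rp[i] + rp[i - 1]) / (r[i]^g * h^2) - mmd(cfull[i])
    du[i[-length(i)]] <- (D * rp[i] / (r[i]^g * h^2))[-length(i)]
    dl[i - 1] <- D * rp[i - 1] / (r[i]^g * h^2)
    J <- Matrix::bandSparse(n, n, k = -1:1, diagonals = list(dl, dd, du))
    dc <- sp_solve(J, -res)
    cvec <- cvec + dc
    # quadratic convergence: a vanishing increment certifies the root even
    # when the residual floor is set by cancellation in the flux stencil
    if (max(abs(dc)) < 1e-12 * max(cR, Km)) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("radial oracle did not converge: residual %.3g", max(abs(res))))
  }
  cfull <- c(cvec, cR)
  cross <- function(thr) {
    below <- cfull < thr
    if (!any(below)) return(0)
    if (all(below)) return(R)
    k <- max(which(below))  # profile is monotone increasing in r
    t <- (thr - cfull[k]) / (cfull[k + 1] - cfull[k])
    r[k] + t * h
  }
  list(r = r, c = cfull,
       necrotic_radius = cross(spec$necrotic_threshold),
       quiescent_radius = cross(spec$quiescent_threshold))
}

#' Acoustic resonance scan
#'
#' Sweeps the drive frequency over a range, recording the cavity response
#' (mean square first-order pressure), and reports the peak with a
#' parabolic refinement on the three points bracketing the maximum.
#'
#' @param mesh medium \code{fem_mesh}
#' @param fluid \code{fluid_properties}
#' @param f_range length-2 vector (Hz)
#' @param d0 drive amplitude (m); the response scale is quadratic in d0 and
#'   the peak location independent of it
#' @param n number of scan points
#' @param extra_damping damping added to the Helmholtz solve
#' @param actuation_direction passed to \code{\link{solve_helmholtz}}; a
#'   shake direction excites antisymmetric modes as well
#' @return list with \code{f}, \code{response}, \code{f_peak}
#' @export
resonance_scan <- function(mesh, fluid, f_range, d0 = 0.1e-9, n = 41,
                           extra_damping = 1e-3, actuation_direction = NULL) {
  stopifnot(length(f_range) == 2, all(f_range > 0))
  fs <- seq(f_range[1], f_range[2], length.out = n)
  resp <- vapply(fs, function(f) {
    fo <- solve_helmholtz(mesh, fluid, acoustic_actuation(f = f, d0 = d0),
                          extra_damping = extra_damping,
                          actuation_direction = actuation_direction)
    mean(Mod(fo$p1)^2)
  }, numeric(1))
  k <- which.max(resp)
  f_peak <- fs[k]
  if (k > 1 && k < n) {
    # parabolic refinement
    y1 <- resp[k - 1]; y2 <- resp[k]; y3 <- resp[k + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) f_peak <- fs[k] + 0.5 * (y1 - y3) / denom * (fs[2] - fs[1])
  }
  list(f = fs, response = resp, f_peak = f_peak)
}

# Mean curl (vorticity) of the mean flow per quadrant of a rectangular
# cavity, evaluated over the bulk (an inner fraction of the domain, away
# from the boundary-layer vortices).
quadrant_vorticity <- function(flow, inner = 0.7) {
  mesh <- flow$mesh
  g <- mesh_geom(mesh)
  curl <- p1_gradient(mesh, flow$vel_p1[, 2])[, 1] -
    p1_gradient(mesh, flow$vel_p1[, 1])[, 2]
  cx <- (g$x[, 1] + g$x[, 2] + g$x[, 3]) / 3
  cy <- (g$y[, 1] + g$y[, 2] + g$y[, 3]) / 3
  W <- max(mesh$nodes[, 1]); H <- max(mesh$nodes[, 2])
  sel <- abs(cx - W / 2) < inner * W / 2 & abs(cy - H / 2) < inner * H / 2
  qmean <- matrix(0, 2, 2)
  for (ix in 1:2) for (iy in 1:2) {
    q <- sel & (cx < W / 2) == (ix == 1) & (cy < H / 2) == (iy == 1)
    qmean[iy, ix] <- sum(curl[q] * g$A[q]) / sum(g$A[q])
  }
  qmean
}

#' Rectangular-cavity streaming benchmark
#'
#' Regenerates the classical boundary-driven (Rayleigh) streaming problem
#' in a closed W x H cavity: side walls actuated in their normal direction
#' at the horizontal half-wave resonance, rigid isothermal top/bottom,
#' zero-mean pressure for the second-order flow. Solves the full
#' thermoviscous first-order system on a boundary-layer-resolved mesh,
#' assembles the streaming forcing and solves the mean flow; extracts
#' profiles along the vertical line x = W/4.
#'
#' @param W_um,H_um cavity size (um); defaults 380 x 160
#' @param f drive frequency (Hz); default 1.97 MHz (the cavity half-wave
#'   resonance for 25 degC water)
#' @param d0 actuation amplitude (m); default 0.1 nm
#' @param fluid \code{fluid_properties}; default 25 degC water
#' @param h_um interior mesh size (um)
#' @param warn_resonance warn if the drive is more than 2 percent away
#'   from the analytic half-wave estimate \eqn{c_a/(2W)}
#' @return list with the sample-line profiles, field objects, quadrant
#'   vorticity pattern and scalar summaries
#' @export
run_muller_benchmark <- function(W_um = 380, H_um = 160, f = 1.97e6,
                                 d0 = 0.1e-9, fluid = water_25C(),
                                 h_um = 4, warn_resonance = TRUE) {
  om <- 2 * pi * f
  dom <- build_validation_geometry(W_um, H_um)
  delta <- viscous_penetration_depth(fluid, om)
  f_half <- fluid$ca / (2 * W_um * 1e-6)
  if (warn_resonance && abs(f - f_half) / f_half > 0.02) {
    warning(sprintf(
      "drive %.4g MHz is %.1f%% from the half-wave resonance %.4g MHz",
      f / 1e6, 100 * abs(f - f_half) / f_half, f_half / 1e6))
  }
  spec <- mesh_spec(n_boundary_layers = 6, h_well_um = h_um,
                    h_channel_um = h_um, growth_rate = 1.5)
  mesh <- generate_mesh(dom, spec, delta)
  act <- acoustic_actuation(f = f, d0 = d0)
  # both side walls oscillate laterally in phase (the cavity is shaken
  # along x), which excites the antisymmetric half-wave pressure mode
  fo <- if (d0 > 0) {
    solve_first_order(mesh, fluid, act,
                      bc_map = list(actuated_wall = c(om * d0 + 0i, 0i),
                                    rigid_wall = "noslip"),
                      actuation_phase = 1)
  } else zero_first_order(mesh, om, 0, "thermoviscous")
  forcing <- assemble_streaming_forcing(fo, fluid)
  flow <- solve_mean_flow(mesh, fluid, forcing = forcing, perfusion = NULL)
  # sample line: the structured column closest to W/4
  xs <- sort(unique(round(mesh$nodes[, 1], 12)))
  xcol <- xs[which.min(abs(xs - W_um * 1e-6 / 4))]
  sel <- which(abs(mesh$nodes[, 1] - xcol) < 1e-12)
  sel <- sel[order(mesh$nodes[sel, 2])]
  profile <- data.frame(
    y = mesh$nodes[sel, 2],
    u1_real = Re(fo$V1[sel, 1]), u1_imag = Im(fo$V1[sel, 1]),
    v1_real = Re(fo$V1[sel, 2]), v1_imag = Im(fo$V1[sel, 2]),
    u2 = flow$vel_p1[sel, 1], v2 = flow$vel_p1[sel, 2])
  u1max <- max(Mod(fo$V1[, 1]))
  v1max <- max(Mod(fo$V1[, 2]))
  # streaming magnitude in the bulk (outside all wall boundary layers)
  H <- H_um * 1e-6; W <- W_um * 1e-6
  bulk <- mesh$nodes[, 2] > 10 * delta & mesh$nodes[, 2] < H - 10 * delta &
    mesh$nodes[, 1] > 10 * delta & mesh$nodes[, 1] < W - 10 * delta
  s2max <- max(sqrt(rowSums(flow$vel_p1[bulk, ]^2)))
  list(profile = profile, first_order = fo, flow = flow, mesh = mesh,
       sample_x = xcol,
       quadrant_vorticity = quadrant_vorticity(flow),
       summary = list(u1_max = u1max, v1_max = v1max,
                      streaming_max_bulk = s2max,
                      slip_scale = rayleigh_slip_estimate(u1max, fluid$ca),
                      f_half_wave = f_half, delta = delta))
}

#' Observed convergence order of the scalar diffusion core
#'
#' Solves a Poisson problem with a manufactured sinusoidal solution on a
#' sequence of uniformly refined rectangle meshes and fits the L2-error
#' decay order; the P1 core should show second order.
#'
#' @param hs_um element sizes (um), decreasing, length >= 2
#' @param W_um,H_um rectangle size (um)
#' @return list with \code{h}, \code{err}, \code{order}
#' @export
poisson_mms_order <- function(hs_um = c(100, 50, 25), W_um = 1000,
                              H_um = 1000) {
  W <- W_um * 1e-6; H <- H_um * 1e-6
  errs <- vapply(hs_um, function(h_um) {
    dom <- build_validation_geometry(W_um, H_um)
    m <- generate_mesh(dom, mesh_spec(n_boundary_layers = 1,
                                      bl_total_um = h_um / 2,
                                      h_well_um = h_um, growth_rate = 1), 1)
    kx <- pi / W; ky <- pi / H
    u_ex <- sin(kx * m$nodes[, 1]) * sin(ky * m$nodes[, 2])
    f <- (kx^2 + ky^2) * u_ex
    K <- p1_stiffness(m)
    b <- p1_load(m, f)
    bnd <- nodes_on_tags(m, unique(m$btag))
    s <- apply_dirichlet(K, b, bnd, u_ex[bnd])
    u <- sp_solve(s$A, s$b)
    w <- lumped_area(m)
    sqrt(sum(w * (u - u_ex)^2) / sum(w))
  }, numeric(1))
  fit <- stats::lm(log(errs) ~ log(hs_um))
  list(h = hs_um, err = errs, order = unname(stats::coef(fit)[2]))
}
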