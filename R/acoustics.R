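#' Time average of the product of two harmonic signals
#'
#' For complex amplitudes \code{a}, \code{b} sharing the \eqn{e^{-i\omega t}}
#' convention, the period average of the product of the two real signals is
#' \eqn{\frac{1}{2}\mathrm{Re}(a\,\bar b)}.
#'
#' @param a,b complex amplitudes (vectors allowed)
#' @return real time-averaged product
#' @export
harmonic_time_average <- function(a, b) {
  0.5 * Re(a * Conj(b))
}

zero_first_order <- function(mesh, omega, d0, mode) {
  n <- nrow(mesh$nodes)
  out <- list(mesh = mesh, omega = omega, d0 = d0, mode = mode,
              p1 = complex(n), rho1 = complex(n),
              V1 = matrix(complex(2 * n), ncol = 2), T1 = complex(n))
  class(out) <- "first_order_field"
  out
}

#' Solve the first-order thermoviscous acoustic equations
#'
#' Frequency-domain linearized compressible flow on the medium mesh:
#' harmonic continuity, momentum with shear and dilatational viscosity, and
#' (optionally) the one-way-coupled temperature equation, with isentropic
#' closure \eqn{p_1 = c_a^2 \rho_1}. Boundary conditions: no-slip on
#' non-actuated walls, prescribed normal velocity on the actuated wall,
#' stress-free at inlet/outlet, isothermal walls. The spheroid surface is a
#' rigid isothermal wall.
#'
#' \code{bc_map} assigns each boundary tag one of: "noslip", "open", or a
#' complex length-2 velocity amplitude (m/s). The default actuation
#' convention is normal velocity \eqn{-i\omega d_0} into the domain.
#'
#' @param mesh medium-region \code{fem_mesh}
#' @param fluid \code{fluid_properties}
#' @param actuation \code{acoustic_actuation}
#' @param bc_map named list of boundary conditions per tag; tags absent
#'   default to "noslip"; "inlet"/"outlet" default to "open"
#' @param include_temperature solve the temperature equation (default TRUE)
#' @param actuation_phase complex unit multiplying \eqn{\omega d_0} for the
#'   actuated-wall normal velocity; default \code{-1i} (chip convention);
#'   the validation benchmark uses \code{+1}
#' @return \code{first_order_field} with complex nodal amplitudes
#' @export
solve_first_order <- function(mesh, fluid, actuation, bc_map = list(),
                              include_temperature = TRUE,
                              actuation_phase = -1i) {
  om <- actuation$omega
  if (actuation$d0 == 0) {
    return(zero_first_order(mesh, om, 0, "thermoviscous"))
  }
  n <- nrow(mesh$nodes)
  rho0 <- fluid$rho0; eta <- fluid$mu; br <- fluid$beta_ratio
  ca2 <- fluid$ca^2
  M <- p1_mass(mesh)
  K <- p1_stiffness(mesh)
  Kxx <- p1_grad_ab(mesh, "x", "x"); Kxy <- p1_grad_ab(mesh, "x", "y")
  Kyx <- p1_grad_ab(mesh, "y", "x"); Kyy <- p1_grad_ab(mesh, "y", "y")
  Gx <- p1_phi_dphi(mesh, "x"); Gy <- p1_phi_dphi(mesh, "y")
  Z <- sp(1, 1, 0, n)
  # dof blocks: u (1..n), v, rho
  Ar <- rbind(
    cbind(eta * K + br * eta * Kxx, br * eta * Kxy, -ca2 * Matrix::t(Gx)),
    cbind(br * eta * Kyx, eta * K + br * eta * Kyy, -ca2 * Matrix::t(Gy)),
    cbind(rho0 * Gx, rho0 * Gy, Z))
  Ai <- rbind(
    cbind(-om * rho0 * M, Z, Z),
    cbind(Z, -om * rho0 * M, Z),
    cbind(Z, Z, -om * M))
  # boundary conditions on velocity dofs
  tags <- unique(mesh$btag)
  idx <- integer(0); vals <- complex(0)
  act_tag <- actuation$actuated_boundary
  for (tg in tags) {
    bc <- bc_map[[tg]]
    if (is.null(bc)) {
      bc <- if (tg %in% c("inlet", "outlet")) "open"
            else if (tg == act_tag) "actuated" else "noslip"
    }
    if (identical(bc, "open")) next
    nds <- nodes_on_tags(mesh, tg)
    if (identical(bc, "noslip")) {
      uv <- cbind(complex(length(nds)), complex(length(nds)))
    } else if (identical(bc, "actuated")) {
      uv <- actuated_wall_velocity(mesh, tg, om * actuation$d0 * actuation_phase)
    } else {
      uv <- matrix(rep(bc, each = length(nds)), ncol = 2)
    }
    idx <- c(idx, nds, nds + n)
    vals <- c(vals, uv[, 1], uv[, 2])
  }
  b <- complex(3 * n)
  x <- solve_complex(Ar, Ai, Re(b), Im(b), idx, vals)
  V1 <- cbind(x[1:n], x[(n + 1):(2 * n)])
  rho1 <- x[(2 * n + 1):(3 * n)]
  if (any(!is.finite(Re(x)))) {
    stop(sprintf("first-order solve produced non-finite values (f = %g Hz, %d nodes)",
                 om / (2 * pi), n))
  }
  T1 <- complex(n)
  if (include_temperature) {
    coefT <- fluid$alpha0 * fluid$T0 * ca2 / (rho0 * fluid$Cp)
    ArT <- fluid$Dth * K
    AiT <- -om * M
    # rhs: coefT * (-i om) M rho1 (Matrix has no complex support)
    rhs <- coefT * (-1i * om) *
      (as.vector(M %*% Re(rho1)) + 1i * as.vector(M %*% Im(rho1)))
    wall_tags <- setdiff(tags, c("inlet", "outlet"))
    wn <- nodes_on_tags(mesh, wall_tags)
    T1 <- solve_complex(ArT, AiT, Re(rhs), Im(rhs), wn, complex(length(wn)))
  }
  out <- list(mesh = mesh, omega = om, d0 = actuation$d0,
              mode = "thermoviscous",
              p1 = ca2 * rho1, rho1 = rho1, V1 = V1, T1 = T1)
  class(out) <- "first_order_field"
  out
}

# Wall-normal velocity amplitude on an actuated boundary: amp * n_hat,
# with n_hat the outward-pointing normal estimated per node (walls here are
# axis-aligned or circular, so nodal averaging of edge normals is exact up
# to corners).
actuated_wall_velocity <- function(mesh, tag, amp) {
  ed <- boundary_edges(mesh, tag)
  nds <- sort(unique(as.vector(ed)))
  nrm <- matrix(0, length(nds), 2)
  len <- edge_lengths(mesh, ed)
  # edge tangent -> normal; orient outward using the domain interior
  for (k in seq_len(nrow(ed))) {
    p1_ <- mesh$nodes[ed[k, 1], ]; p2_ <- mesh$nodes[ed[k, 2], ]
    t_ <- (p2_ - p1_) / sqrt(sum((p2_ - p1_)^2))
    nor <- c(t_[2], -t_[1])
    mid <- (p1_ + p2_) / 2
    if (!point_in_mesh_dir(mesh, mid, nor)) nor <- -nor
    i1 <- match(ed[k, 1], nds); i2 <- match(ed[k, 2], nds)
    nrm[i1, ] <- nrm[i1, ] + nor * len[k] / 2
    nrm[i2, ] <- nrm[i2, ] + nor * len[k] / 2
  }
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # outward wall motion with amplitude amp along -n (wall pushes inward):
  # n.V1 = amp on the boundary, so V1 = amp * n_hat
  structure(cbind(amp * nrm[, 1], amp * nrm[, 2]), nodes = nds)
}

# TRUE if stepping from point p along dir stays inside the mesh bounding
# region (cheap interior test: compare against domain centroid direction).
point_in_mesh_dir <- function(mesh, p, dir) {
  centroid <- colMeans(mesh$nodes)
  sum((centroid - p) * dir) < 0
}

#' Solve bulk pressure acoustics (lossy Helmholtz)
#'
#' Boundary-layer-free description of the first-order field used by the
#' slip-velocity streaming mode: \eqn{\nabla^2 p_1 + k^2 p_1 = 0} with the
#' weakly absorbing wavenumber
#' \eqn{k^2 = (\omega/c_a)^2 (1 + i\,\omega\mu(\beta+1)/(\rho_0 c_a^2))},
#' where \eqn{\mu(\beta+1) = \mu_B + 4\mu/3} is the dilatational viscosity.
#' Rigid walls are homogeneous Neumann, the actuated wall carries
#' \eqn{\partial_n p_1 = \rho_0\omega^2 d_0}, and open boundaries
#' (inlet/outlet) are pressure release.
#'
#' @inheritParams solve_first_order
#' @param extra_damping additional relative damping added to the imaginary
#'   part of \eqn{k^2/k_0^2}; used to represent viscous boundary-layer
#'   dissipation (see \code{\link{acoustic_q_factor}})
#' @param actuation_direction NULL for wall-normal actuation (each actuated
#'   edge pushes along its outward normal); a length-2 unit vector e for a
#'   rigid shake of the actuated walls along e (normal velocity
#'   \eqn{\omega d_0\, n\cdot e}), which also excites antisymmetric modes
#' @return \code{first_order_field} with mode "helmholtz"; the velocity is
#'   the bulk (inviscid) field \eqn{V_1 = \nabla p_1/(i\omega\rho_0)}
#' @export
solve_helmholtz <- function(mesh, fluid, actuation, bc_map = list(),
                            extra_damping = 0, actuation_direction = NULL) {
  om <- actuation$omega
  if (actuation$d0 == 0) {
    return(zero_first_order(mesh, om, 0, "helmholtz"))
  }
  n <- nrow(mesh$nodes)
  rho0 <- fluid$rho0
  k2 <- (om / fluid$ca)^2 *
    complex(real = 1, imaginary = om * fluid$mu * (fluid$beta_ratio + 1) /
              (rho0 * fluid$ca^2) + extra_damping)
  K <- p1_stiffness(mesh)
  M <- p1_mass(mesh)
  Ar <- K - Re(k2) * M
  Ai <- -Im(k2) * M
  b <- complex(n)
  # actuated-wall flux
  act <- actuation$actuated_boundary
  ed <- boundary_edges(mesh, act)
  if (nrow(ed)) {
    len <- edge_lengths(mesh, ed)
    flux <- rho0 * om^2 * actuation$d0
    if (is.null(actuation_direction)) {
      fe <- rep(flux, nrow(ed))
    } else {
      eo <- edge_owner(mesh, act)
      fe <- numeric(nrow(ed))
      for (k in seq_len(nrow(ed))) {
        a <- eo$edge[k, 1]; bb <- eo$edge[k, 2]
        tv <- mesh$nodes[bb, ] - mesh$nodes[a, ]
        tv <- tv / sqrt(sum(tv^2))
        nor <- c(tv[2], -tv[1])
        other <- setdiff(mesh$tri[eo$elem[k], ], c(a, bb))
        mid <- (mesh$nodes[a, ] + mesh$nodes[bb, ]) / 2
        if (sum((mesh$nodes[other, ] - mid) * nor) > 0) nor <- -nor
        fe[k] <- flux * sum(nor * actuation_direction)
      }
    }
    b <- b + tab_sum(c(ed[, 1], ed[, 2]), rep(fe * len / 2, 2), n)
  }
  open_tags <- intersect(unique(mesh$btag), c("inlet", "outlet"))
  open_tags <- c(open_tags, names(bc_map)[vapply(bc_map, identical, TRUE, y = "open")])
  onodes <- nodes_on_tags(mesh, unique(open_tags))
  p1 <- solve_complex(Ar, Ai, Re(b), Im(b), onodes, complex(length(onodes)))
  gp <- p1_gradient(mesh, p1)                 # element-constant complex
  gpn <- cbind(p0_to_p1(mesh, Re(gp[, 1])), p0_to_p1(mesh, Re(gp[, 2]))) +
    1i * cbind(p0_to_p1(mesh, Im(gp[, 1])), p0_to_p1(mesh, Im(gp[, 2])))
  V1 <- gpn / (1i * om * rho0)
  out <- list(mesh = mesh, omega = om, d0 = actuation$d0, mode = "helmholtz",
              p1 = p1, rho1 = p1 / fluid$ca^2, V1 = V1,
              T1 = complex(n))
  class(out) <- "first_order_field"
  out
}

#' Assemble the time-averaged streaming forcing
#'
#' Computes the steady body force
#' \eqn{-\langle\rho_1\partial_t V_1\rangle - \rho_0\langle (V_1\cdot\nabla)V_1\rangle}
#' and mass source \eqn{-\nabla\cdot\langle\rho_1 V_1\rangle} that drive the
#' mean flow, with \eqn{\partial_t \mapsto -i\omega} in amplitude space and
#' products averaged via \code{\link{harmonic_time_average}}. Both are
#' element-constant fields; both vanish identically when the actuation
#' amplitude is zero.
#'
#' @param fo a \code{first_order_field}
#' @param fluid \code{fluid_properties}
#' @return list with \code{body_force} (m x 2, N/m3) and
#'   \code{mass_source} (length m, kg/(m3 s)) on \code{fo$mesh}
#' @export
assemble_streaming_forcing <- function(fo, fluid) {
  mesh <- fo$mesh
  m <- nrow(mesh$tri)
  if (fo$d0 == 0) {
    return(list(mesh = mesh, body_force = matrix(0, m, 2),
                mass_source = numeric(m)))
  }
  om <- fo$omega
  tri <- mesh$tri
  cent <- function(z) (z[tri[, 1]] + z[tri[, 2]] + z[tri[, 3]]) / 3
  u1c <- cent(fo$V1[, 1]); v1c <- cent(fo$V1[, 2]); r1c <- cent(fo$rho1)
  # <rho1 dtV1>
  t1x <- harmonic_time_average(-1i * om * u1c, r1c)
  t1y <- harmonic_time_average(-1i * om * v1c, r1c)
  # rho0 <(V1.grad)V1>
  gu <- p1_gradient(mesh, fo$V1[, 1])
  gv <- p1_gradient(mesh, fo$V1[, 2])
  t2x <- fluid$rho0 * (harmonic_time_average(u1c, gu[, 1]) +
                       harmonic_time_average(v1c, gu[, 2]))
  t2y <- fluid$rho0 * (harmonic_time_average(u1c, gv[, 1]) +
                       harmonic_time_average(v1c, gv[, 2]))
  body <- cbind(-(t1x + t2x), -(t1y + t2y))
  # mass source: -div <rho1 V1>, from the nodal P1 flux field
  fx <- harmonic_time_average(fo$V1[, 1], fo$rho1)
  fy <- harmonic_time_average(fo$V1[, 2], fo$rho1)
  dvg <- p1_gradient(mesh, fx)[, 1] + p1_gradient(mesh, fy)[, 2]
  list(mesh = mesh, body_force = body, mass_source = -dvg)
}

#' Classical limiting (slip) streaming velocity scale
#'
#' For a planar standing wave of bulk velocity amplitude \code{u1}, the
#' Rayleigh boundary-layer analysis gives the limiting streaming velocity
#' scale \eqn{(3/8) u_1^2 / c_a} just outside the viscous layer.
#'
#' @param u1_amplitude first-order velocity amplitude (m/s)
#' @param ca sound speed (m/s)
#' @return velocity scale (m/s)
#' @export
rayleigh_slip_estimate <- function(u1_amplitude, ca) {
  (3 / 8) * u1_amplitude^2 / ca
}

#' Boundary-layer damping of an acoustic cavity mode
#'
#' Inverse quality factor \eqn{1/Q} from viscous dissipation in the wall
#' boundary layers, evaluated perturbatively from a bulk (inviscid)
#' solution: dissipated power per wall area
#' \eqn{\tfrac14 \rho_0\,\omega\,\delta\,|v_t|^2} against the stored
#' acoustic energy \eqn{\tfrac14(\rho_0|v|^2 + |p|^2/\rho_0 c_a^2)}.
#' The thermal boundary-layer loss of isothermal walls,
#' \eqn{\tfrac14 \rho_0\,\omega\,\delta_{th}(\gamma-1)\,|p/(\rho_0 c_a)|^2}
#' per area with \eqn{\gamma - 1 = \alpha_0^2 T_0 c_a^2 / C_p} (about 1
#' percent for water), is included for completeness.
#'
#' @param fo a \code{first_order_field} (bulk solution)
#' @param fluid \code{fluid_properties}
#' @param wall_tags boundary tags treated as rigid walls with viscous
#'   boundary layers
#' @return the dimensionless damping \eqn{1/Q}
#' @export
acoustic_q_factor <- function(fo, fluid, wall_tags) {
  mesh <- fo$mesh
  om <- fo$omega
  g <- mesh_geom(mesh)
  dl <- viscous_penetration_depth(fluid, om)
  tri <- mesh$tri
  cent <- function(z) (z[tri[, 1]] + z[tri[, 2]] + z[tri[, 3]]) / 3
  vv <- Mod(cent(fo$V1[, 1]))^2 + Mod(cent(fo$V1[, 2]))^2
  pp <- Mod(cent(fo$p1))^2
  E <- sum(g$A * (0.25 * fluid$rho0 * vv +
                    0.25 * pp / (fluid$rho0 * fluid$ca^2)))
  dth <- sqrt(2 * fluid$Dth / om)
  gm1 <- fluid$alpha0^2 * fluid$T0 * fluid$ca^2 / fluid$Cp
  P <- 0
  for (tg in intersect(wall_tags, unique(mesh$btag))) {
    ed <- boundary_edges(mesh, tg)
    if (!nrow(ed)) next
    len <- edge_lengths(mesh, ed)
    tvx <- mesh$nodes[ed[, 2], 1] - mesh$nodes[ed[, 1], 1]
    tvy <- mesh$nodes[ed[, 2], 2] - mesh$nodes[ed[, 1], 2]
    tvn <- sqrt(tvx^2 + tvy^2); tvx <- tvx / tvn; tvy <- tvy / tvn
    vmx <- (fo$V1[ed[, 1], 1] + fo$V1[ed[, 2], 1]) / 2
    vmy <- (fo$V1[ed[, 1], 2] + fo$V1[ed[, 2], 2]) / 2
    vt <- vmx * tvx + vmy * tvy
    pw <- Mod((fo$p1[ed[, 1]] + fo$p1[ed[, 2]]) / 2 /
                (fluid$rho0 * fluid$ca))^2
    P <- P + sum(0.25 * fluid$rho0 * om *
                   (dl * Mod(vt)^2 + dth * gm1 * pw) * len)
  }
  P / (om * E)
}

#' Bulk acoustic response with resonance tracking
#'
#' The transducer of the physical device operates at the resonance of the
#' coupled chip; the nominal drive frequency labels that operating point.
#' This routine locates the strongest cavity response within a window
#' around the nominal frequency (maximizing the mean square pressure) and
#' sets the on-resonance amplitude self-consistently with the viscous
#' boundary-layer damping of \code{\link{acoustic_q_factor}}: the damping
#' is evaluated from the modal field and fed back as an effective
#' absorption until fixed (two to three passes suffice).
#'
#' With \code{track = FALSE} the solve runs at the nominal frequency with
#' boundary-layer damping evaluated once.
#'
#' @param mesh medium-region \code{fem_mesh}
#' @param fluid \code{fluid_properties}
#' @param actuation \code{acoustic_actuation} (nominal frequency)
#' @param wall_tags rigid-wall tags used for the damping estimate
#' @param track search for the resonance near the nominal frequency
#' @param span half-width of the search window as a fraction of the
#'   nominal frequency
#' @return list with the \code{first_order_field} \code{fo}, the operating
#'   frequency \code{f_res} and the damping \code{inv_Q}
#' @export
tracked_acoustics <- function(mesh, fluid, actuation, wall_tags,
                              track = TRUE, span = 0.08) {
  if (actuation$d0 == 0) {
    return(list(fo = zero_first_order(mesh, actuation$omega, 0, "helmholtz"),
                f_res = actuation$f, inv_Q = NA_real_))
  }
  solve_at <- function(f, gam) {
    act <- acoustic_actuation(f = f, d0 = actuation$d0,
                              actuated_boundary = actuation$actuated_boundary)
    solve_helmholtz(mesh, fluid, act, extra_damping = gam)
  }
  obj <- function(f, gam) mean(Mod(solve_at(f, gam)$p1)^2)
  gam <- 1e-3
  f0 <- actuation$f
  if (track) {
    f0 <- stats::optimize(function(f) -obj(f, gam),
                          actuation$f * c(1 - span, 1 + span),
                          tol = actuation$f * 1e-4)$minimum
  }
  fo <- solve_at(f0, gam)
  for (i in 1:3) {
    gam_new <- acoustic_q_factor(fo, fluid, wall_tags)
    if (track) {
      f0 <- stats::optimize(function(f) -obj(f, gam_new),
                            c(f0 - 0.02 * actuation$f, f0 + 0.02 * actuation$f),
                            tol = actuation$f * 5e-5)$minimum
    }
    fo <- solve_at(f0, gam_new)
    if (abs(gam_new - gam) < 0.02 * gam_new) {
      gam <- gam_new
      break
    }
    gam <- gam_new
  }
  list(fo = fo, f_res = f0, inv_Q = gam)
}

# Order wall boundary edges into polylines (chains); returns list of node
# index vectors, each a chain, with attribute "closed".
wall_chains <- function(mesh, tags) {
  ed <- boundary_edges(mesh, tags)
  if (nrow(ed) == 0) return(list())
  nds <- sort(unique(as.vector(ed)))
  adj <- vector("list", length(nds))
  li <- match(ed[, 1], nds); ri <- match(ed[, 2], nds)
  for (k in seq_len(nrow(ed))) {
    adj[[li[k]]] <- c(adj[[li[k]]], ri[k])
    adj[[ri[k]]] <- c(adj[[ri[k]]], li[k])
  }
  deg <- lengths(adj)
  visited <- rep(FALSE, length(nds))
  chains <- list()
  walk <- function(start) {
    chain <- start
    visited[start] <<- TRUE
    cur <- start
    closed <- FALSE
    repeat {
      cand <- adj[[cur]][!visited[adj[[cur]]]]
      if (length(cand) == 0) {
        # loop closure: back at a neighbour of the start?
        closed <- length(chain) > 2 && start %in% adj[[cur]]
        break
      }
      cur <- cand[1]
      visited[cur] <<- TRUE
      chain <- c(chain, cur)
    }
    structure(chain, closed = closed)
  }
  for (s in c(which(deg == 1), seq_along(nds))) {
    if (!visited[s]) {
      ch <- walk(s)
      chains[[length(chains) + 1]] <-
        structure(nds[ch], closed = attr(ch, "closed"))
    }
  }
  chains
}

#' Rayleigh limiting slip velocity along walls
#'
#' Converts the bulk first-order velocity into the classical steady slip
#' velocity imposed just outside the viscous boundary layer:
#' \eqn{u_s = -\frac{3}{4\omega}\,\partial_s \langle v_t^2\rangle}
#' with \eqn{\langle v_t^2\rangle = \frac{1}{2}|V_{1,t}|^2} the mean-square
#' tangential velocity and \eqn{s} the wall arc length.
#'
#' @param fo \code{first_order_field} on the flow mesh
#' @param wall_tags tags treated as slip walls
#' @return n x 2 real matrix of wall velocities (zero away from walls)
#' @export
slip_velocity <- function(fo, wall_tags) {
  mesh <- fo$mesh
  n <- nrow(mesh$nodes)
  out <- matrix(0, n, 2)
  if (fo$d0 == 0) return(out)
  om <- fo$omega
  chains <- wall_chains(mesh, wall_tags)
  for (ch in chains) {
    closed <- isTRUE(attr(ch, "closed"))
    pts <- mesh$nodes[ch, , drop = FALSE]
    nn <- nrow(pts)
    if (nn < 3) next
    nxt <- c(2:nn, if (closed) 1L)
    prv <- c(if (closed) nn, 1:(nn - 1))
    if (!closed) { nxt <- c(2:nn, nn); prv <- c(1, 1:(nn - 1)) }
    tx <- pts[nxt, 1] - pts[prv, 1]
    ty <- pts[nxt, 2] - pts[prv, 2]
    ds <- sqrt(tx^2 + ty^2)
    tx <- tx / ds; ty <- ty / ds
    vt <- fo$V1[ch, 1] * tx + fo$V1[ch, 2] * ty
    q <- 0.5 * Mod(vt)^2
    dq <- (q[nxt] - q[prv]) / ds
    us <- -(3 / (4 * om)) * dq
    out[ch, 1] <- us * tx
    out[ch, 2] <- us * ty
  }
  out
}
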