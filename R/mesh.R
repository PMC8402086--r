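#' Mesh resolution specification
#'
#' Controls the triangular mesh: number of graded viscous boundary layers
#' stacked against every wall, their total thickness, the interior target
#' element sizes in the well and in the channel free stream, and the
#' geometric growth rate of the layer stack.
#'
#' When left \code{NULL}, the boundary-layer total thickness defaults to the
#' viscous penetration depth \eqn{\delta} evaluated at the scenario
#' frequency, and the well/channel sizes default to 10 and 20 times
#' \eqn{\delta} respectively.
#'
#' @param n_boundary_layers number of graded layers within the total
#'   boundary-layer thickness (>= 1); default 6
#' @param bl_total_um total boundary-layer thickness in um, or NULL for
#'   \eqn{\delta}
#' @param h_well_um target interior element size in the well/spheroid in um,
#'   or NULL for \eqn{10\delta}
#' @param h_channel_um target element size in the channel in um, or NULL for
#'   \eqn{20\delta}
#' @param growth_rate geometric growth ratio of successive layers (> 1)
#' @return object of class \code{mesh_spec}
#' @export
mesh_spec <- function(n_boundary_layers = 6, bl_total_um = NULL,
                      h_well_um = NULL, h_channel_um = NULL,
                      growth_rate = 1.4) {
  stopifnot(n_boundary_layers >= 1, growth_rate >= 1)
  out <- list(n_bl = as.integer(n_boundary_layers),
              bl_total_um = bl_total_um,
              h_well_um = h_well_um, h_channel_um = h_channel_um,
              growth = growth_rate)
  class(out) <- "mesh_spec"
  out
}

resolve_mesh_spec <- function(spec, delta) {
  bl <- if (is.null(spec$bl_total_um)) delta else spec$bl_total_um * 1e-6
  hw <- if (is.null(spec$h_well_um)) 10 * delta else spec$h_well_um * 1e-6
  hc <- if (is.null(spec$h_channel_um)) 20 * delta else spec$h_channel_um * 1e-6
  if (hw <= bl || hc <= bl) {
    stop("invariant violated: interior max sizes must exceed the boundary-layer thickness")
  }
  list(n_bl = spec$n_bl, bl = bl, hw = hw, hc = hc, g = spec$growth)
}

# Graded layer widths summing to `total`, thinnest first (wall side).
bl_widths <- function(total, n, g) {
  if (n == 1 || g == 1) return(rep(total / n, n))
  w1 <- total * (g - 1) / (g^n - 1)
  w1 * g^(0:(n - 1))
}

# Node positions 0..L: optional graded boundary-layer stacks at either end,
# near-uniform interior at size <= h.
seg_positions <- function(L, h, bl = 0, n_bl = 1, g = 1.4,
                          bl_start = TRUE, bl_end = TRUE) {
  s <- if (bl_start && bl > 0) cumsum(bl_widths(bl, n_bl, g)) else numeric(0)
  e <- if (bl_end && bl > 0) L - rev(cumsum(bl_widths(bl, n_bl, g))) else numeric(0)
  t0 <- if (length(s)) max(s) else 0
  t1 <- if (length(e)) min(e) else L
  if (t1 <= t0) stop("segment too short for the requested boundary layers")
  n_int <- max(1L, ceiling((t1 - t0) / h))
  interior <- seq(t0, t1, length.out = n_int + 1)
  sort(unique(c(0, s, interior, e, L)))
}

# Quads (as index matrix columns a,b,c,d in cyclic order) -> two triangles.
quads_to_tris <- function(a, b, c, d) {
  rbind(cbind(a, b, c), cbind(a, c, d))
}

signed_area <- function(nodes, tri) {
  x <- matrix(nodes[tri, 1], ncol = 3)
  y <- matrix(nodes[tri, 2], ncol = 3)
  0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
         (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
}

orient_tris <- function(nodes, tri) {
  a <- signed_area(nodes, tri)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  tri
}

merge_nodes <- function(nodes, tol = 1e-13) {
  key <- paste(round(nodes[, 1] / tol), round(nodes[, 2] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(nodes = nodes[first, , drop = FALSE], map = map)
}

finish_mesh <- function(nodes, tri, region, domain, sizes) {
  m <- merge_nodes(nodes)
  tri <- matrix(m$map[tri], ncol = 3)
  tri <- orient_tris(m$nodes, tri)
  # boundary edges: edges used by exactly one triangle
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bmask <- cnt[key] == 1
  bedge <- ed[bmask, , drop = FALSE]
  # interface edges: shared by two triangles of different regions
  iedge <- NULL
  if (length(unique(region)) > 1) {
    etri <- rep(seq_len(nrow(tri)), 3)
    ord <- order(key)
    k <- key[ord]; et <- etri[ord]
    dup <- which(k[-1] == k[-length(k)])
    t1 <- et[dup]; t2 <- et[dup + 1]
    diffr <- region[t1] != region[t2]
    iedge <- ed[ord[dup][diffr], , drop = FALSE]
  }
  mesh <- list(nodes = m$nodes, tri = tri, region = region,
               bedge = bedge, btag = rep(NA_character_, nrow(bedge)),
               iedge = iedge,
               domain = domain, sizes = sizes)
  class(mesh) <- "fem_mesh"
  mesh
}

near <- function(x, v, tol) abs(x - v) < tol

tag_chip_boundary <- function(mesh) {
  d <- mesh$domain
  nd <- mesh$nodes
  tol <- 1e-9
  e1 <- mesh$bedge[, 1]; e2 <- mesh$bedge[, 2]
  x1 <- nd[e1, 1]; y1 <- nd[e1, 2]; x2 <- nd[e2, 1]; y2 <- nd[e2, 2]
  on <- function(f) f(x1, y1) & f(x2, y2)
  tag <- rep(NA_character_, length(e1))
  if (d$sph_r > 0) {
    rr1 <- sqrt((x1 - d$sph_c[1])^2 + (y1 - d$sph_c[2])^2)
    rr2 <- sqrt((x2 - d$sph_c[1])^2 + (y2 - d$sph_c[2])^2)
    tag[near(rr1, d$sph_r, tol) & near(rr2, d$sph_r, tol)] <- "spheroid_interface"
  }
  tag[is.na(tag) & on(function(x, y) near(x, 0, tol))] <- "inlet"
  tag[is.na(tag) & on(function(x, y) near(x, d$L, tol))] <- "outlet"
  tag[is.na(tag) & on(function(x, y) near(y, d$Hc, tol))] <- "channel_walls"
  tag[is.na(tag) & on(function(x, y) near(y, 0, tol) &
                        (x <= d$wx0 + tol | x >= d$wx1 - tol))] <- "channel_walls"
  tag[is.na(tag) & on(function(x, y) near(y, d$wy0, tol))] <- "actuated_wall"
  tag[is.na(tag) & on(function(x, y) (near(x, d$wx0, tol) | near(x, d$wx1, tol)) &
                        y < tol)] <- "well_walls"
  if (anyNA(tag)) stop("untagged boundary edge in chip mesh")
  mesh$btag <- tag
  mesh
}

# O-grid angles: uniform set with the exact angles to the well-rectangle
# corners substituted in, so corners are mesh nodes.
ogrid_angles <- function(d, n_theta) {
  cx <- d$sph_c[1]; cy <- d$sph_c[2]
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  corners <- rbind(c(d$wx1, 0), c(d$wx0, 0), c(d$wx0, d$wy0), c(d$wx1, d$wy0))
  ca <- atan2(corners[, 2] - cy, corners[, 1] - cx) %% (2 * pi)
  for (a in ca) {
    i <- which.min(pmin(abs(th - a), 2 * pi - abs(th - a)))
    th[i] <- a
  }
  sort(th)
}

ray_rect_hit <- function(cx, cy, th, d) {
  dx <- cos(th); dy <- sin(th)
  ts <- c(if (abs(dx) > 1e-15) (d$wx0 - cx) / dx else Inf,
          if (abs(dx) > 1e-15) (d$wx1 - cx) / dx else Inf,
          if (abs(dy) > 1e-15) (d$wy0 - cy) / dy else Inf,
          if (abs(dy) > 1e-15) (0 - cy) / dy else Inf)
  best <- Inf
  for (t in ts) {
    if (!is.finite(t) || t <= 0) next
    px <- cx + t * dx; py <- cy + t * dy
    if (px >= d$wx0 - 1e-12 && px <= d$wx1 + 1e-12 &&
        py >= d$wy0 - 1e-12 && py <= 1e-12) best <- min(best, t)
  }
  p <- c(cx + best * dx, cy + best * dy)
  # snap onto the rectangle
  if (near(p[1], d$wx0, 1e-11)) p[1] <- d$wx0
  if (near(p[1], d$wx1, 1e-11)) p[1] <- d$wx1
  if (near(p[2], d$wy0, 1e-11)) p[2] <- d$wy0
  if (near(p[2], 0, 1e-11)) p[2] <- 0
  p
}

#' Generate the boundary-layer-refined triangular mesh
#'
#' For the chip domain, builds a conforming block-structured mesh: a polar
#' mesh inside the spheroid, a radial O-grid between the spheroid surface
#' and the well walls, and a tensor-product grid in the channel whose floor
#' nodes match the well-opening nodes exactly. Graded boundary layers
#' (\code{n_boundary_layers} geometric layers within the total thickness)
#' are stacked against every solid wall. For the rectangular validation
#' cavity, builds a graded tensor-product grid with layers on all four
#' walls.
#'
#' @param domain a \code{planar_domain} from \code{\link{build_chip_geometry}}
#'   or \code{\link{build_validation_geometry}}
#' @param spec a \code{\link{mesh_spec}}
#' @param delta viscous penetration depth in metres (sets the defaults of
#'   \code{spec})
#' @return object of class \code{fem_mesh}: node coordinates in metres,
#'   triangle connectivity, region labels (medium/spheroid) and tagged
#'   boundary edges
#' @export
generate_mesh <- function(domain, spec = mesh_spec(), delta) {
  stopifnot(inherits(domain, "planar_domain"))
  rs <- resolve_mesh_spec(spec, delta)
  if (domain$kind == "rect") {
    return(rect_mesh(domain$W, domain$H, rs, domain$side_tags, domain))
  }
  chip_mesh(domain, rs)
}

rect_mesh <- function(W, H, rs, side_tags, domain) {
  xs <- seg_positions(W, rs$hw, rs$bl, rs$n_bl, rs$g)
  ys <- seg_positions(H, rs$hw, rs$bl, rs$n_bl, rs$g)
  nx <- length(xs); ny <- length(ys)
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  idx <- function(i, j) (j - 1) * nx + i
  i <- rep(1:(nx - 1), times = ny - 1)
  j <- rep(1:(ny - 1), each = nx - 1)
  tri <- quads_to_tris(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
  mesh <- finish_mesh(nodes, tri, rep(1L, nrow(tri)), domain,
                      sizes = rs)
  nd <- mesh$nodes; tol <- 1e-12
  e1 <- mesh$bedge[, 1]; e2 <- mesh$bedge[, 2]
  both <- function(f) f(nd[e1, 1], nd[e1, 2]) & f(nd[e2, 1], nd[e2, 2])
  tag <- rep(NA_character_, nrow(mesh$bedge))
  tag[both(function(x, y) near(x, 0, tol))] <- side_tags$left
  tag[is.na(tag) & both(function(x, y) near(x, W, tol))] <- side_tags$right
  tag[is.na(tag) & both(function(x, y) near(y, 0, tol))] <- side_tags$bottom
  tag[is.na(tag) & both(function(x, y) near(y, H, tol))] <- side_tags$top
  if (anyNA(tag)) stop("untagged boundary edge in rectangle mesh")
  mesh$btag <- tag
  mesh$region_names <- c("medium")
  mesh
}

chip_mesh <- function(d, rs) {
  cx <- d$sph_c[1]; cy <- d$sph_c[2]; R <- d$sph_r
  blocks_nodes <- list(); blocks_tri <- list(); blocks_reg <- list()
  off <- 0L
  add_block <- function(nodes, tri, reg) {
    blocks_nodes[[length(blocks_nodes) + 1]] <<- nodes
    blocks_tri[[length(blocks_tri) + 1]] <<- tri + off
    blocks_reg[[length(blocks_reg) + 1]] <<- reg
    off <<- off + nrow(nodes)
  }

  if (R > 0) {
    n_theta <- max(96L, 2L * ceiling(pi * R / rs$hw))
    th <- ogrid_angles(d, n_theta)
    n_theta <- length(th)
    outer <- t(vapply(th, function(a) ray_rect_hit(cx, cy, a, d),
                      numeric(2)))
    Lray <- sqrt((outer[, 1] - cx)^2 + (outer[, 2] - cy)^2) - R
    # shared radial template: built for the longest ray, reused as fractions
    tmpl <- seg_positions(max(Lray), rs$hw, rs$bl, rs$n_bl, rs$g)
    frac <- tmpl / max(tmpl)
    n_r <- length(frac)
    ct <- cos(th); st <- sin(th)
    rad <- outer(Lray, frac)          # n_theta x n_r distances beyond R
    px <- cx + (R + rad) * ct         # recycles columnwise
    py <- cy + (R + rad) * st
    # force exact outer coordinates
    px[, n_r] <- outer[, 1]; py[, n_r] <- outer[, 2]
    onodes <- cbind(as.vector(px), as.vector(py))
    oid <- function(j, k) (k - 1L) * n_theta + j
    jj <- rep(1:n_theta, times = n_r - 1)
    jn <- rep(c(2:n_theta, 1L), times = n_r - 1)
    kk <- rep(1:(n_r - 1), each = n_theta)
    otri <- quads_to_tris(oid(jj, kk), oid(jn, kk), oid(jn, kk + 1), oid(jj, kk + 1))
    add_block(onodes, otri, rep(1L, nrow(otri)))

    # spheroid disk: rings + centre fan, sharing the interface angles
    n_ring <- max(3L, ceiling(R / rs$hw))
    rr <- R * (1:n_ring) / n_ring
    dn <- cbind(cx + as.vector(outer(ct, rr)), cy + as.vector(outer(st, rr)))
    dn <- rbind(c(cx, cy), dn)
    did <- function(j, m) 1L + (m - 1L) * n_theta + j
    fan <- cbind(rep(1L, n_theta), did(1:n_theta, 1L), did(c(2:n_theta, 1L), 1L))
    dtri <- fan
    if (n_ring > 1) {
      jj <- rep(1:n_theta, times = n_ring - 1)
      jn <- rep(c(2:n_theta, 1L), times = n_ring - 1)
      mm <- rep(1:(n_ring - 1), each = n_theta)
      dtri <- rbind(dtri, quads_to_tris(did(jj, mm), did(jn, mm),
                                        did(jn, mm + 1), did(jj, mm + 1)))
    }
    add_block(dn, dtri, rep(2L, nrow(dtri)))
    open_x <- sort(outer[abs(outer[, 2]) < 1e-12, 1])
  } else {
    # no spheroid: structured well block
    wxs <- d$wx0 + seg_positions(d$wx1 - d$wx0, rs$hw, rs$bl, rs$n_bl, rs$g)
    wys <- d$wy0 + seg_positions(-d$wy0, rs$hw, rs$bl, rs$n_bl, rs$g,
                                 bl_end = FALSE)
    nx <- length(wxs); ny <- length(wys)
    wnodes <- cbind(rep(wxs, times = ny), rep(wys, each = nx))
    widx <- function(i, j) (j - 1) * nx + i
    i <- rep(1:(nx - 1), times = ny - 1); j <- rep(1:(ny - 1), each = nx - 1)
    wtri <- quads_to_tris(widx(i, j), widx(i + 1, j), widx(i + 1, j + 1), widx(i, j + 1))
    add_block(wnodes, wtri, rep(1L, nrow(wtri)))
    open_x <- wxs
  }

  # channel block: floor x-nodes must include the well-opening nodes
  xl <- seg_positions(d$wx0, rs$hc, 0)
  xr <- d$wx1 + seg_positions(d$L - d$wx1, rs$hc, 0)
  xs <- sort(unique(c(xl, open_x, xr)))
  ys <- seg_positions(d$Hc, rs$hc, rs$bl, rs$n_bl, rs$g)
  nx <- length(xs); ny <- length(ys)
  cnodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  cid <- function(i, j) (j - 1) * nx + i
  i <- rep(1:(nx - 1), times = ny - 1); j <- rep(1:(ny - 1), each = nx - 1)
  ctri <- quads_to_tris(cid(i, j), cid(i + 1, j), cid(i + 1, j + 1), cid(i, j + 1))
  add_block(cnodes, ctri, rep(1L, nrow(ctri)))

  nodes <- do.call(rbind, blocks_nodes)
  tri <- do.call(rbind, blocks_tri)
  reg <- unlist(blocks_reg)
  mesh <- finish_mesh(nodes, tri, reg, d, sizes = rs)
  mesh <- tag_chip_boundary(mesh)
  mesh$region_names <- c("medium", "spheroid")
  if (any(signed_area(mesh$nodes, mesh$tri) <= 0)) {
    stop("mesher produced a degenerate or inverted triangle")
  }
  mesh
}

#' Triangle areas of a mesh
#' @param mesh a \code{fem_mesh}
#' @return numeric vector of element areas (m2)
#' @export
tri_areas <- function(mesh) abs(signed_area(mesh$nodes, mesh$tri))

#' Number of elements
#' @param mesh a \code{fem_mesh}
#' @return integer element count
#' @export
n_elements <- function(mesh) nrow(mesh$tri)

#' Extract a submesh by region
#'
#' Keeps the triangles of the requested region (1 = medium, 2 = spheroid),
#' renumbers nodes, and recomputes the boundary; edges of the original
#' tagged boundary keep their tags, newly exposed interface edges get the
#' tag \code{interface_tag}.
#'
#' @param mesh a \code{fem_mesh}
#' @param region integer region id to keep
#' @param interface_tag tag for edges that were interior before extraction
#' @return a \code{fem_mesh} with attribute \code{node_map} giving, for each
#'   submesh node, its index in the parent mesh
#' @export
submesh <- function(mesh, region, interface_tag = "spheroid_interface") {
  keep <- mesh$region == region
  tri <- mesh$tri[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(mesh$nodes)); remap[used] <- seq_along(used)
  sm <- list(nodes = mesh$nodes[used, , drop = FALSE],
             tri = matrix(remap[tri], ncol = 3),
             region = rep(region, nrow(tri)),
             domain = mesh$domain, sizes = mesh$sizes)
  ed <- rbind(sm$tri[, c(1, 2)], sm$tri[, c(2, 3)], sm$tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bmask <- cnt[key] == 1
  sm$bedge <- ed[bmask, , drop = FALSE]
  # inherit tags from the parent boundary where possible
  pkey <- paste(pmin(mesh$bedge[, 1], mesh$bedge[, 2]),
                pmax(mesh$bedge[, 1], mesh$bedge[, 2]))
  skey_parent <- paste(pmin(used[sm$bedge[, 1]], used[sm$bedge[, 2]]),
                       pmax(used[sm$bedge[, 1]], used[sm$bedge[, 2]]))
  hit <- match(skey_parent, pkey)
  sm$btag <- ifelse(is.na(hit), interface_tag, mesh$btag[hit])
  attr(sm, "node_map") <- used
  class(sm) <- "fem_mesh"
  sm
}
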