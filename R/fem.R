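# Finite-element core: vectorised P1/P2 assembly on triangles, built on
# Matrix sparse triplets. All operators act on meshes from generate_mesh().

# Per-triangle geometry: area and P1 basis gradients.
mesh_geom <- function(mesh) {
  if (!is.null(mesh$geom)) return(mesh$geom)
  tri <- mesh$tri
  x <- matrix(mesh$nodes[tri, 1], ncol = 3)
  y <- matrix(mesh$nodes[tri, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  c_ <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A <- 0.5 * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  list(A = A, gx = b / (2 * A), gy = c_ / (2 * A), x = x, y = y)
}

sp <- function(i, j, x, n, m = n) {
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, m))
}

expand_coef <- function(coef, m) {
  if (length(coef) == 1) rep(coef, m) else coef
}

# P1 stiffness: int coef grad(phi_i).grad(phi_j)
p1_stiffness <- function(mesh, coef = 1) {
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  coef <- expand_coef(coef, m)
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- mesh$tri[, a]; jj[[k]] <- mesh$tri[, b]
    xx[[k]] <- coef * g$A * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b])
  }
  sp(unlist(ii), unlist(jj), unlist(xx), n)
}

# P1 mass: int coef phi_i phi_j (exact)
p1_mass <- function(mesh, coef = 1, elems = NULL) {
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  coef <- expand_coef(coef, m)
  sel <- if (is.null(elems)) rep(TRUE, m) else elems
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- mesh$tri[sel, a]; jj[[k]] <- mesh$tri[sel, b]
    xx[[k]] <- (coef * g$A)[sel] / 12 * (1 + (a == b))
  }
  sp(unlist(ii), unlist(jj), unlist(xx), n)
}

# P1 blocks int coef d_a(phi_i) d_b(phi_j), a,b in {"x","y"}
p1_grad_ab <- function(mesh, a, b, coef = 1) {
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  coef <- expand_coef(coef, m)
  da <- if (a == "x") g$gx else g$gy
  db <- if (b == "x") g$gx else g$gy
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (p in 1:3) for (q in 1:3) {
    k <- k + 1
    ii[[k]] <- mesh$tri[, p]; jj[[k]] <- mesh$tri[, q]
    xx[[k]] <- coef * g$A * da[, p] * db[, q]
  }
  sp(unlist(ii), unlist(jj), unlist(xx), n)
}

# P1 block G_a[i,j] = int coef phi_i d_a(phi_j)
p1_phi_dphi <- function(mesh, a, coef = 1) {
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  coef <- expand_coef(coef, m)
  da <- if (a == "x") g$gx else g$gy
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (p in 1:3) for (q in 1:3) {
    k <- k + 1
    ii[[k]] <- mesh$tri[, p]; jj[[k]] <- mesh$tri[, q]
    xx[[k]] <- coef * g$A / 3 * da[, q]
  }
  sp(unlist(ii), unlist(jj), unlist(xx), n)
}

# P1 convection: int phi_i (v . grad phi_j), velocity given at nodes
# (n x 2), optionally restricted to a subset of elements.
p1_convection <- function(mesh, vel, elems = NULL) {
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  sel <- if (is.null(elems)) rep(TRUE, m) else elems
  vx <- matrix(vel[mesh$tri, 1], ncol = 3)
  vy <- matrix(vel[mesh$tri, 2], ncol = 3)
  vxs <- rowSums(vx); vys <- rowSums(vy)
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (p in 1:3) for (q in 1:3) {
    k <- k + 1
    ii[[k]] <- mesh$tri[sel, p]; jj[[k]] <- mesh$tri[sel, q]
    w_x <- (g$A / 12) * (vxs + vx[, p])
    w_y <- (g$A / 12) * (vys + vy[, p])
    xx[[k]] <- (w_x * g$gx[, q] + w_y * g$gy[, q])[sel]
  }
  sp(unlist(ii), unlist(jj), unlist(xx), n)
}

# Streamline-diffusion (SUPG-type) stabilization for P1 advection:
# tau_e * int (v.grad phi_i)(v.grad phi_j), with the optimal-upwind
# parameter tau = h/(2|v|) (coth Pe - 1/Pe), Pe = |v| h / (2 D).
p1_streamline_diffusion <- function(mesh, vel, D_el, elems = NULL) {
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  sel <- if (is.null(elems)) rep(TRUE, m) else elems
  vx <- rowMeans(matrix(vel[mesh$tri, 1], ncol = 3))
  vy <- rowMeans(matrix(vel[mesh$tri, 2], ncol = 3))
  sp_ <- sqrt(vx^2 + vy^2)
  h <- sqrt(2 * g$A)
  D_el <- expand_coef(D_el, m)
  Pe <- sp_ * h / (2 * D_el)
  xi <- ifelse(Pe > 1e-8, 1 / tanh(pmax(Pe, 1e-8)) - 1 / pmax(Pe, 1e-8), 0)
  tau <- ifelse(sp_ > 0, h / (2 * sp_) * xi, 0)
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (p in 1:3) for (q in 1:3) {
    k <- k + 1
    ii[[k]] <- mesh$tri[sel, p]; jj[[k]] <- mesh$tri[sel, q]
    vgp <- vx * g$gx[, p] + vy * g$gy[, p]
    vgq <- vx * g$gx[, q] + vy * g$gy[, q]
    xx[[k]] <- (tau * g$A * vgp * vgq)[sel]
  }
  sp(unlist(ii), unlist(jj), unlist(xx), n)
}

# P1 load vector from nodal (length n) or element-constant (length m) data.
p1_load <- function(mesh, f, elems = NULL) {
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  sel <- if (is.null(elems)) rep(TRUE, m) else elems
  out <- numeric(n)
  if (length(f) == n) {
    fm <- matrix(f[mesh$tri], ncol = 3)
    fs <- rowSums(fm)
    for (p in 1:3) {
      w <- (g$A / 12) * (fs + fm[, p])
      out <- out + tab_sum(mesh$tri[sel, p], w[sel], n)
    }
  } else {
    f <- expand_coef(f, m)
    for (p in 1:3) {
      out <- out + tab_sum(mesh$tri[sel, p], (g$A / 3 * f)[sel], n)
    }
  }
  out
}

tab_sum <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Lumped nodal areas (row sums of the lumped mass matrix).
lumped_area <- function(mesh, elems = NULL) {
  p1_load(mesh, rep(1, nrow(mesh$tri)), elems)
}

# Element-constant gradient of a P1 nodal field.
p1_gradient <- function(mesh, u) {
  g <- mesh_geom(mesh)
  um <- matrix(u[mesh$tri], ncol = 3)
  cbind(rowSums(um * g$gx), rowSums(um * g$gy))
}

# Area-weighted projection of an element field onto P1 nodes.
p0_to_p1 <- function(mesh, f) {
  g <- mesh_geom(mesh)
  num <- numeric(nrow(mesh$nodes))
  for (p in 1:3) num <- num + tab_sum(mesh$tri[, p], g$A * f, nrow(mesh$nodes))
  num / (3 * lumped_area(mesh))
}

## ---- P2 infrastructure -------------------------------------------------

# Edge numbering for 6-node triangles; P2 node order per element:
# v1 v2 v3, mid(v1,v2), mid(v2,v3), mid(v3,v1).
p2_connect <- function(mesh) {
  if (!is.null(mesh$p2)) return(mesh$p2)
  tri <- mesh$tri
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  uk <- unique(key)
  eid <- match(key, uk)
  n <- nrow(mesh$nodes)
  m <- nrow(tri)
  t2 <- cbind(tri, matrix(n + eid, ncol = 3))
  # midpoint coordinates for each unique edge
  first <- !duplicated(eid)
  mid <- (mesh$nodes[ed[first, 1][order(eid[first])], , drop = FALSE] +
          mesh$nodes[ed[first, 2][order(eid[first])], , drop = FALSE]) / 2
  list(t2 = t2, n_p2 = n + length(uk), mid = mid,
       coords = rbind(mesh$nodes, mid))
}

# Degree-5 quadrature on the reference triangle (barycentric, 7 points).
tri_quad7 <- function() {
  a <- 0.059715871789770; b <- 0.470142064105115
  c_ <- 0.797426985353087; d <- 0.101286507323456
  w1 <- 0.225; w2 <- 0.132394152788506; w3 <- 0.125939180544827
  lam <- rbind(c(1/3, 1/3, 1/3),
               c(a, b, b), c(b, a, b), c(b, b, a),
               c(c_, d, d), c(d, c_, d), c(d, d, c_))
  w <- c(w1, w2, w2, w2, w3, w3, w3)
  list(lam = lam, w = w)
}

p2_shape <- function(lam) {
  l1 <- lam[1]; l2 <- lam[2]; l3 <- lam[3]
  N <- c(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
         4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
  # dN/dlambda_a (6 x 3)
  dN <- rbind(c(4 * l1 - 1, 0, 0),
              c(0, 4 * l2 - 1, 0),
              c(0, 0, 4 * l3 - 1),
              c(4 * l2, 4 * l1, 0),
              c(0, 4 * l3, 4 * l2),
              c(4 * l3, 0, 4 * l1))
  list(N = N, dN = dN)
}

# Generic P2 x P2 operator assembly over quadrature points.
# kind: "stiffness" (coef grad.grad), "mass" (coef N N),
#       "convection" (N_i v.grad N_j with v at P2 nodes, n_p2 x 2)
p2_operator <- function(mesh, kind, coef = 1, vel = NULL, elems = NULL) {
  p2 <- p2_connect(mesh)
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri)
  coef <- expand_coef(coef, m)
  sel <- if (is.null(elems)) rep(TRUE, m) else elems
  q <- tri_quad7()
  nq <- length(q$w)
  shp <- lapply(seq_len(nq), function(k) p2_shape(q$lam[k, ]))
  acc_i <- acc_j <- acc_x <- vector("list", 36 * nq)
  cnt <- 0
  for (k in seq_len(nq)) {
    s <- shp[[k]]
    # physical gradients of the 6 shapes at qp k: lists of m-vectors
    gxs <- gys <- vector("list", 6)
    for (p in 1:6) {
      gxs[[p]] <- s$dN[p, 1] * g$gx[, 1] + s$dN[p, 2] * g$gx[, 2] + s$dN[p, 3] * g$gx[, 3]
      gys[[p]] <- s$dN[p, 1] * g$gy[, 1] + s$dN[p, 2] * g$gy[, 2] + s$dN[p, 3] * g$gy[, 3]
    }
    if (kind == "convection") {
      vxq <- vyq <- 0
      for (p in 1:6) {
        vxq <- vxq + s$N[p] * vel[p2$t2[, p], 1]
        vyq <- vyq + s$N[p] * vel[p2$t2[, p], 2]
      }
    }
    wk <- q$w[k] * g$A * coef
    for (a in 1:6) for (b in 1:6) {
      val <- switch(kind,
        stiffness = wk * (gxs[[a]] * gxs[[b]] + gys[[a]] * gys[[b]]),
        mass = wk * (s$N[a] * s$N[b]),
        convection = wk * s$N[a] * (vxq * gxs[[b]] + vyq * gys[[b]]))
      cnt <- cnt + 1
      acc_i[[cnt]] <- p2$t2[sel, a]
      acc_j[[cnt]] <- p2$t2[sel, b]
      acc_x[[cnt]] <- val[sel]
    }
  }
  sp(unlist(acc_i), unlist(acc_j), unlist(acc_x), p2$n_p2)
}

# Divergence coupling D_a[i,j] = int phi_i^{P1} d_a(N_j^{P2})
p2_div_block <- function(mesh, a) {
  p2 <- p2_connect(mesh)
  g <- mesh_geom(mesh)
  n <- nrow(mesh$nodes)
  q <- tri_quad7()
  acc_i <- acc_j <- acc_x <- vector("list", 18 * length(q$w))
  cnt <- 0
  for (k in seq_along(q$w)) {
    s <- p2_shape(q$lam[k, ])
    phi <- q$lam[k, ]  # P1 shapes are the barycentrics
    ga <- if (a == "x") g$gx else g$gy
    for (p in 1:6) {
      dNp <- s$dN[p, 1] * ga[, 1] + s$dN[p, 2] * ga[, 2] + s$dN[p, 3] * ga[, 3]
      for (v in 1:3) {
        cnt <- cnt + 1
        acc_i[[cnt]] <- mesh$tri[, v]
        acc_j[[cnt]] <- p2$t2[, p]
        acc_x[[cnt]] <- q$w[k] * g$A * phi[v] * dNp
      }
    }
  }
  sp(unlist(acc_i), unlist(acc_j), unlist(acc_x), n, p2$n_p2)
}

# P2 load vector from an element-constant force (length m) or P1 nodal
# force (length n).
p2_load <- function(mesh, f) {
  p2 <- p2_connect(mesh)
  g <- mesh_geom(mesh)
  m <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  q <- tri_quad7()
  out <- numeric(p2$n_p2)
  for (k in seq_along(q$w)) {
    s <- p2_shape(q$lam[k, ])
    fq <- if (length(f) == m) f else
      q$lam[k, 1] * f[mesh$tri[, 1]] + q$lam[k, 2] * f[mesh$tri[, 2]] +
      q$lam[k, 3] * f[mesh$tri[, 3]]
    for (p in 1:6) {
      out <- out + tab_sum(p2$t2[, p], q$w[k] * g$A * s$N[p] * fq, p2$n_p2)
    }
  }
  out
}

## ---- boundary utilities ------------------------------------------------

boundary_edges <- function(mesh, tags) {
  sel <- mesh$btag %in% tags
  mesh$bedge[sel, , drop = FALSE]
}

nodes_on_tags <- function(mesh, tags) {
  sort(unique(as.vector(boundary_edges(mesh, tags))))
}

edge_lengths <- function(mesh, ed) {
  sqrt(rowSums((mesh$nodes[ed[, 1], , drop = FALSE] -
                mesh$nodes[ed[, 2], , drop = FALSE])^2))
}

# P2 nodes (vertices + edge midpoints) lying on a tagged boundary.
p2_nodes_on_tags <- function(mesh, tags) {
  p2 <- p2_connect(mesh)
  ed <- boundary_edges(mesh, tags)
  if (nrow(ed) == 0) return(integer(0))
  tri <- mesh$tri
  all_ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(all_ed[, 1], all_ed[, 2]), pmax(all_ed[, 1], all_ed[, 2]))
  uk <- unique(key)
  bkey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  mid_ids <- nrow(mesh$nodes) + match(bkey, uk)
  sort(unique(c(as.vector(ed), mid_ids)))
}

## ---- linear algebra helpers --------------------------------------------

# Row-replacement Dirichlet conditions on a real sparse system.
apply_dirichlet <- function(A, b, idx, vals) {
  if (length(idx) == 0) return(list(A = A, b = b))
  n <- nrow(A)
  mask <- rep(1, n); mask[idx] <- 0
  A <- Matrix::Diagonal(n, mask) %*% A +
    Matrix::sparseMatrix(i = idx, j = idx, x = rep(1, length(idx)),
                         dims = c(n, n))
  b <- b * mask
  b[idx] <- vals
  list(A = A, b = b)
}

sp_solve <- function(A, b) {
  as.vector(Matrix::solve(A, b, sparse = TRUE))
}

# Complex sparse solve via the 2n real block form [[Ar,-Ai],[Ai,Ar]].
# Dirichlet rows (idx, complex vals) are imposed before blocking.
solve_complex <- function(Ar, Ai, br, bi, idx = integer(0), vals = complex(0)) {
  n <- nrow(Ar)
  if (length(idx)) {
    mask <- rep(1, n); mask[idx] <- 0
    D <- Matrix::Diagonal(n, mask)
    Ar <- D %*% Ar + Matrix::sparseMatrix(i = idx, j = idx,
                                          x = rep(1, length(idx)),
                                          dims = c(n, n))
    Ai <- D %*% Ai
    br <- br * mask; br[idx] <- Re(vals)
    bi <- bi * mask; bi[idx] <- Im(vals)
  }
  A <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  x <- sp_solve(A, c(br, bi))
  complex(real = x[1:n], imaginary = x[(n + 1):(2 * n)])
}
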