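#' Necrotic / quiescent zone thresholds
#'
#' Lethal and growth-limiting concentration thresholds for oxygen
#' (0.002644 mM = 2 mmHg and 0.01322 mM = 10 mmHg partial pressure) and
#' glucose (0.2 and 0.5 mM). The two species criteria are combined with a
#' union rule by default: a point is necrotic if either species is below
#' its lethal threshold. (The intersection rule is retained as an option
#' for sensitivity studies, but the union is the rule consistent with the
#' reference results: with standard medium, glucose never reaches its
#' lethal threshold while sizeable necrotic cores still form.)
#'
#' @param necrotic_O2,quiescent_O2 oxygen thresholds (mM)
#' @param necrotic_Gl,quiescent_Gl glucose thresholds (mM)
#' @param combination_rule "union" (default) or "intersection"
#' @return object of class \code{zone_thresholds}
#' @export
zone_thresholds <- function(necrotic_O2 = 0.002644, quiescent_O2 = 0.01322,
                            necrotic_Gl = 0.2, quiescent_Gl = 0.5,
                            combination_rule = c("union", "intersection")) {
  stopifnot(necrotic_O2 < quiescent_O2, necrotic_Gl < quiescent_Gl)
  out <- list(necrotic_O2 = necrotic_O2, quiescent_O2 = quiescent_O2,
              necrotic_Gl = necrotic_Gl, quiescent_Gl = quiescent_Gl,
              combination_rule = match.arg(combination_rule))
  class(out) <- "zone_thresholds"
  out
}

# Clip a convex polygon (rows of xy, with accompanying per-vertex field
# values) to the half-space field < thr, interpolating all fields at the
# crossings. fields is a matrix with one column per scalar field.
clip_below <- function(xy, fields, fcol, thr) {
  nv <- nrow(xy)
  if (nv == 0) return(list(xy = xy, fields = fields))
  keepv <- fields[, fcol] < thr
  if (all(keepv)) return(list(xy = xy, fields = fields))
  if (!any(keepv)) {
    return(list(xy = xy[0, , drop = FALSE], fields = fields[0, , drop = FALSE]))
  }
  out_xy <- matrix(0, 0, 2); out_f <- matrix(0, 0, ncol(fields))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    vi <- fields[i, fcol]; vj <- fields[j, fcol]
    if (vi < thr) {
      out_xy <- rbind(out_xy, xy[i, ]); out_f <- rbind(out_f, fields[i, ])
    }
    if ((vi < thr) != (vj < thr)) {
      t <- (thr - vi) / (vj - vi)
      out_xy <- rbind(out_xy, xy[i, ] + t * (xy[j, ] - xy[i, ]))
      out_f <- rbind(out_f, fields[i, ] + t * (fields[j, ] - fields[i, ]))
    }
  }
  list(xy = out_xy, fields = out_f)
}

poly_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  j <- c(2:n, 1)
  0.5 * abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]))
}

# Area of the sub-triangle region where every listed (field, threshold)
# condition holds (intersection of half-spaces under linear interpolation).
tri_area_below <- function(xy, fields, conds) {
  poly <- list(xy = xy, fields = fields)
  for (cd in conds) {
    poly <- clip_below(poly$xy, poly$fields, cd[1], cd[2])
    if (nrow(poly$xy) < 3) return(0)
  }
  poly_area(poly$xy)
}

# Spheroid area (per criterion) below the given per-species thresholds.
# criterion: "oxygen", "glucose" or "combined"; rule applies to "combined".
area_below_thresholds <- function(mesh, cO2, cGl, thrO2, thrGl, criterion,
                                  rule = "union") {
  sel <- which(mesh$region == 2L)
  tot <- 0
  for (e in sel) {
    vids <- mesh$tri[e, ]
    xy <- mesh$nodes[vids, , drop = FALSE]
    f <- cbind(cO2[vids], cGl[vids])
    a <- switch(criterion,
      oxygen = tri_area_below(xy, f, list(c(1, thrO2))),
      glucose = tri_area_below(xy, f, list(c(2, thrGl))),
      combined = if (rule == "union") {
        tri_area_below(xy, f, list(c(1, thrO2))) +
          tri_area_below(xy, f, list(c(2, thrGl))) -
          tri_area_below(xy, f, list(c(1, thrO2), c(2, thrGl)))
      } else {
        tri_area_below(xy, f, list(c(1, thrO2), c(2, thrGl)))
      })
    tot <- tot + a
  }
  tot
}

#' Classify spheroid tissue into necrotic / quiescent / proliferating zones
#'
#' Pointwise labels on the spheroid nodes under the combination rule, for
#' the oxygen-only, glucose-only and combined criteria. Quiescent is
#' exclusive of necrotic, so the three zones partition the spheroid.
#'
#' @param cO2,cGl \code{concentration_field}s for oxygen and glucose
#' @param thr \code{zone_thresholds}
#' @return object of class \code{zone_map}: nodal labels (1 necrotic,
#'   2 quiescent, 3 proliferating) per criterion plus the aggregate-side
#'   concentration fields
#' @export
classify_zones <- function(cO2, cGl, thr = zone_thresholds()) {
  mesh <- cO2$mesh
  vO2 <- cO2$c_spheroid
  vGl <- cGl$c_spheroid
  lab1 <- function(nec, qui) ifelse(nec, 1L, ifelse(qui, 2L, 3L))
  comb <- if (thr$combination_rule == "union") `|` else `&`
  labels <- list(
    oxygen = lab1(vO2 < thr$necrotic_O2, vO2 < thr$quiescent_O2),
    glucose = lab1(vGl < thr$necrotic_Gl, vGl < thr$quiescent_Gl),
    combined = lab1(comb(vO2 < thr$necrotic_O2, vGl < thr$necrotic_Gl),
                    comb(vO2 < thr$quiescent_O2, vGl < thr$quiescent_Gl)))
  out <- list(mesh = mesh, cO2 = vO2, cGl = vGl, thr = thr, labels = labels)
  class(out) <- "zone_map"
  out
}

#' Zone area fractions of the spheroid
#'
#' Area fractions (percent) of the necrotic, quiescent and proliferating
#' zones for each criterion, integrated with sub-element resolution: the
#' threshold level-set is interpolated linearly within each triangle, which
#' removes the O(h) bias of whole-element labelling. Fractions per
#' criterion sum to 100.
#'
#' @param zm a \code{zone_map}
#' @return nested list \code{fractions[[criterion]][zone]} in percent, plus
#'   \code{area_m2}
#' @export
zone_fractions <- function(zm) {
  mesh <- zm$mesh
  g <- mesh_geom(mesh)
  A <- sum(g$A[mesh$region == 2L])
  rule <- zm$thr$combination_rule
  out <- list()
  for (crit in c("oxygen", "glucose", "combined")) {
    nec <- area_below_thresholds(mesh, zm$cO2, zm$cGl,
                                 zm$thr$necrotic_O2, zm$thr$necrotic_Gl,
                                 crit, rule)
    qb <- area_below_thresholds(mesh, zm$cO2, zm$cGl,
                                zm$thr$quiescent_O2, zm$thr$quiescent_Gl,
                                crit, rule)
    out[[crit]] <- c(necrotic = 100 * nec / A,
                     quiescent = 100 * (qb - nec) / A,
                     proliferating = 100 * (A - qb) / A)
  }
  list(fractions = out, area_m2 = A)
}

#' Acoustic-vs-flow-rate equivalence factor
#'
#' Smallest non-acoustic flow rate whose necrotic fraction does not exceed
#' the acoustic reference's, found by linear interpolation between sweep
#' points, returned as a multiple of the reference flow rate.
#'
#' @param sweep_Q numeric vector of non-acoustic flow rates (uL/min)
#' @param sweep_necrotic matching necrotic fractions (percent)
#' @param reference_necrotic necrotic fraction of the acoustic reference
#' @param reference_Q reference flow rate (uL/min)
#' @return list with \code{ratio} and \code{attained}; if the reference is
#'   not reached within the sweep, \code{attained} is FALSE and
#'   \code{closest} reports the best value
#' @export
equivalent_flow_rate <- function(sweep_Q, sweep_necrotic,
                                 reference_necrotic, reference_Q = 1) {
  ord <- order(sweep_Q)
  Q <- sweep_Q[ord]; nec <- sweep_necrotic[ord]
  hit <- which(nec <= reference_necrotic)
  if (length(hit) == 0) {
    return(list(ratio = NA_real_, attained = FALSE,
                closest = min(nec)))
  }
  k <- hit[1]
  if (k == 1) {
    Qstar <- Q[1]
  } else {
    # interpolate the crossing between the bracketing sweep points
    t <- (nec[k - 1] - reference_necrotic) / (nec[k - 1] - nec[k])
    Qstar <- Q[k - 1] + t * (Q[k] - Q[k - 1])
  }
  list(ratio = Qstar / reference_Q, attained = TRUE, Q_star = Qstar)
}

#' Write scenario reports as CSV (with a JSON mirror)
#'
#' One row per scenario, deterministic column order matching the report
#' schema used across the sweeps.
#'
#' @param reports list of scenario report rows (named lists) as produced by
#'   \code{\link{run_case}}
#' @param csv_path output CSV path
#' @param json_path optional JSON mirror path
#' @return the data frame, invisibly
#' @export
write_report <- function(reports, csv_path, json_path = NULL) {
  cols <- c("scenario", "label", "Q_uLmin", "d0_nm",
            "avg_O2_mM", "avg_Gl_mM",
            "nec_O2_pct", "qui_O2_pct", "pro_O2_pct",
            "nec_Gl_pct", "qui_Gl_pct", "pro_Gl_pct",
            "nec_comb_pct", "qui_comb_pct", "pro_comb_pct",
            "tau_max_dyn_cm2", "lift_N")
  if (length(reports) == 0) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                               dimnames = list(NULL, cols)))
  } else {
    df <- do.call(rbind, lapply(reports, function(r) {
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA)
  }
  invisible(df)
}
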