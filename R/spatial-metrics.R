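# Distance measures: 2D normalized lateral distance along the membrane
# trace, serial-section 3D distance with fractional-area correction,
# nearest-gold distances for pits/vesicles, densities, and pooled
# distribution summaries.

# Project points (n x 2) onto a polyline. Returns arc position along the
# trace (can run beyond [0, L] when the point projects past a terminus,
# in which case the terminal segment is extended), the projected point,
# and the perpendicular distance.
.projectToPolyline <- function(points, trace) {
  nseg <- nrow(trace) - 1L
  seglen <- sqrt(rowSums((trace[-1L, , drop = FALSE] -
                          trace[-nrow(trace), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  n <- nrow(points)
  bestD <- rep(Inf, n); bestArc <- numeric(n)
  bestQ <- matrix(0, n, 2L)
  for (i in seq_len(nseg)) {
    if (seglen[i] == 0) next
    A <- trace[i, ]; B <- trace[i + 1L, ]
    AB <- B - A
    t <- ((points[, 1L] - A[1L]) * AB[1L] +
          (points[, 2L] - A[2L]) * AB[2L]) / sum(AB^2)
    t <- pmin(1, pmax(0, t))
    qx <- A[1L] + t * AB[1L]; qy <- A[2L] + t * AB[2L]
    d <- sqrt((points[, 1L] - qx)^2 + (points[, 2L] - qy)^2)
    upd <- d < bestD
    bestD[upd] <- d[upd]
    bestArc[upd] <- cum[i] + t[upd] * seglen[i]
    bestQ[upd, 1L] <- qx[upd]; bestQ[upd, 2L] <- qy[upd]
  }
  L <- cum[length(cum)]
  # extend past the termini so points beyond the trace keep arc < 0 / > L
  i1 <- which(bestArc < 1e-9)
  if (length(i1)) {
    u <- (trace[2L, ] - trace[1L, ]); u <- u / sqrt(sum(u^2))
    ext <- (points[i1, 1L] - trace[1L, 1L]) * (-u[1L]) +
           (points[i1, 2L] - trace[1L, 2L]) * (-u[2L])
    pos <- ext > 0
    bestArc[i1[pos]] <- -ext[pos]
    bestQ[i1[pos], ] <- cbind(trace[1L, 1L] - ext[pos] * u[1L],
                              trace[1L, 2L] - ext[pos] * u[2L])
  }
  i2 <- which(bestArc > L - 1e-9)
  if (length(i2)) {
    m <- nrow(trace)
    u <- (trace[m, ] - trace[m - 1L, ]); u <- u / sqrt(sum(u^2))
    ext <- (points[i2, 1L] - trace[m, 1L]) * u[1L] +
           (points[i2, 2L] - trace[m, 2L]) * u[2L]
    pos <- ext > 0
    bestArc[i2[pos]] <- L + ext[pos]
    bestQ[i2[pos], ] <- cbind(trace[m, 1L] + ext[pos] * u[1L],
                              trace[m, 2L] + ext[pos] * u[2L])
  }
  list(arc = bestArc, q = bestQ, perp = bestD, L = L)
}

#' Centre and half-width of a membrane trace
#'
#' The centre is the point at half the arc length of the polyline and the
#' half-width is half the total arc length — the quantities by which
#' single-profile lateral distances are normalized.
#'
#' @param trace polyline as a two-column coordinate matrix (nm) with
#'   positive arc length.
#' @return list with `center` (length-2 numeric, a point on the trace),
#'   `halfWidth` (nm), and `length` (total arc length, nm).
#' @examples
#' traceCenterHalfwidth(rbind(c(0, 0), c(60, 0), c(60, 40)))
#' @export
traceCenterHalfwidth <- function(trace) {
  trace <- .asPointMatrix(trace)
  if (nrow(trace) < 2L) stop("trace needs at least 2 vertices")
  seglen <- sqrt(rowSums((trace[-1L, , drop = FALSE] -
                          trace[-nrow(trace), , drop = FALSE])^2))
  L <- sum(seglen)
  if (L <= 0) stop("degenerate trace: zero arc length")
  cum <- c(0, cumsum(seglen))
  s <- L / 2
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seglen))
  t <- if (seglen[i] > 0) (s - cum[i]) / seglen[i] else 0
  center <- trace[i, ] + t * (trace[i + 1L, ] - trace[i, ])
  list(center = as.numeric(center), halfWidth = L / 2, length = L)
}

#' Normalized 2D lateral distance within a profile
#'
#' Each point is projected onto the membrane trace; its raw distance is
#' the arc length from the projection to the trace centre, normalized by
#' the trace half-width so that 0 is exactly at the centre and 1 exactly
#' at the edge. The fractional-area transform (`normalized^2`) maps a
#' uniform surface distribution on a circular PSD to uniform on \[0, 1\].
#' Points projecting beyond a trace terminus keep `normalized > 1` and
#' are flagged, not clamped.
#'
#' @param points point or points to locate: length-2 numeric or an
#'   n x 2 matrix (nm).
#' @param trace membrane polyline, two-column matrix (nm).
#' @param mode `"arc"` (default) measures along the trace;
#'   `"chord"` uses straight-line distances from the projection to the
#'   centre point (sensitivity analysis for curved traces).
#' @return data.frame with one row per point: `raw_nm`, `normalized`,
#'   `fractional_area` (= `normalized^2`), `beyond_edge` (logical).
#' @examples
#' tr <- rbind(c(0, 0), c(100, 0))
#' normalizedDistance2D(c(25, 30), tr)   # projects to (25,0): normalized 0.5
#' @export
normalizedDistance2D <- function(points, trace, mode = c("arc", "chord")) {
  mode <- match.arg(mode)
  points <- .asPointMatrix(points)
  trace <- .asPointMatrix(trace)
  if (nrow(trace) < 2L) stop("trace needs at least 2 vertices")
  ch <- traceCenterHalfwidth(trace)
  pr <- .projectToPolyline(points, trace)
  if (mode == "arc") {
    raw <- abs(pr$arc - ch$length / 2)
    hw <- ch$halfWidth
  } else {
    raw <- sqrt((pr$q[, 1L] - ch$center[1L])^2 +
                (pr$q[, 2L] - ch$center[2L])^2)
    hw <- max(sqrt(sum((trace[1L, ] - ch$center)^2)),
              sqrt(sum((trace[nrow(trace), ] - ch$center)^2)))
  }
  normalized <- raw / hw
  data.frame(raw_nm = raw, normalized = normalized,
             fractional_area = normalized^2,
             beyond_edge = pr$arc < 0 | pr$arc > ch$length)
}

#' Equivalent-circle geometry of a reconstructed synapse
#'
#' The PSD (or AZ) surface area is the sum over sections of trace arc
#' length times section thickness; the equivalent radius is that of the
#' circle with the same area. The 3D centre sits at the middle section's
#' trace centre.
#'
#' @param syn a [SynapseReconstruction-class].
#' @param trace `"psd"` (default) or `"az"`.
#' @return list with `areaUm2`, `rEquivNm`, and `center3d`
#'   (x lateral nm, y nm, z = middle section depth nm).
#' @export
synapseGeometry3D <- function(syn, trace = c("psd", "az")) {
  trace <- match.arg(trace)
  stopifnot(is(syn, "SynapseReconstruction"))
  th <- syn@profiles[[1L]]@sectionThicknessNm
  lens <- vapply(syn@profiles, function(p)
    .polylineLength(if (trace == "psd") p@psdTrace else p@azTrace),
    numeric(1))
  areaNm2 <- sum(lens * th)
  if (areaNm2 <= 0) stop("degenerate reconstruction: zero surface area")
  idx <- vapply(syn@profiles, slot, integer(1), name = "sectionIndex")
  mid <- syn@profiles[[match(syn@middleIndex, idx)]]
  list(areaUm2 = areaNm2 / 1e6,
       rEquivNm = sqrt(areaNm2 / pi),
       center3d = c(mid@offset[1L], mid@offset[2L],
                    syn@middleIndex * th))
}

# Lateral (along-trace) coordinates of a profile's points in the common
# stack frame: arc position relative to the trace centre plus the
# per-profile alignment offset.
.lateralCoords <- function(p, pts, trace = "psd") {
  tr <- if (trace == "psd") p@psdTrace else p@azTrace
  ch <- traceCenterHalfwidth(tr)
  pr <- .projectToPolyline(pts, tr)
  cbind(x = pr$arc - ch$length / 2 + p@offset[1L],
        y = rep(p@offset[2L], nrow(pts)))
}

#' 3D particle coordinates of a reconstruction
#'
#' Builds the coordinate frame used for 3D distances and cluster
#' analysis: x is the along-trace lateral position relative to each
#' section's trace centre (plus the per-profile alignment offset), y the
#' transverse offset, z the section depth `sectionIndex * thickness`.
#'
#' @param syn a [SynapseReconstruction-class].
#' @param kind `"gold"`, `"pits"`, or `"dockedVesicles"`.
#' @param trace which trace anchors the lateral frame, `"psd"` or `"az"`.
#' @return n x 3 matrix with columns `x`, `y`, `z` (nm) and an attribute
#'   `sectionIndex` giving each particle's section.
#' @export
particleLocations3D <- function(syn, kind = c("gold", "pits",
                                              "dockedVesicles"),
                                trace = c("psd", "az")) {
  kind <- match.arg(kind); trace <- match.arg(trace)
  stopifnot(is(syn, "SynapseReconstruction"))
  th <- syn@profiles[[1L]]@sectionThicknessNm
  parts <- lapply(syn@profiles, function(p) {
    pts <- slot(p, kind)
    if (!nrow(pts))
      return(list(xy = matrix(numeric(0), 0L, 2L), idx = integer(0)))
    list(xy = .lateralCoords(p, pts, trace),
         idx = rep(p@sectionIndex, nrow(pts)))
  })
  xy <- do.call(rbind, lapply(parts, `[[`, "xy"))
  idx <- unlist(lapply(parts, `[[`, "idx"))
  out <- cbind(x = xy[, 1L], y = xy[, 2L], z = idx * th)
  attr(out, "sectionIndex") <- idx
  out
}

#' Serial-section 3D distance with fractional-area correction
#'
#' The 3D distance of a particle to the synapse centre combines its
#' in-plane lateral offset from the middle section's trace centre with
#' the axial offset `|sectionIndex - middleIndex| * thickness`
#' (Pythagoras, equal section thickness assumed). Distances are
#' normalized by the equivalent-circle radius of the reconstructed PSD
#' and squared into fractional area, so a particle at `normalized = 0.5`
#' has `fractional_area = 0.25` — equidistant between centre and edge of
#' the equivalent circular PSD.
#'
#' `distance3D()` measures one explicit point; [distances3D()] measures
#' all annotated particles of a kind.
#'
#' @param syn a [SynapseReconstruction-class].
#' @param point length-2 numeric, in-profile coordinates (nm).
#' @param sectionIndex the section the point belongs to.
#' @param trace `"psd"` (default) or `"az"`.
#' @return data.frame row: `raw_nm`, `normalized`, `fractional_area`,
#'   `beyond_edge` (normalized > 1).
#' @examples
#' tr <- rbind(c(-100, 0), c(100, 0))
#' pr <- lapply(0:2, function(i)
#'   ProfileAnnotation("s", i, 40, "rest", "AMPA", tr, tr))
#' syn <- SynapseReconstruction(pr)
#' distance3D(syn, c(30, 0), 0L)  # d_lat 30, dz 40 -> raw 50
#' @export
distance3D <- function(syn, point, sectionIndex, trace = c("psd", "az")) {
  trace <- match.arg(trace)
  stopifnot(is(syn, "SynapseReconstruction"))
  idx <- vapply(syn@profiles, slot, integer(1), name = "sectionIndex")
  j <- match(as.integer(sectionIndex), idx)
  if (is.na(j)) stop("sectionIndex ", sectionIndex, " not in the stack")
  p <- syn@profiles[[j]]
  th <- p@sectionThicknessNm
  geo <- synapseGeometry3D(syn, trace)
  lat <- .lateralCoords(p, .asPointMatrix(point), trace)
  dLat <- abs(lat[, 1L] - geo$center3d[1L])
  dz <- abs(as.integer(sectionIndex) - syn@middleIndex) * th
  raw <- sqrt(dLat^2 + dz^2)
  normalized <- raw / geo$rEquivNm
  data.frame(raw_nm = raw, normalized = normalized,
             fractional_area = normalized^2,
             beyond_edge = normalized > 1)
}

#' @rdname distance3D
#' @param kind which particles to measure (`distances3D` only).
#' @return `distances3D()`: data.frame with one row per particle
#'   (`section_index`, `raw_nm`, `normalized`, `fractional_area`,
#'   `beyond_edge`).
#' @export
distances3D <- function(syn, kind = c("gold", "pits", "dockedVesicles"),
                        trace = c("psd", "az")) {
  kind <- match.arg(kind); trace <- match.arg(trace)
  pts3 <- particleLocations3D(syn, kind, trace)
  geo <- synapseGeometry3D(syn, trace)
  if (!nrow(pts3))
    return(data.frame(section_index = integer(0), raw_nm = numeric(0),
                      normalized = numeric(0), fractional_area = numeric(0),
                      beyond_edge = logical(0)))
  th <- syn@profiles[[1L]]@sectionThicknessNm
  dLat <- abs(pts3[, "x"] - geo$center3d[1L])
  dz <- abs(attr(pts3, "sectionIndex") - syn@middleIndex) * th
  raw <- sqrt(dLat^2 + dz^2)
  normalized <- raw / geo$rEquivNm
  data.frame(section_index = attr(pts3, "sectionIndex"), raw_nm = raw,
             normalized = normalized, fractional_area = normalized^2,
             beyond_edge = normalized > 1)
}

#' Nearest gold particle distance
#'
#' Minimum Euclidean distance (nm) from a feature (docked vesicle or
#' exocytic pit) to any gold particle of the same profile. Profiles
#' without gold return `NA` — an "absent" result to be excluded from
#' pooling, never zero.
#'
#' @param profile a [ProfileAnnotation-class].
#' @param feature length-2 numeric or n x 2 matrix of feature
#'   coordinates (nm).
#' @return numeric vector of distances (nm), `NA` when the profile has
#'   no gold.
#' @export
nearestGoldNm <- function(profile, feature) {
  stopifnot(is(profile, "ProfileAnnotation"))
  feature <- .asPointMatrix(feature)
  g <- profile@gold
  if (!nrow(g)) return(rep(NA_real_, nrow(feature)))
  vapply(seq_len(nrow(feature)), function(i)
    sqrt(min((g[, 1L] - feature[i, 1L])^2 + (g[, 2L] - feature[i, 2L])^2)),
    numeric(1))
}

#' Pooled feature-to-gold distances across a dataset
#'
#' @param ds a [GoldDataset-class].
#' @param kind `"pits"` or `"dockedVesicles"`.
#' @return data.frame with one row per feature in a gold-containing
#'   profile: `synapse_id`, `section_index`, `condition`, `label`,
#'   `distance_nm`. Features in profiles without gold are excluded.
#' @export
nearestGoldDistances <- function(ds, kind = c("pits", "dockedVesicles")) {
  kind <- match.arg(kind)
  stopifnot(is(ds, "GoldDataset"))
  rows <- lapply(ds@profiles, function(p) {
    feats <- slot(p, kind)
    if (!nrow(feats) || !nrow(p@gold)) return(NULL)
    data.frame(synapse_id = p@synapseId, section_index = p@sectionIndex,
               condition = p@condition, label = p@label,
               distance_nm = nearestGoldNm(p, feats),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(synapse_id = character(0), section_index = integer(0),
                      condition = character(0), label = character(0),
                      distance_nm = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Receptor surface density
#'
#' @param count particle count.
#' @param areaUm2 PSD surface area in square micrometres (> 0).
#' @return density in particles per square micrometre.
#' @examples
#' receptorDensity(16, 0.08)  # 200 per um^2
#' @export
receptorDensity <- function(count, areaUm2) {
  if (any(!is.finite(areaUm2)) || any(areaUm2 <= 0))
    stop("areaUm2 must be positive")
  count / areaUm2
}

#' Pool normalized-location distributions by group
#'
#' Per-group medians with seeded percentile-bootstrap confidence
#' intervals and ECDF tables — the tabular analogue of cumulative
#' relative frequency plots.
#'
#' @param x numeric vector of values (e.g. normalized distances), or a
#'   data.frame from [normalizedDistance2D()] / [distances3D()] (the
#'   `measure` column is used).
#' @param group optional grouping vector (same length as the values);
#'   a single pooled group when omitted.
#' @param measure column to pool when `x` is a data.frame.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param excludeBeyondEdge drop values flagged `beyond_edge` (only when
#'   `x` is a data.frame carrying that flag); default `FALSE`.
#' @return list with `summary` (data.frame: `group`, `n`, `median`,
#'   `ci_lo`, `ci_hi`) and `ecdf` (data.frame: `group`, `x`, `F`).
#'   Empty groups are dropped with a warning.
#' @export
poolDistributions <- function(x, group = NULL,
                              measure = c("normalized", "fractional_area",
                                          "raw_nm"),
                              B = 10000L, seed = 1L, conf = 0.95,
                              excludeBeyondEdge = FALSE) {
  measure <- match.arg(measure)
  if (is.data.frame(x)) {
    keep <- rep(TRUE, nrow(x))
    if (excludeBeyondEdge && "beyond_edge" %in% names(x))
      keep <- !x$beyond_edge
    vals <- x[[measure]][keep]
    if (!is.null(group)) group <- group[keep]
  } else vals <- as.numeric(x)
  if (is.null(group)) group <- rep("all", length(vals))
  ok <- is.finite(vals)
  vals <- vals[ok]; group <- as.character(group)[ok]
  if (!length(vals)) stop("no finite values to pool")
  grps <- split(vals, group)
  empty <- names(grps)[lengths(grps) == 0L]
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    grps <- grps[lengths(grps) > 0L]
  }
  a <- (1 - conf) / 2
  seeds <- splitSeed(seed, length(grps))
  summ <- do.call(rbind, lapply(seq_along(grps), function(i) {
    v <- grps[[i]]
    boots <- withSeed(seeds[i], {
      vapply(seq_len(B), function(b)
        stats::median(v[sample.int(length(v), replace = TRUE)]),
        numeric(1))
    })
    ci <- stats::quantile(boots, c(a, 1 - a), names = FALSE, type = 7)
    data.frame(group = names(grps)[i], n = length(v),
               median = stats::median(v), ci_lo = ci[1L], ci_hi = ci[2L],
               stringsAsFactors = FALSE)
  }))
  ecdfTab <- do.call(rbind, lapply(names(grps), function(g) {
    v <- sort(grps[[g]])
    data.frame(group = g, x = v,
               F = seq_along(v) / length(v), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- rownames(ecdfTab) <- NULL
  list(summary = summ, ecdf = ecdfTab)
}
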