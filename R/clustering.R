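# Per-synapse K-means cluster analysis of 3D gold positions: SSD curve,
# knee-point selection of the cluster number, randomization null maps
# over the reconstructed PSD surface, and SSD-vs-size regression.

#' K-means clustering (Lloyd's algorithm)
#'
#' Plain Lloyd iterations (assign, update, repeat until assignments stop
#' changing, at most `maxIter` iterations), best of `nInit` seeded
#' restarts by within-cluster sum of squares. Initial centroids are drawn
#' uniformly at random from the points (no k-means++). Empty clusters
#' are re-seeded to the point farthest from its centroid.
#'
#' @param points n x d coordinate matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param nInit number of random restarts.
#' @param seed integer seed, or `NULL` to consume the caller's stream.
#' @param warmStart optional centroid matrix used as one extra restart.
#' @param maxIter Lloyd iteration cap.
#' @return list with `assignments` (1-based integer vector), `centroids`
#'   (k x d), and `ssd` (within-cluster sum of squared distances).
#' @examples
#' X <- rbind(c(0,0), c(0,1), c(1,0), c(1,1))
#' kmeansLloyd(X, 2, seed = 1)$ssd   # 1.0: pairs across opposite edges
#' @export
kmeansLloyd <- function(points, k, nInit = 10L, seed = NULL,
                        warmStart = NULL, maxIter = 200L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= nrow(points)")
  withSeed(seed, {
    best <- NULL
    starts <- lapply(seq_len(nInit), function(i)
      points[sample.int(n, k), , drop = FALSE])
    if (!is.null(warmStart)) {
      stopifnot(ncol(warmStart) == ncol(points), nrow(warmStart) == k)
      starts <- c(starts, list(as.matrix(warmStart)))
    }
    for (s in starts) {
      fit <- .lloyd_run(points, s, maxIter)
      if (is.null(best) || fit$ssd < best$ssd) best <- fit
    }
    best
  })
}

#' Within-cluster SSD as a function of cluster number
#'
#' Runs [kmeansLloyd()] for k = 1..`kMax`. Each k is additionally warm
#' started from the best solution at k - 1 augmented with the point
#' farthest from its centroid, which guarantees a non-increasing curve.
#'
#' @param points n x d coordinate matrix.
#' @param kMax largest k (default n).
#' @param nInit random restarts per k.
#' @param seed integer seed.
#' @return numeric vector `SSD(k)`, k = 1..kMax; `SSD(n) == 0`.
#' @export
ssdCurveMatrix <- function(points, kMax = nrow(points), nInit = 10L,
                           seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 1L) stop("need at least one point")
  kMax <- min(kMax, n)
  withSeed(seed, {
    out <- numeric(kMax)
    prev <- NULL
    for (k in seq_len(kMax)) {
      warm <- NULL
      if (!is.null(prev) && k > 1L) {
        # previous centroids plus the worst-fit point
        d2 <- rowSums((points - prev$centroids[prev$assignments, ,
                                               drop = FALSE])^2)
        warm <- rbind(prev$centroids, points[which.max(d2), ])
      }
      fit <- kmeansLloyd(points, k, nInit = nInit, warmStart = warm)
      out[k] <- fit$ssd
      prev <- fit
    }
    # the warm start makes the curve non-increasing by construction;
    # cummin guards against floating-point slack
    cummin(out)
  })
}

#' @describeIn ssdCurve SSD curve computed from a coordinate matrix.
#' @param kMax largest k (default the number of points).
#' @param nInit random restarts per k.
#' @param seed integer seed.
#' @export
setMethod("ssdCurve", "matrix", function(x, kMax = nrow(x), nInit = 10L,
                                         seed = NULL, ...)
  ssdCurveMatrix(x, kMax = kMax, nInit = nInit, seed = seed))

#' SSD curve of a point set or cluster result
#'
#' Applied to a coordinate matrix, computes the within-cluster
#' sum-of-squares curve over k (see [ssdCurveMatrix()]); applied to a
#' [ClusterResult-class], returns the stored curve.
#'
#' @param x matrix of coordinates or a [ClusterResult-class].
#' @param ... passed on to [ssdCurveMatrix()].
#' @return numeric vector SSD(k).
#' @name ssdCurve
NULL

#' @describeIn ssdCurve stored curve of a fitted result.
#' @export
setMethod("ssdCurve", "ClusterResult", function(x, ...) x@ssdCurve)

#' Knee point of an SSD curve
#'
#' The knee is the k whose point on the min-max-normalized curve lies
#' farthest (perpendicular distance) from the chord joining
#' `(1, SSD(1))` to `(N, SSD(N))`. Ties break to the smallest k; curves
#' of length <= 2 and flat curves return 1.
#'
#' @param ssd numeric SSD values for k = 1..N.
#' @return integer, the chosen number of clusters.
#' @examples
#' kneePoint(c(100, 10, 8, 6, 5))   # 2
#' kneePoint(c(40, 30, 20, 10))     # 1: no curvature, tie broken low
#' @export
kneePoint <- function(ssd) {
  N <- length(ssd)
  if (N < 1L) stop("empty SSD curve")
  if (N <= 2L) return(1L)
  lo <- min(ssd); hi <- max(ssd)
  if (hi - lo <= 0) return(1L)
  x <- (seq_len(N) - 1) / (N - 1)
  y <- (ssd - lo) / (hi - lo)
  # chord from (x1, y1) to (xN, yN)
  dx <- x[N] - x[1L]; dy <- y[N] - y[1L]
  len <- sqrt(dx^2 + dy^2)
  d <- abs(dx * (y[1L] - y) - (x[1L] - x) * dy) / len
  which.max(d > max(d) - 1e-12)  # first index attaining the max
}

# Maximum normalized chord distance of an SSD curve: the knee's
# prominence. Smooth single-cluster decay curves stay well below the
# sharp elbows produced by genuinely clustered data.
.kneeProminence <- function(ssd) {
  N <- length(ssd)
  if (N <= 2L) return(0)
  lo <- min(ssd); hi <- max(ssd)
  if (hi - lo <= 0) return(0)
  x <- (seq_len(N) - 1) / (N - 1)
  y <- (ssd - lo) / (hi - lo)
  dx <- x[N] - x[1L]; dy <- y[N] - y[1L]
  max(abs(dx * (y[1L] - y) - (x[1L] - x) * dy) / sqrt(dx^2 + dy^2))
}

# knee choice with a no-knee guard: curves whose best elbow is not
# prominent enough are called single-cluster
.kneeGuarded <- function(ssd, threshold) {
  if (.kneeProminence(ssd) < threshold) 1L else kneePoint(ssd)
}

#' Randomized null maps over the PSD surface
#'
#' Generates point sets with the observed number of particles placed
#' uniformly over the reconstructed PSD surface: each point picks a
#' section with probability proportional to trace length x thickness,
#' a position uniform along that section's trace, and depth at the
#' section centre — the null model against which observed clustering is
#' compared.
#'
#' @param syn a [SynapseReconstruction-class] with at least one gold
#'   particle.
#' @param nMaps number of null maps (default 50).
#' @param seed integer master seed; per-map seeds are split from it.
#' @param n number of points per map; defaults to the synapse's gold
#'   count.
#' @return list of `nMaps` coordinate matrices (n x 3) in the same frame
#'   as [particleLocations3D()].
#' @export
randomizeWithinPsd <- function(syn, nMaps = 50L, seed = 1L, n = NULL) {
  stopifnot(is(syn, "SynapseReconstruction"))
  if (is.null(n)) n <- nrow(particleLocations3D(syn, "gold"))
  if (n < 1L) stop("need at least one particle to randomize")
  th <- syn@profiles[[1L]]@sectionThicknessNm
  lens <- vapply(syn@profiles, function(p) .polylineLength(p@psdTrace),
                 numeric(1))
  idx <- vapply(syn@profiles, slot, integer(1), name = "sectionIndex")
  w <- lens * th
  seeds <- splitSeed(seed, nMaps)
  lapply(seq_len(nMaps), function(m) {
    withSeed(seeds[m], {
      sec <- sample.int(length(w), n, replace = TRUE, prob = w)
      pts <- t(vapply(sec, function(j) {
        p <- syn@profiles[[j]]
        s <- stats::runif(1, 0, lens[j])      # arc position on the trace
        c(s - lens[j] / 2 + p@offset[1L], p@offset[2L], idx[j] * th)
      }, numeric(3)))
      colnames(pts) <- c("x", "y", "z")
      pts
    })
  })
}

#' Full per-synapse cluster analysis
#'
#' Composes the pieces: SSD curve over k = 1..N, knee-point choice of k
#' (synapses with fewer than 4 gold particles skip knee selection and
#' report k = 1), K-means fit at the chosen k, and the randomization
#' null — `nMaps` uniform re-placements over the PSD surface, each
#' analysed with its own knee-determined k, whose mean SSD is reported.
#'
#' @param syn a [SynapseReconstruction-class].
#' @param nMaps randomized null maps (default 50; 0 skips the null).
#' @param nInit K-means restarts per k.
#' @param seed integer master seed.
#' @param nullK `"knee"` (default) lets each null map choose its own k;
#'   `"data"` fixes the data's k for all maps.
#' @param kneeThreshold minimum knee prominence (maximum distance from
#'   the min-max-normalized SSD curve to its end-to-end chord, in units
#'   of the normalized plot diagonal) required to accept a knee;
#'   curves below it are called single-cluster. The smooth power-law
#'   decay of an unclustered point set stays below ~0.45 while planted
#'   clusters produce sharp elbows above it.
#' @return a [ClusterResult-class]; for a synapse with no gold, an empty
#'   result with `n = 0` (excluded from downstream regression).
#' @export
clusterAnalysis <- function(syn, nMaps = 50L, nInit = 10L, seed = 1L,
                            nullK = c("knee", "data"),
                            kneeThreshold = 0.5) {
  nullK <- match.arg(nullK)
  stopifnot(is(syn, "SynapseReconstruction"))
  pts <- particleLocations3D(syn, "gold")
  N <- nrow(pts)
  if (N == 0L)
    return(new("ClusterResult", synapseId = syn@synapseId, n = 0L,
               kOpt = 0L, centroids = matrix(numeric(0), 0L, 3L),
               assignments = integer(0), ssdCurve = numeric(0),
               ssdAtKopt = NA_real_, randomizedMeanSsd = NA_real_,
               clusterSizes = integer(0)))
  seeds <- splitSeed(seed, 3L)
  curve <- ssdCurveMatrix(pts[, 1:3, drop = FALSE], nInit = nInit,
                          seed = seeds[1L])
  kopt <- if (N < 4L) 1L else .kneeGuarded(curve, kneeThreshold)
  fit <- kmeansLloyd(pts[, 1:3, drop = FALSE], kopt, nInit = nInit,
                     seed = seeds[2L])
  randMean <- NA_real_
  if (nMaps > 0L) {
    maps <- randomizeWithinPsd(syn, nMaps = nMaps, seed = seeds[3L], n = N)
    mapSeeds <- splitSeed(seeds[3L] + 1L, nMaps)
    ssds <- vapply(seq_along(maps), function(m) {
      mp <- maps[[m]]
      if (nullK == "data") {
        kmeansLloyd(mp, kopt, nInit = nInit, seed = mapSeeds[m])$ssd
      } else {
        cv <- ssdCurveMatrix(mp, nInit = nInit, seed = mapSeeds[m])
        km <- if (N < 4L) 1L else .kneeGuarded(cv, kneeThreshold)
        cv[km]
      }
    }, numeric(1))
    randMean <- mean(ssds)
  }
  new("ClusterResult", synapseId = syn@synapseId, n = as.integer(N),
      kOpt = as.integer(kopt), centroids = fit$centroids,
      assignments = as.integer(fit$assignments), ssdCurve = curve,
      ssdAtKopt = curve[kopt], randomizedMeanSsd = randMean,
      clusterSizes = as.integer(tabulate(fit$assignments, nbins = kopt)))
}

#' Cohort table of cluster results
#'
#' @param results list of [ClusterResult-class].
#' @param areas optional named numeric of PSD areas (um^2) keyed by
#'   synapse id (e.g. from [synapseGeometry3D()]).
#' @return data.frame with one row per analysed synapse: `synapse_id`,
#'   `n`, `k_opt`, `ssd`, `randomized_mean_ssd`, `area_um2`.
#' @export
clusterCohort <- function(results, areas = NULL) {
  rows <- lapply(results, function(r) {
    data.frame(synapse_id = r@synapseId, n = r@n, k_opt = r@kOpt,
               ssd = r@ssdAtKopt, randomized_mean_ssd = r@randomizedMeanSsd,
               area_um2 = if (!is.null(areas)) areas[[r@synapseId]] %||%
                 NA_real_ else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression of cluster SSD on synapse size
#'
#' Ordinary least squares of SSD on PSD area, fitted separately to the
#' observed and the randomized-null SSDs, reporting slope, intercept,
#' R^2 and the two-sided slope p-value.
#'
#' @param cohort data.frame as returned by [clusterCohort()] with a
#'   non-`NA` `area_um2` column; synapses with `n == 0` are dropped.
#' @return data.frame with rows `data` and `randomized`.
#' @export
regressSsdVsSize <- function(cohort) {
  cohort <- cohort[cohort$n > 0L & is.finite(cohort$area_um2), ,
                   drop = FALSE]
  if (nrow(cohort) < 3L) stop("need at least 3 synapses for regression")
  if (stats::var(cohort$area_um2) == 0)
    stop("degenerate regressor: all areas equal")
  fit1 <- function(y) {
    m <- stats::lm(y ~ cohort$area_um2)
    s <- summary(m)
    data.frame(slope = unname(stats::coef(m)[2L]),
               intercept = unname(stats::coef(m)[1L]),
               r_squared = s$r.squared,
               p_value = unname(s$coefficients[2L, 4L]))
  }
  out <- rbind(fit1(cohort$ssd), fit1(cohort$randomized_mean_ssd))
  out <- cbind(series = c("data", "randomized"), out)
  rownames(out) <- NULL
  out
}
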