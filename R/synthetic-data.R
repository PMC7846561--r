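# Synthetic-data generator: placement laws on a disc-shaped PSD/AZ,
# gold-labeling efficiency and background, and the random-sectioning
# forward model that turns 3D synapses into stacks of 2D profiles with
# known ground truth.

#' Particle placement model
#'
#' Placement laws are parameterized on fractional area `u = (r/R)^2`, so
#' the uniform surface law is exactly `u ~ Beta(1, 1)`, edge bias is
#' `u ~ Beta(betaA, 1)` with `betaA > 1`, and centre bias is
#' `u ~ Beta(1, betaB)` with `betaB > 1`. The clustered law scatters
#' Gaussian clusters around centroids drawn on the disc (the centroid
#' radius itself following a Beta fractional-area law when shape
#' parameters are supplied).
#'
#' @param law `"uniform"`, `"edge_biased"`, `"center_biased"`, or
#'   `"clustered"`.
#' @param betaA,betaB Beta shape parameters for the biased laws (and,
#'   for the clustered law, for the centroid radius draw).
#' @param nClusters number of clusters (clustered law).
#' @param clusterSigmaNm Gaussian scatter of each cluster (nm).
#' @param clusterMinSize minimum particles per cluster before the
#'   remainder is distributed at random.
#' @param clusterMinSepNm minimum centroid-to-centroid separation (nm);
#'   centroid draws are rejection-sampled until it holds. 0 disables.
#' @return object of class `"PlacementModel"`.
#' @export
placementModel <- function(law = c("uniform", "edge_biased",
                                   "center_biased", "clustered"),
                           betaA = 1, betaB = 1, nClusters = 1L,
                           clusterSigmaNm = 25, clusterMinSize = 4L,
                           clusterMinSepNm = 0) {
  law <- match.arg(law)
  if (betaA <= 0 || betaB <= 0) stop("Beta shape parameters must be > 0")
  if (law == "edge_biased" && betaA <= 1)
    stop("edge_biased requires betaA > 1")
  if (law == "center_biased" && betaB <= 1)
    stop("center_biased requires betaB > 1")
  if (nClusters < 1L) stop("nClusters must be >= 1")
  if (clusterSigmaNm <= 0) stop("clusterSigmaNm must be > 0")
  structure(list(law = law, betaA = betaA, betaB = betaB,
                 nClusters = as.integer(nClusters),
                 clusterSigmaNm = clusterSigmaNm,
                 clusterMinSize = as.integer(clusterMinSize),
                 clusterMinSepNm = clusterMinSepNm),
            class = "PlacementModel")
}

#' Place particles on a disc-shaped PSD
#'
#' Draws `n` particle positions on a disc of radius `R` according to a
#' [placementModel()]. For the non-clustered laws a fractional area `u`
#' is drawn (uniform: `U(0,1)`; edge: `Beta(betaA, 1)`; centre:
#' `Beta(1, betaB)`), the radius is `R * sqrt(u)`, and the angle uniform.
#' The clustered law draws `nClusters` centroids on the disc (radius
#' scaled to 0.7 R for uniform centroids, or Beta-derived when shapes are
#' given) and scatters Gaussian clusters around them, clamping points to
#' the disc.
#'
#' @param n number of particles (>= 0).
#' @param R disc radius (nm, > 0).
#' @param model a [placementModel()].
#' @param seed integer seed, or `NULL` to consume the caller's RNG stream.
#' @return n x 2 coordinate matrix; for the clustered law, an attribute
#'   `"cluster"` with the true cluster index per particle and
#'   `"centroids"` with the true centroids.
#' @examples
#' pts <- placeParticlesDisc(1000, 150, placementModel("uniform"), seed = 1)
#' median(rowSums(pts^2)) / 150^2   # ~ 0.5: fractional area is U(0,1)
#' @export
placeParticlesDisc <- function(n, R, model = placementModel(), seed = NULL) {
  stopifnot(inherits(model, "PlacementModel"))
  if (n < 0) stop("n must be >= 0")
  if (R <= 0) stop("R must be > 0")
  withSeed(seed, {
    if (n == 0L) {
      out <- matrix(numeric(0), 0L, 2L)
    } else if (model$law == "clustered") {
      k <- model$nClusters
      drawCentroids <- function() {
        uc <- if (model$betaA > 1)
          stats::rbeta(k, model$betaA, 1)
        else if (model$betaB > 1)
          stats::rbeta(k, 1, model$betaB)
        else stats::runif(k)
        rc <- 0.7 * R * sqrt(uc)
        thc <- stats::runif(k, 0, 2 * pi)
        cbind(rc * cos(thc), rc * sin(thc))
      }
      cen <- drawCentroids()
      if (k > 1L && model$clusterMinSepNm > 0) {
        tries <- 0L
        while (min(stats::dist(cen)) < model$clusterMinSepNm &&
               tries < 200L) {
          cen <- drawCentroids()
          tries <- tries + 1L
        }
      }
      # at least clusterMinSize per cluster, remainder at random
      base <- min(model$clusterMinSize, n %/% k)
      assign <- rep(seq_len(k), each = base)
      extra <- n - length(assign)
      if (extra > 0L)
        assign <- c(assign, sample.int(k, extra, replace = TRUE))
      assign <- sample(assign)      # shuffle order
      out <- cen[assign, , drop = FALSE] +
        matrix(stats::rnorm(2L * n, 0, model$clusterSigmaNm), n, 2L)
      # clamp to the disc
      r <- sqrt(rowSums(out^2))
      over <- r > R
      if (any(over)) out[over, ] <- out[over, ] * (R / r[over])
      attr(out, "cluster") <- assign
      attr(out, "centroids") <- cen
    } else {
      u <- switch(model$law,
        uniform = stats::runif(n),
        edge_biased = stats::rbeta(n, model$betaA, 1),
        center_biased = stats::rbeta(n, 1, model$betaB))
      r <- R * sqrt(u)
      th <- stats::runif(n, 0, 2 * pi)
      out <- cbind(r * cos(th), r * sin(th))
    }
    out
  })
}

#' Random-sectioning forward model
#'
#' Slices a disc-shaped synapse carrying 2D particle positions into
#' parallel slabs of the given thickness along a random direction,
#' emulating how each micrograph is a random fixed-thickness segment of
#' a synapse. Each slab that intersects the disc becomes a profile whose
#' PSD/AZ trace spans the chord of the disc at the slab centre (length
#' `2 * sqrt(R^2 - c^2)`); a particle's in-profile position is its signed
#' distance along the chord. Within a slab, uniformly placed particles
#' are uniform along the chord, which is why pooled profile data recover
#' the underlying radial law.
#'
#' @param points n x 2 particle positions on the disc (nm); attributes
#'   are preserved into the mapping below.
#' @param R disc radius (nm).
#' @param thickness slab/section thickness (nm).
#' @param seed integer seed (chord direction and slab phase), or `NULL`.
#' @param synapseId,condition,label metadata for the produced profiles.
#' @param pointKind which annotation slot receives the particles
#'   (`"gold"`, `"pits"`, `"dockedVesicles"`).
#' @return A [SynapseReconstruction-class]; attribute `"pointMap"` gives,
#'   for each input particle, its profile position (row `section`) and
#'   in-profile coordinates, with `NA` for particles falling outside all
#'   kept slabs (numerically, beyond the disc rim).
#' @export
sliceSynapse <- function(points, R, thickness, seed = NULL,
                         synapseId = "syn1", condition = "rest",
                         label = "AMPA", pointKind = "gold") {
  if (thickness <= 0) stop("thickness must be > 0")
  points <- .asPointMatrix(points)
  nSlabs <- ceiling(2 * R / thickness)
  slack <- nSlabs * thickness - 2 * R
  withSeed(seed, {
    theta <- stats::runif(1, 0, 2 * pi)
    phase <- if (slack > 0) stats::runif(1, 0, slack) else 0
  })
  uDir <- c(cos(theta), sin(theta))       # along the chord
  vDir <- c(-sin(theta), cos(theta))      # slab normal
  u <- if (nrow(points)) points %*% uDir else numeric(0)
  v <- if (nrow(points)) points %*% vDir else numeric(0)
  # the disc sits at a random phase within a grid of exactly
  # ceiling(2R/thickness) slabs
  v0 <- -R - phase
  slabs <- 0:(nSlabs - 1L)
  ctr <- v0 + (slabs + 0.5) * thickness
  lo <- v0 + slabs * thickness
  hi <- lo + thickness
  keep <- hi > -R & lo < R              # slab intersects the disc
  slabs <- slabs[keep]; ctr <- ctr[keep]
  lo <- lo[keep]; hi <- hi[keep]
  # rim slabs: take the chord at the centre of the slab-disc overlap
  cEff <- (pmax(lo, -R) + pmin(hi, R)) / 2
  halfChord <- sqrt(R^2 - cEff^2)
  secIdx <- seq_along(slabs) - 1L
  jOf <- if (nrow(points)) floor((v - v0) / thickness) else numeric(0)
  slot <- match(jOf, slabs)
  profs <- vector("list", length(slabs))
  ptSection <- rep(NA_integer_, nrow(points))
  for (i in seq_along(slabs)) {
    inSlab <- which(!is.na(slot) & slot == i)
    ptSection[inSlab] <- secIdx[i]
    tr <- rbind(c(-halfChord[i], 0), c(halfChord[i], 0))
    pts <- if (length(inSlab))
      cbind(u[inSlab], rep(0, length(inSlab)))
    else matrix(numeric(0), 0L, 2L)
    args <- list(synapseId = synapseId, sectionIndex = secIdx[i],
                 sectionThicknessNm = thickness, condition = condition,
                 label = label, azTrace = tr, psdTrace = tr)
    args[[pointKind]] <- pts
    profs[[i]] <- do.call(ProfileAnnotation, args)
  }
  syn <- SynapseReconstruction(profs)
  attr(syn, "pointMap") <- data.frame(
    section = ptSection,
    x = as.numeric(u), y = rep(0, nrow(points)),
    v = as.numeric(v))
  syn
}

#' Stochastic immunogold labeling
#'
#' Each receptor is retained as a gold particle independently with the
#' given labeling efficiency; background (off-target) gold is added as a
#' Poisson count of points placed uniformly on the annulus just outside
#' the PSD disc.
#'
#' @param receptors n x 2 receptor positions (nm).
#' @param efficiency labeling probability in \[0, 1\] (default 0.5).
#' @param backgroundRate expected number of background gold particles for
#'   the whole synapse (scale by profile count upstream as needed).
#' @param R PSD disc radius (nm); background lands on `[R, 1.3 R]`.
#' @param seed integer seed or `NULL`.
#' @return list with `gold` (m x 2 matrix), `kept` (logical per
#'   receptor), and `isBackground` (logical per gold row).
#' @export
applyGoldLabeling <- function(receptors, efficiency = 0.5,
                              backgroundRate = 0, R = 150, seed = NULL) {
  if (efficiency < 0 || efficiency > 1)
    stop("efficiency must be in [0, 1]")
  if (backgroundRate < 0) stop("backgroundRate must be >= 0")
  receptors <- .asPointMatrix(receptors)
  withSeed(seed, {
    kept <- if (nrow(receptors))
      stats::runif(nrow(receptors)) < efficiency else logical(0)
    nbg <- stats::rpois(1L, backgroundRate)
    bg <- if (nbg > 0L) {
      r <- R * sqrt(stats::runif(nbg, 1, 1.3^2))
      th <- stats::runif(nbg, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    } else matrix(numeric(0), 0L, 2L)
    list(gold = rbind(receptors[kept, , drop = FALSE], bg),
         kept = kept,
         isBackground = c(rep(FALSE, sum(kept)), rep(TRUE, nbg)))
  })
}

#' Generator configuration
#'
#' Bundles the study-condition parameters of the synthetic generator.
#' Defaults mirror the conditions the analysis assumes: a 150-nm-radius
#' disc PSD congruent with the AZ, ~50% labeling efficiency, 0.03
#' background gold per profile, 1.9 docked vesicles and 0.28 pits per
#' profile, and 40-nm sections.
#'
#' @param psdRadiusNm PSD disc radius (nm).
#' @param azEqualsPsd logical; when `FALSE`, `azRadiusNm` may differ.
#' @param azRadiusNm AZ radius when not congruent.
#' @param thicknessNm section thickness (40 TEM, 20 block-face).
#' @param nSynapses number of synapses to generate.
#' @param particlesPerSynapse Poisson mean receptor count per synapse.
#' @param labelingEfficiency gold labeling probability.
#' @param backgroundRate expected background gold per profile.
#' @param pitRatePerProfile expected exocytic pits per profile.
#' @param dockedRatePerProfile expected docked vesicles per profile.
#' @param receptorPlacement,pitPlacement [placementModel()]s.
#' @param condition,label metadata applied to all generated profiles.
#' @param seed master seed; per-synapse streams are split from it.
#' @return object of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(psdRadiusNm = 150, azEqualsPsd = TRUE,
                            azRadiusNm = psdRadiusNm, thicknessNm = 40,
                            nSynapses = 100L, particlesPerSynapse = 32,
                            labelingEfficiency = 0.5,
                            backgroundRate = 0.03,
                            pitRatePerProfile = 0.28,
                            dockedRatePerProfile = 1.9,
                            receptorPlacement = placementModel("uniform"),
                            pitPlacement = placementModel("uniform"),
                            condition = "rest", label = "AMPA",
                            seed = 1L) {
  if (labelingEfficiency < 0 || labelingEfficiency > 1)
    stop("labelingEfficiency must be in [0, 1]")
  if (any(c(backgroundRate, pitRatePerProfile, dockedRatePerProfile) < 0))
    stop("rates must be >= 0")
  if (psdRadiusNm <= 0 || thicknessNm <= 0)
    stop("psdRadiusNm and thicknessNm must be > 0")
  structure(list(psdRadiusNm = psdRadiusNm, azEqualsPsd = azEqualsPsd,
                 azRadiusNm = if (azEqualsPsd) psdRadiusNm else azRadiusNm,
                 thicknessNm = thicknessNm,
                 nSynapses = as.integer(nSynapses),
                 particlesPerSynapse = particlesPerSynapse,
                 labelingEfficiency = labelingEfficiency,
                 backgroundRate = backgroundRate,
                 pitRatePerProfile = pitRatePerProfile,
                 dockedRatePerProfile = dockedRatePerProfile,
                 receptorPlacement = receptorPlacement,
                 pitPlacement = pitPlacement,
                 condition = condition, label = label,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Named generator presets
#'
#' Presets emulating the study conditions:
#' \describe{
#'   \item{`AMPA_like`}{two edge-leaning Gaussian receptor clusters on
#'     20-nm block-face sections; ~32 receptors/synapse at 50% labeling.}
#'   \item{`NMDA_like`}{one centre-leaning cluster, ~20 receptors/synapse,
#'     20-nm sections.}
#'   \item{`pits_5ms`}{mildly centre-biased exocytic pits
#'     (`Beta(1, 1.55)` fractional area; pooled 2D median ~0.4), 40-nm
#'     sections, `stim_5ms`.}
#'   \item{`pits_11ms`}{strongly centre-biased pits (`Beta(1, 13.5)`;
#'     pooled 2D median ~0.13), `stim_11ms`.}
#'   \item{`docked`}{uniform docked vesicles along the AZ at 1.9 per
#'     profile, no receptors.}
#' }
#' The pit Beta shapes are numerical calibrations of the forward model
#' (placement + random sectioning) to the stated pooled medians, not
#' constants taken from any measurement.
#'
#' @param name preset name.
#' @param nSynapses number of synapses.
#' @param seed master seed.
#' @param ... overrides passed to [generatorConfig()].
#' @return a `"GeneratorConfig"`.
#' @export
presetConfig <- function(name = c("AMPA_like", "NMDA_like", "pits_5ms",
                                  "pits_11ms", "docked"),
                         nSynapses = 100L, seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    AMPA_like = list(
      thicknessNm = 20, particlesPerSynapse = 32,
      receptorPlacement = placementModel("clustered", betaA = 2.5,
                                         nClusters = 2L,
                                         clusterSigmaNm = 18,
                                         clusterMinSize = 4L,
                                         clusterMinSepNm = 120),
      label = "AMPA"),
    NMDA_like = list(
      thicknessNm = 20, particlesPerSynapse = 20,
      receptorPlacement = placementModel("clustered", betaB = 4,
                                         nClusters = 1L,
                                         clusterSigmaNm = 30,
                                         clusterMinSize = 4L),
      label = "NMDA"),
    pits_5ms = list(
      thicknessNm = 40, particlesPerSynapse = 0,
      pitPlacement = placementModel("center_biased", betaB = 1.55),
      condition = "stim_5ms", label = "control"),
    pits_11ms = list(
      thicknessNm = 40, particlesPerSynapse = 0,
      pitPlacement = placementModel("center_biased", betaB = 13.5),
      condition = "stim_11ms", label = "control"),
    docked = list(
      thicknessNm = 40, particlesPerSynapse = 0,
      pitRatePerProfile = 0, label = "control"))
  args <- utils::modifyList(c(base, list(nSynapses = nSynapses,
                                         seed = seed)),
                            list(...))
  do.call(generatorConfig, args)
}

#' Generate a synthetic annotation dataset with ground truth
#'
#' Composes the placement, labeling and random-sectioning models: for
#' each synapse, receptors are placed on the PSD disc, gold labeling and
#' background are applied, docked vesicles (uniform on the AZ) and
#' exocytic pits (per their placement model) are placed at the configured
#' per-profile rates, and the whole synapse is sliced at a random
#' orientation into fixed-thickness profiles.
#'
#' @param config a [generatorConfig()] or [presetConfig()].
#' @return list with `dataset` (a [GoldDataset-class]) and `truth`, a
#'   per-synapse sidecar list recording the placement law, true receptor
#'   positions and cluster assignments, per-receptor kept flags, and
#'   background flags per gold particle.
#' @examples
#' gen <- generateDataset(presetConfig("NMDA_like", nSynapses = 5, seed = 7))
#' gen$dataset
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  n <- config$nSynapses
  out <- list(profiles = list(), truth = list())
  seeds <- splitSeed(config$seed, max(n, 1L))
  R <- config$psdRadiusNm
  allProfiles <- list()
  truth <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("syn%04d", i)
    synProfiles <- withSeed(seeds[i], {
      nExpProf <- ceiling(2 * R / config$thicknessNm)
      nRec <- if (config$particlesPerSynapse > 0)
        stats::rpois(1L, config$particlesPerSynapse) else 0L
      rec <- placeParticlesDisc(nRec, R, config$receptorPlacement)
      lab <- applyGoldLabeling(rec, config$labelingEfficiency,
                               config$backgroundRate * nExpProf, R)
      nPit <- stats::rpois(1L, config$pitRatePerProfile * nExpProf)
      pit <- placeParticlesDisc(nPit, config$azRadiusNm,
                                config$pitPlacement)
      nDock <- stats::rpois(1L, config$dockedRatePerProfile * nExpProf)
      dock <- placeParticlesDisc(nDock, config$azRadiusNm,
                                 placementModel("uniform"))
      # one shared sectioning geometry for all particle kinds
      nSlabs <- ceiling(2 * R / config$thicknessNm)
      slack <- nSlabs * config$thicknessNm - 2 * R
      theta <- stats::runif(1, 0, 2 * pi)
      phase <- if (slack > 0) stats::runif(1, 0, slack) else 0
      list(rec = rec, lab = lab, pit = pit, dock = dock,
           theta = theta, phase = phase)
    })
    syn <- .sliceAll(synProfiles, R, config, sid)
    allProfiles <- c(allProfiles, syn$profiles)
    truth[[sid]] <- list(
      law = config$receptorPlacement$law,
      placement = config$receptorPlacement[c("betaA", "betaB",
                                             "nClusters")],
      receptors = synProfiles$rec,
      trueCentroids = attr(synProfiles$rec, "centroids"),
      trueCluster = attr(synProfiles$rec, "cluster"),
      kept = synProfiles$lab$kept,
      isBackground = synProfiles$lab$isBackground)
  }
  ds <- GoldDataset(allProfiles,
                    provenance = list(
                      generator = "SynGold::generateDataset",
                      seed = config$seed,
                      law = config$receptorPlacement$law,
                      nSynapses = n))
  list(dataset = ds, truth = truth)
}

# Slice every particle kind of one synapse with a shared chord direction
# and slab phase, producing the profile stack.
.sliceAll <- function(sim, R, config, sid) {
  thickness <- config$thicknessNm
  uDir <- c(cos(sim$theta), sin(sim$theta))
  vDir <- c(-sin(sim$theta), cos(sim$theta))
  v0 <- -R - sim$phase
  slabs <- 0:(ceiling(2 * R / thickness) - 1L)
  lo <- v0 + slabs * thickness
  hi <- lo + thickness
  keep <- hi > -R & lo < R
  slabs <- slabs[keep]; lo <- lo[keep]; hi <- hi[keep]
  cEff <- (pmax(lo, -R) + pmin(hi, R)) / 2
  halfChord <- sqrt(pmax(R^2 - cEff^2, 1e-12))
  azHalf <- if (config$azEqualsPsd) halfChord else {
    Ra <- config$azRadiusNm
    cA <- (pmax(lo, -Ra) + pmin(hi, Ra)) / 2
    sqrt(pmax(Ra^2 - cA^2, 1e-12))
  }
  binPts <- function(pts) {
    if (!nrow(pts)) return(list(u = numeric(0), slot = integer(0)))
    u <- as.numeric(pts %*% uDir)
    v <- as.numeric(pts %*% vDir)
    list(u = u, slot = match(floor((v - v0) / thickness), slabs))
  }
  g <- binPts(sim$lab$gold); p <- binPts(sim$pit); d <- binPts(sim$dock)
  profs <- vector("list", length(slabs))
  for (i in seq_along(slabs)) {
    trPsd <- rbind(c(-halfChord[i], 0), c(halfChord[i], 0))
    trAz <- rbind(c(-azHalf[i], 0), c(azHalf[i], 0))
    sel <- function(b) {
      j <- which(!is.na(b$slot) & b$slot == i)
      if (length(j)) cbind(b$u[j], 0) else matrix(numeric(0), 0L, 2L)
    }
    profs[[i]] <- ProfileAnnotation(
      synapseId = sid, sectionIndex = i - 1L,
      sectionThicknessNm = thickness,
      condition = config$condition, label = config$label,
      azTrace = trAz, psdTrace = trPsd,
      dockedVesicles = sel(d), pits = sel(p), gold = sel(g))
  }
  list(profiles = profs)
}
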