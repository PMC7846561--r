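test_that("disc placement follows the fractional-area laws", {
  R <- 150
  # uniform: (r/R)^2 is U(0,1); median 0.5, KS-indistinguishable
  pts <- placeParticlesDisc(1e4, R, placementModel("uniform"), seed = 1)
  u <- rowSums(pts^2) / R^2
  expect_lt(abs(median(u) - 0.5), 0.02)
  expect_gt(suppressWarnings(stats::ks.test(u, "punif"))$p.value, 0.01)

  # centre bias Beta(1, 3): median (r/R)^2 = 1 - 2^(-1/3)
  ptsC <- placeParticlesDisc(1e5, R, placementModel("center_biased",
                                                    betaB = 3), seed = 2)
  expect_lt(abs(median(rowSums(ptsC^2) / R^2) - (1 - 2^(-1 / 3))), 0.01)

  # edge bias Beta(3, 1): median (r/R)^2 = 2^(-1/3)
  ptsE <- placeParticlesDisc(1e5, R, placementModel("edge_biased",
                                                    betaA = 3), seed = 3)
  expect_lt(abs(median(rowSums(ptsE^2) / R^2) - 2^(-1 / 3)), 0.01)

  expect_identical(placeParticlesDisc(0, R, seed = 4),
                   matrix(numeric(0), 0, 2))
  expect_error(placementModel("edge_biased", betaA = 0.5), "betaA > 1")
  expect_error(placementModel("uniform", betaA = -1), "> 0")
})

test_that("clustered placement plants the requested clusters on the disc", {
  m <- placementModel("clustered", nClusters = 2L, clusterSigmaNm = 20,
                      clusterMinSize = 4L)
  pts <- placeParticlesDisc(20, 150, m, seed = 9)
  expect_equal(nrow(pts), 20L)
  expect_true(all(rowSums(pts^2) <= 150^2 + 1e-9))
  cl <- attr(pts, "cluster")
  expect_equal(sort(unique(cl)), 1:2)
  expect_true(all(tabulate(cl) >= 4L))
  cen <- attr(pts, "centroids")
  expect_equal(dim(cen), c(2L, 2L))
})

test_that("random sectioning produces chord traces and consistent geometry", {
  # particle at the disc centre always lands at its profile's trace
  # centre: normalized distance 0
  syn <- sliceSynapse(rbind(c(0, 0)), R = 150, thickness = 40, seed = 3)
  pm <- attr(syn, "pointMap")
  prof <- profiles(syn)[[pm$section[1L] + 1L]]
  d <- normalizedDistance2D(c(pm$x[1L], 0), psdTrace(prof))
  expect_equal(d$normalized, 0)   # u = 0 is every chord's midpoint
  expect_equal(pm$x[1L], 0)

  # R = 150, thickness = 40: at most ceiling(300/40) = 8 profiles
  counts <- vapply(1:50, function(s)
    nProfiles(sliceSynapse(matrix(numeric(0), 0, 2), 150, 40, seed = s)),
    integer(1))
  expect_true(all(counts <= 8L))
  expect_true(all(counts >= 7L))

  # trace lengths follow the chord formula at the slab centres
  syn2 <- sliceSynapse(matrix(numeric(0), 0, 2), 150, 40, seed = 12)
  lens <- vapply(profiles(syn2), function(p)
    SynGold:::.polylineLength(psdTrace(p)), numeric(1))
  expect_true(all(lens <= 300 + 1e-9))
  expect_lt(sum(lens * 40) / (pi * 150^2), 1.15)
  expect_gt(sum(lens * 40) / (pi * 150^2), 0.85)
})

test_that("pooled 2D normalized distances from sliced uniform synapses are uniform", {
  # Monte-Carlo oracle for the forward model: within a slab, uniform
  # disc points are uniform along the chord, so |u|/L ~ U(0,1)
  set.seed(21)
  vals <- unlist(lapply(1:150, function(i) {
    pts <- placeParticlesDisc(30, 150, placementModel("uniform"))
    syn <- sliceSynapse(pts, 150, 40)
    unlist(lapply(profiles(syn), function(p) {
      if (!nrow(gold(p))) return(NULL)
      normalizedDistance2D(gold(p), psdTrace(p))$normalized
    }))
  }))
  expect_gt(length(vals), 1000)
  expect_lt(abs(median(vals) - 0.5), 0.03)
})

test_that("gold labeling keeps receptors binomially and adds background", {
  rec <- placeParticlesDisc(10000, 150, seed = 31)
  lab <- applyGoldLabeling(rec, efficiency = 1, backgroundRate = 0,
                           seed = 1)
  expect_identical(lab$gold, rec)

  lab0 <- applyGoldLabeling(rec, efficiency = 0, backgroundRate = 5,
                            R = 150, seed = 2)
  expect_true(all(lab0$isBackground))
  expect_true(all(rowSums(lab0$gold^2) >= 150^2))

  labH <- applyGoldLabeling(rec, efficiency = 0.5, backgroundRate = 0,
                            seed = 3)
  # binomial 99% CI around 5000
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(sum(labH$kept), ci[1L])
  expect_lte(sum(labH$kept), ci[2L])
  expect_error(applyGoldLabeling(rec, efficiency = 1.2), "0, 1")
})

test_that("generateDataset is deterministic and respects configured rates", {
  expect_equal(nProfiles(generateDataset(
    generatorConfig(nSynapses = 0L, seed = 1))$dataset), 0L)

  cfg <- presetConfig("AMPA_like", nSynapses = 5, seed = 42)
  g1 <- generateDataset(cfg)
  g2 <- generateDataset(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeAnnotations(g1$dataset, f1); writeAnnotations(g2$dataset, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  expect_identical(g1$truth, g2$truth)

  # "docked" preset: mean docked per profile within 3 SE of 1.9
  gd <- generateDataset(presetConfig("docked", nSynapses = 70, seed = 5))
  nd <- vapply(profiles(gd$dataset), function(p)
    nrow(dockedVesicles(p)), integer(1))
  expect_gt(length(nd), 450)
  se <- sqrt(1.9 / length(nd))
  expect_lt(abs(mean(nd) - 1.9), 3 * se)
})

test_that("forward model recovers the planted placement bias", {
  med <- function(preset, n, seed) {
    gen <- generateDataset(presetConfig(preset, nSynapses = n,
                                        seed = seed))
    d <- do.call(rbind, lapply(profiles(gen$dataset), function(p) {
      if (!nrow(pits(p))) return(NULL)
      normalizedDistance2D(pits(p), azTrace(p))
    }))
    median(d$normalized)
  }
  m5 <- med("pits_5ms", 300, 8)
  m11 <- med("pits_11ms", 300, 9)
  expect_lt(m5, 0.5)          # centre-biased
  expect_lt(m11, m5)          # 11 ms pits are far more central
  expect_lt(abs(m5 - 0.4), 0.05)
  expect_lt(abs(m11 - 0.13), 0.04)

  # uniform receptors come out unbiased, edge-biased come out high
  genU <- generateDataset(generatorConfig(
    nSynapses = 150, particlesPerSynapse = 10, labelingEfficiency = 1,
    backgroundRate = 0, pitRatePerProfile = 0,
    dockedRatePerProfile = 0, seed = 10))
  dU <- do.call(rbind, lapply(profiles(genU$dataset), function(p) {
    if (!nrow(gold(p))) return(NULL)
    normalizedDistance2D(gold(p), psdTrace(p))
  }))
  expect_lt(abs(median(dU$normalized) - 0.5), 0.03)

  genE <- generateDataset(generatorConfig(
    nSynapses = 120, particlesPerSynapse = 10, labelingEfficiency = 1,
    backgroundRate = 0, pitRatePerProfile = 0,
    dockedRatePerProfile = 0,
    receptorPlacement = placementModel("edge_biased", betaA = 3),
    seed = 11))
  dE <- do.call(rbind, lapply(profiles(genE$dataset), function(p) {
    if (!nrow(gold(p))) return(NULL)
    normalizedDistance2D(gold(p), psdTrace(p))
  }))
  expect_gt(median(dE$normalized), 0.55)
})

test_that("generated datasets pass annotation validation and carry truth", {
  gen <- generateDataset(presetConfig("NMDA_like", nSynapses = 6,
                                      seed = 13))
  expect_true(validObject(gen$dataset))
  expect_equal(length(gen$truth), 6L)
  t1 <- gen$truth[[1L]]
  expect_equal(t1$law, "clustered")
  expect_equal(length(t1$kept), nrow(t1$receptors))
  # observed gold = kept receptors + background
  nGold <- sum(vapply(profiles(gen$dataset), function(p)
    nrow(gold(p)), integer(1)))
  nKeptBg <- sum(vapply(gen$truth, function(t)
    sum(t$kept) + sum(t$isBackground), numeric(1)))
  expect_lte(nGold, nKeptBg)  # rim background can fall outside all slabs
  expect_gte(nGold, sum(vapply(gen$truth, function(t) sum(t$kept),
                               numeric(1))))
})
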