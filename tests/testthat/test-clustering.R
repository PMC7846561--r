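test_that("Lloyd k-means handles the textbook cases", {
  X <- matrix(5, 6, 3)
  expect_equal(kmeansLloyd(X, 3, seed = 1)$ssd, 0)

  # unit square, k = 2: optimum pairs opposite edges, SSD = 4 * 0.5^2
  sq <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(kmeansLloyd(sq, 2, nInit = 10, seed = 2)$ssd, 1.0)

  fitN <- kmeansLloyd(sq, 4, seed = 3)
  expect_equal(fitN$ssd, 0)
  expect_equal(sort(fitN$assignments), 1:4)

  expect_error(kmeansLloyd(sq, 5, seed = 1), "1 <= k")
  expect_error(kmeansLloyd(sq, 0, seed = 1), "1 <= k")
})

test_that("Lloyd matches the exhaustive-partition optimum on small instances", {
  set.seed(101)
  misses <- 0L
  for (i in 1:200) {
    n <- sample(4:8, 1)
    k <- sample(1:3, 1)
    k <- min(k, n)
    # half the instances have planted structure, half are uniform
    X <- if (i %% 2 == 0) {
      matrix(rnorm(n * 3, sd = 30), n, 3)
    } else {
      centers <- matrix(rnorm(k * 3, sd = 80), k, 3)
      centers[sample(k, n, replace = TRUE), ] + matrix(rnorm(n * 3, sd = 10),
                                                       n, 3)
    }
    got <- kmeansLloyd(X, k, nInit = 30, seed = i)$ssd
    want <- bruteForceSsd(X, k)
    if (!isTRUE(all.equal(got, want, tolerance = 1e-8))) misses <- misses + 1L
  }
  expect_equal(misses, 0L)
})

test_that("SSD curves are monotone with SSD(N) = 0", {
  expect_equal(ssdCurveMatrix(matrix(c(1, 2, 3), 1, 3)), 0)

  # two tight, well-separated blobs
  set.seed(5)
  blobs <- rbind(matrix(rnorm(15, sd = 2), 5, 3),
                 matrix(rnorm(15, 200, sd = 2), 5, 3))
  cv <- ssdCurveMatrix(blobs, seed = 6)
  expect_gt(cv[1L], 100 * cv[2L])
  expect_equal(cv[length(cv)], 0)
  expect_true(all(diff(cv) <= 1e-9))

  # uniform points drop much more gently from k=1 to k=2
  unif <- matrix(runif(30, 0, 200), 10, 3)
  cu <- ssdCurveMatrix(unif, seed = 7)
  expect_gt(cu[2L] / cu[1L], cv[2L] / cv[1L])
  expect_true(all(diff(cu) <= 1e-9))

  # generic random instances stay monotone (property check)
  for (i in 1:20) {
    Xi <- matrix(rnorm(3 * sample(3:12, 1)), ncol = 3)
    expect_true(all(diff(ssdCurveMatrix(Xi, seed = i)) <= 1e-9))
  }
})

test_that("knee point maximizes normalized distance to the chord", {
  expect_equal(kneePoint(c(100, 10, 8, 6, 5)), 2L)
  expect_equal(kneePoint(c(40, 30, 20, 10)), 1L)   # linear: tie -> low
  expect_equal(kneePoint(0), 1L)
  expect_equal(kneePoint(c(7, 7)), 1L)
  expect_equal(kneePoint(c(5, 4, 0, 0, 0)), 3L)
  expect_error(kneePoint(numeric(0)), "empty")
})

test_that("randomized null maps are uniform over the PSD surface", {
  profs <- lapply(0:2, function(i)
    makeProfile("w", i, halfWidth = c(50, 150, 100)[i + 1],
                gold = if (i == 1L) matrix(0, 3, 2) else NULL))
  syn <- SynapseReconstruction(profs)
  maps <- randomizeWithinPsd(syn, nMaps = 40, seed = 9)
  expect_length(maps, 40L)
  expect_true(all(vapply(maps, nrow, integer(1)) == 3L))
  expect_identical(randomizeWithinPsd(syn, nMaps = 40, seed = 9), maps)

  # per-slice counts proportional to trace length x thickness
  big <- randomizeWithinPsd(syn, nMaps = 1, seed = 10, n = 10000)[[1L]]
  secOf <- big[, "z"] / 40
  obs <- tabulate(secOf + 1L, nbins = 3L)
  expect_gt(stats::chisq.test(obs, p = c(100, 300, 200) / 600)$p.value,
            0.01)
  # z at slice centres, x within each slice's trace
  expect_true(all(big[secOf == 0, "x"] >= -50 & big[secOf == 0, "x"] <= 50))
})

test_that("cluster analysis recovers planted structure and beats its null", {
  # two well-separated planted clusters, sliced and reconstructed:
  # recovered in >= 80% of replicates
  rec2 <- vapply(1:40, function(i) {
    set.seed(900 + i)
    pts <- placeParticlesDisc(16, 150,
      placementModel("clustered", nClusters = 2L, clusterSigmaNm = 15,
                     clusterMinSize = 6L, clusterMinSepNm = 140))
    syn <- sliceSynapse(pts, 150, 20)
    res <- clusterAnalysis(syn, nMaps = 0L, seed = i)
    expect_true(all(diff(res@ssdCurve) <= 1e-9))
    expect_equal(sum(res@clusterSizes), res@n)
    res@kOpt
  }, integer(1))
  expect_gte(mean(rec2 == 2L), 0.8)

  # a single tight blob selects k = 1 and beats its uniform null
  set.seed(12)
  blob <- list(makeProfile("blob", 0L,
                           gold = matrix(rnorm(16, sd = 3), 8, 2)))
  resB <- clusterAnalysis(SynapseReconstruction(blob), nMaps = 10L,
                          seed = 3)
  expect_equal(resB@kOpt, 1L)
  # tight data clusters beat uniform re-placements
  expect_lt(resB@ssdAtKopt, resB@randomizedMeanSsd)

  # N < 4 skips knee selection
  tiny <- makeStack(goldPerSection = list("1" = matrix(rnorm(6, sd = 40),
                                                       3, 2)))
  expect_equal(clusterAnalysis(tiny, nMaps = 0L, seed = 1)@kOpt, 1L)

  # no gold: empty result
  expect_equal(clusterAnalysis(makeStack(), nMaps = 0L, seed = 1)@n, 0L)
})

test_that("SSD-vs-size regression matches closed-form least squares", {
  cohort <- data.frame(synapse_id = letters[1:5], n = 5L,
                       area_um2 = c(0.02, 0.04, 0.06, 0.08, 0.10),
                       ssd = 2 * c(0.02, 0.04, 0.06, 0.08, 0.10),
                       randomized_mean_ssd = c(5, 3, 8, 2, 7))
  fit <- suppressWarnings(regressSsdVsSize(cohort))  # exact fit warns
  expect_equal(fit$slope[1L], 2)
  expect_equal(fit$r_squared[1L], 1)

  # hand-computed OLS for the randomized series
  x <- cohort$area_um2; y <- cohort$randomized_mean_ssd
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope[2L], beta)
  expect_equal(fit$intercept[2L], mean(y) - beta * mean(x))

  # independent response: R^2 near zero over many synapses
  set.seed(30)
  big <- data.frame(synapse_id = as.character(1:100), n = 5L,
                    area_um2 = runif(100), ssd = rnorm(100),
                    randomized_mean_ssd = rnorm(100))
  expect_lt(regressSsdVsSize(big)$r_squared[1L], 0.08)

  expect_error(regressSsdVsSize(cohort[1:2, ]), "at least 3")
  same <- cohort; same$area_um2 <- 0.05
  expect_error(regressSsdVsSize(same), "degenerate")
})

test_that("cohort tables summarize cluster results", {
  gen <- generateDataset(presetConfig("NMDA_like", nSynapses = 3,
                                      seed = 77))
  recs <- reconstructSynapses(gen$dataset)
  results <- lapply(seq_along(recs), function(i)
    clusterAnalysis(recs[[i]], nMaps = 5L, seed = i))
  areas <- lapply(recs, function(s) synapseGeometry3D(s)$areaUm2)
  tab <- clusterCohort(results, areas = areas)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$randomized_mean_ssd[tab$n > 0] >= 0))
  expect_true(all(tab$area_um2 > 0))
})
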