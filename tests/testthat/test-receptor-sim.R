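test_that("glutamate transient conserves mass and peaks at r^2/(4D)", {
  p <- glutamateParams(tauClearMs = Inf)
  # integrate C * h over the plane at two times: total molecules
  for (t in c(0.05, 0.5)) {
    r <- seq(0, 5000, by = 2)                 # nm
    conc <- glutamateConc(r, t, p)            # uM
    dens <- conc * SynGold:::AVOGADRO_UM3 * p$cleftHeightNm / 1000
    total <- sum(dens * 2 * pi * (r / 1000) * (2 / 1000))
    expect_equal(total, p$nGlu, tolerance = 1e-3)
  }

  # C(0, t) decreases monotonically
  ts <- seq(0.001, 5, by = 0.001)
  expect_true(all(diff(glutamateConc(0, ts, p)) < 0))

  # dense-grid peak time at 100 nm matches t* = r^2/(4D)
  c100 <- glutamateConc(100, ts, p)
  expect_equal(ts[which.max(c100)], 0.1^2 / (4 * p$D), tolerance = 0.05)
  expect_error(glutamateConc(100, 0), "> 0")
})

test_that("EPSP template honors its knots and support", {
  expect_equal(epspTemplate(4), 25)
  expect_equal(epspTemplate(8), 25 * 2 / 3)
  expect_equal(epspTemplate(c(0, 15, 20, -3)), c(0, 0, 0, 0))
  tt <- seq(0, 15, by = 0.001)
  v <- epspTemplate(tt)
  expect_equal(max(v), 25)              # no overshoot above the peak knot
  expect_lt(abs(tt[which.max(v)] - 4), 0.01)
  expect_lt(epspTemplate(10), 2.5)      # almost back to rest by 10 ms
  expect_true(all(v >= 0))
})

test_that("voltage traces follow the protocol", {
  tt <- seq(0, 30, by = 0.01)
  sc0 <- Scenario(voltageMode = "clamped_rest")
  expect_equal(unique(voltageTrace(sc0, tt)), -70)
  sc45 <- Scenario(voltageMode = "clamped_depol", deltaMv = 45)
  expect_equal(unique(voltageTrace(sc45, tt)), -25)

  ev2 <- data.frame(t_ms = c(1, 6),
                    site = c("AMPA_cluster", "NMDA_cluster"))
  v2 <- voltageTrace(Scenario(ev2, voltageMode = "epsp_coupled"), tt)
  ev1 <- data.frame(t_ms = 1, site = "AMPA_cluster")
  v1 <- voltageTrace(Scenario(ev1, voltageMode = "epsp_coupled"), tt)
  expect_gt(max(v2), max(v1))           # summation...
  expect_lte(max(v2), -70 + 45)         # ...capped at +45 above rest
  expect_equal(max(v1), -70 + 25)

  noEv <- Scenario(voltageMode = "epsp_coupled")
  expect_equal(unique(voltageTrace(noEv, tt)), -70)
})

test_that("Mg block rates follow the Woodhull sign convention", {
  p <- mgBlockParams()
  r0 <- mgRates(0, p)
  expect_equal(r0$kBlock, p$kBlock0 * p$mgMM)
  expect_equal(r0$kUnblock, p$kUnblock0)

  vs <- seq(-70, 0, by = 1)
  r <- mgRates(vs, p)
  blocked <- r$kBlock / (r$kBlock + r$kUnblock)
  expect_true(all(diff(blocked) < 0))   # relief with depolarization
  expect_true(all(diff(r$kBlock) < 0))
  expect_true(all(diff(r$kUnblock) > 0))

  # scalar arithmetic oracle at the two working potentials
  expect_equal(mgRates(-70, p)$kBlock, 1 * exp(70 / 17))
  expect_equal(mgRates(-25, p)$kUnblock, 3 * exp(-25 / 20))
  expect_equal(mgRates(-70, mgBlockParams(mgMM = 0))$kBlock, 0)
})

test_that("mean-field integration conserves occupancy and hits equilibria", {
  # no glutamate: everything stays in the resting state
  sch <- ampaScheme()
  res0 <- integrateMeanfield(sch, function(t) rep(0, length(t)),
                             function(t) rep(-70, length(t)),
                             durationMs = 5, dtMs = 0.001)
  expect_equal(unname(res0$occupancy[nrow(res0$occupancy), "C0"]), 1)
  expect_equal(res0$openAuc, 0)
  expect_lt(res0$maxDrift, 1e-6)

  # two-state open/closed scheme under saturating ligand: the
  # closed-form equilibrium beta'/(alpha + beta')
  two <- kineticScheme(states = c("C", "O"),
                       transitions = data.frame(
                         from = c("C", "O"), to = c("O", "C"),
                         type = c("glu", "const"), rate = c(0.002, 1),
                         slope = 1),
                       open = "O", initial = "C")
  resEq <- integrateMeanfield(two, function(t) rep(5000, length(t)),
                              function(t) rep(-70, length(t)),
                              durationMs = 10, dtMs = 0.001)
  expect_equal(unname(resEq$occupancy[nrow(resEq$occupancy), "O"]),
               10 / 11, tolerance = 1e-6)

  # step-then-zero ligand: open fraction decays at the closing rate
  pulse <- function(t) ifelse(t < 2, 5000, 0)
  resDec <- integrateMeanfield(two, pulse,
                               function(t) rep(-70, length(t)),
                               durationMs = 8, dtMs = 0.001,
                               saveEveryMs = 0.5)
  o <- resDec$occupancy[, "O"]
  late <- resDec$time > 3
  lambda <- -coef(lm(log(o[late]) ~ resDec$time[late]))[[2]]
  expect_equal(lambda, 1, tolerance = 0.01)

  expect_error(integrateMeanfield(two, function(t) rep(0, length(t)),
                                  function(t) rep(-70, length(t)),
                                  durationMs = 1, dtMs = 0.1),
               "dtMs")
})

test_that("scenario simulation responds to release location and Mg block", {
  # no events: nothing opens
  quiet <- simulateScenario(Scenario(durationMs = 10))
  expect_equal(max(quiet@open), 0)
  expect_equal(unname(quiet@auc), c(0, 0))

  # a release at the AMPA cluster drives AMPA far above Mg-blocked NMDA
  sc <- Scenario(data.frame(t_ms = 1, site = "AMPA_cluster"),
                 voltageMode = "clamped_rest", durationMs = 30)
  r <- simulateScenario(sc)
  expect_gt(r@peak[["AMPA"]], 10 * r@peak[["NMDA"]])
  expect_true(all(r@open >= 0))
  expect_true(all(r@open[, "AMPA"] <= 20 + 1e-9))

  # explicit release points: AMPA activation falls with distance
  peaks <- vapply(c(0, 50, 100, 200), function(d) {
    sce <- Scenario(data.frame(t_ms = 1, site = "point", x = -50 + d,
                               y = 0),
                    voltageMode = "clamped_rest", durationMs = 25)
    simulateScenario(sce)@peak[["AMPA"]]
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))

  # paired same-site releases 9 ms apart: desensitization depresses
  # the second AMPA response
  sc2 <- Scenario(data.frame(t_ms = c(1, 10),
                             site = c("AMPA_cluster", "AMPA_cluster")),
                  voltageMode = "clamped_rest", durationMs = 40)
  tr <- openTrace(simulateScenario(sc2))
  p1 <- max(tr$AMPA[tr$t_ms < 10])
  p2 <- max(tr$AMPA[tr$t_ms >= 10])
  expect_lt(p2, p1)
})

test_that("stochastic trials agree with the mean field within 3 SE", {
  sc <- Scenario(data.frame(t_ms = c(1, 6),
                            site = c("AMPA_cluster", "NMDA_cluster")),
                 voltageMode = "epsp_coupled", durationMs = 40,
                 dtUs = 2, trials = 48L, seed = 11)
  mf <- simulateScenario(sc)
  st <- simulateScenario(sc, mode = "stochastic")
  for (k in c("AMPA", "NMDA")) {
    se <- stats::sd(st@trialAuc[[k]]) / sqrt(length(st@trialAuc[[k]]))
    expect_lt(abs(mf@auc[[k]] - mean(st@trialAuc[[k]])), 3 * se + 1e-6)
    # open counts are integers within the cluster size
    expect_true(all(st@trialTraces[[k]] >= 0))
    expect_true(all(st@trialTraces[[k]] <=
                      clusterGeometry()$counts[[k]]))
  }
  # same seed reproduces the stochastic run exactly
  st2 <- simulateScenario(sc, mode = "stochastic")
  expect_identical(st@trialAuc, st2@trialAuc)
})

test_that("scenario grid emits the full pattern/delay/mode crossing", {
  g <- scenarioGrid(delays = c(0, 5), patterns = c("A-N", "N-N"),
                    modes = c("clamped_rest", "mg_free"),
                    durationMs = 20, dtUs = 5)
  expect_equal(nrow(g), 2 * 2 * 2 * 2)   # x2 receptor kinds
  expect_setequal(unique(g$voltage_mode), c("clamped_rest", "mg_free"))
  expect_true(all(g$auc >= 0))
  # without Mg the same scenarios open far more NMDA receptors
  n_rest <- g$auc[g$kind == "NMDA" & g$voltage_mode == "clamped_rest"]
  n_free <- g$auc[g$kind == "NMDA" & g$voltage_mode == "mg_free"]
  expect_true(all(n_free > n_rest))
})
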