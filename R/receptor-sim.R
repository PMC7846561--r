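# Desk-scale receptor activation simulator: closed-form glutamate
# transient in the cleft, AMPA/NMDA kinetic schemes with
# voltage-dependent Mg block, EPSP waveform coupling, and the scenario
# grid over release patterns, delays and voltage protocols.

V_REST <- -70      # mV
EPSP_CAP <- 45     # mV above rest, the two-release depolarization level
AVOGADRO_UM3 <- 602.2140857  # molecules per um^3 at 1 uM

#' Glutamate transient parameters
#'
#' @param nGlu glutamate molecules per vesicle fusion (default 2000).
#' @param cleftHeightNm synaptic cleft height (nm, default 20).
#' @param D lateral diffusion coefficient (um^2/ms, default 0.3).
#' @param tauClearMs first-order clearance time constant standing in for
#'   astrocytic/neuropil transporter uptake (ms, default 1). `Inf`
#'   disables clearance (mass is then conserved in the cleft slab).
#' @return object of class `"GlutamateParams"`.
#' @export
glutamateParams <- function(nGlu = 2000, cleftHeightNm = 20, D = 0.3,
                            tauClearMs = 1) {
  if (any(c(nGlu, cleftHeightNm, D, tauClearMs) <= 0))
    stop("all glutamate parameters must be positive")
  structure(list(nGlu = nGlu, cleftHeightNm = cleftHeightNm, D = D,
                 tauClearMs = tauClearMs), class = "GlutamateParams")
}

#' Glutamate concentration after a single release
#'
#' Closed-form 2D point-source diffusion in the cleft slab with
#' first-order clearance:
#' `C(r, t) = nGlu / (h * 4 * pi * D * t) * exp(-r^2 / (4 D t)) *
#' exp(-t / tau)`, converted to micromolar. At `tauClearMs = Inf` the
#' lateral integral of `C * h` equals `nGlu` at all times (mass
#' conservation); the peak at lateral distance r occurs at
#' `t* = r^2 / (4 D)`.
#'
#' @param rNm lateral distance from the release site (nm).
#' @param tMs time since release (ms, > 0; evaluate from 1e-3 ms — the
#'   integrator's first sample — rather than 0).
#' @param p a [glutamateParams()].
#' @return concentration in uM, vectorized over `rNm`/`tMs`.
#' @examples
#' glutamateConc(100, 0.01, glutamateParams())
#' @export
glutamateConc <- function(rNm, tMs, p = glutamateParams()) {
  if (any(tMs <= 0)) stop("tMs must be > 0 (evaluate from 1e-3 ms)")
  rUm <- rNm / 1000
  hUm <- p$cleftHeightNm / 1000
  dens <- p$nGlu / (4 * pi * p$D * tMs) * exp(-rUm^2 / (4 * p$D * tMs))
  dens / hUm / AVOGADRO_UM3 * exp(-tMs / p$tauClearMs)
}

#' Single-release EPSP voltage template
#'
#' Monotone piecewise-cubic interpolant (Fritsch–Carlson) through the
#' knots (0, 0), (4, 25), (8, 50/3), (10, 2), (15, 0) ms/mV: the
#' depolarization peaks at exactly +25 mV, has declined to exactly 2/3
#' of the peak at 8 ms, is almost back to rest by 10 ms, and is 0
#' outside \[0, 15\] ms.
#'
#' @param tMs time since the release event (ms), vectorized.
#' @return depolarization above rest (mV).
#' @examples
#' epspTemplate(c(4, 8))   # 25, 16.67
#' @export
epspTemplate <- function(tMs) {
  out <- numeric(length(tMs))
  # rising limb: cubic smoothstep from (0, 0) to the (4, 25) peak with
  # zero slope at both ends (monotone, no overshoot)
  up <- tMs > 0 & tMs < 4
  s <- tMs[up] / 4
  out[up] <- 25 * (3 * s^2 - 2 * s^3)
  # falling limb: Fritsch-Carlson monotone cubic through the stated
  # knots, so the 8-ms value is exactly 2/3 of the peak
  down <- tMs >= 4 & tMs < 15
  if (any(down)) {
    f <- stats::splinefun(c(4, 8, 10, 15), c(25, 50 / 3, 2, 0),
                          method = "monoH.FC")
    out[down] <- f(tMs[down])
  }
  out
}

#' Membrane voltage trace for a scenario
#'
#' `"clamped_rest"` holds -70 mV; `"clamped_depol"` holds
#' -70 + `deltaMv`; `"epsp_coupled"` adds one [epspTemplate()] per
#' release event, summed linearly and capped at -70 + 45 mV (the
#' two-release depolarization level).
#'
#' @param scenario a [Scenario-class].
#' @param tMs time grid (ms).
#' @return voltage in mV at each time.
#' @export
voltageTrace <- function(scenario, tMs) {
  stopifnot(is(scenario, "Scenario"))
  switch(scenario@voltageMode,
    clamped_rest = rep(V_REST, length(tMs)),
    clamped_depol = rep(V_REST + scenario@deltaMv, length(tMs)),
    epsp_coupled = {
      dv <- numeric(length(tMs))
      for (te in scenario@events$t_ms) dv <- dv + epspTemplate(tMs - te)
      V_REST + pmin(dv, EPSP_CAP)
    })
}

#' Voltage-dependent magnesium block parameters
#'
#' Woodhull-style exponential voltage dependence: the block rate falls
#' and the unblock rate rises e-fold per `vBlockSlope` / `vUnblockSlope`
#' millivolts of depolarization.
#'
#' @param mgMM extracellular Mg concentration (mM, default 1; 0 for
#'   Mg-free conditions).
#' @param kBlock0 block rate at 0 mV per mM Mg (1/ms/mM).
#' @param kUnblock0 unblock rate at 0 mV (1/ms).
#' @param vBlockSlope,vUnblockSlope e-fold voltage slopes (mV, > 0).
#' @return object of class `"MgBlockParams"`.
#' @export
mgBlockParams <- function(mgMM = 1, kBlock0 = 1, kUnblock0 = 3,
                          vBlockSlope = 17, vUnblockSlope = 20) {
  if (mgMM < 0) stop("mgMM must be >= 0")
  if (any(c(kBlock0, kUnblock0, vBlockSlope, vUnblockSlope) <= 0))
    stop("rates and slopes must be positive")
  structure(list(mgMM = mgMM, kBlock0 = kBlock0, kUnblock0 = kUnblock0,
                 vBlockSlope = vBlockSlope,
                 vUnblockSlope = vUnblockSlope),
            class = "MgBlockParams")
}

#' Magnesium block/unblock rates at a membrane potential
#'
#' @param vMv membrane potential (mV), vectorized.
#' @param p a [mgBlockParams()].
#' @return list with `kBlock` and `kUnblock` (1/ms). The equilibrium
#'   blocked fraction `kBlock / (kBlock + kUnblock)` is strictly
#'   decreasing in voltage.
#' @examples
#' mgRates(c(-70, -25, 0), mgBlockParams())
#' @export
mgRates <- function(vMv, p = mgBlockParams()) {
  list(kBlock = p$kBlock0 * p$mgMM * exp(-vMv / p$vBlockSlope),
       kUnblock = p$kUnblock0 * exp(vMv / p$vUnblockSlope))
}

#' Receptor kinetic scheme
#'
#' A named-state Markov scheme with transition rate laws that are
#' constant (`"const"`, 1/ms), proportional to glutamate concentration
#' (`"glu"`, 1/ms/uM), or voltage-dependent Mg block/unblock
#' (`"mg_block"`, `"mg_unblock"`: `rate * exp(-V/slope)` and
#' `rate * exp(V/slope)`).
#'
#' @param states character vector of state names.
#' @param transitions data.frame with columns `from`, `to`, `type`,
#'   `rate`, `slope` (slope used only by the Mg types).
#' @param open name of the conducting state.
#' @param initial name of the resting state.
#' @return object of class `"KineticScheme"`.
#' @seealso [ampaScheme()], [nmdaScheme()]
#' @export
kineticScheme <- function(states, transitions, open, initial) {
  stopifnot(all(c("from", "to", "type", "rate") %in% names(transitions)))
  if (!"slope" %in% names(transitions)) transitions$slope <- 1
  if (!all(transitions$from %in% states) ||
      !all(transitions$to %in% states))
    stop("transition endpoints must be named states")
  if (any(transitions$rate < 0)) stop("rates must be >= 0")
  if (!all(transitions$type %in% c("const", "glu", "mg_block",
                                   "mg_unblock")))
    stop("unknown rate-law type")
  if (!open %in% states || !initial %in% states)
    stop("open and initial must be named states")
  structure(list(states = states, transitions = transitions,
                 open = open, initial = initial),
            class = "KineticScheme")
}

#' AMPA receptor kinetic scheme
#'
#' Two sequential glutamate binding steps, fast gating, and a slowly
#' recovering desensitized state entered from the doubly bound closed
#' state. The default rates are representative values chosen so that
#' deactivation is fast (a few ms), desensitization recovery is slow
#' (tens of ms, so paired releases less than ~15 ms apart depress the
#' second response), and a release 100 nm away activates the cluster
#' substantially less than a release directly above it.
#'
#' @param kon binding rate per site (1/ms/uM).
#' @param koff unbinding rate per site (1/ms).
#' @param beta,alpha opening and closing rates (1/ms).
#' @param kDes desensitization rate from the doubly bound state (1/ms).
#' @param kRec recovery rate from desensitization (1/ms).
#' @return a [kineticScheme()] with states C0, C1, C2, O, D.
#' @export
ampaScheme <- function(kon = 0.009, koff = 4, beta = 10, alpha = 4,
                       kDes = 1.2, kRec = 0.02) {
  kineticScheme(
    states = c("C0", "C1", "C2", "O", "D"),
    transitions = data.frame(
      from = c("C0", "C1", "C1", "C2", "C2", "O", "C2", "D"),
      to   = c("C1", "C0", "C2", "C1", "O", "C2", "D", "C2"),
      type = c("glu", "const", "glu", "const", "const", "const",
               "const", "const"),
      rate = c(2 * kon, koff, kon, 2 * koff, beta, alpha, kDes, kRec),
      slope = 1),
    open = "O", initial = "C0")
}

#' NMDA receptor kinetic scheme with Mg block
#'
#' Two glutamate binding steps with slow unbinding (bound dwell on the
#' order of tens of milliseconds, so receptors stay bound across the
#' EPSP time course), slow gating, a desensitized state entered from
#' the doubly bound state at a ligand-proportional rate (so strong
#' direct exposures desensitize more than weak distant ones), and a
#' voltage-dependent Mg-blocked state reachable only from the open state
#' (non-trapping: unblock returns to open). A receptor therefore fluxes
#' only when glutamate is bound at a time when the Mg block is relieved.
#'
#' @param kon binding rate per site (1/ms/uM).
#' @param koff unbinding rate per site (1/ms).
#' @param beta,alpha opening and closing rates (1/ms).
#' @param kDesGlu ligand-proportional desensitization rate from the
#'   doubly bound state (1/ms/uM).
#' @param kRec recovery rate from desensitization (1/ms).
#' @param mg a [mgBlockParams()]; `mgMM = 0` removes the block.
#' @param trapping if `TRUE`, glutamate may unbind while blocked
#'   (blocked decays to the resting state at `koff`); default `FALSE`.
#' @return a [kineticScheme()] with states C0, C1, C2, O, D, B.
#' @export
nmdaScheme <- function(kon = 0.012, koff = 0.06, beta = 0.08,
                       alpha = 0.2, kDesGlu = 0.003, kRec = 0.02,
                       mg = mgBlockParams(), trapping = FALSE) {
  tr <- data.frame(
    from = c("C0", "C1", "C1", "C2", "C2", "O", "C2", "D", "O", "B"),
    to   = c("C1", "C0", "C2", "C1", "O", "C2", "D", "C2", "B", "O"),
    type = c("glu", "const", "glu", "const", "const", "const", "glu",
             "const", "mg_block", "mg_unblock"),
    rate = c(2 * kon, koff, kon, 2 * koff, beta, alpha, kDesGlu, kRec,
             mg$kBlock0 * mg$mgMM, mg$kUnblock0),
    slope = c(1, 1, 1, 1, 1, 1, 1, 1, mg$vBlockSlope, mg$vUnblockSlope))
  if (trapping)
    tr <- rbind(tr, data.frame(from = "B", to = "C0", type = "const",
                               rate = 2 * koff, slope = 1))
  kineticScheme(states = c("C0", "C1", "C2", "O", "D", "B"),
                transitions = tr, open = "O", initial = "C0")
}

#' Default receptor schemes for a simulation
#'
#' @param mgMM extracellular Mg (mM); 0 gives the Mg-free condition.
#' @return list with elements `AMPA` and `NMDA`.
#' @export
receptorSchemes <- function(mgMM = 1) {
  list(AMPA = ampaScheme(), NMDA = nmdaScheme(mg = mgBlockParams(mgMM)))
}

.compileScheme <- function(scheme) {
  idx <- function(s) match(s, scheme$states) - 1L
  typeCode <- c(const = 0L, glu = 1L, mg_block = 2L, mg_unblock = 3L)
  list(n = length(scheme$states),
       from = idx(scheme$transitions$from),
       to = idx(scheme$transitions$to),
       type = unname(typeCode[scheme$transitions$type]),
       rate = scheme$transitions$rate,
       slope = scheme$transitions$slope,
       open = idx(scheme$open),
       initial = idx(scheme$initial))
}

#' Mean-field integration of a kinetic scheme
#'
#' Integrates the master equation of a [kineticScheme()] with
#' time-varying glutamate and voltage inputs by classic fourth-order
#' Runge-Kutta on a fixed grid, starting with all receptors in the
#' resting state. Occupancies are renormalized every step (drift below
#' 1e-6 per step) and instability aborts with advice to reduce `dtMs`.
#'
#' @param scheme a [kineticScheme()].
#' @param concFn function of time (ms) returning glutamate (uM).
#' @param voltFn function of time (ms) returning voltage (mV).
#' @param durationMs integration window (ms).
#' @param dtMs time step (ms, <= 0.01 = 10 us).
#' @param saveEveryMs saved-trace resolution (ms).
#' @return list with `time` (ms), `occupancy` (saved matrix, one column
#'   per state), `openAuc` (time-integral of open occupancy, full
#'   resolution), `openPeak`, `openPeakTime`, `maxDrift`.
#' @export
integrateMeanfield <- function(scheme, concFn, voltFn, durationMs = 250,
                               dtMs = 0.001, saveEveryMs = 0.05) {
  stopifnot(inherits(scheme, "KineticScheme"))
  if (dtMs > 0.01) stop("dtMs must be <= 0.01 ms (10 us)")
  cs <- .compileScheme(scheme)
  nSteps <- max(1L, round(durationMs / dtMs))
  tHalf <- seq(0, by = dtMs / 2, length.out = 2L * nSteps + 1L)
  conc <- concFn(tHalf)
  volt <- voltFn(tHalf)
  stopifnot(length(conc) == length(tHalf), length(volt) == length(tHalf))
  p0 <- numeric(cs$n); p0[cs$initial + 1L] <- 1
  saveEvery <- max(1L, round(saveEveryMs / dtMs))
  res <- .meanfield_rk4(p0, cs$from, cs$to, cs$type, cs$rate, cs$slope,
                        conc, volt, dtMs, cs$open, saveEvery)
  occ <- res$occupancy
  colnames(occ) <- scheme$states
  list(time = res$time, occupancy = occ, openAuc = res$auc,
       openPeak = res$peak, openPeakTime = res$peakTime,
       maxDrift = res$maxDrift)
}

#' Receptor cluster geometry on the PSD
#'
#' Deterministic cluster placement: one AMPA and one NMDA cluster on the
#' PSD disc, 100 nm centroid-to-centroid by default, with ~20 AMPA and
#' ~15 NMDA receptors.
#'
#' @param interClusterNm centroid-to-centroid distance (nm).
#' @param counts named counts per cluster.
#' @param psdRadiusNm PSD disc radius (nm), used for random release
#'   sites.
#' @return object of class `"ClusterGeometry"` with cluster positions
#'   symmetric about the origin.
#' @export
clusterGeometry <- function(interClusterNm = 100,
                            counts = c(AMPA = 20L, NMDA = 15L),
                            psdRadiusNm = 150) {
  structure(list(AMPA = c(-interClusterNm / 2, 0),
                 NMDA = c(interClusterNm / 2, 0),
                 counts = counts, psdRadiusNm = psdRadiusNm),
            class = "ClusterGeometry")
}

# Resolve event sites to coordinates (nm). Random sites are uniform
# over the PSD disc, drawn from the scenario seed.
.resolveEventSites <- function(scenario, geometry) {
  ev <- scenario@events
  if (!nrow(ev)) return(cbind(x = numeric(0), y = numeric(0)))
  xy <- matrix(NA_real_, nrow(ev), 2L)
  for (i in seq_len(nrow(ev))) {
    xy[i, ] <- switch(ev$site[i],
      AMPA_cluster = geometry$AMPA,
      NMDA_cluster = geometry$NMDA,
      point = c(ev$x[i], ev$y[i]),
      random = withSeed(scenario@seed + i, {
        r <- geometry$psdRadiusNm * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        c(r * cos(th), r * sin(th))
      }))
  }
  colnames(xy) <- c("x", "y")
  xy
}

# Summed glutamate input at a cluster position for all release events.
.concAt <- function(pos, sites, times, tMs, glu) {
  out <- numeric(length(tMs))
  for (i in seq_along(times)) {
    d <- sqrt(sum((pos - sites[i, ])^2))
    dtE <- tMs - times[i]
    act <- dtE > 0
    if (any(act))
      out[act] <- out[act] + glutamateConc(d, pmax(dtE[act], 1e-3), glu)
  }
  out
}

#' Simulate a release/voltage scenario
#'
#' For each receptor kind the glutamate input is the summed transient of
#' all release events evaluated at that cluster's distance from each
#' release site; the membrane voltage follows the scenario's protocol.
#' `"meanfield"` mode integrates occupancy probabilities; `"stochastic"`
#' runs `trials` independent per-receptor Markov chains (fixed-step
#' thinning) and reports their mean.
#'
#' @param scenario a [Scenario-class].
#' @param geometry a [clusterGeometry()].
#' @param schemes list with `AMPA` and `NMDA` [kineticScheme()]s.
#' @param mode `"meanfield"` (default) or `"stochastic"`.
#' @param glu a [glutamateParams()].
#' @param saveEveryMs saved-trace resolution (ms).
#' @return a [SimResult-class].
#' @examples
#' sc <- Scenario(data.frame(t_ms = 1, site = "AMPA_cluster"),
#'                voltageMode = "clamped_rest", durationMs = 30)
#' simulateScenario(sc)
#' @export
simulateScenario <- function(scenario, geometry = clusterGeometry(),
                             schemes = receptorSchemes(),
                             mode = c("meanfield", "stochastic"),
                             glu = glutamateParams(),
                             saveEveryMs = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  sites <- .resolveEventSites(scenario, geometry)
  dtMs <- scenario@dtUs / 1000
  nSteps <- max(1L, round(scenario@durationMs / dtMs))
  tHalf <- seq(0, by = dtMs / 2, length.out = 2L * nSteps + 1L)
  volt <- voltageTrace(scenario, tHalf)
  saveEvery <- max(1L, round(saveEveryMs / dtMs))
  kinds <- names(schemes)
  traces <- list(); aucs <- peaks <- peakTs <- numeric(0)
  trialTraces <- list(); trialAuc <- list()
  timeOut <- NULL
  seeds <- splitSeed(scenario@seed, length(kinds))
  for (j in seq_along(kinds)) {
    kind <- kinds[j]
    count <- geometry$counts[[kind]]
    conc <- .concAt(geometry[[kind]], sites, scenario@events$t_ms,
                    tHalf, glu)
    cs <- .compileScheme(schemes[[kind]])
    if (mode == "meanfield") {
      p0 <- numeric(cs$n); p0[cs$initial + 1L] <- 1
      res <- .meanfield_rk4(p0, cs$from, cs$to, cs$type, cs$rate,
                            cs$slope, conc, volt, dtMs, cs$open,
                            saveEvery)
      timeOut <- res$time
      traces[[kind]] <- res$occupancy[, cs$open + 1L] * count
      aucs[kind] <- res$auc * count
      peaks[kind] <- res$peak * count
      peakTs[kind] <- res$peakTime
    } else {
      res <- withSeed(seeds[j],
        .stochastic_sim(count, scenario@trials, cs$initial, cs$from,
                        cs$to, cs$type, cs$rate, cs$slope, conc, volt,
                        dtMs, cs$open, saveEvery))
      timeOut <- res$time
      mt <- colMeans(res$traces)
      traces[[kind]] <- mt
      aucs[kind] <- mean(res$aucs)
      peaks[kind] <- max(mt)
      peakTs[kind] <- res$time[which.max(mt)]
      trialTraces[[kind]] <- res$traces
      trialAuc[[kind]] <- res$aucs
    }
  }
  open <- do.call(cbind, traces)
  colnames(open) <- kinds
  new("SimResult", timeMs = as.numeric(timeOut), open = open,
      auc = aucs, peak = peaks, peakTimeMs = peakTs,
      trialTraces = trialTraces, trialAuc = trialAuc,
      scenario = scenario)
}

#' Scenario grid over release patterns, delays and voltage modes
#'
#' Runs the full crossing of two-release patterns (`"A-N"`: first
#' release at the AMPA cluster, second at the NMDA cluster; `"N-A"`,
#' `"N-N"`, `"A-A"` analogous), inter-release delays, and voltage
#' protocols (`"mg_free"` is clamped rest with 0 mM Mg). The first
#' release occurs at `firstEventMs`; the second follows after the delay.
#'
#' @param delays inter-release delays (ms).
#' @param patterns subset of `c("A-N", "N-A", "N-N", "A-A")`.
#' @param modes subset of `c("clamped_rest", "clamped_depol30",
#'   "clamped_depol45", "epsp_coupled", "mg_free")`.
#' @param durationMs,dtUs integration window and step.
#' @param firstEventMs time of the first release (ms).
#' @param geometry a [clusterGeometry()].
#' @param glu a [glutamateParams()].
#' @param seed integer seed (only random release sites consume it).
#' @return tidy data.frame: `pattern`, `delay_ms`, `voltage_mode`,
#'   `kind`, `auc`, `peak`, `peak_time_ms`.
#' @export
scenarioGrid <- function(delays = c(0, 5, 8, 10, 20, 50),
                         patterns = c("A-N", "N-A", "N-N", "A-A"),
                         modes = c("clamped_rest", "clamped_depol30",
                                   "clamped_depol45", "epsp_coupled",
                                   "mg_free"),
                         durationMs = 250, dtUs = 1, firstEventMs = 1,
                         geometry = clusterGeometry(),
                         glu = glutamateParams(), seed = 1L) {
  siteOf <- c(A = "AMPA_cluster", N = "NMDA_cluster")
  rows <- list()
  for (mode in modes) {
    schemes <- receptorSchemes(mgMM = if (mode == "mg_free") 0 else 1)
    vm <- switch(mode,
                 clamped_rest = , mg_free = "clamped_rest",
                 clamped_depol30 = , clamped_depol45 = "clamped_depol",
                 epsp_coupled = "epsp_coupled")
    dmv <- switch(mode, clamped_depol30 = 30, clamped_depol45 = 45, 0)
    for (pat in patterns) {
      ab <- strsplit(pat, "-")[[1L]]
      for (d in delays) {
        sc <- Scenario(
          events = data.frame(t_ms = c(firstEventMs, firstEventMs + d),
                              site = unname(siteOf[ab])),
          voltageMode = vm, deltaMv = dmv, durationMs = durationMs,
          dtUs = dtUs, seed = seed)
        res <- simulateScenario(sc, geometry = geometry,
                                schemes = schemes, glu = glu)
        for (kind in colnames(res@open))
          rows[[length(rows) + 1L]] <- data.frame(
            pattern = pat, delay_ms = d, voltage_mode = mode,
            kind = kind, auc = res@auc[[kind]],
            peak = res@peak[[kind]],
            peak_time_ms = res@peakTimeMs[[kind]],
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
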