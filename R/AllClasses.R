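#' @import methods
NULL

.validPointMatrix <- function(x, name, minRows = 0L) {
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 2L)
    return(sprintf("'%s' must be a numeric matrix with 2 columns", name))
  if (nrow(x) < minRows)
    return(sprintf("'%s' must have at least %d rows", name, minRows))
  if (nrow(x) > 0L && !all(is.finite(x)))
    return(sprintf("'%s' contains non-finite coordinates", name))
  TRUE
}

.polylineLength <- function(trace) {
  if (nrow(trace) < 2L) return(0)
  sum(sqrt(rowSums(diff(trace)^2)))
}

.CONDITIONS <- c("rest", "stim_5ms", "stim_11ms")
.LABELS <- c("AMPA", "NMDA", "control")

#' Single-section synaptic annotation
#'
#' One 2D electron-micrograph section's worth of traced structures: the
#' active-zone (AZ) and postsynaptic-density (PSD) membrane polylines and
#' the point annotations lying along them (docked synaptic vesicles,
#' exocytic pits, and immunogold particles), together with condition and
#' receptor-label metadata. Coordinates are Cartesian nanometres with an
#' arbitrary per-profile origin; the section's depth never appears as a
#' stored coordinate but is derived as `sectionIndex * sectionThicknessNm`.
#'
#' @slot synapseId character scalar grouping profiles of one synapse.
#' @slot sectionIndex integer position within the serial stack.
#' @slot sectionThicknessNm positive section thickness in nm (40 for TEM
#'   sections, 20 for block-face slices; any positive value is accepted).
#' @slot condition one of `"rest"`, `"stim_5ms"`, `"stim_11ms"`.
#' @slot label one of `"AMPA"`, `"NMDA"`, `"control"`.
#' @slot azTrace,psdTrace two-column coordinate matrices (nm) with at
#'   least two vertices and positive arc length.
#' @slot dockedVesicles,pits,gold two-column coordinate matrices (nm),
#'   possibly with zero rows.
#' @slot offset length-2 numeric lateral alignment offset (dx, dy) applied
#'   when profiles are stacked into a 3D reconstruction; defaults to (0,0).
#'
#' @seealso [ProfileAnnotation()] for the constructor,
#'   [readAnnotations()] for the on-disk format.
#' @export
setClass("ProfileAnnotation",
  representation(
    synapseId = "character",
    sectionIndex = "integer",
    sectionThicknessNm = "numeric",
    condition = "character",
    label = "character",
    azTrace = "matrix",
    psdTrace = "matrix",
    dockedVesicles = "matrix",
    pits = "matrix",
    gold = "matrix",
    offset = "numeric"
  )
)

setValidity("ProfileAnnotation", function(object) {
  msgs <- character()
  if (length(object@synapseId) != 1L || !nzchar(object@synapseId))
    msgs <- c(msgs, "'synapseId' must be a non-empty string")
  if (length(object@sectionIndex) != 1L || is.na(object@sectionIndex))
    msgs <- c(msgs, "'sectionIndex' must be a single integer")
  if (length(object@sectionThicknessNm) != 1L ||
      !is.finite(object@sectionThicknessNm) || object@sectionThicknessNm <= 0)
    msgs <- c(msgs, "'sectionThicknessNm' must be a single positive number")
  if (!identical(length(object@condition), 1L) ||
      !object@condition %in% .CONDITIONS)
    msgs <- c(msgs, sprintf("'condition' must be one of: %s",
                            paste(.CONDITIONS, collapse = ", ")))
  if (!identical(length(object@label), 1L) || !object@label %in% .LABELS)
    msgs <- c(msgs, sprintf("'label' must be one of: %s",
                            paste(.LABELS, collapse = ", ")))
  for (tr in c("azTrace", "psdTrace")) {
    chk <- .validPointMatrix(slot(object, tr), tr, minRows = 2L)
    if (!isTRUE(chk)) msgs <- c(msgs, chk)
    else if (.polylineLength(slot(object, tr)) <= 0)
      msgs <- c(msgs, sprintf("'%s' must have positive arc length", tr))
  }
  for (pt in c("dockedVesicles", "pits", "gold")) {
    chk <- .validPointMatrix(slot(object, pt), pt)
    if (!isTRUE(chk)) msgs <- c(msgs, chk)
  }
  if (length(object@offset) != 2L || !all(is.finite(object@offset)))
    msgs <- c(msgs, "'offset' must be two finite numbers (dx, dy)")
  if (length(msgs)) msgs else TRUE
})

.asPointMatrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L)
    return(matrix(numeric(0), 0L, 2L))
  if (is.matrix(x)) return(unname(x))
  if (is.numeric(x) && length(x) == 2L) return(matrix(x, 1L, 2L))
  if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
  stop("cannot interpret point coordinates")
}

#' Construct a ProfileAnnotation
#'
#' @param synapseId synapse identifier shared by all sections of a synapse.
#' @param sectionIndex integer section index within the serial stack.
#' @param sectionThicknessNm section thickness in nm (> 0).
#' @param condition stimulation condition (`"rest"`, `"stim_5ms"`,
#'   `"stim_11ms"`).
#' @param label receptor label (`"AMPA"`, `"NMDA"`, `"control"`).
#' @param azTrace,psdTrace polylines as two-column matrices (nm).
#' @param dockedVesicles,pits,gold point sets as two-column matrices (nm);
#'   empty by default.
#' @param offset lateral alignment offset `c(dx, dy)` in nm.
#' @return A validated [ProfileAnnotation-class] object.
#' @examples
#' tr <- rbind(c(-100, 0), c(100, 0))
#' ProfileAnnotation("syn1", 0L, 40, "rest", "AMPA",
#'                   azTrace = tr, psdTrace = tr,
#'                   gold = rbind(c(50, 5)))
#' @export
ProfileAnnotation <- function(synapseId, sectionIndex, sectionThicknessNm,
                              condition, label, azTrace, psdTrace,
                              dockedVesicles = NULL, pits = NULL,
                              gold = NULL, offset = c(0, 0)) {
  new("ProfileAnnotation",
      synapseId = as.character(synapseId),
      sectionIndex = as.integer(sectionIndex),
      sectionThicknessNm = as.numeric(sectionThicknessNm),
      condition = as.character(condition),
      label = as.character(label),
      azTrace = .asPointMatrix(azTrace),
      psdTrace = .asPointMatrix(psdTrace),
      dockedVesicles = .asPointMatrix(dockedVesicles),
      pits = .asPointMatrix(pits),
      gold = .asPointMatrix(gold),
      offset = as.numeric(offset))
}

#' Collection of annotated synaptic profiles
#'
#' A flat collection of [ProfileAnnotation-class] records plus free-form
#' provenance metadata (generator seed and configuration for synthetic
#' data, or the import source for real annotations). The pair
#' (`synapseId`, `sectionIndex`) is unique across the collection.
#'
#' @slot profiles list of [ProfileAnnotation-class] objects.
#' @slot provenance named list of free-form metadata.
#' @seealso [GoldDataset()], [readAnnotations()], [generateDataset()]
#' @export
setClass("GoldDataset",
  representation(profiles = "list", provenance = "list"))

setValidity("GoldDataset", function(object) {
  msgs <- character()
  ok <- vapply(object@profiles, is, logical(1), class2 = "ProfileAnnotation")
  if (!all(ok))
    msgs <- c(msgs, "all elements of 'profiles' must be ProfileAnnotation")
  else if (length(object@profiles)) {
    keys <- vapply(object@profiles, function(p)
      paste(p@synapseId, p@sectionIndex, sep = "\r"), character(1))
    if (anyDuplicated(keys)) {
      d <- keys[duplicated(keys)][1L]
      msgs <- c(msgs, sprintf(
        "duplicate (synapseId, sectionIndex) pair: (%s)",
        gsub("\r", ", ", d)))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GoldDataset
#'
#' @param profiles list of [ProfileAnnotation-class] objects.
#' @param provenance named list of free-form metadata.
#' @return A validated [GoldDataset-class].
#' @export
GoldDataset <- function(profiles = list(), provenance = list()) {
  new("GoldDataset", profiles = unname(profiles),
      provenance = as.list(provenance))
}

#' Serial-section reconstruction of one synapse
#'
#' An ordered stack of profiles sharing a `synapseId`, with contiguous
#' section indices and a common thickness. The middle section anchors all
#' 3D distance measurements: the 3D distance of a particle is computed to
#' the centre of the AZ/PSD trace in the middle section, combining the
#' in-plane offset with `deltaSection * thickness` axially.
#'
#' @slot synapseId character scalar.
#' @slot profiles list of [ProfileAnnotation-class], ascending
#'   `sectionIndex`, contiguous, equal thickness.
#' @slot middleIndex the `sectionIndex` of the median section.
#' @seealso [SynapseReconstruction()], [distance3D()], [clusterAnalysis()]
#' @export
setClass("SynapseReconstruction",
  representation(synapseId = "character", profiles = "list",
                 middleIndex = "integer"))

setValidity("SynapseReconstruction", function(object) {
  msgs <- character()
  if (!length(object@profiles))
    msgs <- c(msgs, "a reconstruction needs at least one profile")
  else {
    ids <- vapply(object@profiles, slot, character(1), name = "synapseId")
    if (!all(ids == object@synapseId))
      msgs <- c(msgs, "all profiles must share the reconstruction synapseId")
    idx <- vapply(object@profiles, slot, integer(1), name = "sectionIndex")
    if (is.unsorted(idx, strictly = TRUE) ||
        !identical(idx, seq.int(idx[1L], length.out = length(idx))))
      msgs <- c(msgs, "section indices must be ascending and contiguous")
    th <- vapply(object@profiles, slot, numeric(1),
                 name = "sectionThicknessNm")
    if (length(unique(th)) != 1L)
      msgs <- c(msgs, "all profiles must have the same section thickness")
    if (!object@middleIndex %in% idx)
      msgs <- c(msgs, "middleIndex must be one of the section indices")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SynapseReconstruction
#'
#' Profiles are sorted by section index; the middle section defaults to
#' the median index.
#'
#' @param profiles list of [ProfileAnnotation-class] sharing one synapse id.
#' @param middleIndex optional explicit middle `sectionIndex`; defaults to
#'   the median section of the stack.
#' @return A validated [SynapseReconstruction-class].
#' @export
SynapseReconstruction <- function(profiles, middleIndex = NULL) {
  if (!length(profiles)) stop("a reconstruction needs at least one profile")
  idx <- vapply(profiles, slot, integer(1), name = "sectionIndex")
  profiles <- profiles[order(idx)]
  idx <- sort(idx)
  if (is.null(middleIndex))
    middleIndex <- idx[ceiling(length(idx) / 2)]
  new("SynapseReconstruction",
      synapseId = profiles[[1L]]@synapseId,
      profiles = unname(profiles),
      middleIndex = as.integer(middleIndex))
}

#' Per-synapse K-means cluster analysis result
#'
#' Output of [clusterAnalysis()]: the within-cluster sum-of-squares (SSD)
#' curve over k = 1..N, the knee-point choice of cluster number, the
#' fitted centroids and assignments at that k, and the mean SSD over
#' randomized null maps in which the same number of particles is placed
#' uniformly over the reconstructed PSD surface.
#'
#' @slot synapseId character scalar.
#' @slot n number of gold particles analysed.
#' @slot kOpt chosen number of clusters.
#' @slot centroids kOpt x 3 matrix (nm).
#' @slot assignments integer cluster label per particle.
#' @slot ssdCurve SSD(k) for k = 1..N (nm^2), non-increasing.
#' @slot ssdAtKopt SSD at the chosen k (nm^2).
#' @slot randomizedMeanSsd mean SSD over null maps, each evaluated at its
#'   own knee-point k (nm^2); `NA` if no null maps were run.
#' @slot clusterSizes particles per cluster; sums to `n`.
#' @export
setClass("ClusterResult",
  representation(synapseId = "character", n = "integer", kOpt = "integer",
                 centroids = "matrix", assignments = "integer",
                 ssdCurve = "numeric", ssdAtKopt = "numeric",
                 randomizedMeanSsd = "numeric", clusterSizes = "integer"))

setValidity("ClusterResult", function(object) {
  msgs <- character()
  if (object@n > 0L) {
    if (length(object@ssdCurve) != object@n)
      msgs <- c(msgs, "ssdCurve must have one entry per k = 1..N")
    if (any(diff(object@ssdCurve) > 1e-8 * max(object@ssdCurve[1L], 1)))
      msgs <- c(msgs, "ssdCurve must be non-increasing")
    if (sum(object@clusterSizes) != object@n)
      msgs <- c(msgs, "clusterSizes must sum to the particle count")
    if (object@kOpt < 1L || object@kOpt > object@n)
      msgs <- c(msgs, "kOpt must lie in 1..N")
  }
  if (length(msgs)) msgs else TRUE
})

#' Release/voltage scenario for the receptor simulator
#'
#' Describes a sequence of single-vesicle glutamate release events on the
#' postsynaptic disc together with the membrane-voltage protocol, the
#' integration window, and the trial structure for the stochastic mode.
#'
#' @slot events data.frame with columns `t_ms` and `site`
#'   (`"AMPA_cluster"`, `"NMDA_cluster"`, `"random"`, or `"point"`) and,
#'   for explicit points, `x`/`y` in nm.
#' @slot voltageMode `"clamped_rest"`, `"clamped_depol"`, or
#'   `"epsp_coupled"`.
#' @slot deltaMv depolarization above rest for `"clamped_depol"` (mV).
#' @slot durationMs integration window (ms).
#' @slot dtUs time step (microseconds).
#' @slot trials number of stochastic trials.
#' @slot seed integer master seed.
#' @seealso [Scenario()], [simulateScenario()]
#' @export
setClass("Scenario",
  representation(events = "data.frame", voltageMode = "character",
                 deltaMv = "numeric", durationMs = "numeric",
                 dtUs = "numeric", trials = "integer", seed = "integer"))

setValidity("Scenario", function(object) {
  msgs <- character()
  ev <- object@events
  if (nrow(ev)) {
    if (!all(c("t_ms", "site") %in% names(ev)))
      msgs <- c(msgs, "events need columns 't_ms' and 'site'")
    else {
      if (any(ev$t_ms < 0 | ev$t_ms >= object@durationMs))
        msgs <- c(msgs, "event times must lie within [0, durationMs)")
      okSite <- ev$site %in% c("AMPA_cluster", "NMDA_cluster", "random",
                               "point")
      if (!all(okSite)) msgs <- c(msgs, "unknown release site")
    }
  }
  if (!object@voltageMode %in% c("clamped_rest", "clamped_depol",
                                 "epsp_coupled"))
    msgs <- c(msgs, "unknown voltage mode")
  if (object@dtUs <= 0 || object@dtUs > 10)
    msgs <- c(msgs, "dtUs must be in (0, 10] microseconds")
  if (object@durationMs <= 0) msgs <- c(msgs, "durationMs must be positive")
  if (object@trials < 1L) msgs <- c(msgs, "trials must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Scenario
#'
#' @param events data.frame with columns `t_ms`, `site` (and `x`, `y` for
#'   `site == "point"`). Use `data.frame(t_ms = numeric(0), site =
#'   character(0))` for a release-free control.
#' @param voltageMode voltage protocol; `"clamped_rest"` holds the
#'   membrane at rest (-70 mV), `"clamped_depol"` at rest + `deltaMv`,
#'   `"epsp_coupled"` adds one EPSP waveform template per release event
#'   (linear summation, capped at rest + 45 mV).
#' @param deltaMv depolarization for `"clamped_depol"`; presets 30 and 45.
#' @param durationMs integration window, default 250 ms.
#' @param dtUs time step in microseconds, default 1.
#' @param trials stochastic trials, default 48.
#' @param seed integer seed for stochastic mode and random release sites.
#' @return A validated [Scenario-class].
#' @examples
#' Scenario(data.frame(t_ms = c(1, 6),
#'                     site = c("AMPA_cluster", "NMDA_cluster")),
#'          voltageMode = "epsp_coupled")
#' @export
Scenario <- function(events = data.frame(t_ms = numeric(0),
                                         site = character(0)),
                     voltageMode = c("clamped_rest", "clamped_depol",
                                     "epsp_coupled"),
                     deltaMv = 0, durationMs = 250, dtUs = 1,
                     trials = 48L, seed = 1L) {
  voltageMode <- match.arg(voltageMode)
  new("Scenario", events = events, voltageMode = voltageMode,
      deltaMv = as.numeric(deltaMv), durationMs = as.numeric(durationMs),
      dtUs = as.numeric(dtUs), trials = as.integer(trials),
      seed = as.integer(seed))
}

#' Receptor simulation result
#'
#' Mean open-receptor-count traces per receptor kind, their time integrals
#' (AUC), peak open counts and peak times, and (in stochastic mode) the
#' per-trial traces.
#'
#' @slot timeMs saved time grid (ms).
#' @slot open matrix of mean open receptor counts, one column per kind.
#' @slot auc named numeric, time-integral of open counts (count * ms),
#'   computed at full step resolution.
#' @slot peak,peakTimeMs named numeric, maximum open count and its time.
#' @slot trialTraces list of per-trial open-count matrices (stochastic
#'   mode only; empty otherwise).
#' @slot trialAuc list of per-trial AUC vectors (stochastic mode only).
#' @slot scenario the [Scenario-class] that was run.
#' @export
setClass("SimResult",
  representation(timeMs = "numeric", open = "matrix", auc = "numeric",
                 peak = "numeric", peakTimeMs = "numeric",
                 trialTraces = "list", trialAuc = "list",
                 scenario = "Scenario"))
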