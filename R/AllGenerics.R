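#' @include AllClasses.R
NULL

#' Accessors for annotation containers
#'
#' Small accessor family for the S4 containers: `profiles()` returns the
#' list of [ProfileAnnotation-class] records, `provenance()` the metadata
#' list, `nProfiles()` the number of records, `synapseId()` the synapse
#' identifier(s), and `azTrace()`, `psdTrace()`, `gold()`, `pits()`,
#' `dockedVesicles()` the coordinate matrices of a single profile.
#'
#' @param x a [GoldDataset-class], [SynapseReconstruction-class], or
#'   [ProfileAnnotation-class] as appropriate.
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("nProfiles", function(x) standardGeneric("nProfiles"))
#' @rdname accessors
#' @export
setGeneric("synapseId", function(x) standardGeneric("synapseId"))
#' @rdname accessors
#' @export
setGeneric("azTrace", function(x) standardGeneric("azTrace"))
#' @rdname accessors
#' @export
setGeneric("psdTrace", function(x) standardGeneric("psdTrace"))
#' @rdname accessors
#' @export
setGeneric("gold", function(x) standardGeneric("gold"))
#' @rdname accessors
#' @export
setGeneric("pits", function(x) standardGeneric("pits"))
#' @rdname accessors
#' @export
setGeneric("dockedVesicles", function(x) standardGeneric("dockedVesicles"))
#' @rdname accessors
#' @export
setGeneric("sectionIndex", function(x) standardGeneric("sectionIndex"))

#' @rdname accessors
#' @export
setMethod("profiles", "GoldDataset", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("profiles", "SynapseReconstruction", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("provenance", "GoldDataset", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("nProfiles", "GoldDataset", function(x) length(x@profiles))
#' @rdname accessors
#' @export
setMethod("nProfiles", "SynapseReconstruction",
          function(x) length(x@profiles))
#' @rdname accessors
#' @export
setMethod("synapseId", "ProfileAnnotation", function(x) x@synapseId)
#' @rdname accessors
#' @export
setMethod("synapseId", "SynapseReconstruction", function(x) x@synapseId)
#' @rdname accessors
#' @export
setMethod("synapseId", "GoldDataset", function(x)
  unique(vapply(x@profiles, slot, character(1), name = "synapseId")))
#' @rdname accessors
#' @export
setMethod("azTrace", "ProfileAnnotation", function(x) x@azTrace)
#' @rdname accessors
#' @export
setMethod("psdTrace", "ProfileAnnotation", function(x) x@psdTrace)
#' @rdname accessors
#' @export
setMethod("gold", "ProfileAnnotation", function(x) x@gold)
#' @rdname accessors
#' @export
setMethod("pits", "ProfileAnnotation", function(x) x@pits)
#' @rdname accessors
#' @export
setMethod("dockedVesicles", "ProfileAnnotation", function(x)
  x@dockedVesicles)
#' @rdname accessors
#' @export
setMethod("sectionIndex", "ProfileAnnotation", function(x) x@sectionIndex)

#' Cluster-result accessors
#'
#' `kOpt()` returns the knee-point number of clusters, `centroids()` the
#' kOpt x 3 centroid matrix, `assignments()` the per-particle cluster
#' labels, and `ssdCurve()` applied to a [ClusterResult-class] the stored
#' SSD(k) curve (applied to a coordinate matrix it computes one, see
#' [ssdCurve()]).
#'
#' @param x a [ClusterResult-class].
#' @name cluster-accessors
NULL

#' @rdname cluster-accessors
#' @export
setGeneric("kOpt", function(x) standardGeneric("kOpt"))
#' @rdname cluster-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname cluster-accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname cluster-accessors
#' @export
setMethod("kOpt", "ClusterResult", function(x) x@kOpt)
#' @rdname cluster-accessors
#' @export
setMethod("centroids", "ClusterResult", function(x) x@centroids)
#' @rdname cluster-accessors
#' @export
setMethod("assignments", "ClusterResult", function(x) x@assignments)

#' @rdname ssdCurve
#' @export
setGeneric("ssdCurve", function(x, ...) standardGeneric("ssdCurve"))

#' Simulation-result accessors
#'
#' `auc()` returns the named vector of open-count time integrals,
#' `openTrace()` a data.frame of the saved mean open-count traces.
#'
#' @param x a [SimResult-class].
#' @name sim-accessors
NULL

#' @rdname sim-accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname sim-accessors
#' @export
setGeneric("openTrace", function(x) standardGeneric("openTrace"))
#' @rdname sim-accessors
#' @export
setMethod("auc", "SimResult", function(x) x@auc)
#' @rdname sim-accessors
#' @export
setMethod("openTrace", "SimResult", function(x)
  data.frame(t_ms = x@timeMs, x@open, check.names = FALSE))

setMethod("show", "ProfileAnnotation", function(object) {
  cat(sprintf(
    "ProfileAnnotation %s section %d (%g nm, %s, %s)\n",
    object@synapseId, object@sectionIndex, object@sectionThicknessNm,
    object@condition, object@label))
  cat(sprintf("  PSD trace: %d vertices, %.0f nm; gold %d, pits %d, docked %d\n",
              nrow(object@psdTrace), .polylineLength(object@psdTrace),
              nrow(object@gold), nrow(object@pits),
              nrow(object@dockedVesicles)))
})

setMethod("show", "GoldDataset", function(object) {
  ids <- synapseId(object)
  cat(sprintf("GoldDataset: %d profiles from %d synapses\n",
              length(object@profiles), length(ids)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "),
        "\n")
})

setMethod("show", "SynapseReconstruction", function(object) {
  idx <- vapply(object@profiles, slot, integer(1), name = "sectionIndex")
  ng <- sum(vapply(object@profiles, function(p) nrow(p@gold), integer(1)))
  cat(sprintf(
    "SynapseReconstruction %s: sections %d..%d (middle %d), %d gold\n",
    object@synapseId, min(idx), max(idx), object@middleIndex, ng))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult %s: N = %d, k_opt = %d, SSD = %.1f nm^2\n",
              object@synapseId, object@n, object@kOpt, object@ssdAtKopt))
  if (is.finite(object@randomizedMeanSsd))
    cat(sprintf("  randomized-null mean SSD = %.1f nm^2\n",
                object@randomizedMeanSsd))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario: %d release event(s), %s, %g ms at %g us\n",
              nrow(object@events), object@voltageMode, object@durationMs,
              object@dtUs))
})

setMethod("show", "SimResult", function(object) {
  cat("SimResult:\n")
  for (k in colnames(object@open))
    cat(sprintf("  %s: peak %.2f open at %.2f ms, AUC %.1f count*ms\n",
                k, object@peak[[k]], object@peakTimeMs[[k]],
                object@auc[[k]]))
})
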