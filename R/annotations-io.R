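# Reading, writing, validation, blinding and flat-table export of
# annotation datasets. JSON is the canonical on-disk format (polylines
# need nesting); CSV export is lossy and one-point-per-row.

.profileToList <- function(p) {
  list(
    synapse_id = p@synapseId,
    section_index = p@sectionIndex,
    section_thickness_nm = p@sectionThicknessNm,
    condition = p@condition,
    label = p@label,
    az_trace = unname(apply(p@azTrace, 1L, c, simplify = FALSE)),
    psd_trace = unname(apply(p@psdTrace, 1L, c, simplify = FALSE)),
    docked_vesicles = unname(apply(p@dockedVesicles, 1L, c,
                                   simplify = FALSE)),
    pits = unname(apply(p@pits, 1L, c, simplify = FALSE)),
    gold = unname(apply(p@gold, 1L, c, simplify = FALSE)),
    offset = p@offset)
}

.profileFromList <- function(rec, where) {
  need <- c("synapse_id", "section_index", "section_thickness_nm",
            "condition", "label", "az_trace", "psd_trace")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop(sprintf("record %s: missing field(s) %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  tryCatch(
    ProfileAnnotation(
      synapseId = rec$synapse_id,
      sectionIndex = rec$section_index,
      sectionThicknessNm = rec$section_thickness_nm,
      condition = rec$condition,
      label = rec$label,
      azTrace = .asPointMatrix(rec$az_trace),
      psdTrace = .asPointMatrix(rec$psd_trace),
      dockedVesicles = .asPointMatrix(rec$docked_vesicles),
      pits = .asPointMatrix(rec$pits),
      gold = .asPointMatrix(rec$gold),
      offset = if (is.null(rec$offset)) c(0, 0) else as.numeric(rec$offset)),
    error = function(e)
      stop(sprintf("record %s (synapse_id %s): %s", where,
                   rec$synapse_id %||% "?", conditionMessage(e)),
           call. = FALSE))
}

#' Read an annotation dataset from JSON
#'
#' Parses and validates the canonical annotation JSON: a top-level object
#' with a `provenance` map and a `profiles` array, each profile carrying
#' the AZ/PSD polylines and the point annotations in nm. Every record is
#' validated (trace geometry, finiteness, enums) and duplicate
#' `(synapse_id, section_index)` pairs are rejected; errors name the
#' offending record.
#'
#' @param path path to a JSON file written by [writeAnnotations()] or
#'   conforming to the same schema.
#' @return A [GoldDataset-class].
#' @seealso [writeAnnotations()], [exportFeatureTable()]
#' @examples
#' tr <- rbind(c(-100, 0), c(100, 0))
#' ds <- GoldDataset(list(ProfileAnnotation("s1", 0L, 40, "rest", "AMPA",
#'                                          tr, tr)))
#' f <- tempfile(fileext = ".json")
#' writeAnnotations(ds, f)
#' nProfiles(readAnnotations(f))
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty annotation file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$profiles))
    stop("not an annotation file (no 'profiles' array): ", path)
  profs <- lapply(seq_along(obj$profiles), function(i)
    .profileFromList(obj$profiles[[i]], where = sprintf("#%d", i)))
  GoldDataset(profiles = profs,
              provenance = as.list(obj$provenance %||% list()))
}

#' Write an annotation dataset to JSON
#'
#' Serializes a [GoldDataset-class] to the canonical JSON schema with
#' 17 significant digits so that `readAnnotations(writeAnnotations(ds))`
#' reproduces every coordinate bit-for-bit.
#'
#' @param ds a validated [GoldDataset-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(ds, path) {
  stopifnot(is(ds, "GoldDataset"))
  validObject(ds)
  for (p in ds@profiles) validObject(p)
  obj <- list(provenance = ds@provenance,
              profiles = lapply(ds@profiles, .profileToList))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "list")
  invisible(path)
}

#' Blind a dataset for scoring
#'
#' Profiles are returned in a seeded random order under opaque synapse
#' ids, emulating the practice of pooling and shuffling micrographs from
#' one experiment before blinded annotation scoring. The key table
#' inverts the id mapping.
#'
#' @param ds a non-empty [GoldDataset-class].
#' @param seed integer; the permutation and id assignment are
#'   reproducible from it.
#' @return A list with elements `dataset` (the blinded
#'   [GoldDataset-class]) and `key` (data.frame with columns `blind_id`,
#'   `original_id`).
#' @export
blindShuffle <- function(ds, seed) {
  stopifnot(is(ds, "GoldDataset"))
  if (!nProfiles(ds)) stop("cannot blind an empty dataset")
  ids <- vapply(ds@profiles, slot, character(1), name = "synapseId")
  uids <- unique(ids)
  withSeed(seed, {
    blind <- sprintf("blind_%04d", sample.int(length(uids)))
    ord <- sample.int(length(ds@profiles))
  })
  names(blind) <- uids
  profs <- lapply(ds@profiles[ord], function(p) {
    p@synapseId <- unname(blind[[p@synapseId]])
    p
  })
  list(dataset = GoldDataset(profs,
                             provenance = c(ds@provenance,
                                            list(blinded = TRUE))),
       key = data.frame(blind_id = unname(blind), original_id = uids,
                        stringsAsFactors = FALSE))
}

#' Flatten a dataset to one row per annotated point
#'
#' @param ds a [GoldDataset-class].
#' @return data.frame with columns `synapse_id`, `section_index`, `kind`
#'   (`"gold"`, `"vesicle"`, `"pit"`), `x`, `y`, `condition`, `label`;
#'   one row per point, zero rows for an empty dataset.
#' @seealso [writeFeatureCSV()]
#' @export
exportFeatureTable <- function(ds) {
  stopifnot(is(ds, "GoldDataset"))
  rows <- lapply(ds@profiles, function(p) {
    kinds <- list(gold = p@gold, vesicle = p@dockedVesicles, pit = p@pits)
    do.call(rbind, lapply(names(kinds), function(k) {
      m <- kinds[[k]]
      if (!nrow(m)) return(NULL)
      data.frame(synapse_id = p@synapseId, section_index = p@sectionIndex,
                 kind = k, x = m[, 1L], y = m[, 2L],
                 condition = p@condition, label = p@label,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(synapse_id = character(0), section_index = integer(0),
                      kind = character(0), x = numeric(0), y = numeric(0),
                      condition = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write the flat feature table as CSV
#'
#' UTF-8, header row, one annotated point per row. Lossy relative to the
#' JSON format (polylines are not representable).
#'
#' @param ds a [GoldDataset-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(ds, path) {
  utils::write.csv(exportFeatureTable(ds), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Group a dataset's profiles into serial-section reconstructions
#'
#' @param ds a [GoldDataset-class] whose profiles of each synapse have
#'   contiguous section indices and a common thickness.
#' @return Named list of [SynapseReconstruction-class], one per synapse.
#' @export
reconstructSynapses <- function(ds) {
  stopifnot(is(ds, "GoldDataset"))
  ids <- vapply(ds@profiles, slot, character(1), name = "synapseId")
  out <- lapply(split(ds@profiles, ids), SynapseReconstruction)
  out[unique(ids)]
}
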