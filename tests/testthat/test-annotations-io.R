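test_that("JSON round trip reproduces every coordinate bit-for-bit", {
  set.seed(1)
  profs <- lapply(1:4, function(i)
    makeProfile(sprintf("syn%d", (i + 1) %/% 2), i %% 2,
                gold = matrix(runif(6, -90, 90), 3, 2),
                pits = matrix(runif(2, -90, 90), 1, 2),
                docked = matrix(runif(4, -90, 90), 2, 2)))
  ds <- GoldDataset(profs, provenance = list(source = "unit-test"))
  f <- tempfile(fileext = ".json")
  writeAnnotations(ds, f)
  ds2 <- readAnnotations(f)
  expect_equal(nProfiles(ds2), 4L)
  for (i in 1:4) {
    expect_identical(gold(profiles(ds2)[[i]]), gold(profiles(ds)[[i]]))
    expect_identical(psdTrace(profiles(ds2)[[i]]),
                     psdTrace(profiles(ds)[[i]]))
  }
  expect_identical(exportFeatureTable(ds2), exportFeatureTable(ds))

  # empty dataset round-trips too
  f2 <- tempfile(fileext = ".json")
  writeAnnotations(GoldDataset(), f2)
  expect_match(paste(readLines(f2), collapse = ""), "\"profiles\":\\s*\\[\\]")
  expect_equal(nProfiles(readAnnotations(f2)), 0L)
})

test_that("readAnnotations validates records and names offenders", {
  # duplicate (synapse_id, section_index)
  ds <- GoldDataset(list(makeProfile("s1", 0L), makeProfile("s1", 1L)))
  f <- tempfile(fileext = ".json")
  writeAnnotations(ds, f)
  txt <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  txt$profiles[[2L]]$section_index <- 0L
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(txt, f2, auto_unbox = TRUE, digits = I(17))
  expect_error(readAnnotations(f2), "duplicate.*s1, 0")

  # hand-written fixture: 3-vertex az trace, 5 gold points
  fixture <- list(provenance = list(), profiles = list(list(
    synapse_id = "sfix", section_index = 2L, section_thickness_nm = 40,
    condition = "stim_5ms", label = "NMDA",
    az_trace = list(c(0, 0), c(60, 0), c(60, 40)),
    psd_trace = list(c(0, 0), c(100, 0)),
    docked_vesicles = list(), pits = list(c(10, 5)),
    gold = list(c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(5, 5)))))
  f3 <- tempfile(fileext = ".json")
  jsonlite::write_json(fixture, f3, auto_unbox = TRUE, digits = I(17))
  ds3 <- readAnnotations(f3)
  p <- profiles(ds3)[[1L]]
  expect_equal(nrow(gold(p)), 5L)
  expect_equal(nrow(azTrace(p)), 3L)
  expect_equal(nrow(pits(p)), 1L)
  expect_equal(p@condition, "stim_5ms")

  # schema violations are rejected with the record named
  bad <- fixture
  bad$profiles[[1L]]$az_trace <- list(c(0, 0))   # single-vertex trace
  f4 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f4, auto_unbox = TRUE, digits = I(17))
  expect_error(readAnnotations(f4), "record #1")

  # empty and missing files
  f5 <- tempfile(); file.create(f5)
  expect_error(readAnnotations(f5), "empty")
  expect_error(readAnnotations(tempfile()), "not found")
})

test_that("invalid annotations cannot be constructed or written", {
  expect_error(makeProfile(gold = matrix(c(NA, 1), 1, 2)), "non-finite")
  expect_error(ProfileAnnotation("s", 0L, 40, "rest", "AMPA",
                                 azTrace = rbind(c(0, 0), c(0, 0)),
                                 psdTrace = straightTrace()),
               "positive arc length")
  expect_error(ProfileAnnotation("s", 0L, -40, "rest", "AMPA",
                                 azTrace = straightTrace(),
                                 psdTrace = straightTrace()),
               "positive")
  expect_error(ProfileAnnotation("s", 0L, 40, "poked", "AMPA",
                                 azTrace = straightTrace(),
                                 psdTrace = straightTrace()),
               "condition")
  expect_error(GoldDataset(list(makeProfile("a", 0L),
                                makeProfile("a", 0L))),
               "duplicate")
})

test_that("blindShuffle is a reproducible bijection with an inverting key", {
  ds <- GoldDataset(lapply(1:5, function(i)
    makeProfile(sprintf("syn%d", i), 0L)))
  b1 <- blindShuffle(ds, seed = 1)
  b2 <- blindShuffle(ds, seed = 1)
  expect_identical(vapply(profiles(b1$dataset), synapseId, character(1)),
                   vapply(profiles(b2$dataset), synapseId, character(1)))
  expect_identical(b1$key, b2$key)

  # key inverts the mapping
  blinded <- vapply(profiles(b1$dataset), synapseId, character(1))
  orig <- b1$key$original_id[match(blinded, b1$key$blind_id)]
  expect_setequal(orig, sprintf("syn%d", 1:5))
  # bijection: 5 distinct opaque ids
  expect_equal(length(unique(b1$key$blind_id)), 5L)

  # different seeds give a different permutation (fixed seeds chosen so)
  b3 <- blindShuffle(ds, seed = 2)
  expect_false(identical(b1$key$blind_id, b3$key$blind_id))
  expect_error(blindShuffle(GoldDataset(), 1), "empty")
})

test_that("feature table has one row per point and correct columns", {
  p1 <- makeProfile("s1", 0L, gold = rbind(c(1, 2), c(3, 4)),
                    pits = rbind(c(5, 6)))
  p2 <- makeProfile("s1", 1L)       # empty -> contributes 0 rows
  tab <- exportFeatureTable(GoldDataset(list(p1, p2)))
  expect_equal(nrow(tab), 3L)
  expect_equal(sort(unique(tab$kind)), c("gold", "pit"))
  expect_equal(names(tab), c("synapse_id", "section_index", "kind",
                             "x", "y", "condition", "label"))
  expect_equal(nrow(exportFeatureTable(GoldDataset())), 0L)

  # mixed dataset: per-kind row counts match per-profile point counts
  gen <- generateDataset(presetConfig("AMPA_like", nSynapses = 4,
                                      seed = 3))
  tab2 <- exportFeatureTable(gen$dataset)
  nGold <- sum(vapply(profiles(gen$dataset),
                      function(p) nrow(gold(p)), integer(1)))
  expect_equal(sum(tab2$kind == "gold"), nGold)

  f <- tempfile(fileext = ".csv")
  writeFeatureCSV(gen$dataset, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(tab2))
})

test_that("reconstructSynapses groups profiles into valid stacks", {
  ds <- GoldDataset(c(lapply(0:2, function(i) makeProfile("a", i)),
                      lapply(0:1, function(i) makeProfile("b", i))))
  recs <- reconstructSynapses(ds)
  expect_named(recs, c("a", "b"))
  expect_equal(nProfiles(recs$a), 3L)
  expect_equal(recs$a@middleIndex, 1L)
  expect_equal(recs$b@middleIndex, 0L)
  # gaps in section indices are rejected
  expect_error(SynapseReconstruction(list(makeProfile("c", 0L),
                                          makeProfile("c", 2L))),
               "contiguous")
})
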