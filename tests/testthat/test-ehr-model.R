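test_that("distinct-date consolidation counts and deduplication follow the coding rules", {
  map <- tinyMap()
  ev <- tinyEvents()
  counts <- consolidatePhecodes(ev, map)

  # two distinct dates of codes mapping to 295.1 -> count 2; the two
  # different 295.x codes on 2001-01-01 collapse to one date
  expect_equal(counts[patientId == "p1" & phecode == "295.1", n], 2L)
  # two vocabularies hitting the same phecode on different dates
  expect_equal(counts[patientId == "p2" & phecode == "296", n], 2L)
  # single instance
  expect_equal(counts[patientId == "p4" & phecode == "295.1", n], 1L)

  # brute-force oracle: count unique (patient, phecode, date) triples
  mp <- as.data.table(map@table)
  joined <- mp[as.data.table(ev), on = c("vocabulary", "code"), nomatch = 0L]
  brute <- unique(joined[, .(patientId, phecode, date)])[
    , .(n = .N), by = .(patientId, phecode)]
  setkey(brute, patientId, phecode)
  expect_equal(as.data.frame(counts), as.data.frame(brute),
               ignore_attr = TRUE)

  # idempotence on an already-deduplicated stream
  expect_equal(as.data.frame(consolidatePhecodes(ev, map)),
               as.data.frame(counts))

  # zero mappable codes
  evBad <- data.table(patientId = "p9", vocabulary = "ICD9",
                      code = "999.99", date = data.table::as.IDate("2001-01-01"))
  c2 <- consolidatePhecodes(evBad, map)
  expect_equal(nrow(c2), 0L)
  expect_equal(attr(c2, "unmapped"), 1L)

  # unknown vocabulary rejected
  evUnk <- data.table(patientId = "p1", vocabulary = "SNOMED",
                      code = "1", date = data.table::as.IDate("2001-01-01"))
  expect_error(consolidatePhecodes(evUnk, map), "vocabulary")
  expect_error(PhecodeMap(data.frame(vocabulary = character(),
                                     code = character(),
                                     phecode = character())), "empty")
})

test_that("vocabulary independence: same code string in different vocabularies maps separately", {
  tab <- data.frame(vocabulary = c("ICD9", "ICD10"),
                    code = c("100", "100"),
                    phecode = c("A", "B"), stringsAsFactors = FALSE)
  map <- PhecodeMap(tab)
  ev <- data.table(patientId = "p1",
                   vocabulary = c("ICD9", "ICD10"),
                   code = "100",
                   date = data.table::as.IDate(c("2001-01-01", "2001-01-02")))
  counts <- consolidatePhecodes(ev, map)
  expect_equal(counts[phecode == "A", n], 1L)
  expect_equal(counts[phecode == "B", n], 1L)
})

test_that("status assignment implements case >= 2, single missing, exclusion removal", {
  map <- tinyMap()
  # p1: 295.1 x2 -> case; p3: 297 once -> missing for 297, and 297 occurrence
  # excludes p3 from 296 controls; p4: 295.1 once -> missing
  pe <- phecodeExperiment(tinyEvents(), tinyDemographics(), map)
  st <- statusMatrix(pe)
  expect_equal(st["295.1", "p1"], 1L)
  expect_equal(st["295.1", "p4"], NA_integer_)
  expect_equal(st["296", "p2"], 1L)
  expect_equal(st["296", "p3"], NA_integer_)     # exclusion-range removal
  expect_equal(st["296", "p1"], 0L)              # untouched control
  expect_equal(st["297", "p3"], NA_integer_)     # single instance

  # exclusion removal never demotes a case: give p3 two 296 dates too
  ev2 <- rbind(tinyEvents(), data.table(
    patientId = "p3", vocabulary = "ICD9", code = "296.00",
    date = data.table::as.IDate(c("2003-02-01", "2003-03-01"))))
  st2 <- statusMatrix(phecodeExperiment(ev2, tinyDemographics(), map))
  expect_equal(st2["296", "p3"], 1L)

  # partition property: every cell is exactly one of case/control/missing
  expect_true(all(st %in% c(0L, 1L, NA_integer_)))
})

test_that("adding a code event never demotes status for the mapped phecode", {
  map <- tinyMap()
  ev <- tinyEvents()
  rank <- function(s) ifelse(is.na(s), 1L, ifelse(s == 0L, 0L, 2L))
  base <- statusMatrix(phecodeExperiment(ev, tinyDemographics(), map))
  extra <- data.table(patientId = c("p4", "p3"),
                      vocabulary = "ICD9",
                      code = c("295.00", "297.00"),
                      date = data.table::as.IDate(c("2004-05-01", "2003-06-01")))
  for (i in seq_len(nrow(extra))) {
    ev2 <- rbind(ev, extra[i])
    st2 <- statusMatrix(phecodeExperiment(ev2, tinyDemographics(), map))
    ph <- map@table$phecode[match(extra$code[i], map@table$code)]
    expect_gte(rank(st2[ph, extra$patientId[i]]),
               rank(base[ph, extra$patientId[i]]))
  }
})

test_that("demographic covariates follow the burden and record-length conventions", {
  map <- tinyMap()
  pe <- phecodeExperiment(tinyEvents(), tinyDemographics(), map)
  cd <- as.data.frame(SummarizedExperiment::colData(pe))
  # p1 has {295.1: 2} -> 1 unique phecode (only one phecode with >= 1)
  expect_equal(cd["p1", "uniquePhecodeCount"], 1L)
  # p4 has a single-instance phecode -> still counts toward burden
  expect_equal(cd["p4", "uniquePhecodeCount"], 1L)
  expect_equal(cd["p4", "logUniquePhecodes"], log(2))
  # p1: events 2001-01-01 .. 2001-02-01 -> 31 days
  expect_equal(cd["p1", "recordLength"], 31L)
  # single visit date -> 0
  expect_equal(cd["p3", "recordLength"], 0L)
  # zero-phecode patient: ln(0 + 1) = 0
  dm5 <- rbind(tinyDemographics(),
               data.table(patient_id = "p5", current_age = 20, ehr_age = 20,
                          sex = "male", race = "White"))
  pe5 <- phecodeExperiment(tinyEvents(), dm5, map)
  cd5 <- as.data.frame(SummarizedExperiment::colData(pe5))
  expect_equal(cd5["p5", "logUniquePhecodes"], 0)
  expect_equal(cd5["p5", "recordLength"], 0L)
  # brute-force unique-count oracle on counts
  counts <- consolidatePhecodes(tinyEvents(), map)
  brute <- counts[, .(u = sum(n >= 1)), by = patientId]
  expect_equal(cd[brute$patientId, "uniquePhecodeCount"], brute$u)
})

test_that("patients with events but no demographics are excluded with a message", {
  map <- tinyMap()
  dm <- tinyDemographics(c("p1", "p2", "p3"))  # p4 missing
  expect_message(pe <- phecodeExperiment(tinyEvents(), dm, map), regexp = NA)
  expect_false("p4" %in% colnames(pe))
})

test_that("exclusion ranges expand numerically against the map universe", {
  tab <- data.frame(vocabulary = "ICD9",
                    code = sprintf("c%d", 1:5),
                    phecode = c("295.1", "295.2", "296", "300", "300.5"),
                    stringsAsFactors = FALSE)
  map <- PhecodeMap(tab, excludeRanges = c("295.1" = "295-296.99",
                                           "300" = "300-300.2, 296-296.5"))
  expect_setequal(phecodeExclusions(map, "295.1"),
                  c("295.1", "295.2", "296"))
  expect_setequal(phecodeExclusions(map, "300"), c("300", "296"))
  expect_equal(phecodeExclusions(map, "296"), character())
  expect_error(PhecodeMap(tab, excludeRanges = c("295.1" = "295-xx")),
               "malformed")
})

test_that("file readers round-trip the external formats and validate schemas", {
  dir <- withr::local_tempdir()
  ev <- tinyEvents()
  evOut <- ev[, .(patient_id = patientId, vocabulary, code,
                  date = as.character(date))]
  fwrite(evOut, file.path(dir, "ev.tsv"), sep = "\t")
  back <- readCodeEvents(file.path(dir, "ev.tsv"))
  expect_equal(as.data.frame(back[order(patientId, code, date)]),
               as.data.frame(unique(ev)[order(patientId, code, date)]))

  dm <- tinyDemographics()
  fwrite(dm, file.path(dir, "dm.tsv"), sep = "\t")
  dmBack <- readDemographics(file.path(dir, "dm.tsv"))
  expect_equal(dmBack$patientId, dm$patient_id)

  # malformed date fails with the offending row
  bad <- copy(evOut)[2, date := "01/02/2001"]
  fwrite(bad, file.path(dir, "bad.tsv"), sep = "\t")
  expect_error(readCodeEvents(file.path(dir, "bad.tsv")), "row 2")

  # ehr_age > current_age rejected
  dmBad <- copy(dm)[1, ehr_age := 99]
  fwrite(dmBad, file.path(dir, "dmbad.tsv"), sep = "\t")
  expect_error(readDemographics(file.path(dir, "dmbad.tsv")), "ehr_age")

  # phecode map CSV dialect round-trip, including the exclusion range
  map <- tinyMap()
  writePhecodeMap(map, file.path(dir, "map.csv"))
  mapBack <- readPhecodeMap(file.path(dir, "map.csv"))
  expect_setequal(phecodeUniverse(mapBack), phecodeUniverse(map))
  expect_setequal(phecodeExclusions(mapBack, "296"),
                  phecodeExclusions(map, "296"))
})
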