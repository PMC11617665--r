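test_that("parsing builds records, logs rejects and fails on empty input", {
  lib <- compound_library(c("a", "b", "c"), c("CCO", "c1ccccc1", "CCN"))
  expect_s3_class(lib, "curated_library")
  expect_equal(nrow(lib$records), 3L)

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = paste0("m", 1:5),
                       smiles = c("CCO", "C1CC", "c1ccccc1", "CC(=O)O", "CCCC"),
                       activity_um = c(1, 2, 3, 4, 5)), f, row.names = FALSE)
  lib <- parse_library(f, "csv")
  expect_equal(nrow(lib$records), 4L)
  expect_equal(lib$rejected$id, "m2")
  expect_equal(lib$report$n_records[lib$report$step == "input"], 5L)

  f2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol-one", "c1ccccc1 mol two"), f2)
  lib2 <- parse_library(f2, "smiles")
  expect_equal(lib2$records$id, c("mol-one", "mol two"))

  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "x", smiles = "notasmiles("), f3, row.names = FALSE)
  expect_error(parse_library(f3, "csv"), "no parsable")
  expect_error(parse_library("/nonexistent/file.csv", "csv"), "not found")
})

test_that("SDF entries without an id get one assigned", {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(eth = "CCO", benz = "c1ccccc1")))
  f <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  txt <- readLines(f)
  txt[1] <- "first_mol"
  # blank the second molecule's title line
  ends <- which(txt == "$$$$")
  txt[ends[1] + 1L] <- ""
  writeLines(txt, f)
  lib <- parse_library(f, "sdf")
  expect_equal(nrow(lib$records), 2L)
  expect_equal(lib$records$id[1], "first_mol")
  expect_match(lib$records$id[2], "^mol[0-9]+$")
})

test_that("molecular-weight window is inclusive and uses the desalted parent", {
  lib <- compound_library(
    c("benzene", "estradiol", "salt"),
    c("c1ccccc1", "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O", "CC(=O)[O-].[Na+]"))
  # estradiol C18H24O2 with standard average atomic weights
  expect_equal(lib$records$mw[2], 272.388, tolerance = 1e-3)
  # the salt record's MW is that of the neutralized acetic-acid parent
  expect_equal(lib$records$mw[3], 60.052, tolerance = 1e-3)

  flt <- filter_molecular_weight(lib)
  expect_equal(flt$records$id, "estradiol")

  at_bound <- compound_library("b", "c1ccccc1")
  at_bound$records$mw <- 160.0
  expect_equal(nrow(filter_molecular_weight(at_bound)$records), 1L)
  expect_error(filter_molecular_weight(lib, 500, 100), "min_mw")
})

test_that("deduplication collapses canonical keys and keeps the most potent", {
  lib <- compound_library(
    c("k1", "k2", "k3", "k4"),
    c("c1ccccc1", "C1=CC=CC=C1", "CCO", "OCC"),
    activity_um = c(50, 5, NA, NA))
  dd <- deduplicate(lib)
  expect_equal(nrow(dd$records), 2L)
  # kekulized and aromatic benzene are one molecule; 5 uM wins over 50 uM
  expect_equal(dd$records$activity_value[dd$records$id == "k2"], 5)
  # both ethanol spellings collapse; first by input order kept when no activity
  expect_true("k3" %in% dd$records$id)

  distinct <- compound_library(c("a", "b"), c("CCO", "CCN"))
  expect_equal(deduplicate(distinct)$records$id, c("a", "b"))
})

test_that("activity filter is strict-greater-than and exempts unannotated drugs", {
  lib <- compound_library(c("at", "over", "drug"), c("CCO", "CCN", "CCC"),
                          activity_um = c(100, 150, NA))
  fl <- filter_activity(lib)
  expect_setequal(fl$records$id, c("at", "drug"))
  expect_error(filter_activity(lib, -1), "non-negative")
})

test_that("curation is idempotent, order-stable and report counts chain", {
  df <- gen_library(n_scaffolds = 3, decorations_per_scaffold = 4,
                    duplicate_fraction = 0.25, mw_violation_fraction = 0.25,
                    high_activity_fraction = 0.25, seed = 9)
  lib <- compound_library(df$id, df$smiles, df$activity_um,
                          df$activity_type, df$source_class)
  cur <- curate_library(lib)
  # idempotence: a second pass changes nothing
  again <- curate_library(cur)
  expect_equal(again$records, cur$records)
  # order stability: survivors appear in input order
  expect_equal(cur$records$id,
               lib$records$id[lib$records$id %in% cur$records$id])
  # counts are non-increasing along the funnel
  expect_true(all(diff(cur$report$n_records[-1]) <= 0))
  expect_equal(tail(cur$report$n_records, 1), nrow(cur$records))
  # every planted violator is gone, every clean compound survives
  truth <- attr(df, "truth")
  expect_setequal(cur$records$id, truth$id[truth$planted == "ok"])
})

test_that("library round-trips through CSV with a JSON report", {
  lib <- curate_library(compound_library(c("a", "b"),
                                         c("CCCCCCCCCCCCCc1ccccc1",
                                           "CCCCCCCCCCCCCCc1ccncc1")))
  f <- withr::local_tempfile(fileext = ".csv")
  rf <- withr::local_tempfile(fileext = ".json")
  write_library(lib, f, rf)
  back <- read.csv(f)
  expect_equal(back$id, lib$records$id)
  rep <- jsonlite::read_json(rf)
  expect_equal(rep$activity_filter, nrow(lib$records))
})
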