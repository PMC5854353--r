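test_that("registry enforces its structural invariants", {
  reg <- load_registry()
  expect_s3_class(reg, "myz_registry")
  expect_false(anyDuplicated(names(reg)) > 0)
  for (ch in reg) {
    if (ch$kind == "ratio") {
      expect_false(is.null(ch$numerator_id))
      expect_false(reg[[ch$numerator_id]]$kind == "ratio")
      expect_false(reg[[ch$denominator_id]]$kind == "ratio")
    }
    if (ch$kind == "categorical") expect_gt(length(ch$allowed_states), 0)
    if (ch$kind == "linear") expect_identical(ch$unit, "mm")
  }
})

test_that("the bundle holds the expected per-morph profile complement", {
  counts <- table(ds$morphs$morph)
  expect_equal(as.integer(counts[c("fundatrix", "aptera", "alata", "ovipara", "male")]),
               c(5L, 10L, 7L, 6L, 6L))
  # the genus tables alone: 5 fundatrices, 9 apterae, 6 alatae, 5 oviparae,
  # 5 males, plus the four morphs of R. canadensis
  not_canadensis <- ds$morphs[ds$morphs$taxon != "canadensis", ]
  expect_equal(as.integer(table(not_canadensis$morph)[c("fundatrix", "aptera", "alata", "ovipara", "male")]),
               c(5L, 9L, 6L, 5L, 5L))
  expect_equal(sum(ds$morphs$taxon == "canadensis"), 4L)
  expect_equal(nrow(ds$morphs), 34L)
})

test_that("query_range returns transcribed values and distinguishes lookup errors", {
  expect_equal(unname(query_range(ds, "oezdemirae", "ovipara", "PSEUDO_TIBIA_III")),
               c(61, 80))
  expect_equal(unname(query_range(ds, "canadensis", "male", "RHIN_ANT_III")),
               c(21, 21))
  expect_identical(query_range(ds, "rosarum", "aptera", "FRONTAL_TUBERCLE"),
                   "quadrate")
  expect_error(query_range(ds, "tuatayae", "alata", "BL"), "no alata profile")
  expect_error(query_range(ds, "nobody", "aptera", "BL"), "unknown taxon")
  expect_error(query_range(ds, "rosarum", "aptera", "NOT_A_CHAR"),
               "unknown character")
  expect_error(query_range(ds, "tianshanica", "aptera", "ANT"), "not recorded")
})

test_that("the curated and as-printed layers differ exactly at the documented corrections", {
  # anomaly corrected in the curated layer
  expect_equal(unname(query_range(ds_printed, "tuatayae", "aptera", "ANT_IV")),
               c(0.08, 1.10))
  expect_equal(unname(query_range(ds, "tuatayae", "aptera", "ANT_IV")),
               c(0.08, 0.10))
  expect_equal(unname(query_range(ds_printed, "bucktoni", "aptera", "GPW")),
               c(0.3, 0.20))
  expect_equal(unname(query_range(ds, "bucktoni", "aptera", "GPW")),
               c(0.13, 0.20))
  # whole-antenna range of the tianshanica apterae is unrecoverable as printed
  expect_equal(unname(query_range(ds_printed, "tianshanica", "aptera", "ANT")),
               c(0.16, 0.18))
  expect_error(query_range(ds, "tianshanica", "aptera", "ANT"), "not recorded")
})

test_that("table-provenance entries keep their verbatim printed string", {
  tab <- ds_printed$profiles[grepl("^T[1-6]$", ds_printed$profiles$provenance), ]
  simple <- grepl("^[0-9.]+(–[0-9.]+)?$", tab$as_printed)
  expect_true(all(simple))
  parts <- strsplit(tab$as_printed, "–")
  lo <- as.numeric(vapply(parts, `[`, "", 1L))
  hi <- as.numeric(vapply(parts, function(p) p[length(p)], ""))
  expect_equal(lo, tab$lo)
  expect_equal(hi, tab$hi)
})

test_that("writer composed with loader is the identity on the bundle", {
  out <- file.path(tempdir(), "bundle_roundtrip")
  unlink(out, recursive = TRUE)
  write_reference(ds, out)
  for (f in names(ds$raw)) {
    orig <- file.path(ds$path, f)
    expect_identical(readBin(file.path(out, f), "raw", file.size(orig)),
                     readBin(orig, "raw", file.size(orig)),
                     info = f)
  }
  ds2 <- load_reference(out)
  expect_equal(ds2$profiles, ds$profiles)
})

test_that("degenerate bundles are rejected wholesale", {
  empty <- file.path(tempdir(), "empty_bundle")
  dir.create(empty, showWarnings = FALSE)
  expect_error(load_reference(empty), "missing file")

  dup <- file.path(tempdir(), "dup_bundle")
  unlink(dup, recursive = TRUE)
  write_reference(ds, dup)
  m <- readLines(file.path(dup, "measurements.csv"))
  writeLines(c(m, m[2]), file.path(dup, "measurements.csv"))
  expect_error(load_reference(dup), "duplicated profile entry")
})

test_that("the audit flags the printed anomalies and passes the curated layer", {
  v <- validate_dataset(ds_printed)
  errs <- v[v$severity == "error", ]
  expect_gte(nrow(errs), 2)
  expect_true(any(errs$taxon == "tuatayae" & errs$character_id == "ANT_IV"))
  expect_true(any(errs$taxon == "bucktoni" & errs$character_id == "GPW"))
  # deterministic ordering
  expect_identical(order(errs$taxon, errs$morph, errs$character_id),
                   seq_len(nrow(errs)))
  expect_equal(nrow(validate_dataset(ds)), 0L)
})

test_that("the audit catches constructed violations", {
  broken <- ds
  i <- which(broken$profiles$character_id == "BL")[1]
  broken$profiles$lo[i] <- 2.0
  broken$profiles$hi[i] <- 1.0
  v <- validate_dataset(broken)
  expect_true(any(v$severity == "error" &
                  v$character_id == "BL" &
                  grepl("inverted", v$message)))
})
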