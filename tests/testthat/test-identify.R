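test_that("midpoint specimens score 1.0 on their own table characters", {
  for (i in seq_len(nrow(ds$morphs))) {
    tx <- ds$morphs$taxon[i]; mo <- ds$morphs$morph[i]
    sp <- midpoint_specimen(ds, tx, mo)
    sc <- score_profile(sp, ds, tx, mo)
    tab <- sc$verdicts[grepl("^T[1-6]$", sc$verdicts$provenance), ]
    expect_true(all(tab$verdict == "in"), info = paste(tx, mo))
    expect_true(tx %in% top_candidates(identify_specimen(sp, ds)),
                info = paste(tx, mo))
  }
})

test_that("a pseudosensoria count of 70 matches only the oezdemirae oviparae", {
  sp <- myz_specimen("ov", "ovipara", counts = c(PSEUDO_TIBIA_III = 70))
  ov_taxa <- intersect(ds$morphs$taxon[ds$morphs$morph == "ovipara"], myzaphis_spp)
  verdicts <- vapply(ov_taxa, function(tx) {
    sc <- score_profile(sp, ds, tx, "ovipara")
    sc$verdicts$verdict[sc$verdicts$character_id == "PSEUDO_TIBIA_III"]
  }, character(1))
  expect_identical(names(verdicts)[verdicts == "in"], "oezdemirae")
})

test_that("a 0.06 mm dorsal abdominal seta separates the long-setae fundatrix", {
  sp <- myz_specimen("fx", "fundatrix", linear = c(SETA_ABD = 0.06))
  fx_taxa <- ds$morphs$taxon[ds$morphs$morph == "fundatrix"]
  verdicts <- vapply(fx_taxa, function(tx) {
    sc <- score_profile(sp, ds, tx, "fundatrix")
    sc$verdicts$verdict[sc$verdicts$character_id == "SETA_ABD"]
  }, character(1))
  expect_identical(unname(verdicts["tianshanica"]), "in")
  # bucktoni, rezwanii and tuatayae print far shorter setae; the rosarum
  # range (0.005-0.065 mm) is printed wide enough to contain 0.06
  expect_true(all(verdicts[c("bucktoni", "rezwanii", "tuatayae")] == "out"))
})

test_that("scoring and identification guard their preconditions", {
  sp <- myz_specimen("x", "aptera", linear = c(BL = 1.5))
  expect_error(score_profile(sp, ds, "rosarum", "ovipara"), "does not match")
  lonely <- myz_specimen("lone", "aptera", states = c(WINGS = "absent"))
  stranger <- myz_specimen("str", "aptera", linear = c(HLS = 0.02))
  expect_error(score_profile(stranger, ds, "rosarum"), "no evaluable")
  id <- identify_specimen(lonely, ds)
  expect_equal(nrow(id$ranking), 0L)   # below min_characters everywhere
  expect_gt(length(id$warnings), 0)
  expect_error(identify_specimen(myz_specimen("n", "nymph"), ds),
               "no profiles for morph 'nymph'")
})

test_that("scores agree with a naive containment oracle", {
  naive_score <- function(sp, ds, tx, mo) {
    sp <- ratio_closure(sp, ds$registry)
    vals <- myzaphid:::specimen_values(sp)
    prof <- ds$profiles[ds$profiles$taxon == tx & ds$profiles$morph == mo, ]
    n_in <- 0L; n_eval <- 0L
    for (i in seq_len(nrow(prof))) {
      id <- prof$character_id[i]
      if (!id %in% names(vals)) next
      n_eval <- n_eval + 1L
      hit <- if (!is.na(prof$state[i])) identical(as.character(vals[[id]]), prof$state[i])
             else { v <- as.numeric(vals[[id]]); v >= prof$lo[i] && v <= prof$hi[i] }
      if (hit) n_in <- n_in + 1L
    }
    if (n_eval == 0L) return(NULL)
    n_in / n_eval
  }
  for (seed in 1:6) {
    tx <- sample(ds$morphs$taxon, 1)
    mo <- ds$morphs$morph[ds$morphs$taxon == tx][1]
    sp <- random_specimen(ds, tx, mo, seed + 100)
    for (other in unique(ds$morphs$taxon[ds$morphs$morph == mo])) {
      expected <- naive_score(sp, ds, other, mo)
      if (is.null(expected)) next
      expect_equal(score_profile(sp, ds, other, mo)$score, expected,
                   info = paste(seed, other, mo))
    }
  }
})

test_that("adding an in-range character never lowers the match count", {
  set.seed(42)
  for (rep in 1:5) {
    tx <- "rosarum"; mo <- "aptera"
    sp <- random_specimen(ds, tx, mo, rep + 200, keep = 0.5)
    base_sc <- score_profile(sp, ds, tx, mo)
    prof <- ds$profiles[ds$profiles$taxon == tx & ds$profiles$morph == mo, ]
    lin <- prof[prof$kind == "linear" &
                !prof$character_id %in% names(sp$linear), ]
    if (!nrow(lin)) next
    j <- sample(nrow(lin), 1)
    sp2 <- sp
    sp2$linear[lin$character_id[j]] <- (lin$lo[j] + lin$hi[j]) / 2
    sp2$ratios <- NULL
    new_sc <- score_profile(sp2, ds, tx, mo)
    expect_gte(sum(new_sc$verdicts$verdict == "in"),
               sum(base_sc$verdicts$verdict == "in"))
    # verdicts of previously evaluated raw characters are unchanged
    shared <- intersect(base_sc$verdicts$character_id, new_sc$verdicts$character_id)
    shared <- setdiff(shared, new_sc$verdicts$character_id[new_sc$verdicts$kind == "ratio"])
    old <- base_sc$verdicts[match(shared, base_sc$verdicts$character_id), "verdict"]
    new <- new_sc$verdicts[match(shared, new_sc$verdicts$character_id), "verdict"]
    expect_identical(old, new)
  }
})

test_that("rankings are sorted by score with alphabetical ties", {
  sp <- midpoint_specimen(ds, "rosarum", "aptera")
  rk <- identify_specimen(sp, ds)$ranking
  expect_true(all(diff(rk$score) <= 0))
  ties <- split(rk$taxon, rk$score)
  for (group in ties) expect_identical(group, sort(group))
})
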