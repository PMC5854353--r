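test_that("the six bundled keys load with the documented terminal complements", {
  expect_setequal(names(keys),
    c("myzaphis_fundatrices", "myzaphis_apterae", "myzaphis_alatae",
      "myzaphis_oviparae", "myzaphis_males", "macrosiphini_genera_222"))
  n_term <- vapply(keys, function(k)
    length(unique(myzaphid:::key_terminals(k))), integer(1))
  expect_equal(n_term[["myzaphis_apterae"]], 8L)
  expect_equal(n_term[["myzaphis_fundatrices"]], 5L)
  expect_equal(n_term[["myzaphis_alatae"]], 6L)
  expect_equal(n_term[["myzaphis_oviparae"]], 5L)
  expect_equal(n_term[["myzaphis_males"]], 5L)
  expect_equal(n_term[["macrosiphini_genera_222"]], 9L)
})

test_that("structural validation rejects malformed keys", {
  k <- keys$myzaphis_oviparae
  cyclic <- k
  cyclic$couplets[["4"]]$a <- list(predicates = cyclic$couplets[["4"]]$a$predicates,
                                   goto = "1")
  expect_error(validate_key(cyclic, ds), "cycle")

  orphan <- k
  orphan$couplets[["99"]] <- orphan$couplets[["4"]]
  expect_error(validate_key(orphan, ds), "unreachable")

  alien <- k
  alien$couplets[["4"]]$a$taxon <- "martian"
  expect_error(validate_key(alien, ds), "not in the taxonomy")

  badchar <- k
  badchar$couplets[["1"]]$a$predicates[[1]]$character <- "NOPE"
  expect_error(validate_key(badchar, ds), "unregistered character")
})

test_that("lead evaluation has three-valued semantics", {
  reg <- ds$registry
  apt3a <- keys$myzaphis_apterae$couplets[["3"]]$a
  long_setae <- myz_specimen("s", "aptera", linear = c(SETA_ABD = 0.07),
                             states = c(DORSAL_SETA_FORM = "long-pointed"))
  expect_identical(evaluate_lead(long_setae, apt3a, reg), "true")

  fx2b <- keys$myzaphis_fundatrices$couplets[["2"]]$b
  # SIPH missing: the SIPH/cauda conjunct is undecidable, nothing is false
  no_siph <- myz_specimen("s", "fundatrix",
                          linear = c(CAUDA = 0.2, PT = 0.09, BASE = 0.09,
                                     URS = 0.08, ANT_V = 0.17))
  expect_identical(evaluate_lead(no_siph, fx2b, reg), "unknown")
  # PT/BASE = 0.5 against "0.88 or more" is decidably false
  low_pt <- myz_specimen("s", "fundatrix", linear = c(PT = 0.04, BASE = 0.08))
  expect_identical(evaluate_lead(low_pt, fx2b, reg), "false")
})

test_that("traversal follows single, both or neither leads deterministically", {
  sp <- midpoint_specimen(ds, "tianshanica", "aptera")
  tr <- traverse(sp, keys$myzaphis_apterae, ds$registry)
  expect_identical(tr$terminals, "tianshanica")
  expect_identical(tr$trace$couplet, c("1", "3"))

  # one secondary rhinarium on ANT III settles the genus key at couplet 1
  rhin <- myz_specimen("r", "aptera", counts = c(RHIN_ANT_III = 3))
  expect_identical(traverse(rhin, keys$macrosiphini_genera_222,
                            ds$registry)$terminals, "Hydaphias")

  # total ignorance returns every terminal, every couplet branched
  blank <- myz_specimen("b", "aptera")
  trb <- traverse(blank, keys$myzaphis_apterae, ds$registry)
  expect_setequal(trb$terminals,
                  c("bucktoni", "juchnevitschae", "oezdemirae", "rezwanii",
                    "rosarum", "tianshanica", "tuatayae", "turanica"))
  expect_true(all(trb$trace$decision == "both"))

  # decidably failing both leads yields an empty terminal set
  neither <- myz_specimen("n", "fundatrix",
                          linear = c(SETA_ABD = 0.5),
                          states = c(DORSAL_SETA_FORM = "short-blunt"))
  trn <- traverse(neither, keys$myzaphis_fundatrices, ds$registry)
  expect_length(trn$terminals, 0)
  expect_match(trn$notes, "no terminal")

  expect_error(traverse(blank, keys$myzaphis_males, ds$registry),
               "does not match key scope")
})

test_that("key audit replays profiles along their own paths", {
  # the tianshanica path through the apterae key holds exactly
  f <- audit_key(keys$myzaphis_apterae, ds)
  expect_false(any(f$taxon == "tianshanica"))

  # the about-expanded fundatrix couplet is only partially met by the
  # rezwanii profile ranges
  f2 <- audit_key(keys$myzaphis_fundatrices, ds)
  expect_true(any(f2$taxon == "rezwanii" & f2$severity == "warning"))

  # as printed, the alate key's last couplet contradicts the bucktoni
  # profile outright
  f3 <- audit_key(keys_printed$myzaphis_alatae, ds_printed)
  expect_true(any(f3$taxon == "bucktoni" & f3$severity == "error" &
                  f3$character_id == "ANT_IV_ANT_III"))
  # curated, the couplet is reconcilable with the profile
  f4 <- audit_key(keys$myzaphis_alatae, ds)
  expect_false(any(f4$taxon == "bucktoni" & f4$severity == "error" &
                   f4$character_id == "ANT_IV_ANT_III"))

  # a lead interval no aphid can satisfy fails for every taxon on its path
  tiny <- keys$myzaphis_oviparae
  tiny$couplets <- list("1" = list(
    a = list(predicates = list(list(character = "BL", op = "in",
                                    lo = 0, hi = 0.01)), taxon = "rosarum"),
    b = list(predicates = list(list(character = "BL", op = "in",
                                    lo = 0, hi = 0.01)), taxon = "turanica")))
  tiny$root <- "1"
  tiny$couplets[["1"]]$a$predicates <-
    lapply(tiny$couplets[["1"]]$a$predicates, myzaphid:::normalize_predicate, 0.05)
  tiny$couplets[["1"]]$b$predicates <-
    lapply(tiny$couplets[["1"]]$b$predicates, myzaphid:::normalize_predicate, 0.05)
  ft <- audit_key(tiny, ds)
  expect_setequal(ft$taxon, c("rosarum", "turanica"))
  expect_true(all(ft$severity == "error"))
})
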