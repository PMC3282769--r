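# Hand-built scaffold: STRT at 52, HCLP at 268, otherwise poly-A background
# (alanine matches no rule pattern, so each trait can be implanted alone).
scaffold <- function(length = 340) {
  chars <- rep("A", length)
  chars[52:55] <- c("S", "T", "R", "T")
  chars[268:271] <- c("H", "C", "L", "P")
  chars
}
as_rec <- function(chars, id = "scaffold")
  seq_record(id, paste(chars, collapse = ""))

test_that("anchor location picks the STRT/HCLP pair at family spacing", {
  rec <- as_rec(scaffold())
  an <- locate_anchors(rec)
  expect_identical(an$strt_start, 52L)
  expect_identical(an$hclp_start, 268L)

  # decoy STRT far upstream: spacing 266 exceeds the family window, the
  # genuine pair at spacing 216 must still be chosen
  chars <- scaffold()
  chars[2:5] <- c("S", "T", "R", "T")
  an2 <- locate_anchors(as_rec(chars))
  expect_identical(an2$strt_start, 52L)

  chars <- scaffold()
  chars[268:271] <- "A"
  an3 <- locate_anchors(as_rec(chars))
  expect_true(is.na(an3$hclp_start))
  expect_identical(classify(as_rec(chars))$verdict, "NOT_TRANSCARBAMYLASE")
})

test_that("lysine-upstream rule reads the residue two before STRT", {
  chars <- scaffold()
  chars[50] <- "Q"
  rec <- as_rec(chars)
  an <- locate_anchors(rec)
  oc <- rule_lysine_upstream(rec, an)
  expect_identical(oc$status, "ptc_like")
  expect_identical(oc$evidence, "Q50")

  chars[50] <- "K"
  oc2 <- rule_lysine_upstream(as_rec(chars), an)
  expect_identical(oc2$status, "otc_like")

  near <- list(strt_start = 2L, hclp_start = 218L)
  expect_identical(rule_lysine_upstream(rec, near)$status, "inapplicable")
})

test_that("230-loop rule separates the PTC loop from the OTC SMG loop", {
  chars <- scaffold()
  chars[227:233] <- strsplit("DVWYGLY", "")[[1]]
  rec <- as_rec(chars)
  an <- locate_anchors(rec)
  oc <- rule_230_loop(rec, an)
  expect_identical(oc$status, "ptc_like")
  expect_identical(oc$evidence, "YGLY@230")

  chars2 <- scaffold()
  chars2[229:232] <- c("V", "S", "M", "G")
  oc2 <- rule_230_loop(as_rec(chars2), an)
  expect_identical(oc2$status, "otc_like")

  oc3 <- rule_230_loop(as_rec(scaffold()), an)
  expect_identical(oc3$status, "absent")

  both <- scaffold()
  both[227:233] <- strsplit("DVWYGLY", "")[[1]]
  both[219:222] <- c("V", "S", "M", "G")
  expect_identical(rule_230_loop(as_rec(both), an)$status, "absent")
})

test_that("C-terminal extension rule applies the tail thresholds", {
  an <- list(strt_start = 52L, hclp_start = 268L)
  expect_identical(
    rule_cterm_extension(as_rec(scaffold(340)), an)$status, "ptc_like")
  expect_identical(
    rule_cterm_extension(as_rec(scaffold(318)), an)$status, "otc_like")
  # tail of 58 sits between the OTC (55) and PTC (60) thresholds
  expect_identical(
    rule_cterm_extension(as_rec(scaffold(329)), an)$status, "absent")
})

test_that("helix-13 rule needs both the signature and helical context", {
  chars <- scaffold()
  chars[330:334] <- c("L", "A", "A", "F", "L")
  rec <- as_rec(chars)
  an <- locate_anchors(rec)
  oc <- rule_helix13(rec, an)
  expect_identical(oc$status, "ptc_like")  # poly-A context is helix-favoring

  gly <- scaffold()
  gly[311:340] <- "G"
  gly[330:334] <- c("L", "A", "A", "F", "L")
  oc2 <- rule_helix13(as_rec(gly), an)
  expect_identical(oc2$status, "absent")  # signature present, context not

  nosig <- scaffold()
  nosig[311:340] <- rep(c("G", "P"), 15)
  expect_identical(rule_helix13(as_rec(nosig), an)$status, "absent")

  short <- seq_record("short", strrep("A", 20))
  expect_identical(
    rule_helix13(short, list(strt_start = NA, hclp_start = NA))$status,
    "inapplicable")
})

test_that("classification combines the five rules into the family verdict", {
  ptc <- generate_ptc_like(3)
  rep_ptc <- classify(ptc)
  expect_identical(rep_ptc$verdict, "PTC")
  expect_identical(rep_ptc$score, 5L)

  otc <- generate_otc_like(3)
  expect_identical(classify(otc)$verdict, "OTC")

  expect_identical(classify(random_protein(300, seed = 4))$verdict,
                   "NOT_TRANSCARBAMYLASE")

  # the engineered 230-loop swap: YGLY -> VSMG flips only that rule and
  # demotes the verdict to unclassified
  eng <- ablate(ptc, "loop230")
  rep_eng <- classify(eng)
  expect_identical(rep_eng$verdict, "TRANSCARBAMYLASE_UNCLASSIFIED")
  st <- rule_statuses(rep_eng)
  expect_identical(unname(st["loop230"]), "otc_like")
  expect_true(all(st[setdiff(names(st), "loop230")] == "ptc_like"))
})

test_that("classification is deterministic and never calls PTC over an OTC lysine", {
  ptc <- generate_ptc_like(9)
  r1 <- classify(ptc); r2 <- classify(ptc)
  expect_identical(r1, r2)
  for (seed in 1:6) {
    k <- ablate(generate_ptc_like(seed), "lysine_upstream")
    rep <- classify(k)
    expect_identical(unname(rule_statuses(rep)["lysine_upstream"]),
                     "otc_like")
    expect_false(rep$verdict == "PTC")
  }
})

test_that("tabular reports carry one row per record with evidence", {
  recs <- list(generate_ptc_like(1), generate_otc_like(1))
  tab <- classify_records(recs)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$verdict, c("PTC", "OTC"))
  expect_identical(tab$strt_start, c(52L, 52L))
  expect_true(all(grepl("lysine_upstream=", tab$evidence)))
})
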