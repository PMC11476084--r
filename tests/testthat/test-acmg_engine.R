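# Evidence assignment and five-tier combination.

test_that("the 50-nt NMD rule follows hand computation on toy transcripts", {
  tr <- two_exon_transcript()  # exons 200 + 100, junction at 200
  expect_true(predict_nmd(tr, 100))   # 100 nt upstream of the junction
  expect_false(predict_nmd(tr, 180))  # only 20 nt upstream
  expect_false(predict_nmd(tr, 150))  # exactly 50 nt: not "more than 50"
  expect_true(predict_nmd(tr, 149))
  expect_false(predict_nmd(tr, 250))  # last exon

  single <- transcript_model(300L, 1L, 300L)
  expect_false(predict_nmd(single, 100))

  expect_error(predict_nmd(tr, 0), "outside the CDS")
  expect_error(predict_nmd(transcript_model(c(200, 100), 10, 250), 5),
               "outside the CDS")
})

test_that("PVS1 strength follows the reduced loss-of-function decision tree", {
  tr <- two_exon_transcript()
  th <- threshold_config()
  rec <- function(...) toy_records(list(...))[1, ]

  expect_equal(assign_pvs1(rec(consequence = "nonsense", ptc_pos = 100L), tr, th)$strength,
               "very_strong")
  expect_equal(assign_pvs1(rec(consequence = "frameshift", ptc_pos = 180L), tr, th)$strength,
               "strong")  # NMD escape
  expect_equal(assign_pvs1(rec(consequence = "missense", revel = 0.5), tr, th)$strength,
               "none")
  expect_equal(assign_pvs1(rec(consequence = "canonical_splice", spliceai = 0.25), tr, th)$strength,
               "very_strong")
  expect_equal(assign_pvs1(rec(consequence = "canonical_splice", spliceai = 0.15), tr, th)$strength,
               "strong")
  expect_equal(assign_pvs1(rec(consequence = "canonical_splice"), tr, th)$strength,
               "very_strong")  # no score available: keep default strength
  expect_equal(assign_pvs1(rec(consequence = "initiation_codon"), tr, th)$strength,
               "moderate")
  expect_error(assign_pvs1(rec(consequence = "nonsense", ptc_pos = 100L), NULL, th),
               "transcript")
  expect_error(assign_pvs1(rec(consequence = "nonsense"), tr, th), "PTC")
})

test_that("REVEL and SpliceAI tiers are inclusive at their boundaries", {
  th <- threshold_config()
  mis <- function(r) toy_records(list(consequence = "missense", revel = r))[1, ]
  spl <- function(d) toy_records(list(consequence = "splice_region", spliceai = d))[1, ]

  cases <- list(
    list(0.97, "PP3", "strong"), list(0.932, "PP3", "strong"),
    list(0.80, "PP3", "moderate"), list(0.773, "PP3", "moderate"),
    list(0.644, "PP3", "supporting"),
    list(0.50, "PP3", "none"), list(0.30, "PP3", "none"),
    list(0.290, "BP4", "supporting"), list(0.183, "BP4", "moderate"),
    list(0.016, "BP4", "strong"), list(0.003, "BP4", "very_strong"),
    list(0.001, "BP4", "very_strong")
  )
  for (cs in cases) {
    ev <- assign_computational(mis(cs[[1]]), th)
    expect_equal(unname(c(ev$code, ev$strength)), c(cs[[2]], cs[[3]]),
                 info = sprintf("REVEL %.3f", cs[[1]]))
  }

  expect_equal(assign_computational(spl(0.19), th)$code, "BP4")
  expect_equal(assign_computational(spl(0.20), th)$code, "PP3")
  expect_equal(assign_computational(spl(0.20), th)$strength, "supporting")

  bad <- mis(0.5); bad$revel <- 1.2
  expect_error(assign_computational(bad, th), "outside")
})

test_that("PM2 uses an inclusive popmax allele-frequency cutoff", {
  th <- threshold_config()  # cutoff 1e-4, supporting
  absent <- toy_records(list(consequence = "nonsense", ptc_pos = 10L),
                        counts = list(a = c(0L, 20000L), b = c(0L, 5000L)))[1, ]
  expect_equal(assign_pm2(absent, th)$strength, "supporting")

  common <- toy_records(list(), counts = list(a = c(200L, 20000L)))[1, ]
  expect_equal(assign_pm2(common, th)$strength, "none")

  at_cutoff <- toy_records(list(), counts = list(a = c(2L, 20000L)))[1, ]
  expect_equal(assign_pm2(at_cutoff, th)$strength, "supporting")  # AF exactly 1e-4

  # populations with an = 0 are ignored
  empty_an <- toy_records(list(), counts = list(a = c(0L, 0L), b = c(1L, 20000L)))[1, ]
  expect_equal(assign_pm2(empty_an, th)$strength, "supporting")
})

test_that("evidence combination reproduces the combining-table examples", {
  ev <- function(...) dplyr::bind_rows(...)
  expect_equal(combine_evidence(ev(evidence("PVS1", "very_strong"),
                                   evidence("PM2", "moderate"))),
               "likely_pathogenic")
  expect_equal(combine_evidence(ev(evidence("PVS1", "very_strong"),
                                   evidence("PM2", "supporting"),
                                   evidence("PS1", "strong"))),
               "pathogenic")
  expect_equal(combine_evidence(no_ev <- evidence("PP3", "none")),
               "uncertain_significance")
  expect_equal(combine_evidence(ev(evidence("PVS1", "very_strong"))),
               "uncertain_significance")  # very strong alone does not suffice
  expect_equal(combine_evidence(ev(evidence("BA1", "stand_alone"))), "benign")
  expect_equal(combine_evidence(ev(evidence("BS1", "strong"),
                                   evidence("BS2", "strong"))), "benign")
  expect_equal(combine_evidence(ev(evidence("BS1", "strong"),
                                   evidence("BP4", "supporting"))),
               "likely_benign")
  expect_equal(combine_evidence(ev(evidence("BP4", "supporting"),
                                   evidence("BP7", "supporting"))),
               "likely_benign")
  # contradictory pathogenic and benign rule hits resolve to VUS
  expect_equal(combine_evidence(ev(evidence("PVS1", "very_strong"),
                                   evidence("PS1", "strong"),
                                   evidence("BS1", "strong"),
                                   evidence("BS2", "strong"))),
               "uncertain_significance")
  expect_error(combine_evidence(ev(evidence("PM2", "moderate"),
                                   evidence("PM2", "supporting"))),
               "duplicate")
})

test_that("evidence constructor rejects invalid strength/code pairings", {
  expect_error(evidence("PS1", "stand_alone"), "stand_alone")
  expect_error(evidence("BA1", "strong"), "BA1")
  expect_error(evidence("PXX", "strong"), "unknown evidence code")
})

test_that("classification composes evidence deterministically per record", {
  tr <- two_exon_transcript()
  th <- threshold_config(pm2_strength = "moderate")
  recs <- toy_records(
    list(pos = 1L, consequence = "nonsense", ptc_pos = 100L),   # rare LoF, NMD+
    list(pos = 2L, consequence = "missense", revel = 0.40),     # common missense
    counts = list(a = c(1L, 20000L))
  )
  recs$ac_a[2] <- 400L
  cls <- classify_all(recs, tr, th)
  expect_equal(cls$class, c("likely_pathogenic", "uncertain_significance"))

  # empty input -> empty map
  empty <- classify_all(recs[0, ], tr, th)
  expect_equal(nrow(empty), 0L)

  # permutation invariance
  cls_rev <- classify_all(recs[2:1, ], tr, th)
  expect_equal(cls_rev[order(cls_rev$key), ]$class, cls[order(cls$key), ]$class)
})

test_that("loss-of-function and missense computational paths are exclusive", {
  b <- palb2_fixture_bundle()
  for (nm in names(b$tables)) {
    rec <- apply_quality_filters(b$tables[[nm]])
    cls <- classify_all(rec, b$transcript, b$thresholds)
    both <- grepl("PVS1", cls$evidence) &
      (grepl("PP3", cls$evidence) | grepl("BP4", cls$evidence))
    expect_false(any(both))
  }
})

test_that("qualifying sets follow the per-source filter semantics", {
  recs <- toy_records(list(pos = 1L), list(pos = 2L), list(pos = 3L))
  k <- recs$key
  cls <- tibble::tibble(key = k, class = c("likely_pathogenic",
                                           "uncertain_significance", "benign"))
  expect_equal(qualify_by_source(recs, classifications = cls, source = "acmg"), k[1])

  cv <- tibble::tibble(key = k, assertion = c("Pathogenic", "Conflicting",
                                              "Likely_benign"))
  expect_equal(qualify_by_source(recs, assertions = cv, source = "clinvar"), k[1])

  hg <- tibble::tibble(key = k, assertion = c("DM", "DM?", "DP"))
  expect_equal(qualify_by_source(recs, assertions = hg, source = "hgmd"), k[1])

  expect_error(qualify_by_source(recs, source = "cosmic"), "unknown source")
})
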