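let7 <- mature_mirna("let-7a", "UGAGGUAGUAGGUUGUAUAGUU")

test_that("find_seed_sites reproduces the worked examples", {
  s <- find_seed_sites("GGGGCTACCTCAGGGG", let7)
  expect_equal(nrow(s), 1)
  expect_equal(s$site_type, "8mer")
  expect_equal(c(s$start, s$end), c(4L, 12L))

  # all-G UTR: seed match needs "CTACCT..." content
  expect_equal(nrow(find_seed_sites(strrep("G", 50), let7)), 0)

  s6 <- find_seed_sites("TACCTCT", let7)
  expect_equal(s6$site_type, "6mer")
  expect_equal(c(s6$start, s6$end), c(0L, 6L))

  expect_equal(nrow(find_seed_sites("", let7)), 0)
})

test_that("find_seed_sites equals the brute-force oracle on random sequences", {
  set.seed(11)
  mirs <- c(list(let7), synth_mirnas(3, 2))
  for (len in c(50, 200, 1000, 5000)) {
    # AT-rich alphabet raises seed-match density
    utr <- random_seq(len, c("A", "C", "G", "T", "T", "A"))
    for (mir in mirs) {
      got <- find_seed_sites(utr, mir)
      want <- oracle_seed_sites(utr, mir)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$site_type, want$site_type)
    }
  }
  # planted multi-type fixture: every canonical type present
  # (seed6 match TACCTC; m8-pairing base C; A1 adenosine)
  utr <- paste0("CC", "GCTACCTCAG",          # 8mer
                "CCCC", "GCTACCTCG",         # 7mer-m8 (no A1)
                "CCCC", "GTACCTCAG",         # 7mer-A1 (no m8 match)
                "CCCC", "GTACCTCG")          # 6mer (neither)
  got <- find_seed_sites(utr, let7)
  expect_equal(got$site_type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  want <- oracle_seed_sites(utr, let7)
  expect_equal(got$start, want$start)
  expect_equal(got$site_type, want$site_type)
})

test_that("sites never span N or masked offsets", {
  set.seed(12)
  for (rep in 1:10) {
    utr <- random_seq(300, c("A", "C", "G", "T", "N"))
    s <- find_seed_sites(utr, let7)
    if (nrow(s)) {
      for (i in seq_len(nrow(s)))
        expect_false(grepl("N", substr(utr, s$start[i] + 1, s$end[i])))
    }
  }
  # masked span suppressed
  utr <- "GGGGCTACCTCAGGGG"
  expect_equal(nrow(find_seed_sites(utr, let7, known_mask = 5L)), 0)
  expect_equal(nrow(find_seed_sites(utr, let7, known_mask = 14L)), 1)
})

test_that("context_score follows its three documented terms", {
  cfg <- pipeline_config()
  utr_au <- paste0(strrep("A", 30), "CTACCTCA", strrep("T", 30))
  utr_gc <- paste0(strrep("G", 30), "CTACCTCA", strrep("C", 30))
  s8 <- list(start = 30L, end = 38L, site_type = "8mer")
  s6 <- list(start = 30L, end = 36L, site_type = "6mer")
  expect_gt(context_score(s8, utr_au, let7, cfg),
            context_score(s6, utr_au, let7, cfg))
  expect_gt(context_score(s8, utr_au, let7, cfg),
            context_score(s8, utr_gc, let7, cfg))
  # arithmetic oracle: type 1.0 + AU fraction 1.0 + position bonus, x10
  expect_equal(context_score(s8, utr_au, let7, cfg), (1.0 + 1.0 + 0.3) * 10)
  expect_equal(context_score(s8, utr_gc, let7, cfg), (1.0 + 0.0 + 0.3) * 10)
  # site start < 15 from the 5' end but within 15-500 of the 3' end
  utr_short <- paste0("GG", "CTACCTCAG", strrep("G", 40))
  s_near <- list(start = 2L, end = 10L, site_type = "8mer")
  expect_equal(context_score(s_near, utr_short, let7, cfg),
               (1.0 + 0.0 + 0.3) * 10)
  expect_error(context_score(list(site_type = "compensatory"), "A", let7),
               "compensatory")
})

test_that("accessibility: buried stem is closed, unstructured site is open", {
  # 20-bp perfect hairpin stem covering the whole site
  stem1 <- paste0("GGGGGG", "CTACCTCA", "GGGGGG")
  hp <- paste0(stem1, "AAAAAA", rcmp(stem1))
  s <- find_seed_sites(hp, let7)
  expect_equal(s$site_type, "8mer")
  expect_false(assess_accessibility(s[1, ], hp, 150))

  # C-flanked site: nothing can pair at all
  open_utr <- paste0(strrep("C", 20), "CTACCTCA", strrep("C", 20))
  s2 <- find_seed_sites(open_utr, let7)
  expect_true(assess_accessibility(s2[1, ], open_utr, 150))
})

test_that("accessibility boundary: >=4 unpaired seed positions decide", {
  # Sites are designed so the free seed positions are A in a T-free
  # sequence (unpairable) and the paired ones sit in a forced full G/C
  # duplex; 4 free -> accessible, 3 free -> not.
  m4 <- boundary_mirna_free4()
  seq4 <- paste0(strrep("A", 10), "GGGGGG", "GCGAAAAA", strrep("A", 6),
                 "CGCCCCCCC", strrep("A", 10))
  s4 <- find_seed_sites(seq4, m4)
  expect_equal(s4$site_type, "8mer")
  expect_true(assess_accessibility(s4[1, ], seq4, 150))

  m3 <- boundary_mirna_free3()
  seq3 <- paste0(strrep("A", 10), "GGGGGG", "GCGCAAAA", strrep("A", 6),
                 "GCGCCCCCCC", strrep("A", 10))
  s3 <- find_seed_sites(seq3, m3)
  expect_equal(s3$site_type, "8mer")
  expect_false(assess_accessibility(s3[1, ], seq3, 150))
})

test_that("accessibility is deterministic", {
  set.seed(31)
  utr <- random_seq(400)
  s <- find_seed_sites(utr, let7)
  if (nrow(s) == 0) {
    utr <- paste0(substr(utr, 1, 100), "GCTACCTCAG", substr(utr, 111, 400))
    s <- find_seed_sites(utr, let7)
  }
  a1 <- vapply(seq_len(nrow(s)), function(i)
    assess_accessibility(s[i, ], utr, 150), logical(1))
  a2 <- vapply(seq_len(nrow(s)), function(i)
    assess_accessibility(s[i, ], utr, 150), logical(1))
  expect_identical(a1, a2)
})

test_that("rank_overrepresentation matches the closed form and is monotone", {
  expect_equal(rank_overrepresentation(0, "ACGT", let7), 1.0)
  # uniform-composition UTR of length 100: p = (1/4)^7 over 94 positions
  utr <- strrep("ACGT", 25)
  expect_equal(rank_overrepresentation(1, utr, let7),
               1 - (1 - 0.25^7)^94, tolerance = 1e-12)
  p <- vapply(0:4, rank_overrepresentation, numeric(1),
              utr_sequence = utr, mirna = let7)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("compensatory sites require one seed defect plus 3' support", {
  # miRNA nt layout (let-7a): seed nt2-8 GAGGUAG; nt13-17 = GUUGU
  mseq <- chartr("U", "T", let7$sequence)
  seed_match <- rcmp(substr(mseq, 2, 8))       # CTACCTC
  comp3p <- rcmp(substr(mseq, 13, 17))         # pairs nt 13-17
  # perfect seed only: excluded
  utr_perfect <- paste0(strrep("C", 20), seed_match, "A", strrep("C", 20))
  expect_equal(nrow(find_compensatory_sites(utr_perfect, let7)), 0)

  # one central mismatch + full 3' complement 3 nt upstream
  broken <- seed_match
  substr(broken, 4, 4) <- "G"                  # central defect
  utr_comp <- paste0(strrep("C", 10), comp3p, "CCC", broken, strrep("C", 10))
  got <- find_compensatory_sites(utr_comp, let7)
  expect_equal(nrow(got), 1)
  expect_equal(got$site_type, "compensatory")
  expect_equal(got$predictor, "compensatory")
  expect_equal(c(got$start, got$end), c(18L, 25L))

  # same defect, no 3' pairing anywhere
  utr_nocomp <- paste0(strrep("C", 13), "CCC", broken, strrep("C", 10))
  expect_equal(nrow(find_compensatory_sites(utr_nocomp, let7)), 0)

  # single-nucleotide UTR bulge with 3' support
  bulged <- paste0(substr(seed_match, 1, 3), "G", substr(seed_match, 4, 7))
  utr_bulge <- paste0(strrep("C", 10), comp3p, "CC", bulged, strrep("C", 10))
  got_b <- find_compensatory_sites(utr_bulge, let7)
  expect_equal(nrow(got_b), 1)
  expect_equal(got_b$end - got_b$start, 8L)
})

test_that("compensatory sites never duplicate canonical spans", {
  set.seed(21)
  mirs <- synth_mirnas(4, 9)
  found <- 0L
  violations <- 0L
  for (rep in 1:8) {
    utr <- random_seq(400, c("A", "C", "G", "T", "A", "T"))
    for (mir in mirs) {
      # plant a compensatory construct for this miRNA into the random UTR
      mseq <- chartr("U", "T", mir$sequence)
      broken <- rcmp(substr(mseq, 2, 8))
      substr(broken, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                      substr(broken, 4, 4))[1]
      insert <- paste0(rcmp(substr(mseq, 13, 17)), "CC", broken)
      utr_p <- paste0(substr(utr, 1, 100), insert, substr(utr, 101, 400))
      canon <- find_seed_sites(utr_p, mir)
      comp <- find_compensatory_sites(utr_p, mir)
      found <- found + nrow(comp)
      violations <- violations +
        length(intersect(paste(comp$start, comp$end),
                         paste(canon$start, canon$end)))
    }
  }
  expect_gte(found, 8L)       # planted constructs are recovered
  expect_equal(violations, 0L)
})

test_that("check_conservation is presence-based on the miRNA family", {
  site <- list(start = 4L, end = 12L, site_type = "8mer")
  expect_true(check_conservation(site, "GGGGCTACCTCAGGGG", let7))
  expect_false(check_conservation(site, strrep("G", 30), let7))
  # 7mer-A1 in the ortholog suffices even though the pig site is an 8mer
  expect_true(check_conservation(site,
                                 paste0(strrep("G", 5), "CTACCTCA",
                                        strrep("G", 5)), let7))
  expect_error(check_conservation(site, "", let7), "non-empty")
})

test_that("predict_sites assembles per-predictor tables", {
  utr <- make_test_utr(paste0(strrep("C", 20), "GCTACCTCAG", strrep("C", 20)))
  out <- predict_sites(utr, list(let7))
  expect_true(all(out$predictor %in%
                    c("seed_context", "accessibility", "compensatory")))
  sc <- out[out$predictor == "seed_context", ]
  expect_equal(nrow(sc), 1)
  expect_equal(sc$site_type, "8mer")
  expect_false(any(is.na(sc$score)))
  ac <- out[out$predictor == "accessibility", ]
  if (nrow(ac)) expect_true(all(ac$accessible))
})
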