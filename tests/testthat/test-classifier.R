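mk_site <- function(mirna = "miR-X", start = 10L, end = 18L, type = "8mer",
                    predictor = "seed_context", score = 10, utr_id = "t1") {
  data.frame(utr_id = utr_id, mirna_name = mirna, start = start, end = end,
             site_type = type, predictor = predictor, score = score,
             accessible = NA, stringsAsFactors = FALSE)
}
snp0 <- snp_record("chr", 15L, "A", "G")

test_that("created / disrupted / perturbed statuses follow the definitions", {
  ref <- mk_site(score = 12)
  none <- empty_sites()
  # ref-only key -> disrupted
  pm <- classify_polymirts(ref, none, snp0)
  expect_equal(pm$status, "disrupted")
  expect_equal(pm$ref_score, 12)
  expect_true(is.na(pm$var_score))
  # var-only key -> created
  pm2 <- classify_polymirts(none, mk_site(type = "7mer-A1", end = 17L), snp0)
  expect_equal(pm2$status, "created")
  expect_true(is.na(pm2$ref_score))
  # shared key, score delta rules (strict > 2 units)
  pm3 <- classify_polymirts(mk_site(score = 1.0), mk_site(score = 3.5), snp0)
  expect_equal(pm3$status, "perturbed")
  expect_equal(classify_polymirts(mk_site(score = 1.0),
                                  mk_site(score = 2.5), snp0) |> nrow(), 0)
  # mismatched UTR ids refuse to classify
  expect_error(classify_polymirts(mk_site(utr_id = "a"),
                                  mk_site(utr_id = "b"), snp0), "mix")
})

test_that("truncation masks turn disruption into unknown", {
  ref <- mk_site(start = 10L, end = 18L)
  # mask overlapping the span: unknown, never disrupted
  pm <- classify_polymirts(ref, empty_sites(), snp0,
                           variant_known_mask = 17L)
  expect_equal(pm$status, "unknown")
  # mask outside the span: plain disruption
  pm2 <- classify_polymirts(ref, empty_sites(), snp0,
                            variant_known_mask = 30L)
  expect_equal(pm2$status, "disrupted")
  # unknown occurs iff the mask overlaps a reference span
  pm3 <- classify_polymirts(ref, empty_sites(), snp0,
                            variant_known_mask = c(5L, 9L, 18L))
  expect_equal(pm3$status, "disrupted")
})

test_that("classification is symmetric under ref/var swap", {
  set.seed(13)
  mirs <- synth_mirnas(6, 3)
  for (rep in 1:6) {
    utr <- random_seq(300, c("A", "C", "G", "T", "A", "T"))
    pos <- sample(50:250, 1)
    ref <- substr(utr, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    var <- utr
    substr(var, pos, pos) <- alt
    rs <- do.call(rbind, lapply(mirs, function(m)
      find_seed_sites(utr, m, "t1")))
    vs <- do.call(rbind, lapply(mirs, function(m)
      find_seed_sites(var, m, "t1")))
    rs$predictor <- rep("seed_context", nrow(rs))
    vs$predictor <- rep("seed_context", nrow(vs))
    rs$score <- rep(0, nrow(rs))
    vs$score <- rep(0, nrow(vs))
    fwd <- classify_polymirts(rs, vs, snp_record("chr", pos, ref, alt))
    rev_ <- classify_polymirts(vs, rs, snp_record("chr", pos, alt, ref))
    key <- function(d) sort(paste(d$mirna_name, d$start, d$end, d$site_type))
    expect_equal(key(fwd[fwd$status == "created", ]),
                 key(rev_[rev_$status == "disrupted", ]))
    expect_equal(key(fwd[fwd$status == "disrupted", ]),
                 key(rev_[rev_$status == "created", ]))
  }
})

test_that("one SNP can create for one miRNA and disrupt for another", {
  ref <- mk_site(mirna = "miR-B", start = 12L, end = 20L)
  var <- mk_site(mirna = "miR-A", start = 12L, end = 20L)
  pm <- classify_polymirts(ref, var, snp0)
  expect_setequal(pm$status, c("created", "disrupted"))
  tl <- tally_created_disrupted(pm)
  expect_equal(tl$created, 1L)
  expect_equal(tl$disrupted, 1L)
})

test_that("snp_distance is recorded relative to the site span", {
  u <- make_test_utr(strrep("A", 60))
  s <- snp_record("chr1", 15L, "A", "G")   # offset 14
  pm <- classify_polymirts(mk_site(start = 10L, end = 18L), empty_sites(), s,
                           utr = u)
  expect_equal(pm$snp_distance, 0L)
  pm2 <- classify_polymirts(mk_site(start = 30L, end = 38L), empty_sites(),
                            s, utr = u)
  expect_equal(pm2$snp_distance, 16L)   # 30 - 14
})

test_that("summarize_consensus partitions the Venn regions exactly", {
  mk3 <- function(n, off = 0) do.call(rbind, lapply(seq_len(n), function(i)
    mk_site(mirna = paste0("m", i + off), start = i * 10L,
            end = i * 10L + 8L)))
  # identical sets
  s <- mk3(3)
  cs <- summarize_consensus(list(seed_context = s, accessibility = s,
                                 compensatory = s))
  expect_equal(unname(cs[["all_three"]]), 3L)
  expect_equal(sum(cs), 3L)
  expect_equal(attr(cs, "total"), 3L)
  # pairwise disjoint
  cs2 <- summarize_consensus(list(seed_context = mk3(2),
                                  accessibility = mk3(3, 10),
                                  compensatory = mk3(4, 20)))
  expect_equal(unname(cs2[["seed_context_only"]]), 2L)
  expect_equal(unname(cs2[["accessibility_only"]]), 3L)
  expect_equal(unname(cs2[["compensatory_only"]]), 4L)
  expect_equal(sum(cs2), 9L)
})

test_that("summarize_consensus equals set-algebra enumeration on random sets", {
  set.seed(17)
  for (rep in 1:20) {
    pool <- paste0("m", 1:8, "\r", 10 * (1:8), "\r", 10 * (1:8) + 8)
    pick <- function() sample(pool, sample(0:8, 1))
    A <- pick(); B <- pick(); C <- pick()
    tosites <- function(keys) {
      if (!length(keys)) return(empty_sites())
      parts <- do.call(rbind, strsplit(keys, "\r"))
      mk_site(mirna = parts[, 1], start = as.integer(parts[, 2]),
              end = as.integer(parts[, 3]))
    }
    cs <- summarize_consensus(list(seed_context = tosites(A),
                                   accessibility = tosites(B),
                                   compensatory = tosites(C)))
    expect_equal(unname(unclass(cs)), oracle_venn(A, B, C),
                 ignore_attr = TRUE)
  }
})

test_that("tally_created_disrupted partitions by status and reports unknown", {
  expect_equal(nrow(tally_created_disrupted(
    classify_polymirts(empty_sites(), empty_sites(), snp0))), 0)
  pm <- rbind(
    classify_polymirts(mk_site(), empty_sites(), snp0),                    # disrupted
    classify_polymirts(empty_sites(), mk_site(mirna = "m2"), snp0),       # created
    classify_polymirts(mk_site(mirna = "m3"), empty_sites(), snp0,
                       variant_known_mask = 11L))                          # unknown
  tl <- tally_created_disrupted(pm)
  expect_equal(tl$created, 1L)
  expect_equal(tl$disrupted, 1L)
  expect_equal(tl$unknown, 1L)
  expect_equal(tl$created + tl$disrupted + tl$perturbed + tl$unknown,
               nrow(pm))
})
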