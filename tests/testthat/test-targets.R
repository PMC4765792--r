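test_that("target scoring follows the penalty scheme with seed doubling", {
  m <- "TGACAGAAGAGAGTGAGCAC"
  perfect <- rc_chr(m)
  expect_equal(score_target_site(m, perfect)$expectation, 0)
  # G:U wobble opposite miRNA position 1 costs 0.5 (outside the seed)
  # position 1 of the miRNA pairs the LAST base of the window
  m_gu <- m
  substr(m_gu, 1, 1) <- "G"
  w <- rc_chr(m_gu)
  substr(w, nchar(w), nchar(w)) <- "T"
  expect_equal(score_target_site(m_gu, w)$expectation, 0.5)
  # the same wobble at position 5 is doubled (seed region 2-13)
  m5 <- m
  substr(m5, 5, 5) <- "G"
  w5 <- rc_chr(m5)
  substr(w5, nchar(w5) - 4, nchar(w5) - 4) <- "T"
  expect_equal(score_target_site(m5, w5)$expectation, 1.0)
  expect_error(score_target_site("", "ACGT"), "empty")
})

test_that("the scorer matches exhaustive enumeration on short duplexes", {
  set.seed(17)
  for (i in 1:200) {
    mlen <- sample(8:12, 1)
    d <- sample(0:3, 1)
    m <- rand_seq(mlen)
    w <- rand_seq(mlen + d)
    expect_equal(score_target_site(m, w)$expectation,
                 target_score_oracle(m, w), info = paste(m, w))
  }
})

test_that("transcriptome scanning retains sites at the 3.0 cutoff only", {
  set.seed(23)
  m <- rand_seq(21)
  tx_hit <- paste0(rand_seq(50), rc_chr(m), rand_seq(50))
  tx_miss <- rand_seq(120)
  res <- scan_transcriptome(c(mir1 = m),
                            c(t1 = tx_hit, t2 = tx_miss), cutoff = 3.0)
  expect_true(any(res$transcript_id == "t1" & res$expectation == 0))
  # a site scoring above the cutoff is dropped: corrupt the seed heavily
  bad <- rc_chr(m)
  substr(bad, 3, 6) <- rc_chr(substr(bad, 3, 6)) # scrambles pairing
  res2 <- scan_transcriptome(c(mir1 = m),
                             c(t1 = paste0(rand_seq(30), bad, rand_seq(30))),
                             cutoff = 3.0)
  expect_true(all(res2$expectation <= 3.0))
  # predicted cleavage sits opposite miRNA position 10
  hit <- res[res$transcript_id == "t1" & res$expectation == 0, ][1, ]
  expect_equal(hit$cleavage_pos, hit$end - 9L)
})

test_that("raising the cutoff never removes interactions (monotone filter)", {
  set.seed(41)
  m <- rand_seq(21)
  txs <- stats::setNames(lapply(1:5, function(i)
    paste0(rand_seq(40), rc_chr(m), rand_seq(40))), paste0("t", 1:5))
  txs <- vapply(txs, identity, character(1))
  lo <- scan_transcriptome(c(x = m), txs, cutoff = 1.0)
  hi <- scan_transcriptome(c(x = m), txs, cutoff = 3.0)
  key <- function(d) paste(d$mirna_id, d$transcript_id, d$start)
  expect_true(all(key(lo) %in% key(hi)))
})

test_that("degradome profiles accumulate 5'-end counts per transcript", {
  set.seed(29)
  t1 <- rand_seq(300)
  t2 <- paste0(rand_seq(100), substr(t1, 100, 140), rand_seq(60))
  tag_unique <- substr(t1, 100, 119)  # occurs in both transcripts
  tag_t1 <- substr(t1, 50, 70)
  profs <- build_degradome_profile(
    stats::setNames(c(7L, 3L), c(tag_unique, tag_t1)),
    c(t1 = t1, t2 = t2))
  expect_equal(unname(profs$t1[["100"]]), 7L)
  expect_equal(unname(profs$t1[["50"]]), 3L)
  expect_equal(unname(profs$t2[["101"]]), 7L) # multi-transcript tag counted twice
  expect_length(build_degradome_profile(stats::setNames(2L, rand_seq(25)),
                                        c(t1 = t1))$t1, 0L)
})

test_that("cleavage validation is inclusive at |offset| = 5 and fails at 6", {
  inter <- data.frame(mirna_id = "m", transcript_id = "t1",
                      start = 90L, end = 110L, expectation = 0,
                      cleavage_pos = 100L, status = "unvalidated",
                      tag_support = 0L, stringsAsFactors = FALSE)
  at <- function(p) stats::setNames(list(stats::setNames(5L, p)), "t1")
  expect_equal(validate_cleavage(inter, at("100"))$status, "validated")
  expect_equal(validate_cleavage(inter, at("105"))$status, "validated")
  expect_equal(validate_cleavage(inter, at("95"))$status, "validated")
  expect_equal(validate_cleavage(inter, at("106"))$status, "unvalidated")
  expect_equal(validate_cleavage(inter, at("94"))$status, "unvalidated")
  v <- validate_cleavage(inter, at("103"))
  expect_equal(v$tag_support, 5L)
})

test_that("pathway annotation flags targets and summarizes per pathway", {
  inter <- data.frame(mirna_id = c("m1", "m2"), transcript_id = c("g1", "g2"),
                      start = 1L, end = 21L, expectation = 0,
                      cleavage_pos = 10L, status = "unvalidated",
                      tag_support = 0L, stringsAsFactors = FALSE)
  out <- annotate_pathway_targets(inter, list(lipid = "g1",
                                              GSL = c("g1", "g2")))
  expect_true(out$pathway_lipid[1] && !out$pathway_lipid[2])
  expect_true(all(out$pathway_GSL))
  s <- attr(out, "pathway_summary")
  expect_equal(s$n_targets[s$pathway == "GSL"], 2L)
  expect_warning(annotate_pathway_targets(inter, list(x = "nope")),
                 "not among")
  out2 <- annotate_pathway_targets(inter, list())
  expect_null(attr(out2, "pathway_summary"))
})
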