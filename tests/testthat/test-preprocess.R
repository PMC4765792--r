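make_lib <- function(counts, ...) srna_library(counts, id = "t", ...)

test_that("length filter drops reads outside the 18-44 nt clean-read range", {
  lib <- make_lib(stats::setNames(c(5L, 10L, 2L),
                                  c(rand_seq(17), rand_seq(21), rand_seq(45))))
  f <- length_filter(lib, 18, 44)
  expect_equal(length(f$reads), 1L)
  expect_equal(nchar(names(f$reads)), 21L)
  expect_equal(f$clean_total, 10)
  # identity when bounds already cover the observed range
  lib2 <- make_lib(stats::setNames(c(1L, 2L), c(rand_seq(20), rand_seq(24))))
  expect_identical(length_filter(lib2, 20, 24)$reads, lib2$reads)
  # empty library passes through
  expect_equal(length(length_filter(make_lib(integer()))$reads), 0L)
  # idempotence
  expect_identical(length_filter(f, 18, 44)$reads, f$reads)
  expect_error(length_filter(lib, 0, 10))
})

test_that("ncRNA filtering removes substrings with class-priority tallies", {
  set.seed(2)
  trna <- rand_seq(80)
  rrna <- rand_seq(120)
  frag_t <- substr(trna, 10, 30)            # tRNA fragment
  frag_both <- substr(rrna, 5, 25)          # also planted into the tRNA ref
  trna2 <- paste0(rand_seq(20), frag_both, rand_seq(20))
  keep <- rand_seq(22)
  lib <- make_lib(stats::setNames(c(4L, 6L, 3L), c(frag_t, frag_both, keep)))
  ref <- list(snoRNA = rand_seq(60), tRNA = c(trna, trna2), rRNA = rrna)
  f <- filter_ncrna(lib, ref)
  expect_setequal(names(f$reads), keep)
  rep <- attr(f, "removal_report")
  # read matching both rRNA and tRNA is tallied once, under tRNA (< rRNA)
  expect_equal(rep$unique_removed[rep$class == "tRNA"], 2L)
  expect_equal(rep$unique_removed[rep$class == "rRNA"], 0L)
  expect_equal(sum(rep$count_removed), 10)
  # clean total untouched by default (pre-ncRNA denominator)
  expect_equal(f$clean_total, 13)
  # reverse-strand fragments are caught too
  librc <- make_lib(stats::setNames(2L, rc_chr(frag_t)))
  expect_equal(length(filter_ncrna(librc, ref)$reads), 0L)
  # idempotence
  expect_identical(filter_ncrna(f, ref)$reads, f$reads)
})

test_that("RPM follows count / clean_total x 1e6", {
  expect_equal(compute_rpm(0, 5000), 0)
  expect_equal(compute_rpm(12345, 12345), 1e6)
  expect_equal(compute_rpm(50, 1e7), 5)
  expect_error(compute_rpm(5, 0), "positive")
  # sum over a library equals 1e6 x retained/clean
  lib <- make_lib(stats::setNames(c(10L, 30L), c(rand_seq(20), rand_seq(21))),
                  clean_total = 80)
  expect_equal(sum(compute_rpm(lib$reads, lib$clean_total)),
               1e6 * 40 / 80)
})
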