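test_that("exact mapping equals a naive all-positions scan on both strands", {
  set.seed(7)
  g <- fixture_genome(7, 300)
  reads <- c(substr(g$seqs[["A01"]], 50, 70),
             rc_chr(substr(g$seqs[["C01"]], 100, 123)),
             rand_seq(21))
  lib <- srna_library(stats::setNames(c(3L, 5L, 2L), reads), id = "t")
  aln <- map_reads_exact(lib, g)
  for (r in reads) {
    got <- aln[aln$read == r, c("chrom", "start", "end", "strand")]
    rownames(got) <- NULL
    want <- naive_map_oracle(r, g$seqs)
    want <- want[order(want$chrom, want$start, want$strand), ]
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("mapping a read and its reverse complement flips strands only", {
  g <- fixture_genome(13, 300)
  r <- substr(g$seqs[["A01"]], 30, 51)
  a1 <- map_reads_exact(stats::setNames(2L, r), g)
  a2 <- map_reads_exact(stats::setNames(2L, rc_chr(r)), g)
  expect_equal(a1$start, a2$start)
  expect_equal(a1$end, a2$end)
  expect_true(all(a1$strand != a2$strand))
})

test_that("a read planted on homeologous positions maps to both subgenomes", {
  set.seed(5)
  a <- rand_seq(400); c_ <- rand_seq(400)
  read <- rand_seq(21)
  substr(a, 101, 121) <- read
  substr(c_, 201, 221) <- read
  g <- genome_set(c(A01 = a, C01 = c_))
  aln <- map_reads_exact(stats::setNames(4L, read), g)
  expect_equal(nrow(aln), 2L)
  expect_setequal(assign_subgenome(aln$chrom, g), c("A", "C"))
  # oracle cross-check
  expect_equal(nrow(naive_map_oracle(read, g$seqs)), 2L)
})

test_that("U is treated as T, N never matches, bad characters error", {
  g <- genome_set(c(A01 = "ACGTACGTNNNNACGTACGTGGGG"))
  r_u <- chartr("T", "U", substr(g$seqs[["A01"]], 1, 8))
  aln <- map_reads_exact(stats::setNames(2L, r_u), g)
  expect_true(nrow(aln) >= 1)
  # the N block can never be covered
  expect_true(all(aln$start >= 12 | aln$end <= 8))
  expect_error(map_reads_exact(stats::setNames(2L, "ACGTXCGT"), g), "ACGTU")
})

test_that("unmapped reads are flagged and BED export has six columns", {
  g <- fixture_genome(3, 200)
  reads <- stats::setNames(c(2L, 2L),
                           c(substr(g$seqs[["A01"]], 10, 30), strrep("A", 21)))
  aln <- map_reads_exact(reads, g)
  expect_identical(attr(aln, "unmapped"), strrep("A", 21))
  tf <- withr::local_tempfile(fileext = ".bed")
  alignments_to_bed(aln, tf)
  expect_equal(length(strsplit(readLines(tf)[1], "\t")[[1]]), 6L)
})
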