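# minimal hand-built ExpressionMatrix for the pure-arithmetic operations
manual_matrix <- function(rpm, subgenome = NULL, libmeta = NULL) {
  n <- nrow(rpm)
  loci <- data.frame(locus_id = rownames(rpm),
                     subgenome = subgenome %||% rep("A", n),
                     mature_seq = strrep("A", 21),
                     stringsAsFactors = FALSE)
  meta <- libmeta %||% data.frame(
    id = colnames(rpm), line = colnames(rpm), tissue = "seedling",
    environment = "E1", clean_total = 1e6, stringsAsFactors = FALSE)
  structure(list(loci = loci, counts = rpm, rpm = rpm, libraries = meta),
            class = "ExpressionMatrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reads are counted within mature spans, dual-subgenome twice", {
  set.seed(71)
  a <- rand_seq(500); c_ <- rand_seq(500)
  shared <- rand_seq(21)
  a_only <- rand_seq(21)
  substr(a, 101, 121) <- shared
  substr(c_, 301, 321) <- shared
  substr(a, 201, 221) <- a_only
  g <- genome_set(c(A01 = a, C01 = c_))
  loci <- data.frame(
    locus_id = c("LA", "LC", "LAONLY"), chrom = c("A01", "C01", "A01"),
    strand = "+", mature_start = c(100L, 300L, 200L),
    mature_end = c(121L, 321L, 221L),
    mature_seq = c(shared, shared, a_only),
    subgenome = c("A", "C", "A"), stringsAsFactors = FALSE)
  lib <- srna_library(stats::setNames(c(7L, 3L), c(shared, a_only)),
                      id = "L1", clean_total = 1e6)
  cm <- count_mature_reads(lib, loci, genome = g)
  expect_equal(cm$count, c(7, 7, 3)) # the shared read is counted twice
  expect_equal(cm$rpm, c(7, 7, 3))   # at 1e6 clean reads RPM == count
  # conservation: A tally + C tally = mapped count + one extra per dual read
  expect_equal(sum(cm$count), (7 + 3) + 7)
})

test_that("a read extending beyond the mature span is not counted", {
  set.seed(72)
  a <- rand_seq(400)
  g <- genome_set(c(A01 = a))
  mat <- substr(a, 101, 121)
  long_read <- substr(a, 95, 130) # overlaps but extends past the span
  loci <- data.frame(locus_id = "L1", chrom = "A01", strand = "+",
                     mature_start = 100L, mature_end = 121L,
                     mature_seq = mat, subgenome = "A",
                     stringsAsFactors = FALSE)
  lib <- srna_library(stats::setNames(c(5L, 4L), c(mat, long_read)),
                      id = "L", clean_total = 1000)
  cm <- count_mature_reads(lib, loci, genome = g)
  expect_equal(cm$count, 5)
  # the 2-nt slack admits slight 5'/3' shifts
  iso <- substr(a, 100, 120)
  cm2 <- count_mature_reads(srna_library(stats::setNames(2L, iso), id = "L",
                                         clean_total = 1000),
                            loci, genome = g)
  expect_equal(cm2$count, 2)
})

test_that("identical subgenome vectors give ratio 1 and p 1", {
  rpm <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 1,
                dimnames = list(paste0("l", 1:6), "L1"))
  mat <- manual_matrix(rpm, subgenome = rep(c("A", "C"), each = 3))
  pr <- subgenome_partition_test(mat)
  expect_equal(pr$ratio, 1)
  expect_equal(pr$p_value, 1)
  expect_match(pr$test, "exact")
})

test_that("the exact rank-sum p equals the permutation oracle on tiny groups", {
  cases <- list(list(a = c(1, 2, 3), c = c(4, 5, 6)),
                list(a = c(10, 30, 50), c = c(20, 40, 60)),
                list(a = c(1, 5, 9, 13), c = c(2, 4, 8)),
                list(a = c(2, 7, 11, 19, 23, 31), c = c(3, 5, 13, 17, 29, 37)))
  for (cs in cases) {
    rpm <- matrix(c(cs$a, cs$c), ncol = 1,
                  dimnames = list(paste0("l", seq_along(c(cs$a, cs$c))), "L1"))
    mat <- manual_matrix(rpm, subgenome = rep(c("A", "C"),
                                              c(length(cs$a), length(cs$c))))
    pr <- subgenome_partition_test(mat)
    expect_equal(pr$p_value, ranksum_permutation_oracle(cs$a, cs$c),
                 tolerance = 1e-10)
  }
})

test_that("per-mature and per-Mb statistics use their own denominators", {
  g <- genome_set(c(A01 = strrep("ACGT", 2500), C01 = strrep("ACGT", 5000)))
  rpm <- matrix(c(10, 20, 30, 40), ncol = 1,
                dimnames = list(paste0("l", 1:4), "L1"))
  mat <- manual_matrix(rpm, subgenome = c("A", "A", "C", "C"))
  pm <- subgenome_partition_test(mat, mode = "per_mature")
  expect_equal(pm$mean_A, 15)
  expect_equal(pm$mean_C, 35)
  expect_equal(pm$ratio, 35 / 15)
  pmb <- subgenome_partition_test(mat, mode = "per_mb", genome = g)
  expect_equal(pmb$mean_A, 30 / (1e4 / 1e6))
  expect_equal(pmb$mean_C, 70 / (2e4 / 1e6))
})

test_that("locus density is loci per megabase", {
  g <- genome_set(c(A01 = strrep("A", 1e6 - 1e5), A02 = strrep("C", 1e5),
                    C01 = strrep("G", 5e5)))
  loci <- data.frame(subgenome = c(rep("A", 10), rep("C", 0)))
  d <- mirna_density(loci, g)
  expect_equal(unname(d[["A"]]), 10)
  expect_equal(unname(d[["C"]]), 0)
  # mirrors the printed-scale arithmetic: 103 loci on 100 Mb -> 1.03
  expect_equal(103 / 100, 1.03)
})

test_that("differential expression uses a strict two-fold boundary", {
  rpm <- cbind(L1 = c(10, 30, 20), L2 = c(10, 10, 10))
  rownames(rpm) <- paste0("l", 1:3)
  mat <- manual_matrix(rpm)
  de <- differential_expression(mat, "L1", "L2", fold = 2, eps = 0)
  expect_equal(de$de, c(FALSE, TRUE, FALSE)) # 1x, 3x, exactly 2x
  expect_equal(de$direction, c("ns", "up", "ns"))
  expect_error(differential_expression(mat, character(), "L2"), "non-empty")
})

test_that("heredity calls are inclusive at the two-fold boundary", {
  rpm <- cbind(P1 = c(10, 10, 10, 0), P2 = c(10, 10, 10, 0),
               D1 = c(10, 20, 19.9, 0), D2 = c(10, 20, 19.9, 0))
  rownames(rpm) <- paste0("l", 1:4)
  mat <- manual_matrix(rpm)
  h <- heredity_classification(mat, "P1", "P2", c("D1", "D2"))
  expect_equal(h$call, c("additive", "non-additive", "additive", "additive"))
  expect_equal(h$mpv, c(10, 10, 10, 0))
  s <- attr(h, "summary")
  expect_equal(s$n_nonadditive, 1L)
  expect_equal(s$ratio_nonadditive_additive, 1 / 3)
})

test_that("scaling all counts and totals by 10 changes nothing", {
  set.seed(31)
  rpm <- matrix(stats::rpois(40, 50), ncol = 4,
                dimnames = list(paste0("l", 1:10),
                                c("P1", "P2", "D1", "D2")))
  mat1 <- manual_matrix(rpm, subgenome = rep(c("A", "C"), 5))
  mat10 <- mat1
  mat10$counts <- mat1$counts * 10
  mat10$libraries$clean_total <- mat1$libraries$clean_total * 10
  # RPM is invariant, hence so are ratios and calls
  expect_equal(mat10$counts[, 1] / mat10$libraries$clean_total[1],
               mat1$counts[, 1] / mat1$libraries$clean_total[1])
  p1 <- subgenome_partition_test(mat1, c("P1", "P2"))
  p10 <- subgenome_partition_test(mat10, c("P1", "P2"))
  expect_equal(p1$ratio, p10$ratio)
  expect_equal(p1$p_value, p10$p_value)
})
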