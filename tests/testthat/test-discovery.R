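test_that("read support below two in every library yields no candidates", {
  g <- fixture_genome(21, 800)
  r <- substr(g$seqs[["A01"]], 101, 121)
  aln1 <- map_reads_exact(stats::setNames(1L, r), g)
  aln1$library <- "L1"
  expect_equal(nrow(cluster_and_excise(aln1, g)), 0L)
  # exactly two reads in one library passes the gate
  aln2 <- map_reads_exact(stats::setNames(2L, r), g)
  aln2$library <- "L1"
  cands <- cluster_and_excise(aln2, g)
  expect_equal(length(unique(cands$candidate_id)), 1L)
  expect_equal(nrow(cands), 2L) # two windows per candidate
})

test_that("windows are clipped at chromosome ends without error", {
  g <- fixture_genome(22, 600)
  r <- substr(g$seqs[["A01"]], 3, 23) # cluster at chromosome start
  aln <- map_reads_exact(stats::setNames(3L, r), g)
  aln$library <- "L1"
  cands <- cluster_and_excise(aln, g)
  left <- cands[cands$window == 1, ]
  expect_equal(left$win_start, 0L)
  right <- cands[cands$window == 2, ]
  expect_lte(right$win_end, 600L)
})

test_that("the candidate mature is the most abundant read, ties by sequence", {
  set.seed(77)
  g <- fixture_genome(77, 800)
  r1 <- substr(g$seqs[["A01"]], 200, 220)
  r2 <- substr(g$seqs[["A01"]], 205, 226) # overlaps r1
  lib <- stats::setNames(c(9L, 4L), c(r1, r2))
  aln <- map_reads_exact(lib, g)
  aln$library <- "L1"
  cands <- cluster_and_excise(aln, g)
  expect_true(all(cands$mature_seq == r1))
})

test_that("acceptance gates apply the exact quoted boundaries", {
  dup_ok <- list(ok = TRUE, matched_nt = 19L, bulge_nt = 1L,
                 spacing_nt = 45L, reason = NA)
  fold_at <- function(dg) list(delta_g = dg)
  # dG must be strictly below -18
  r <- call_mirna(fold_at(-17.5), dup_ok, 10L)
  expect_false(r$accepted)
  expect_match(paste(r$reasons, collapse = " "), "delta_g")
  expect_false(call_mirna(fold_at(-18), dup_ok, 10L)$accepted)
  expect_true(call_mirna(fold_at(-18.01), dup_ok, 10L)$accepted)
  # matched must be strictly more than 16
  d16 <- utils::modifyList(dup_ok, list(matched_nt = 16L))
  expect_false(call_mirna(fold_at(-25), d16, 10L)$accepted)
  expect_true(call_mirna(fold_at(-25),
                         utils::modifyList(dup_ok, list(matched_nt = 17L)),
                         10L)$accepted)
  # bulges strictly fewer than four
  d4 <- utils::modifyList(dup_ok, list(bulge_nt = 4L))
  expect_false(call_mirna(fold_at(-25), d4, 10L)$accepted)
  expect_true(call_mirna(fold_at(-25),
                         utils::modifyList(dup_ok, list(bulge_nt = 3L)),
                         10L)$accepted)
  # spacing strictly below 300
  d300 <- utils::modifyList(dup_ok, list(spacing_nt = 300L))
  expect_false(call_mirna(fold_at(-25), d300, 10L)$accepted)
  expect_true(call_mirna(fold_at(-25),
                         utils::modifyList(dup_ok, list(spacing_nt = 299L)),
                         10L)$accepted)
  # at least two reads in a library
  expect_false(call_mirna(fold_at(-25), dup_ok, 1L)$accepted)
  expect_true(call_mirna(fold_at(-25), dup_ok, 2L)$accepted)
  # a fully passing candidate
  expect_true(call_mirna(fold_at(-25), dup_ok, 10L)$accepted)
  # rejection records carry every failed criterion
  r2 <- call_mirna(fold_at(-10), d16, 1L)
  expect_length(r2$reasons, 3L)
})

test_that("conserved/novel classification uses edit distance with boundary 2", {
  ref <- list(miR156 = "TGACAGAAGAGAGTGAGCAC",
              miR172 = "AGAATCTTGATGATGCTGCAT")
  expect_equal(classify_mirna("TGACAGAAGAGAGTGAGCAC", ref),
               list(class = "conserved", family = "miR156", distance = 0L))
  two_off <- "TGACAGAAGAGAGTGAGGGC"
  expect_equal(classify_mirna(two_off, ref)$class, "conserved")
  expect_equal(classify_mirna(two_off, ref)$distance, 2L)
  three_off <- "TGACAGAAGAGAGTGAGGGG"
  cl3 <- classify_mirna(three_off, ref)
  expect_equal(cl3$class, "novel")
  expect_gte(cl3$distance, 3L)
  # U and length heterogeneity are handled (global edit distance)
  expect_equal(classify_mirna("UGACAGAAGAGAGUGAGCACA", ref)$distance, 1L)
  # symmetry of the distance
  expect_equal(unname(utils::adist(two_off, ref$miR156)),
               unname(utils::adist(ref$miR156, two_off)))
  expect_error(classify_mirna("", ref), "empty")
})

test_that("subgenome assignment follows chromosome labels", {
  g <- genome_set(c(A03 = "ACGTACGT", C07 = "ACGTACGT",
                    scaffold_0012 = "ACGTACGT"))
  expect_equal(assign_subgenome("A03", g), "A")
  expect_equal(assign_subgenome("C07", g), "C")
  expect_equal(assign_subgenome("scaffold_0012", g), "unplaced")
  expect_error(assign_subgenome("B99", g), "unknown")
})

test_that("tightening the energy threshold never enlarges the accepted set", {
  set.seed(55)
  cfg <- simulation_config(seed = 55, n_mirna_loci_per_subgenome = 6,
                           chromosome_length = 1.2e5,
                           n_protein_genes_per_chromosome = 30,
                           n_losses = 0, n_gains = 0, library_depth = 2e4,
                           mutation_rate = 0, n_dh_lines = 0,
                           n_repeat_windows_per_chromosome = 2)
  sim <- simulate_genomes(cfg)
  sim <- simulate_srna_libraries(sim)
  libs <- sim$libraries["T_E1"]
  th_loose <- mirna_thresholds()
  th_tight <- utils::modifyList(th_loose, list(dg_max = -25))
  loose <- discover_mirnas(libs, sim$tetraploid, thresholds = th_loose)
  tight <- discover_mirnas(libs, sim$tetraploid, thresholds = th_tight)
  key <- function(x) paste(x$chrom, x$strand, x$mature_start)
  expect_true(all(key(tight) %in% key(loose)))
  expect_lte(nrow(tight), nrow(loose))
})
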