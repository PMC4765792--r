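make_genes <- function(chrom, n, start = 1000, spacing = 1000,
                       fam_offset = 0) {
  data.frame(seqid = chrom, source = ".", type = "gene",
             start = start + (seq_len(n) - 1) * spacing,
             end = start + (seq_len(n) - 1) * spacing + 300L,
             score = ".", strand = "+", phase = ".", attributes = "",
             ID = paste0("g", fam_offset + seq_len(n)),
             Parent = NA_character_,
             ortho_family = paste0("OG", fam_offset + seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("flanking-gene extraction returns the 10 nearest genes per side", {
  ann <- make_genes("A01", 24)
  # locus in the middle: 12 genes on each side
  locus_start <- ann$end[12] + 100L
  ctx <- extract_flanking_genes("A01", locus_start, locus_start + 100L, ann)
  expect_length(ctx$upstream, 10L)
  expect_length(ctx$downstream, 10L)
  # nearest first
  expect_equal(ctx$upstream[1], "OG12")
  expect_equal(ctx$downstream[1], "OG13")
  # locus three genes from the chromosome start
  ctx2 <- extract_flanking_genes("A01", ann$end[3] + 10L, ann$end[3] + 50L,
                                 ann)
  expect_length(ctx2$upstream, 3L)
  expect_length(ctx2$downstream, 10L)
  # two loci sharing a neighbourhood get identical contexts
  ctx3 <- extract_flanking_genes("A01", locus_start + 5L, locus_start + 80L,
                                 ann)
  expect_identical(ctx, ctx3)
  expect_error(extract_flanking_genes("Z01", 1, 2, ann), "Z01")
})

test_that("microsynteny classes follow the shared-flank definition", {
  q <- structure(list(upstream = paste0("OG", 1:10),
                      downstream = paste0("OG", 11:20)),
                 class = "FlankContext")
  expect_equal(test_microsynteny(q, q)$set_class, 1L)
  expect_true(test_microsynteny(q, q)$syntenic)
  none <- structure(list(upstream = paste0("X", 1:10),
                         downstream = paste0("Y", 1:10)),
                    class = "FlankContext")
  s4 <- test_microsynteny(q, none)
  expect_equal(s4$set_class, 4L)
  expect_false(s4$syntenic)
  up1 <- structure(list(upstream = c("OG5", paste0("X", 1:9)),
                        downstream = paste0("Y", 1:10)),
                   class = "FlankContext")
  s2 <- test_microsynteny(q, up1)
  expect_equal(s2$set_class, 2L)
  expect_true(s2$syntenic)
  expect_equal(s2$shared_upstream, 1L)
  dn1 <- structure(list(upstream = paste0("X", 1:10),
                        downstream = c("OG15")),
                   class = "FlankContext")
  expect_equal(test_microsynteny(q, dn1)$set_class, 3L)
  # symmetry of the syntenic verdict
  for (s in list(none, up1, dn1)) {
    expect_equal(test_microsynteny(q, s)$syntenic,
                 test_microsynteny(s, q)$syntenic)
  }
})

test_that("homology search retains verbatim copies and drops fragments", {
  set.seed(61)
  prec <- rand_seq(120)
  g_full <- rand_seq(30000)
  substr(g_full, 5001, 5120) <- prec
  genome <- genome_set(c(A01 = g_full))
  h <- find_mirna_homologs(c(q1 = prec), genome)
  expect_equal(nrow(h), 1L)
  expect_equal(h$coverage, 1.0)
  expect_equal(h$start, 5000L)
  expect_lt(h$evalue, 1e-5)
  # 50% fragment: coverage below 0.9 discards the hit
  g_frag <- rand_seq(30000)
  substr(g_frag, 5001, 5060) <- substr(prec, 1, 60)
  expect_equal(nrow(find_mirna_homologs(c(q1 = prec),
                                        genome_set(c(A01 = g_frag)))), 0L)
  # seven dispersed identical copies: exactly five hits returned
  g7 <- rand_seq(60000)
  for (k in 1:7) substr(g7, k * 7000 + 1, k * 7000 + 120) <- prec
  h7 <- find_mirna_homologs(c(q1 = prec), genome_set(c(A01 = g7)))
  expect_equal(nrow(h7), 5L)
  # reverse-strand copies are found
  grc <- rand_seq(30000)
  substr(grc, 9001, 9120) <- rc_chr(prec)
  hrc <- find_mirna_homologs(c(q1 = prec), genome_set(c(A01 = grc)))
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$start, 9000L)
  expect_error(find_mirna_homologs(c(q = rand_seq(30)), genome), "40 nt")
})

test_that("planted losses and gains are recovered exactly", {
  cfg <- simulation_config(seed = 19, n_mirna_loci_per_subgenome = 15,
                           chromosome_length = 2e5,
                           n_protein_genes_per_chromosome = 40,
                           n_losses = 4, n_gains = 3, mutation_rate = 0,
                           library_depth = 1e4, n_dh_lines = 0,
                           n_repeat_windows_per_chromosome = 2)
  sim <- simulate_genomes(cfg)
  truth <- sim$truth
  tet_tab <- truth$loci[truth$loci$present_in_tetraploid, ]
  prog <- truth$loci[truth$loci$origin == "ancestral", ]
  gl <- call_gain_loss(
    tet_tab, prog[prog$subgenome == "A", ], prog[prog$subgenome == "C", ],
    genomes = list(tet = sim$tetraploid, A = sim$progenitor_A,
                   C = sim$progenitor_C),
    annotations = list(tet = sim$annotations$tet, A = sim$annotations$A,
                       C = sim$annotations$C))
  expect_setequal(gl$lost$locus_id, truth$lost_locus_ids)
  expect_setequal(gl$gained$locus_id, truth$gained_locus_ids)
  # an unmutated conserved locus sits in neither list and matches its own
  # subgenome
  surv <- setdiff(prog$locus_id, truth$lost_locus_ids)
  expect_false(any(surv %in% gl$gained$locus_id))
  expect_equal(nrow(gl$opposite_subgenome), 0L)
})

test_that("family copy-number deltas follow (A_n + C_n) - (A_r + C_o)", {
  mk <- function(fams, sg = NULL) data.frame(
    family = fams,
    subgenome = if (is.null(sg)) rep("A", length(fams)) else sg,
    stringsAsFactors = FALSE)
  tet <- mk(c(rep("miR156", 36)), sg = c(rep("A", 17), rep("C", 19)))
  pa <- mk(rep("miR156", 17))
  pc <- mk(rep("miR156", 15))
  tab <- family_copy_table(tet, pa, pc)
  expect_equal(tab$A_n, 17)
  expect_equal(tab$C_n, 19)
  expect_equal(tab$delta, (17 + 19) - (17 + 15))
  # absent families are excluded; zero delta when counts balance
  tet2 <- mk(rep("miR172", 4), sg = c("A", "A", "C", "C"))
  tab2 <- family_copy_table(tet2, mk(rep("miR172", 2)), mk(rep("miR172", 2)))
  expect_equal(tab2$delta, 0)
  expect_false("miR156" %in% tab2$family)
})

test_that("the density track counts loci per fixed window", {
  g <- genome_set(c(A01 = strrep("ACGT", 2500))) # 10 kb
  loci <- data.frame(chrom = "A01", precursor_start = c(100, 1500, 9800))
  tr <- locus_density_track(loci, g, window = 5000)
  expect_equal(tr$n_loci, c(2, 1))
  expect_equal(tr$win_end[2], 10000)
})
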