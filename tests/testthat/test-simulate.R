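small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 5, n_mirna_loci_per_subgenome = 8,
         chromosome_length = 1.5e5, n_protein_genes_per_chromosome = 30,
         n_losses = 2, n_gains = 1, library_depth = 2e4,
         mutation_rate = 0, n_dh_lines = 2,
         n_repeat_windows_per_chromosome = 2, n_target_transcripts = 4),
    list(...))
  do.call(simulation_config, args)
}

test_that("the configuration is validated", {
  expect_error(simulation_config(subgenome_bias_rho = 0), "positive")
  expect_error(simulation_config(background_fraction = 1.2), "0, 1")
  expect_error(simulation_config(mutation_rate = -0.1), "0, 1")
  expect_error(simulation_config(repeat_bias_c = -1), "positive")
})

test_that("placement failures name the violated capacity constraint", {
  expect_error(simulate_genomes(simulation_config(
    seed = 1, n_mirna_loci_per_subgenome = 40, chromosome_length = 1e5,
    n_protein_genes_per_chromosome = 10)), "capacity")
  expect_error(simulate_genomes(simulation_config(
    seed = 1, n_mirna_loci_per_subgenome = 30, chromosome_length = 3e4,
    n_protein_genes_per_chromosome = 40, verify_discoverable = FALSE)),
    "capacity")
})

test_that("the identity case puts every progenitor locus in the tetraploid", {
  cfg <- small_cfg(n_losses = 0, n_gains = 0)
  sim <- simulate_genomes(cfg)
  truth <- sim$truth$loci
  expect_true(all(truth$present_in_tetraploid))
  # syntenic position: identical sequence at identical coordinates
  for (i in seq_len(nrow(truth))) {
    prog <- if (truth$subgenome[i] == "A") sim$progenitor_A else
      sim$progenitor_C
    expect_identical(
      substr(sim$tetraploid$seqs[[truth$chrom[i]]],
             truth$precursor_start[i] + 1, truth$precursor_end[i]),
      substr(prog$seqs[[truth$chrom[i]]],
             truth$precursor_start[i] + 1, truth$precursor_end[i]))
  }
})

test_that("loss and gain counts are exactly as configured", {
  sim <- simulate_genomes(small_cfg())
  expect_length(sim$truth$lost_locus_ids, 2L)
  expect_length(sim$truth$gained_locus_ids, 1L)
  # conservation: tetraploid loci = 2n - losses + gains
  expect_equal(sum(sim$truth$loci$present_in_tetraploid), 2 * 8 - 2 + 1)
  # lost loci absent from the tetraploid annotation, present in a progenitor
  ann_ids <- sim$annotations$tet$ID[sim$annotations$tet$type == "MIRNA"]
  expect_false(any(sim$truth$lost_locus_ids %in% ann_ids))
  prog_ids <- c(sim$annotations$A$ID, sim$annotations$C$ID)
  expect_true(all(sim$truth$lost_locus_ids %in% prog_ids))
  # gained loci present only in the tetraploid
  expect_true(all(sim$truth$gained_locus_ids %in% ann_ids))
  expect_false(any(sim$truth$gained_locus_ids %in% prog_ids))
})

test_that("every mature is a substring of its precursor and discoverable", {
  sim <- simulate_genomes(small_cfg())
  truth <- sim$truth$loci
  for (i in seq_len(nrow(truth))) {
    prec <- sim$truth$precursor_seqs[[truth$locus_id[i]]]
    expect_true(grepl(truth$mature_seq[i], prec, fixed = TRUE))
    # duplex acceptance by construction (bare precursor)
    f <- fold_hairpin(prec)
    off <- regexpr(truth$mature_seq[i], prec, fixed = TRUE)
    d <- evaluate_duplex(f, off, off + nchar(truth$mature_seq[i]) - 1L)
    expect_true(call_mirna(f, d, 2L)$accepted, info = truth$locus_id[i])
  }
  # every locus is flanked by at least 10 genes per side
  ann <- sim$annotations$tet
  for (i in which(truth$present_in_tetraploid)) {
    ctx <- extract_flanking_genes(truth$chrom[i], truth$precursor_start[i],
                                  truth$precursor_end[i], ann)
    expect_length(ctx$upstream, 10L)
    expect_length(ctx$downstream, 10L)
  }
})

test_that("identical config and seed give byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- simulate_genomes(small_cfg())
    sim <- simulate_srna_libraries(sim)
    sim <- simulate_transcripts(sim)
    sim <- simulate_degradome(sim)
    write_simulation(sim, d)
  }
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("library composition follows depth, background and bias settings", {
  sim <- simulate_srna_libraries(simulate_genomes(small_cfg()))
  lib <- sim$libraries$T_E1
  expect_equal(sum(as.numeric(lib$reads)), 2e4)
  expect_equal(lib$clean_total, 2e4)
  lc <- attr(lib, "locus_counts")
  # mature reads are (1 - background_fraction) of the depth
  expect_equal(sum(lc), round(2e4 * 0.7))
  # background 24-mers dominate the remaining reads
  bg <- lib$reads[!names(lib$reads) %in%
                  sim$truth$loci$tet_mature_seq]
  expect_equal(sum(as.numeric(bg)), 2e4 - sum(lc))
  expect_true(all(nchar(names(bg)) == 24L))
  expect_error(simulate_srna_libraries(
    utils::modifyList(sim, list(config = small_cfg(library_depth = 0)))),
    "positive")
})

test_that("a balanced bias (rho = 1) gives symmetric subgenome totals", {
  ratios <- vapply(1:6, function(s) {
    cfg <- small_cfg(subgenome_bias_rho = 1, background_fraction = 0,
                     n_losses = 0, n_gains = 0)
    cfg$seed <- 100 + s
    sim <- simulate_srna_libraries(simulate_genomes(cfg))
    mat <- expression_matrix_from_truth(sim, c("T_E1", "N_E1"))
    subgenome_partition_test(mat)$ratio
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.15)
})

test_that("degradome tags pile at planted sites; decoys stay signal-free", {
  sim <- simulate_genomes(small_cfg())
  sim <- simulate_srna_libraries(sim)
  sim <- simulate_transcripts(sim)
  # with zero noise every 5' end coincides with a planted position
  sim0 <- sim
  sim0$config$degradome_noise_fraction <- 0
  sim0 <- simulate_degradome(sim0)
  prof0 <- build_degradome_profile(sim0$degradome, sim0$transcripts)
  for (i in seq_len(nrow(sim0$truth$cleavage_sites))) {
    cs <- sim0$truth$cleavage_sites[i, ]
    p <- prof0[[cs$transcript_id]]
    expect_true(as.character(cs$position) %in% names(p))
    # the planted position is the mode
    expect_equal(as.integer(names(p)[which.max(p)]), cs$position)
  }
  # two sites on one transcript give a bimodal histogram
  tx <- sim0$transcripts[[1]]
  ln <- nchar(tx)
  m2 <- sim0$truth$loci$tet_mature_seq[
    sim0$truth$loci$present_in_tetraploid][2]
  pos2 <- sim0$truth$cleavage_sites$position[1] + 200L
  substr(tx, pos2 - 10L, pos2 - 10L + 20L) <- rc_chr(m2)
  tags2 <- stats::setNames(c(9L, 9L),
                           c(substr(tx, sim0$truth$cleavage_sites$position[1],
                                    sim0$truth$cleavage_sites$position[1] + 19L),
                             substr(tx, pos2, pos2 + 19L)))
  p2 <- build_degradome_profile(tags2, c(t = tx))$t
  modes <- as.integer(names(p2)[p2 == max(p2)])
  expect_setequal(modes, c(sim0$truth$cleavage_sites$position[1], pos2))
  # with default noise, decoy neighbourhoods carry no tags
  simn <- simulate_degradome(sim)
  profn <- build_degradome_profile(simn$degradome, simn$transcripts)
  for (i in seq_len(nrow(simn$truth$decoy_sites))) {
    ds <- simn$truth$decoy_sites[i, ]
    p <- profn[[ds$transcript_id]]
    if (length(p))
      expect_false(any(abs(as.integer(names(p)) - ds$position) <= 5))
  }
})
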