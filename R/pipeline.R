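#' Default pipeline configuration
#'
#' Every analysis threshold is exposed and defaults to its standard value:
#' hairpin free-energy cutoff -18 kcal/mol (strict), more than 16 matched
#' nucleotides, fewer than 4 bulges, mature/star spacing under 300 nt, at
#' least 2 reads in a library, conserved/novel boundary at 2 mismatches,
#' target expectation cutoff 3.0, degradome window 5 nt, 10 flanking genes,
#' top 5 homology hits, coverage > 0.9, significance < 1e-5, two-fold
#' heredity/DE threshold, pseudo-count 0.1 RPM.
#'
#' @param ... overrides (nested lists are merged).
#' @return a validated configuration list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = "polymir_run",
    seed = 1L,
    stages = list(simulate = TRUE, preprocess = TRUE, discover = TRUE,
                  targets = TRUE, degradome = TRUE, synteny = TRUE,
                  express = TRUE, report = TRUE),
    sim = list(n_mirna_loci_per_subgenome = 30L, chromosome_length = 4e5,
               n_protein_genes_per_chromosome = 60L, library_depth = 2e5,
               n_target_transcripts = 20L, mutation_rate = 0),
    min_len = 18L, max_len = 44L,
    dg_cutoff = -18, min_matched = 17L, max_bulges = 3L, max_spacing = 299L,
    min_reads = 2L, conservation_distance = 2L,
    expectation_cutoff = 3.0, degradome_window = 5L,
    flank_genes = 10L, top_hits = 5L, coverage = 0.9, significance = 1e-5,
    fold = 2, eps = 0.1, slack = 2L, flank = 300L,
    discovery_libraries = NULL)
  over <- list(...)
  for (k in names(over)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(over[[k]]))
      utils::modifyList(cfg[[k]], over[[k]]) else over[[k]]
  }
  stopifnot(cfg$dg_cutoff < 0, cfg$min_matched > 0, cfg$max_bulges >= 0,
            cfg$max_spacing > 0, cfg$min_reads >= 1,
            cfg$expectation_cutoff >= 0, cfg$degradome_window >= 0,
            cfg$flank_genes >= 1, cfg$top_hits >= 1,
            cfg$coverage > 0, cfg$coverage <= 1, cfg$significance > 0,
            cfg$fold > 1, cfg$eps >= 0)
  structure(cfg, class = c("PipelineConfig", "list"))
}

pipeline_thresholds <- function(cfg) {
  list(dg_max = cfg$dg_cutoff, min_matched = cfg$min_matched,
       max_bulges = cfg$max_bulges, max_spacing = cfg$max_spacing,
       min_reads = cfg$min_reads)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in dependency order (simulate, preprocess,
#' discover, targets, degradome, synteny, express, report), writing each
#' stage's tables plus a JSON sidecar of parameters and counts into the run
#' directory, and a final aggregated report. Rerunning with an identical
#' configuration (including the seed) reproduces identical outputs; the log
#' file (`pipeline.log`, wall-clock timings) is the only non-reproducible
#' artifact.
#'
#' @param config a [pipeline_config()].
#' @return the report (a list), invisibly; all outputs under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "pipeline.log")
  cat("", file = logf)
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  sidecar <- function(stage, params, counts) {
    jsonlite::write_json(list(stage = stage, parameters = params,
                              counts = counts),
                         file.path(cfg$out_dir, paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  state <- list()
  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' needs '", what,
           "' from an earlier stage that was not run")
  }
  t_all <- Sys.time()
  # --- simulate -------------------------------------------------------
  if (isTRUE(cfg$stages$simulate)) {
    t0 <- Sys.time()
    sim_cfg <- do.call(simulation_config, c(list(seed = cfg$seed), cfg$sim))
    sim <- simulate_genomes(sim_cfg)
    sim <- simulate_srna_libraries(sim)
    sim <- simulate_transcripts(sim)
    sim <- simulate_degradome(sim)
    write_simulation(sim, file.path(cfg$out_dir, "simulate"))
    state$sim <- sim
    sidecar("simulate", unclass(sim_cfg),
            list(loci = nrow(sim$truth$loci),
                 lost = length(sim$truth$lost_locus_ids),
                 gained = length(sim$truth$gained_locus_ids),
                 libraries = length(sim$libraries)))
    logmsg("simulate: ", nrow(sim$truth$loci), " loci, ",
           length(sim$libraries), " libraries (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")
  }
  # --- preprocess -----------------------------------------------------
  if (isTRUE(cfg$stages$preprocess)) {
    need("sim", "preprocess")
    t0 <- Sys.time()
    state$libraries <- lapply(state$sim$libraries, length_filter,
                              min_len = cfg$min_len, max_len = cfg$max_len)
    sidecar("preprocess", list(min_len = cfg$min_len, max_len = cfg$max_len),
            list(libraries = length(state$libraries),
                 clean_totals = lapply(state$libraries,
                                       function(l) l$clean_total)))
    logmsg("preprocess: length filter ", cfg$min_len, "-", cfg$max_len,
           " nt (", round(as.numeric(Sys.time() - t0, units = "secs"), 1),
           "s)")
  }
  # --- discover -------------------------------------------------------
  if (isTRUE(cfg$stages$discover)) {
    need("libraries", "discover")
    t0 <- Sys.time()
    disc_ids <- cfg$discovery_libraries
    if (is.null(disc_ids))
      disc_ids <- names(state$libraries)[
        vapply(state$libraries, function(l) l$line %in% c("T", "N"),
               logical(1))]
    loci <- discover_mirnas(state$libraries[disc_ids],
                            state$sim$tetraploid,
                            reference = state$sim$reference,
                            flank = cfg$flank,
                            thresholds = pipeline_thresholds(cfg))
    state$loci <- loci
    dir.create(file.path(cfg$out_dir, "discover"), showWarnings = FALSE)
    utils::write.table(loci, file.path(cfg$out_dir, "discover", "loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_mirna_gff3(loci, file.path(cfg$out_dir, "discover", "loci.gff3"))
    rej <- attr(loci, "rejections")
    if (!is.null(rej))
      utils::write.table(rej, file.path(cfg$out_dir, "discover",
                                        "rejections.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    sidecar("discover",
            c(pipeline_thresholds(cfg), list(flank = cfg$flank,
                                             libraries = disc_ids)),
            list(loci = nrow(loci),
                 conserved = sum(loci$class == "conserved", na.rm = TRUE),
                 novel = sum(loci$class == "novel", na.rm = TRUE),
                 rejected = if (is.null(rej)) 0L else nrow(rej)))
    logmsg("discover: ", nrow(loci), " loci accepted (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")
  }
  # --- targets --------------------------------------------------------
  if (isTRUE(cfg$stages$targets)) {
    need("loci", "targets")
    t0 <- Sys.time()
    mirnas <- stats::setNames(state$loci$mature_seq, state$loci$locus_id)
    interactions <- scan_transcriptome(mirnas, state$sim$transcripts,
                                       cutoff = cfg$expectation_cutoff)
    state$interactions <- interactions
    dir.create(file.path(cfg$out_dir, "targets"), showWarnings = FALSE)
    utils::write.table(interactions,
                       file.path(cfg$out_dir, "targets", "interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sidecar("targets", list(cutoff = cfg$expectation_cutoff),
            list(interactions = nrow(interactions),
                 mirnas_with_targets = length(unique(interactions$mirna_id))))
    logmsg("targets: ", nrow(interactions), " interactions (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")
  }
  # --- degradome ------------------------------------------------------
  if (isTRUE(cfg$stages$degradome)) {
    need("interactions", "degradome")
    t0 <- Sys.time()
    profiles <- build_degradome_profile(state$sim$degradome,
                                        state$sim$transcripts)
    interactions <- validate_cleavage(state$interactions, profiles,
                                      window = cfg$degradome_window)
    state$interactions <- interactions
    write_tplot_data(profiles, file.path(cfg$out_dir, "targets",
                                         "tplot_data.tsv"))
    utils::write.table(interactions,
                       file.path(cfg$out_dir, "targets",
                                 "interactions_validated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sidecar("degradome", list(window = cfg$degradome_window),
            list(validated = sum(interactions$status == "validated"),
                 unvalidated = sum(interactions$status == "unvalidated")))
    logmsg("degradome: ", sum(interactions$status == "validated"),
           " validated interactions (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")
  }
  # --- synteny --------------------------------------------------------
  if (isTRUE(cfg$stages$synteny)) {
    need("loci", "synteny")
    t0 <- Sys.time()
    ann <- state$sim$annotations
    prog_loci <- function(a) {
      m <- a[a$type == "MIRNA", , drop = FALSE]
      data.frame(locus_id = m$ID, chrom = m$seqid,
                 precursor_start = m$start, precursor_end = m$end,
                 stringsAsFactors = FALSE)
    }
    gl <- call_gain_loss(
      state$loci, prog_loci(ann$A), prog_loci(ann$C),
      genomes = list(tet = state$sim$tetraploid,
                     A = state$sim$progenitor_A,
                     C = state$sim$progenitor_C),
      annotations = list(tet = ann$tet, A = ann$A, C = ann$C),
      k = cfg$flank_genes, min_coverage = cfg$coverage,
      max_evalue = cfg$significance, top_n = cfg$top_hits)
    state$gain_loss <- gl
    dir.create(file.path(cfg$out_dir, "synteny"), showWarnings = FALSE)
    for (nm in names(gl))
      utils::write.table(gl[[nm]],
                         file.path(cfg$out_dir, "synteny",
                                   paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    track <- locus_density_track(state$loci, state$sim$tetraploid)
    utils::write.table(track, file.path(cfg$out_dir, "synteny",
                                        "density_track.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sidecar("synteny",
            list(flank_genes = cfg$flank_genes, top_hits = cfg$top_hits,
                 coverage = cfg$coverage, significance = cfg$significance),
            list(lost = nrow(gl$lost), gained = nrow(gl$gained),
                 opposite_subgenome = nrow(gl$opposite_subgenome)))
    logmsg("synteny: ", nrow(gl$lost), " lost, ", nrow(gl$gained),
           " gained (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")
  }
  # --- express --------------------------------------------------------
  if (isTRUE(cfg$stages$express)) {
    need("loci", "express")
    t0 <- Sys.time()
    mat <- build_expression_matrix(state$libraries, state$loci,
                                   state$sim$tetraploid, slack = cfg$slack)
    state$expression <- mat
    dir.create(file.path(cfg$out_dir, "express"), showWarnings = FALSE)
    write_expression_matrix(mat, file.path(cfg$out_dir, "express",
                                           "expression_matrix.tsv"))
    meta <- mat$libraries
    partition <- list()
    for (env in unique(meta$environment)) {
      for (set in list(c("T", "N"), grep("^DH", unique(meta$line),
                                         value = TRUE))) {
        if (!length(set) || !all(set %in% meta$line)) next
        ids <- meta$id[meta$line %in% set & meta$environment == env]
        for (mode in c("per_mature", "per_mb")) {
          pr <- subgenome_partition_test(mat, ids, mode = mode,
                                         genome = state$sim$tetraploid)
          partition[[length(partition) + 1L]] <- data.frame(
            statistic = mode, environment = env,
            library_set = paste(set, collapse = "/"),
            mean_A = pr$mean_A, mean_C = pr$mean_C, ratio_CA = pr$ratio,
            p_value = pr$p_value, test = pr$test, stringsAsFactors = FALSE)
        }
      }
    }
    partition <- do.call(rbind, partition)
    utils::write.table(partition, file.path(cfg$out_dir, "express",
                                            "partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    heredity <- NULL
    dh <- meta$id[grepl("^DH", meta$line)]
    if (length(dh)) {
      heredity <- heredity_classification(
        mat, meta$id[meta$line == "T"], meta$id[meta$line == "N"], dh,
        fold = cfg$fold, eps = cfg$eps)
      utils::write.table(heredity, file.path(cfg$out_dir, "express",
                                             "heredity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(attr(heredity, "summary"),
                           file.path(cfg$out_dir, "express",
                                     "heredity_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    state$partition <- partition
    state$heredity <- heredity
    density <- mirna_density(state$loci, state$sim$tetraploid)
    state$density <- density
    sidecar("express", list(slack = cfg$slack, fold = cfg$fold,
                            eps = cfg$eps),
            list(partition_rows = nrow(partition),
                 heredity = if (is.null(heredity)) NULL else
                   attr(heredity, "summary")))
    logmsg("express: ", nrow(partition), " partition rows (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")
  }
  # --- report ---------------------------------------------------------
  report <- NULL
  if (isTRUE(cfg$stages$report)) {
    need("loci", "report")
    loci <- state$loci
    report <- list(
      seed = cfg$seed,
      backend = list(energy_model = "simplified nearest-neighbor",
                     package_version =
                       as.character(utils::packageVersion("polymir"))),
      loci = list(total = nrow(loci),
                  conserved = sum(loci$class == "conserved", na.rm = TRUE),
                  novel = sum(loci$class == "novel", na.rm = TRUE),
                  per_subgenome = as.list(table(loci$subgenome))),
      density_per_mb = as.list(state$density),
      gain_loss = if (!is.null(state$gain_loss)) list(
        lost = nrow(state$gain_loss$lost),
        gained = nrow(state$gain_loss$gained),
        opposite_subgenome = nrow(state$gain_loss$opposite_subgenome)),
      targets = if (!is.null(state$interactions)) list(
        interactions = nrow(state$interactions),
        validated = sum(state$interactions$status == "validated")),
      partition = if (!is.null(state$partition))
        lapply(seq_len(nrow(state$partition)), function(i)
          as.list(state$partition[i, c("statistic", "environment",
                                       "library_set", "mean_A", "mean_C",
                                       "ratio_CA", "p_value")])),
      heredity = if (!is.null(state$heredity)) attr(state$heredity,
                                                    "summary"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logmsg("report written (total ",
           round(as.numeric(Sys.time() - t_all, units = "secs"), 1), "s)")
  }
  invisible(report)
}
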