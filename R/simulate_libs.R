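derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483629)
}

# planted per-locus expression expectations for every line x environment.
# Base abundance is log-normal per homeolog pair; the C copy is scaled by
# subgenome_bias_rho relative to its A homeolog; the second parent and the
# second environment get independent log-normal perturbations; DH lines
# follow the mid-parent mean except for the planted non-additive loci.
plant_expression <- function(truth, config) {
  tab <- truth$loci[truth$loci$present_in_tetraploid, , drop = FALSE]
  pair_ids <- unique(tab$pair_id)
  base_pair <- stats::setNames(
    stats::rlnorm(length(pair_ids), config$expr_meanlog, config$expr_sdlog),
    pair_ids)
  base <- base_pair[tab$pair_id]
  base <- ifelse(tab$origin == "gained",
                 stats::rlnorm(nrow(tab), config$expr_meanlog,
                               config$expr_sdlog), base)
  base <- ifelse(tab$subgenome == "C", base * config$subgenome_bias_rho, base)
  delta_n <- stats::rlnorm(nrow(tab), 0, config$parent_divergence_sdlog)
  gamma_e2 <- stats::rlnorm(nrow(tab), 0, config$env_effect_sdlog)
  expr <- data.frame(locus_id = tab$locus_id,
                     T_E1 = base, N_E1 = base * delta_n,
                     T_E2 = base * gamma_e2,
                     N_E2 = base * delta_n * gamma_e2,
                     stringsAsFactors = FALSE)
  n_non <- round(config$nonadditive_fraction * nrow(tab))
  non_idx <- if (n_non > 0) sample(nrow(tab), n_non) else integer()
  factors <- rep(1, nrow(tab))
  if (length(non_idx))
    factors[non_idx] <- sample(config$nonadditive_factors, length(non_idx),
                               replace = TRUE)
  expr$DH_E1 <- (expr$T_E1 + expr$N_E1) / 2 * factors
  expr$DH_E2 <- (expr$T_E2 + expr$N_E2) / 2 * factors
  list(expression = expr,
       dh_nonadditive_ids = tab$locus_id[non_idx],
       dh_factors = stats::setNames(factors, tab$locus_id))
}

#' Simulate the small-RNA libraries of the study design
#'
#' Generates one collapsed library per line and environment (two parental
#' lines `T` and `N` plus `n_dh_lines` double-haploid lines, each in `E1`
#' and `E2`). Mature-miRNA reads are drawn multinomially with per-locus
#' expectations from the planted expression model; background reads are
#' 24-nt sequences drawn from annotated repeat windows with a C:A
#' subgenome ratio of `repeat_bias_c`.
#'
#' @param sim result of [simulate_genomes()].
#' @return `sim` with `$libraries` (list of [srna_library()]) added and the
#'   truth ledger extended with the expression table, non-additive locus
#'   ids and per-locus true counts (`attr(lib, "locus_counts")` per
#'   library).
#' @export
simulate_srna_libraries <- function(sim) {
  config <- sim$config
  truth <- sim$truth
  if (!nrow(truth$loci)) stop("planted truth has no loci")
  if (config$library_depth <= 0) stop("library_depth must be positive")
  if (config$subgenome_bias_rho <= 0)
    stop("subgenome_bias_rho must be positive")
  set.seed(derive_seed(config$seed, 2L))
  planted <- plant_expression(truth, config)
  truth$expression <- planted$expression
  truth$dh_nonadditive_ids <- planted$dh_nonadditive_ids
  truth$dh_factors <- planted$dh_factors
  tab <- truth$loci[truth$loci$present_in_tetraploid, , drop = FALSE]
  lines <- c("T", "N",
             if (config$n_dh_lines > 0) paste0("DH", seq_len(config$n_dh_lines)))
  reps <- tet_repeat_windows(sim)
  libs <- list()
  for (env in c("E1", "E2")) {
    for (line in lines) {
      col <- paste0(if (grepl("^DH", line)) "DH" else line, "_", env)
      expect <- planted$expression[[col]]
      lib <- draw_library(tab, expect, reps, config,
                          id = paste0(line, "_", env), line = line,
                          environment = env)
      libs[[lib$id]] <- lib
    }
  }
  sim$truth <- truth
  sim$libraries <- libs
  sim
}

tet_repeat_windows <- function(sim) {
  ann <- sim$annotations$tet
  reps <- ann[ann$type == "repeat_region", , drop = FALSE]
  if (!nrow(reps)) return(NULL)
  data.frame(chrom = reps$seqid, start = reps$start, end = reps$end,
             subgenome = assign_subgenome(reps$seqid, sim$tetraploid),
             seq = substring(sim$tetraploid$seqs[reps$seqid],
                             reps$start + 1L, reps$end),
             stringsAsFactors = FALSE)
}

draw_library <- function(tab, expect, reps, config, id, line, environment) {
  depth <- config$library_depth
  n_bg <- round(depth * config$background_fraction)
  n_mat <- depth - n_bg
  locus_counts <- stats::setNames(
    as.vector(stats::rmultinom(1, n_mat, prob = expect)), tab$locus_id)
  mat_counts <- tapply(locus_counts, tab$tet_mature_seq, sum)
  bg_counts <- integer()
  if (n_bg > 0 && !is.null(reps)) {
    pc <- config$repeat_bias_c / (1 + config$repeat_bias_c)
    n_c <- stats::rbinom(1, n_bg, pc)
    bg_seqs <- c(draw_background(reps[reps$subgenome == "C", ], n_c, config),
                 draw_background(reps[reps$subgenome == "A", ], n_bg - n_c,
                                 config))
    t_ <- table(bg_seqs)
    bg_counts <- stats::setNames(as.integer(t_), names(t_))
  }
  all_counts <- c(mat_counts, bg_counts)
  agg <- tapply(as.numeric(all_counts), names(all_counts), sum)
  agg <- agg[agg > 0] # loci may draw zero reads at low depth
  lib <- srna_library(stats::setNames(as.integer(agg), names(agg)), id = id,
                      line = line, tissue = "seedling",
                      environment = environment,
                      clean_total = depth)
  attr(lib, "locus_counts") <- locus_counts
  lib
}

draw_background <- function(windows, n, config) {
  if (n <= 0 || !nrow(windows)) return(character())
  len <- config$background_read_length
  wi <- sample(nrow(windows), n, replace = TRUE)
  out <- character(n)
  for (w in unique(wi)) {
    sel <- which(wi == w)
    maxs <- nchar(windows$seq[w]) - len + 1L
    starts <- sample(maxs, length(sel), replace = TRUE)
    out[sel] <- substring(windows$seq[w], starts, starts + len - 1L)
  }
  flip <- stats::runif(n) < 0.5
  if (any(flip)) out[flip] <- reverse_complement(out[flip])
  out
}

#' Expression matrix from generator-recorded true counts
#'
#' Builds an [build_expression_matrix()]-compatible object directly from the
#' per-locus read counts the generator recorded while drawing each library
#' (no mapping involved). Useful for statistical properties of the
#' downstream estimators that do not depend on the read-mapping path.
#'
#' @param sim result of [simulate_srna_libraries()].
#' @param library_ids libraries to include (default: all).
#' @return an `ExpressionMatrix`.
#' @export
expression_matrix_from_truth <- function(sim, library_ids = NULL) {
  libs <- sim$libraries
  if (!is.null(library_ids)) libs <- libs[library_ids]
  loci <- sim$truth$loci[sim$truth$loci$present_in_tetraploid, , drop = FALSE]
  counts <- vapply(libs, function(l) attr(l, "locus_counts")[loci$locus_id],
                   numeric(nrow(loci)))
  dimnames(counts) <- list(loci$locus_id,
                           vapply(libs, function(l) l$id, character(1)))
  totals <- vapply(libs, function(l) l$clean_total, numeric(1))
  rpm <- sweep(counts, 2, totals, "/") * 1e6
  meta <- data.frame(
    id = colnames(counts),
    line = vapply(libs, function(l) l$line, character(1)),
    tissue = vapply(libs, function(l) l$tissue, character(1)),
    environment = vapply(libs, function(l) l$environment, character(1)),
    clean_total = totals, stringsAsFactors = FALSE)
  structure(list(loci = loci, counts = counts, rpm = rpm, libraries = meta),
            class = "ExpressionMatrix")
}

#' Simulate target transcripts with planted cleavage sites
#'
#' For `n_target_transcripts` tetraploid loci (in locus order) a transcript
#' is generated containing a near-perfect reverse-complement site of the
#' mature miRNA (perfect, or with one non-seed mismatch). The planted
#' cleavage position (opposite miRNA positions 10-11) and one certified
#' signal-free decoy position at offset at least 8 nt are recorded in the
#' truth ledger.
#'
#' @param sim result of [simulate_genomes()] (libraries not required).
#' @return `sim` with `$transcripts` (named character vector) added and
#'   `truth$cleavage_sites` / `truth$decoy_sites` filled.
#' @export
simulate_transcripts <- function(sim) {
  config <- sim$config
  set.seed(derive_seed(config$seed, 3L))
  tab <- sim$truth$loci[sim$truth$loci$present_in_tetraploid, , drop = FALSE]
  n <- min(config$n_target_transcripts, nrow(tab))
  tab <- tab[seq_len(n), , drop = FALSE]
  L <- config$transcript_length
  transcripts <- character(n)
  cleav <- list(); decoys <- list()
  for (i in seq_len(n)) {
    mat <- tab$tet_mature_seq[i]
    mlen <- nchar(mat)
    site <- reverse_complement(mat)
    if (stats::runif(1) < 0.4) {
      # one mismatch opposite a non-seed miRNA position (14..mlen)
      k <- sample(14:mlen, 1)          # miRNA position
      site <- substitute_at(site, mlen - k + 1L)
    }
    tx <- random_seq(L)
    s <- sample(seq(101L, L - mlen - 100L), 1)
    substr(tx, s, s + mlen - 1L) <- site
    tid <- paste0("tx-", tab$locus_id[i])
    transcripts[i] <- tx
    names(transcripts)[i] <- tid
    e <- s + mlen - 1L
    pos <- e - 9L
    cleav[[i]] <- data.frame(mirna_id = tab$locus_id[i], transcript_id = tid,
                             position = pos, stringsAsFactors = FALSE)
    off <- sample(8:15, 1) * sample(c(-1L, 1L), 1)
    dpos <- min(max(pos + off, 1L), L)
    decoys[[i]] <- data.frame(transcript_id = tid, position = dpos,
                              stringsAsFactors = FALSE)
  }
  sim$transcripts <- transcripts
  sim$truth$cleavage_sites <- do.call(rbind, cleav)
  sim$truth$decoy_sites <- do.call(rbind, decoys)
  sim
}

#' Simulate a degradome (PARE) tag library
#'
#' For every planted cleavage site, tags whose 5' end sits exactly at the
#' site form the modal signal (counts spread over several tag lengths).
#' Uniform positional noise tags are added per transcript, resampled away
#' from the certified signal-free decoy neighbourhoods recorded in the
#' truth ledger (the decoys exist precisely to certify absence of signal).
#'
#' @param sim result of [simulate_transcripts()].
#' @param noise_exclusion_window half-width of the decoy exclusion zone in
#'   nt (default 5, matching the downstream validation window).
#' @return `sim` with `$degradome` (named integer vector of tag counts)
#'   added.
#' @export
simulate_degradome <- function(sim, noise_exclusion_window = 5L) {
  config <- sim$config
  if (is.null(sim$truth$cleavage_sites) || !nrow(sim$truth$cleavage_sites))
    stop("no planted cleavage sites: run simulate_transcripts() first")
  set.seed(derive_seed(config$seed, 4L))
  tags <- character(); counts <- integer()
  sites <- sim$truth$cleavage_sites
  for (i in seq_len(nrow(sites))) {
    tx <- sim$transcripts[[sites$transcript_id[i]]]
    pos <- sites$position[i]
    lens <- 19:24
    split <- as.vector(stats::rmultinom(1, config$degradome_signal_tags,
                                        rep(1, length(lens))))
    for (j in seq_along(lens)) {
      if (split[j] == 0L) next
      tag <- substr(tx, pos, min(pos + lens[j] - 1L, nchar(tx)))
      tags <- c(tags, tag); counts <- c(counts, split[j])
    }
  }
  total_signal <- sum(counts)
  nf <- config$degradome_noise_fraction
  n_noise <- round(nf / (1 - nf) * total_signal)
  if (n_noise > 0) {
    decoys <- sim$truth$decoy_sites
    tx_ids <- names(sim$transcripts)
    for (k in seq_len(n_noise)) {
      repeat {
        tid <- sample(tx_ids, 1)
        tx <- sim$transcripts[[tid]]
        pos <- sample(nchar(tx) - 20L, 1)
        dp <- decoys$position[decoys$transcript_id == tid]
        if (!length(dp) || all(abs(pos - dp) > noise_exclusion_window)) break
      }
      tags <- c(tags, substr(tx, pos, pos + 19L))
      counts <- c(counts, 1L)
    }
  }
  agg <- tapply(counts, tags, sum)
  sim$degradome <- stats::setNames(as.integer(agg), names(agg))
  sim
}

#' Write a complete simulation to disk
#'
#' Emits the external representation of the synthetic study: genome FASTAs,
#' GFF3 annotations, collapsed small-RNA FASTAs, degradome and transcript
#' FASTAs, the mature reference, the truth ledger (TSV + JSON) and the
#' configuration (YAML).
#'
#' @param sim result of the `simulate_*` chain.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_genome_fasta(sim$progenitor_A, p("progenitor_A.fa"))
  write_genome_fasta(sim$progenitor_C, p("progenitor_C.fa"))
  write_genome_fasta(sim$tetraploid, p("tetraploid.fa"))
  write_gff3(sim$annotations$A, p("progenitor_A.gff3"))
  write_gff3(sim$annotations$C, p("progenitor_C.gff3"))
  write_gff3(sim$annotations$tet, p("tetraploid.gff3"))
  write_fasta(stats::setNames(unlist(sim$reference), names(sim$reference)),
              p("mature_reference.fa"))
  if (!is.null(sim$libraries))
    for (lib in sim$libraries)
      write_srna_fasta(lib, p(paste0("srna_", lib$id, ".fa")))
  if (!is.null(sim$transcripts))
    write_fasta(sim$transcripts, p("transcripts.fa"))
  if (!is.null(sim$degradome)) {
    ord <- order(-sim$degradome, names(sim$degradome))
    write_fasta(stats::setNames(
      names(sim$degradome)[ord],
      sprintf("tag%d_x%d", seq_along(ord), sim$degradome[ord])),
      p("degradome.fa"))
  }
  utils::write.table(sim$truth$loci, p("truth_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_json <- list(
    lost_locus_ids = sim$truth$lost_locus_ids,
    gained_locus_ids = sim$truth$gained_locus_ids,
    dh_nonadditive_ids = sim$truth$dh_nonadditive_ids)
  if (!is.null(sim$truth$expression))
    truth_json$expression <- sim$truth$expression
  if (!is.null(sim$truth$cleavage_sites))
    truth_json$cleavage_sites <- sim$truth$cleavage_sites
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(unclass(sim$config), p("config.yaml"))
  invisible(dir)
}
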