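#' Default simulation configuration
#'
#' Parameters of the synthetic allopolyploid study design: two progenitor
#' genomes (A and C) carrying homeologous MIRNA pairs, an allotetraploid
#' derived from them with planted locus losses and gains, two parental
#' lines plus derived double-haploid (DH) lines sequenced in two
#' environments, a planted C:A subgenome expression bias, and
#' repeat-derived background reads biased to the C subgenome.
#'
#' @param ... overrides for any default.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chromosomes_per_subgenome = 2L,
    chromosome_length = 1e6,
    n_mirna_loci_per_subgenome = 100L,
    n_protein_genes_per_chromosome = 150L,
    n_losses = 10L,
    n_gains = 5L,
    subgenome_bias_rho = 0.55,
    library_depth = 1e6,
    background_fraction = 0.3,
    repeat_bias_c = 10.3,
    n_dh_lines = 4L,
    nonadditive_fraction = 0.3,
    nonadditive_factors = c(4, 0.25),
    mutation_rate = 0.002,
    mature_length = 21L,
    loop_range = c(40L, 80L),
    conserved_fraction = 0.43,
    n_reference_families = 30L,
    expr_meanlog = 0,
    expr_sdlog = 1,
    parent_divergence_sdlog = 0.3,
    env_effect_sdlog = 0.2,
    background_read_length = 24L,
    n_repeat_windows_per_chromosome = 10L,
    repeat_window_length = 2000L,
    gap_range = c(200L, 800L),
    gene_length = 300L,
    transcript_length = 2000L,
    n_target_transcripts = 50L,
    degradome_signal_tags = 20L,
    degradome_noise_fraction = 0.2,
    verify_discoverable = TRUE)
  cfg <- utils::modifyList(cfg, list(...))
  with(cfg, {
    stopifnot(seed == as.integer(seed),
              n_chromosomes_per_subgenome >= 1,
              chromosome_length > 0,
              n_mirna_loci_per_subgenome >= 1,
              n_protein_genes_per_chromosome >= 1,
              n_losses >= 0, n_gains >= 0,
              library_depth >= 0, n_dh_lines >= 0,
              mature_length >= 18, mature_length <= 25)
    if (subgenome_bias_rho <= 0) stop("subgenome_bias_rho must be positive")
    if (background_fraction < 0 || background_fraction > 1)
      stop("background_fraction must lie in [0, 1]")
    if (nonadditive_fraction < 0 || nonadditive_fraction > 1)
      stop("nonadditive_fraction must lie in [0, 1]")
    if (mutation_rate < 0 || mutation_rate > 1)
      stop("mutation_rate must lie in [0, 1]")
    if (repeat_bias_c <= 0) stop("repeat_bias_c must be positive")
  })
  structure(cfg, class = c("SimulationConfig", "list"))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

gc_fraction <- function(s) {
  nchar(gsub("[^GC]", "", s)) / nchar(s)
}

# mature sequences are drawn with GC >= 0.4 (typical of plant matures), so
# that a perfect 21-bp stem clears the -18 kcal/mol gate with margin; an
# AT-extreme mature could never form an acceptable hairpin
random_mature <- function(n) {
  repeat {
    s <- random_seq(n)
    if (gc_fraction(s) >= 0.4) return(s)
  }
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

substitute_at <- function(seq, pos, base = NULL) {
  v <- strsplit(seq, "")[[1]]
  for (p in pos) {
    v[p] <- if (is.null(base)) sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
            else base
  }
  paste(v, collapse = "")
}

# star arm: reverse complement of the mature with 1-3 planted G:U wobbles
# and at most one true mismatch, so the duplex keeps a comfortable margin
# over the >16-matched / <4-bulged acceptance gates (a mismatch bulges one
# nucleotide on each strand; wobbles still pair)
make_star <- function(mature) {
  len <- nchar(mature)
  star <- reverse_complement(mature)
  k <- sample(1:3, 1)
  pos <- sample(seq_len(len), k) # positions on the mature
  n_mod <- 0L
  n_mm <- 0L
  for (p in pos) {
    q <- len - p + 1L # partner index on the star
    mb <- substr(mature, p, p)
    if (mb == "G") {
      star <- substitute_at(star, q, "T") # G:U wobble (still pairs)
      n_mod <- n_mod + 1L
    } else if (mb == "T") {
      star <- substitute_at(star, q, "G")
      n_mod <- n_mod + 1L
    } else if (n_mm < 1L) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")[[mb]]
      star <- substitute_at(star, q,
                            sample(setdiff(c("A", "C", "G", "T"), comp), 1))
      n_mm <- n_mm + 1L
      n_mod <- n_mod + 1L
    }
  }
  if (n_mod == 0L) {
    # guarantee at least one modification so the star never equals the
    # exact reverse complement (which would map the mature to both strands)
    p <- pos[1]
    q <- len - p + 1L
    comp <- c(A = "T", C = "G", G = "C", T = "A")[[substr(mature, p, p)]]
    star <- substitute_at(star, q,
                          sample(setdiff(c("A", "C", "G", "T"), comp), 1))
  }
  star
}

make_hairpin <- function(mature, arm, loop_range, loop_len = NULL) {
  if (is.null(loop_len))
    loop_len <- sample(loop_range[1]:loop_range[2], 1)
  loop <- random_seq(loop_len)
  star <- make_star(mature)
  if (arm == "5p") paste0(mature, loop, star) else paste0(star, loop, mature)
}

#' Simulate progenitor and allotetraploid genomes with planted truth
#'
#' Ancestral MIRNA hairpin loci (discoverable by construction) are placed
#' on the progenitor chromosomes in homeologous A/C pairs, each flanked by
#' at least 10 protein-coding gene loci per side (genes carry `ortho_family`
#' labels shared between a progenitor and its tetraploid subgenome). The
#' tetraploid inherits mutated copies of both progenitors; `n_losses`
#' randomly chosen loci are disrupted in place and `n_gains` loci are
#' duplicated into new gene neighbourhoods elsewhere in the tetraploid.
#' Every event is recorded in the planted-truth ledger.
#'
#' @param config a [simulation_config()].
#' @return list with elements `progenitor_A`, `progenitor_C`, `tetraploid`
#'   ([genome_set()]s), `annotations` (list `A`, `C`, `tet` of GFF-style
#'   feature tables), `truth` (`PlantedTruth`: `loci` table,
#'   `lost_locus_ids`, `gained_locus_ids`, `expression`,
#'   `dh_nonadditive_ids`, `dh_factors`), `reference` (family -> mature
#'   list for classification), `config`.
#' @export
simulate_genomes <- function(config = simulation_config()) {
  set.seed(config$seed)
  n_sub <- config$n_mirna_loci_per_subgenome
  n_chr <- config$n_chromosomes_per_subgenome
  # reference set of known mature miRNAs (miRBase-like)
  ref_names <- sprintf("miR%d", 100 + seq_len(config$n_reference_families))
  reference <- stats::setNames(
    lapply(ref_names, function(x) random_mature(config$mature_length)),
    ref_names)
  # ancestral homeolog pairs: family, A mature, C mature (>=1 substitution
  # apart so exact mapping assigns reads unambiguously to a subgenome)
  pairs <- vector("list", n_sub)
  used <- character()
  ref_vec <- chartr("U", "T", unlist(reference))
  for (i in seq_len(n_sub)) {
    repeat {
      if (stats::runif(1) < config$conserved_fraction) {
        fam <- sample(ref_names, 1)
        matA <- substitute_at(reference[[fam]],
                              sample(config$mature_length,
                                     sample(0:1, 1)))
        cls <- "conserved"
      } else {
        fam <- NA_character_
        matA <- random_mature(config$mature_length)
        if (min(utils::adist(matA, ref_vec)) <= 3) next
        cls <- "novel"
      }
      matC <- substitute_at(matA, sample(config$mature_length, 1))
      if (gc_fraction(matA) < 0.4 || gc_fraction(matC) < 0.4) next
      if (cls == "conserved" && min(utils::adist(matC, ref_vec)) > 2) next
      if (cls == "novel" && min(utils::adist(matC, ref_vec)) <= 2) next
      if (!(matA %in% used) && !(matC %in% used) && matA != matC) break
    }
    used <- c(used, matA, matC)
    pairs[[i]] <- list(pair_id = sprintf("pair%04d", i), family = fam,
                       class = cls, mature = list(A = matA, C = matC),
                       arm = sample(c("5p", "3p"), 1),
                       strand = sample(c("+", "-"), 1))
  }
  per_chr <- diff(floor(seq(0, n_sub, length.out = n_chr + 1)))
  gap <- function() sample(config$gap_range[1]:config$gap_range[2], 1)
  build <- list(A = NULL, C = NULL)
  og_counter <- 0L
  for (sg in c("A", "C")) {
    chroms <- list(); feats <- list(); loci_rows <- list()
    pair_idx <- 0L
    for (ci in seq_len(n_chr)) {
      chrom <- sprintf("%s%02d", sg, ci)
      m <- per_chr[ci]
      n_genes <- config$n_protein_genes_per_chromosome
      if (n_genes < m + 19L)
        stop("capacity: n_protein_genes_per_chromosome (", n_genes,
             ") must be at least loci-per-chromosome + 19 (", m + 19L,
             ") so every locus keeps 10 flanking genes per side")
      seqc <- random_seq(config$chromosome_length)
      cursor <- 1L
      place_gene <- function() {
        og_counter <<- og_counter + 1L
        s <- cursor
        e <- cursor + config$gene_length - 1L
        feats[[length(feats) + 1L]] <<- data.frame(
          seqid = chrom, source = "polymir_sim", type = "gene",
          start = s - 1L, end = e, score = ".",
          strand = sample(c("+", "-"), 1), phase = ".",
          attributes = "", ID = sprintf("g-%s-OG%05d", sg, og_counter),
          Parent = NA_character_,
          ortho_family = sprintf("OG%05d", og_counter),
          stringsAsFactors = FALSE)
        cursor <<- e + gap()
      }
      for (k in seq_len(10L)) place_gene()
      for (li in seq_len(m)) {
        pair_idx <- pair_idx + 1L
        p <- pairs[[sum(per_chr[seq_len(ci - 1L)]) + li]]
        mat <- p$mature[[sg]]
        hp <- make_hairpin(mat, p$arm, config$loop_range)
        s <- cursor
        e <- cursor + nchar(hp) - 1L
        patch <- if (p$strand == "+") hp else reverse_complement(hp)
        substr(seqc, s, e) <- patch
        # mature genomic interval inside the precursor
        off <- if (p$arm == "5p") 0L else nchar(hp) - nchar(mat)
        if (p$strand == "+") {
          ms <- s - 1L + off
        } else {
          ms <- s - 1L + (nchar(hp) - nchar(mat) - off)
        }
        lid <- sprintf("%s-%s", p$pair_id, sg)
        loci_rows[[length(loci_rows) + 1L]] <- data.frame(
          locus_id = lid, pair_id = p$pair_id, origin = "ancestral",
          subgenome = sg, chrom = chrom, strand = p$strand,
          precursor_start = s - 1L, precursor_end = e,
          mature_start = ms, mature_end = ms + nchar(mat),
          mature_seq = mat, arm = p$arm, family = p$family, class = p$class,
          precursor_seq = hp, stringsAsFactors = FALSE)
        cursor <- e + gap()
        place_gene()
      }
      while (sum(vapply(feats, function(f) f$seqid == chrom, logical(1))) <
             n_genes)
        place_gene()
      # repeat windows in the chromosome tail (siRNA background source)
      for (k in seq_len(config$n_repeat_windows_per_chromosome)) {
        s <- cursor
        e <- cursor + config$repeat_window_length - 1L
        if (e > config$chromosome_length)
          stop("capacity: chromosome_length ", config$chromosome_length,
               " too small to place genes, loci and repeat windows ",
               "(needed > ", e, " nt)")
        feats[[length(feats) + 1L]] <- data.frame(
          seqid = chrom, source = "polymir_sim", type = "repeat_region",
          start = s - 1L, end = e, score = ".", strand = "+", phase = ".",
          attributes = "", ID = sprintf("rep-%s-%02d", chrom, k),
          Parent = NA_character_, ortho_family = NA_character_,
          stringsAsFactors = FALSE)
        cursor <- e + 500L
      }
      if (cursor > config$chromosome_length)
        stop("capacity: chromosome_length ", config$chromosome_length,
             " too small (layout needs ", cursor, " nt)")
      chroms[[chrom]] <- seqc
    }
    build[[sg]] <- list(chroms = chroms, feats = do.call(rbind, feats),
                        loci = do.call(rbind, loci_rows))
  }
  loci <- rbind(build$A$loci, build$C$loci)
  # tetraploid: mutated copies of both progenitors
  tet_seqs <- c(lapply(build$A$chroms, mutate_seq, rate = config$mutation_rate),
                lapply(build$C$chroms, mutate_seq, rate = config$mutation_rate))
  tet_feats <- rbind(build$A$feats, build$C$feats)
  loci$present_in_tetraploid <- TRUE
  loci$tet_mature_seq <- vapply(seq_len(nrow(loci)), function(i) {
    g <- tet_seqs[[loci$chrom[i]]]
    s <- substr(g, loci$mature_start[i] + 1L, loci$mature_end[i])
    if (loci$strand[i] == "+") s else reverse_complement(s)
  }, character(1))
  # losses: disrupt the locus span in place
  lost_ids <- character()
  if (config$n_losses > 0) {
    if (config$n_losses > nrow(loci))
      stop("n_losses exceeds the number of planted loci")
    lost <- sample(nrow(loci), config$n_losses)
    for (i in lost) {
      g <- tet_seqs[[loci$chrom[i]]]
      substr(g, loci$precursor_start[i] + 1L, loci$precursor_end[i]) <-
        random_seq(loci$precursor_end[i] - loci$precursor_start[i])
      tet_seqs[[loci$chrom[i]]] <- g
    }
    loci$present_in_tetraploid[lost] <- FALSE
    loci$tet_mature_seq[lost] <- NA_character_
    lost_ids <- loci$locus_id[lost]
  }
  # gains: duplicate a surviving locus into a new gene neighbourhood
  gained_ids <- character()
  if (config$n_gains > 0) {
    surv <- which(loci$present_in_tetraploid)
    src <- sample(surv, config$n_gains, replace = config$n_gains > length(surv))
    gain_rows <- list()
    for (k in seq_along(src)) {
      i <- src[k]
      src_g <- tet_seqs[[loci$chrom[i]]]
      prec <- substr(src_g, loci$precursor_start[i] + 1L,
                     loci$precursor_end[i])
      # choose an intergenic gap between two genes on a random chromosome,
      # away from the source locus's own flanking-gene neighbourhood (a
      # copy landing next to its source would be syntenic with the
      # progenitor and the "gained" truth label would be false)
      src_ctx <- extract_flanking_genes(loci$chrom[i],
                                        loci$precursor_start[i],
                                        loci$precursor_end[i],
                                        tet_feats)
      src_fams <- c(src_ctx$upstream, src_ctx$downstream)
      repeat {
        chrom <- sample(names(tet_seqs), 1)
        genes <- tet_feats[tet_feats$seqid == chrom &
                           tet_feats$type == "gene", , drop = FALSE]
        genes <- genes[order(genes$start), ]
        gi <- sample(10:(nrow(genes) - 10L), 1)
        gap_s <- genes$end[gi] + 20L
        gap_e <- genes$start[gi + 1L] - 20L
        if (gap_e - gap_s < nchar(prec)) next
        near <- genes$ortho_family[max(1L, gi - 10L):min(nrow(genes),
                                                         gi + 11L)]
        if (!length(intersect(near, src_fams))) break
      }
      s <- gap_s + 1L
      e <- s + nchar(prec) - 1L
      g <- tet_seqs[[chrom]]
      substr(g, s, e) <- prec
      tet_seqs[[chrom]] <- g
      lid <- sprintf("gain%02d-%s", k, loci$locus_id[i])
      off <- if (loci$arm[i] == "5p") 0L else
        nchar(prec) - nchar(loci$mature_seq[i])
      ms <- if (loci$strand[i] == "+") s - 1L + off else
        s - 1L + (nchar(prec) - nchar(loci$mature_seq[i]) - off)
      gain_rows[[k]] <- data.frame(
        locus_id = lid, pair_id = loci$pair_id[i], origin = "gained",
        subgenome = substr(chrom, 1, 1), chrom = chrom,
        strand = loci$strand[i], precursor_start = s - 1L,
        precursor_end = e, mature_start = ms,
        mature_end = ms + nchar(loci$mature_seq[i]),
        mature_seq = loci$tet_mature_seq[i], arm = loci$arm[i],
        family = loci$family[i], class = loci$class[i],
        # stored in hairpin orientation, like the ancestral rows
        precursor_seq = if (loci$strand[i] == "+") prec else
          reverse_complement(prec),
        present_in_tetraploid = TRUE,
        tet_mature_seq = loci$tet_mature_seq[i], stringsAsFactors = FALSE)
      gained_ids <- c(gained_ids, lid)
    }
    loci <- rbind(loci, do.call(rbind, gain_rows))
  }
  genomes <- list(
    progenitor_A = genome_set(unlist(build$A$chroms)),
    progenitor_C = genome_set(unlist(build$C$chroms)),
    tetraploid = genome_set(unlist(tet_seqs)))
  # MIRNA features per genome annotation
  mirna_feat <- function(tab) {
    if (!nrow(tab)) return(empty_gff())
    data.frame(seqid = tab$chrom, source = "polymir_sim", type = "MIRNA",
               start = tab$precursor_start, end = tab$precursor_end,
               score = ".", strand = tab$strand, phase = ".",
               attributes = "", ID = tab$locus_id, Parent = NA_character_,
               ortho_family = NA_character_, stringsAsFactors = FALSE)
  }
  fill_attrs <- function(f) {
    f$attributes <- ifelse(
      is.na(f$ortho_family), paste0("ID=", f$ID),
      paste0("ID=", f$ID, ";ortho_family=", f$ortho_family))
    f[order(f$seqid, f$start), ]
  }
  annA <- fill_attrs(rbind(build$A$feats,
                           mirna_feat(loci[loci$subgenome == "A" &
                                           loci$origin == "ancestral", ])))
  annC <- fill_attrs(rbind(build$C$feats,
                           mirna_feat(loci[loci$subgenome == "C" &
                                           loci$origin == "ancestral", ])))
  annT <- fill_attrs(rbind(tet_feats,
                           mirna_feat(loci[loci$present_in_tetraploid, ])))
  truth <- structure(list(
    loci = loci[, setdiff(names(loci), "precursor_seq")],
    precursor_seqs = stats::setNames(loci$precursor_seq, loci$locus_id),
    lost_locus_ids = lost_ids, gained_locus_ids = gained_ids,
    expression = NULL, dh_nonadditive_ids = character(),
    dh_factors = numeric(), cleavage_sites = NULL, decoy_sites = NULL),
    class = "PlantedTruth")
  sim <- list(progenitor_A = genomes$progenitor_A,
              progenitor_C = genomes$progenitor_C,
              tetraploid = genomes$tetraploid,
              annotations = list(A = annA, C = annC, tet = annT),
              truth = truth, reference = reference, config = config)
  if (config$verify_discoverable && config$mutation_rate == 0)
    sim <- verify_planted_loci(sim)
  sim
}

# re-fold every planted locus exactly as discovery will see it (precursor
# plus genomic flank) and regenerate hairpins that fail the acceptance
# gates, so that recovery tests measure the pipeline, not the generator
verify_planted_loci <- function(sim, max_tries = 20L) {
  cfg <- sim$config
  loci <- sim$truth$loci
  genomes <- list(A = sim$progenitor_A, C = sim$progenitor_C)
  for (i in which(loci$origin == "ancestral")) {
    sg <- loci$subgenome[i]
    for (try in seq_len(max_tries)) {
      if (locus_discoverable(loci[i, ], genomes[[sg]])) break
      if (try == max_tries)
        stop("could not construct a discoverable hairpin for ",
             loci$locus_id[i])
      # regenerate the hairpin in place (same mature and total length so
      # all coordinates stay valid; new loop and star)
      old_len <- loci$precursor_end[i] - loci$precursor_start[i]
      loop_len <- old_len - 2L * nchar(loci$mature_seq[i])
      hp <- make_hairpin(loci$mature_seq[i], loci$arm[i], cfg$loop_range,
                         loop_len = loop_len)
      patch <- if (loci$strand[i] == "+") hp else reverse_complement(hp)
      g <- genomes[[sg]]$seqs[[loci$chrom[i]]]
      substr(g, loci$precursor_start[i] + 1L, loci$precursor_end[i]) <- patch
      genomes[[sg]]$seqs[[loci$chrom[i]]] <- g
      sim$truth$precursor_seqs[[loci$locus_id[i]]] <- hp
    }
  }
  sim$progenitor_A <- genomes$A
  sim$progenitor_C <- genomes$C
  # tetraploid copies are identical at mutation_rate 0: re-derive them
  tet <- sim$tetraploid
  for (chrom in names(tet$seqs)) {
    sg <- if (chrom %in% names(genomes$A$seqs)) "A" else "C"
    base <- genomes[[sg]]$seqs[[chrom]]
    # keep disruptions and gains by re-patching
    g <- base
    for (i in which(!sim$truth$loci$present_in_tetraploid &
                    sim$truth$loci$chrom == chrom)) {
      substr(g, sim$truth$loci$precursor_start[i] + 1L,
             sim$truth$loci$precursor_end[i]) <-
        substr(tet$seqs[[chrom]], sim$truth$loci$precursor_start[i] + 1L,
               sim$truth$loci$precursor_end[i])
    }
    for (i in which(sim$truth$loci$origin == "gained" &
                    sim$truth$loci$chrom == chrom)) {
      src_id <- sub("^gain[0-9]+-", "", sim$truth$loci$locus_id[i])
      hp <- sim$truth$precursor_seqs[[src_id]]
      patch <- if (sim$truth$loci$strand[i] == "+") hp else
        reverse_complement(hp)
      substr(g, sim$truth$loci$precursor_start[i] + 1L,
             sim$truth$loci$precursor_end[i]) <- patch
    }
    tet$seqs[[chrom]] <- g
  }
  sim$tetraploid <- tet
  sim
}

locus_discoverable <- function(l, genome, flank = 300L,
                               thresholds = mirna_thresholds()) {
  chrom_len <- nchar(genome$seqs[[l$chrom]])
  # try the window that contains the hairpin first
  first_right <- (l$arm == "5p") == (l$strand == "+")
  for (w in if (first_right) c(2L, 1L) else c(1L, 2L)) {
    ws <- if (w == 1L) max(l$mature_start - flank, 0L) else l$mature_start
    we <- if (w == 1L) l$mature_end else min(l$mature_end + flank, chrom_len)
    gseq <- substr(genome$seqs[[l$chrom]], ws + 1L, we)
    if (l$strand == "+") {
      m_from <- l$mature_start - ws + 1L
      m_to <- l$mature_end - ws
    } else {
      gseq <- reverse_complement(gseq)
      m_from <- we - l$mature_end + 1L
      m_to <- we - l$mature_start
    }
    fold <- tryCatch(fold_hairpin(gseq), error = function(e) NULL)
    if (is.null(fold)) next
    duplex <- evaluate_duplex(fold, m_from, m_to)
    if (call_mirna(fold, duplex, 2L, thresholds)$accepted) return(TRUE)
  }
  FALSE
}
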