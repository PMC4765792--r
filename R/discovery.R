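#' Cluster mapped reads and excise candidate precursor windows
#'
#' Overlapping read alignments (per chromosome and strand) are merged into
#' clusters. For each cluster the candidate mature is the most abundant read
#' (summed over libraries; ties broken by the lexicographically smallest
#' sequence), and two windows are excised around it:
#' `[mature_start - flank, mature_end]` and
#' `[mature_start, mature_end + flank]`, clipped at chromosome ends. Reads
#' whose count is below `min_count` in every library are excluded before
#' clustering (the "at least two reads in a library" gate).
#'
#' @param alignments data.frame from [map_reads_exact()] with an added
#'   `library` column identifying the source library of each row.
#' @param genome a [genome_set()].
#' @param flank window extension in nt (default 300, the maximum
#'   mature/star spacing considered downstream).
#' @param min_count per-library support gate (default 2).
#' @return data.frame with one row per candidate window: `candidate_id`,
#'   `window` (1 = left flank, 2 = right flank), `chrom`, `strand`,
#'   `win_start`/`win_end` (0-based half-open), `seq` (window sequence in
#'   the orientation of the candidate read), `mature_from`/`mature_to`
#'   (1-based positions of the mature within `seq`), `mature_seq`,
#'   `mature_start`/`mature_end` (genomic, 0-based half-open),
#'   `max_lib_count`, `total_count`.
#' @export
cluster_and_excise <- function(alignments, genome, flank = 300L,
                               min_count = 2L) {
  stopifnot(inherits(genome, "GenomeSet"))
  if (!nrow(alignments)) return(empty_candidates())
  if (is.null(alignments$library)) alignments$library <- "lib1"
  max_lib <- tapply(alignments$count,
                    list(alignments$read, alignments$library), max)
  max_lib_count <- apply(max_lib, 1, max, na.rm = TRUE)
  keep_reads <- names(max_lib_count)[max_lib_count >= min_count]
  aln <- alignments[alignments$read %in% keep_reads, , drop = FALSE]
  if (!nrow(aln)) return(empty_candidates())
  # total count per read (across libraries), counted once per unique library
  tot <- tapply(aln$count[!duplicated(paste(aln$read, aln$library))],
                aln$read[!duplicated(paste(aln$read, aln$library))], sum)
  out <- list()
  cid <- 0L
  for (key in unique(paste(aln$chrom, aln$strand))) {
    chrom <- sub(" .*$", "", key)
    strand <- sub("^.* ", "", key)
    sub <- aln[aln$chrom == chrom & aln$strand == strand, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    chrom_len <- nchar(genome$seqs[[chrom]])
    for (ci in seq_along(red)) {
      rows <- sub[S4Vectors_from(ov)[S4Vectors_to(ov) == ci], , drop = FALSE]
      cand_tot <- tot[unique(rows$read)]
      best <- names(cand_tot)[order(-cand_tot, names(cand_tot))][1]
      brow <- rows[rows$read == best, , drop = FALSE][1, ]
      cid <- cid + 1L
      for (w in 1:2) {
        ws <- if (w == 1L) max(brow$start - flank, 0L) else brow$start
        we <- if (w == 1L) brow$end else min(brow$end + flank, chrom_len)
        gseq <- substr(genome$seqs[[chrom]], ws + 1L, we)
        if (strand == "+") {
          m_from <- brow$start - ws + 1L
          m_to <- brow$end - ws
        } else {
          gseq <- reverse_complement(gseq)
          m_from <- we - brow$end + 1L
          m_to <- we - brow$start
        }
        out[[length(out) + 1L]] <- data.frame(
          candidate_id = sprintf("cand%04d", cid), window = w,
          chrom = chrom, strand = strand, win_start = ws, win_end = we,
          seq = gseq, mature_from = m_from, mature_to = m_to,
          mature_seq = best, mature_start = brow$start,
          mature_end = brow$end,
          max_lib_count = unname(max_lib_count[best]),
          total_count = unname(tot[best]), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

S4Vectors_from <- function(h) methods::slot(h, "from")
S4Vectors_to <- function(h) methods::slot(h, "to")

empty_candidates <- function() {
  data.frame(candidate_id = character(), window = integer(),
             chrom = character(), strand = character(), win_start = integer(),
             win_end = integer(), seq = character(), mature_from = integer(),
             mature_to = integer(), mature_seq = character(),
             mature_start = integer(), mature_end = integer(),
             max_lib_count = integer(), total_count = integer(),
             stringsAsFactors = FALSE)
}

#' Default MIRNA acceptance thresholds
#'
#' The hairpin acceptance gates: free energy strictly below -18 kcal/mol,
#' strictly more than 16 matched nucleotides and strictly fewer than 4
#' bulged nucleotides between miRNA and miRNA*, mature/star spacing
#' strictly below 300 nt, and at least 2 supporting reads in one library.
#'
#' @return named list of thresholds.
#' @export
mirna_thresholds <- function() {
  list(dg_max = -18, min_matched = 17L, max_bulges = 3L,
       max_spacing = 299L, min_reads = 2L)
}

#' Accept or reject a candidate MIRNA locus
#'
#' Applies the duplex acceptance gates to a folded candidate. All criteria
#' are evaluated so that a rejection record carries every failed criterion.
#'
#' @param fold a [fold_hairpin()] result for the candidate window.
#' @param duplex an [evaluate_duplex()] result for the mature interval.
#' @param max_lib_count maximum per-library read support of the mature.
#' @param thresholds list as from [mirna_thresholds()].
#' @return list with `accepted` (logical) and `reasons` (character vector of
#'   failed criteria, empty when accepted).
#' @export
call_mirna <- function(fold, duplex, max_lib_count,
                       thresholds = mirna_thresholds()) {
  reasons <- character()
  if (!isTRUE(duplex$ok)) {
    reasons <- c(reasons, paste0("duplex: ", duplex$reason))
  } else {
    if (!(duplex$matched_nt >= thresholds$min_matched))
      reasons <- c(reasons, sprintf("matched_nt %d <= %d", duplex$matched_nt,
                                    thresholds$min_matched - 1L))
    if (!(duplex$bulge_nt <= thresholds$max_bulges))
      reasons <- c(reasons, sprintf("bulge_nt %d >= %d", duplex$bulge_nt,
                                    thresholds$max_bulges + 1L))
    if (!(duplex$spacing_nt <= thresholds$max_spacing))
      reasons <- c(reasons, sprintf("spacing_nt %d >= %d", duplex$spacing_nt,
                                    thresholds$max_spacing + 1L))
  }
  if (!(fold$delta_g < thresholds$dg_max))
    reasons <- c(reasons, sprintf("delta_g %.2f >= %.2f", fold$delta_g,
                                  thresholds$dg_max))
  if (!(max_lib_count >= thresholds$min_reads))
    reasons <- c(reasons, sprintf("max library support %d < %d",
                                  max_lib_count, thresholds$min_reads))
  list(accepted = length(reasons) == 0L, reasons = reasons)
}

#' Classify a mature miRNA as conserved or novel
#'
#' The distance to the reference is the minimum global edit distance (unit
#' costs, U and T equivalent) over all known mature sequences. A mature
#' within `max_mismatch` edits of a known miRNA is conserved and inherits
#' the family of the closest reference (ties broken by the
#' lexicographically smallest family name); otherwise it is novel.
#'
#' @param mature mature sequence.
#' @param reference named list mapping family name to character vector(s) of
#'   known mature sequences, as from [read_mature_reference()].
#' @param max_mismatch conserved/novel boundary (default 2).
#' @return list with `class` (`"conserved"`/`"novel"`), `family` (`NA` for
#'   novel) and `distance`.
#' @export
classify_mirna <- function(mature, reference, max_mismatch = 2L) {
  if (!nzchar(mature)) stop("empty mature sequence")
  if (!length(reference)) stop("empty reference")
  mat <- chartr("U", "T", toupper(mature))
  fam_names <- names(reference)
  best_d <- Inf
  best_fam <- NA_character_
  for (fam in fam_names[order(fam_names)]) {
    refs <- chartr("U", "T", toupper(reference[[fam]]))
    d <- min(utils::adist(mat, refs))
    if (d < best_d) {
      best_d <- d
      best_fam <- fam
    }
  }
  if (best_d <= max_mismatch)
    list(class = "conserved", family = best_fam, distance = as.integer(best_d))
  else
    list(class = "novel", family = NA_character_,
         distance = as.integer(best_d))
}

#' Subgenome of origin of a locus
#'
#' @param chrom chromosome id of the locus.
#' @param genome a [genome_set()].
#' @return `"A"`, `"C"` or `"unplaced"`.
#' @export
assign_subgenome <- function(chrom, genome) {
  stopifnot(inherits(genome, "GenomeSet"))
  if (!all(chrom %in% names(genome$subgenome_of)))
    stop("unknown chromosome: ",
         paste(setdiff(chrom, names(genome$subgenome_of)), collapse = ", "))
  unname(genome$subgenome_of[chrom])
}

#' Discover MIRNA loci from small-RNA libraries
#'
#' End-to-end discovery: exact mapping of each library, read clustering and
#' precursor window excision, hairpin folding, miRNA/miRNA* duplex
#' evaluation, acceptance gating, duplicate merging, conserved/novel
#' classification and subgenome assignment. The same mature arising at two
#' genomic positions yields two loci; identical loci found in multiple
#' libraries are merged.
#'
#' @param libraries list of [srna_library()] objects (or a single one).
#' @param genome a [genome_set()].
#' @param reference optional mature reference (see
#'   [read_mature_reference()]); when `NULL`, classification columns are
#'   `NA`.
#' @param flank window extension in nt (default 300).
#' @param thresholds acceptance gates, see [mirna_thresholds()].
#' @param backend folding backend passed to [fold_hairpin()].
#' @param novel_prefix name stem for novel miRNAs (numbered in discovery
#'   order).
#' @return data.frame of accepted loci (class `mirna_loci` in column
#'   layout): coordinates are genomic 0-based half-open. Rejection records
#'   are attached as attribute `"rejections"`.
#' @export
discover_mirnas <- function(libraries, genome, reference = NULL,
                            flank = 300L, thresholds = mirna_thresholds(),
                            backend = "nn",
                            novel_prefix = "bna_novel_miRX") {
  if (inherits(libraries, "SmallRNALibrary")) libraries <- list(libraries)
  aln <- do.call(rbind, lapply(libraries, function(lib) {
    a <- map_reads_exact(lib, genome)
    if (nrow(a)) a$library <- lib$id
    a
  }))
  cands <- cluster_and_excise(aln, genome, flank = flank,
                              min_count = thresholds$min_reads)
  loci <- list()
  rejections <- list()
  if (nrow(cands)) for (id in unique(cands$candidate_id)) {
    rows <- cands[cands$candidate_id == id, , drop = FALSE]
    found <- FALSE
    fail <- character()
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      fold <- tryCatch(fold_hairpin(r$seq, backend = backend),
                       error = function(e) NULL)
      if (is.null(fold)) {
        fail <- c(fail, sprintf("window %d: unfoldable", r$window))
        next
      }
      duplex <- evaluate_duplex(fold, r$mature_from, r$mature_to)
      call <- call_mirna(fold, duplex, r$max_lib_count, thresholds)
      if (call$accepted) {
        star_seq <- substr(r$seq, duplex$star_start, duplex$star_end)
        g <- window_to_genomic(r, duplex$star_start, duplex$star_end)
        prec_start <- min(r$mature_start, g[1])
        prec_end <- max(r$mature_end, g[2])
        loci[[length(loci) + 1L]] <- data.frame(
          chrom = r$chrom, strand = r$strand,
          precursor_start = prec_start, precursor_end = prec_end,
          mature_start = r$mature_start, mature_end = r$mature_end,
          mature_seq = r$mature_seq, star_start = g[1], star_end = g[2],
          star_seq = star_seq, arm = duplex$arm, delta_g = fold$delta_g,
          matched_nt = duplex$matched_nt, bulge_nt = duplex$bulge_nt,
          spacing_nt = duplex$spacing_nt,
          max_lib_count = r$max_lib_count, total_count = r$total_count,
          stringsAsFactors = FALSE)
        found <- TRUE
        break
      }
      fail <- c(fail, sprintf("window %d: %s", r$window,
                              paste(call$reasons, collapse = "; ")))
    }
    if (!found)
      rejections[[length(rejections) + 1L]] <- data.frame(
        candidate_id = id, chrom = rows$chrom[1],
        mature_start = rows$mature_start[1], mature_end = rows$mature_end[1],
        strand = rows$strand[1], mature_seq = rows$mature_seq[1],
        reasons = paste(fail, collapse = " | "), stringsAsFactors = FALSE)
  }
  out <- if (length(loci)) do.call(rbind, loci) else NULL
  if (!is.null(out)) {
    key <- paste(out$chrom, out$strand, out$mature_start, out$mature_end)
    out <- out[!duplicated(key), , drop = FALSE]
    out <- out[order(out$chrom, out$mature_start, out$strand), , drop = FALSE]
    out$locus_id <- sprintf("pm-%s-%04d", out$chrom,
                            stats::ave(seq_len(nrow(out)), out$chrom,
                                       FUN = seq_along))
    out$subgenome <- assign_subgenome(out$chrom, genome)
    out$class <- NA_character_
    out$family <- NA_character_
    out$distance <- NA_integer_
    if (!is.null(reference)) {
      novel_n <- 0L
      for (i in seq_len(nrow(out))) {
        cl <- classify_mirna(out$mature_seq[i], reference)
        out$class[i] <- cl$class
        out$distance[i] <- cl$distance
        if (cl$class == "conserved") {
          out$family[i] <- cl$family
        } else {
          novel_n <- novel_n + 1L
          out$family[i] <- paste0(novel_prefix, novel_n)
        }
      }
    }
    # per-library support of the mature sequence
    for (lib in libraries) {
      cn <- paste0("count_", lib$id)
      out[[cn]] <- as.integer(lib$reads[out$mature_seq])
      out[[cn]][is.na(out[[cn]])] <- 0L
    }
    rownames(out) <- NULL
    out <- out[, c("locus_id", setdiff(names(out), "locus_id"))]
  } else {
    out <- empty_loci()
  }
  attr(out, "rejections") <- if (length(rejections))
    do.call(rbind, rejections) else NULL
  out
}

window_to_genomic <- function(r, from, to) {
  # map 1-based [from, to] in the folded window back to genomic 0-based
  if (r$strand == "+") c(r$win_start + from - 1L, r$win_start + to)
  else c(r$win_end - to, r$win_end - from + 1L)
}

empty_loci <- function() {
  data.frame(locus_id = character(), chrom = character(), strand = character(),
             precursor_start = integer(), precursor_end = integer(),
             mature_start = integer(), mature_end = integer(),
             mature_seq = character(), star_start = integer(),
             star_end = integer(), star_seq = character(), arm = character(),
             delta_g = numeric(), matched_nt = integer(), bulge_nt = integer(),
             spacing_nt = integer(), max_lib_count = integer(),
             total_count = integer(), subgenome = character(),
             class = character(), family = character(), distance = integer(),
             stringsAsFactors = FALSE)
}

#' Write discovered loci as GFF3 (precursor + mature + star)
#'
#' @param loci data.frame from [discover_mirnas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mirna_gff3 <- function(loci, path) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = l$chrom, source = "polymir", type = "MIRNA",
      start = l$precursor_start, end = l$precursor_end, score = ".",
      strand = l$strand, phase = ".",
      attributes = gff_attributes(ID = l$locus_id, class = l$class,
                                  family = l$family),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = l$chrom, source = "polymir", type = "miRNA",
      start = l$mature_start, end = l$mature_end, score = ".",
      strand = l$strand, phase = ".",
      attributes = gff_attributes(ID = paste0(l$locus_id, ".mature"),
                                  Parent = l$locus_id),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = l$chrom, source = "polymir", type = "miRNA_star",
      start = l$star_start, end = l$star_end, score = ".",
      strand = l$strand, phase = ".",
      attributes = gff_attributes(ID = paste0(l$locus_id, ".star"),
                                  Parent = l$locus_id),
      stringsAsFactors = FALSE)
  }
  write_gff3(if (length(rows)) do.call(rbind, rows) else empty_gff(), path)
}
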