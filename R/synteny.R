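#' Extract the flanking protein-coding gene context of a locus
#'
#' Returns the `k` nearest protein-coding genes on each side of the locus
#' (fewer near chromosome ends), ordered by genomic distance from the
#' locus. Gene identity across genomes is keyed by the `ortho_family`
#' attribute of the annotation.
#'
#' @param chrom,start,end locus interval (0-based half-open) and chromosome.
#' @param annotation gene annotation as from [read_gff3()]; only rows with
#'   `type == "gene"` are used.
#' @param k flanking genes per side (default 10).
#' @return list of class `FlankContext` with `upstream` and `downstream`
#'   character vectors of ortho-family labels, nearest first.
#' @export
extract_flanking_genes <- function(chrom, start, end, annotation, k = 10L) {
  genes <- annotation[annotation$type == "gene" &
                      annotation$seqid == chrom, , drop = FALSE]
  if (!nrow(genes))
    stop("no protein-coding genes annotated on chromosome ", chrom)
  lab <- ifelse(is.na(genes$ortho_family), genes$ID, genes$ortho_family)
  up <- which(genes$end <= start)
  dn <- which(genes$start >= end)
  up <- up[order(genes$end[up], decreasing = TRUE)]
  dn <- dn[order(genes$start[dn])]
  structure(list(upstream = unique(lab[up])[seq_len(min(k, length(unique(lab[up]))))],
                 downstream = unique(lab[dn])[seq_len(min(k, length(unique(lab[dn]))))]),
            class = "FlankContext")
}

#' Microsynteny test between two flanking-gene contexts
#'
#' A pair is syntenic when it shares at least one identical flanking
#' protein-coding gene (by ortho-family label) upstream or downstream. The
#' four synteny sets are: 1 = shared genes on both sides, 2 = upstream
#' only, 3 = downstream only, 4 = neither; sets 1-3 are syntenic.
#'
#' @param query,subject `FlankContext` objects built with the same
#'   ortho-family labelling.
#' @return list with `shared_upstream`, `shared_downstream`, `set_class`
#'   (1-4) and `syntenic` (logical).
#' @export
test_microsynteny <- function(query, subject) {
  su <- length(intersect(query$upstream, subject$upstream))
  sd <- length(intersect(query$downstream, subject$downstream))
  set_class <- if (su >= 1L && sd >= 1L) 1L else if (su >= 1L) 2L
               else if (sd >= 1L) 3L else 4L
  list(shared_upstream = su, shared_downstream = sd,
       set_class = set_class, syntenic = set_class <= 3L)
}

# Karlin-Altschul lambda for a +match/-mismatch scheme at uniform base
# composition: solves sum_ij p_i p_j exp(lambda * s_ij) = 1.
ka_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

#' Find homologous copies of a precursor in a genome
#'
#' Seed-and-extend ungapped-core local search: exact seed words of the
#' query are located in the subject genome (both strands), collapsed per
#' diagonal, and extended without gaps to the maximal-scoring segment
#' (match +1, mismatch -2). Hits are gated on query coverage and a
#' Karlin-Altschul style significance, then the best `top_n` are returned.
#'
#' @param queries named character vector of precursor sequences (each at
#'   least `word` nt; precursors shorter than 40 nt are refused).
#' @param genome a [genome_set()].
#' @param word seed word length (default 12).
#' @param min_coverage minimum fraction of the query covered by the
#'   ungapped core (default 0.9, strict: coverage must exceed it).
#' @param max_evalue significance gate (default 1e-5, strict).
#' @param top_n hits retained per query (default 5), best score first with
#'   deterministic tie-break by (chromosome, start).
#' @param match,mismatch ungapped scoring (default +1/-2).
#' @param ka_k Karlin-Altschul K constant (default 0.3).
#' @return data.frame of hits: `query`, `chrom`, `start` (0-based), `end`,
#'   `strand`, `score`, `coverage`, `evalue`.
#' @export
find_mirna_homologs <- function(queries, genome, word = 12L,
                                min_coverage = 0.9, max_evalue = 1e-5,
                                top_n = 5L, match = 1, mismatch = -2,
                                ka_k = 0.3) {
  stopifnot(inherits(genome, "GenomeSet"))
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  queries <- chartr("U", "T", toupper(queries))
  if (any(nchar(queries) < 40L))
    stop("precursor query shorter than 40 nt")
  lambda <- ka_lambda(match, mismatch)
  db_len <- 2 * sum(nchar(genome$seqs))
  # seed dictionary: every word-mer of every query
  seeds <- list()
  for (q in names(queries)) {
    s <- queries[[q]]
    n <- nchar(s) - word + 1L
    if (n < 1L) next
    off <- seq_len(n)
    seeds[[q]] <- data.frame(query = q, offset = off,
                             mer = substring(s, off, off + word - 1L),
                             stringsAsFactors = FALSE)
  }
  seeds <- do.call(rbind, seeds)
  seeds <- seeds[!grepl("[^ACGT]", seeds$mer), , drop = FALSE]
  dict <- Biostrings::DNAStringSet(seeds$mer)
  pd <- Biostrings::PDict(dict)
  cand <- list()
  for (chrom in names(genome$seqs)) {
    for (strand in c("+", "-")) {
      subject_seq <- if (strand == "+") genome$seqs[[chrom]] else
        reverse_complement(genome$seqs[[chrom]])
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject_seq))
      n_per <- lengths(m)
      if (!sum(n_per)) next
      ir <- unlist(m)
      idx <- rep(seq_len(nrow(seeds)), n_per)
      diag0 <- (IRanges::start(ir) - 1L) - (seeds$offset[idx] - 1L)
      key <- paste(seeds$query[idx], diag0)
      first <- !duplicated(key)
      cand[[length(cand) + 1L]] <- data.frame(
        query = seeds$query[idx][first], chrom = chrom, strand = strand,
        diag = diag0[first], seed_off = seeds$offset[idx][first],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_homologs())
  cand <- do.call(rbind, cand)
  subjects <- list("+" = genome$seqs,
                   "-" = vapply(genome$seqs, reverse_complement,
                                character(1)))
  hits <- list()
  for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    qseq <- queries[[cc$query]]
    qlen <- nchar(qseq)
    subject_seq <- subjects[[cc$strand]][[cc$chrom]]
    slen <- nchar(subject_seq)
    # clip the query projection onto the subject along this diagonal
    q_from <- max(1L, 1L - cc$diag)
    q_to <- min(qlen, slen - cc$diag)
    if (q_to - q_from + 1L < word) next
    qv <- strsplit(substr(qseq, q_from, q_to), "")[[1]]
    sv <- strsplit(substr(subject_seq, cc$diag + q_from,
                          cc$diag + q_to), "")[[1]]
    sc <- ifelse(qv == sv & qv != "N", match, mismatch)
    seg <- best_segment_containing(sc, cc$seed_off - q_from + 1L,
                                   min(cc$seed_off - q_from + 1L + word - 1L,
                                       length(sc)))
    if (is.null(seg)) next
    coverage <- (seg$to - seg$from + 1L) / qlen
    evalue <- ka_k * qlen * db_len * exp(-lambda * seg$score)
    if (!(coverage > min_coverage) || !(evalue < max_evalue)) next
    # subject coordinates (0-based, on the + strand of the chromosome)
    s_from0 <- cc$diag + q_from + seg$from - 2L
    s_to0 <- cc$diag + q_from + seg$to - 1L
    if (cc$strand == "-") {
      tmp <- slen - s_to0
      s_to0 <- slen - s_from0
      s_from0 <- tmp
    }
    hits[[length(hits) + 1L]] <- data.frame(
      query = cc$query, chrom = cc$chrom, start = s_from0, end = s_to0,
      strand = cc$strand, score = seg$score, coverage = coverage,
      evalue = evalue, stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty_homologs())
  hits <- do.call(rbind, hits)
  # dedupe identical cores, keep top_n per query
  out <- list()
  for (q in unique(hits$query)) {
    h <- hits[hits$query == q, , drop = FALSE]
    h <- h[!duplicated(paste(h$chrom, h$start, h$end, h$strand)), ,
           drop = FALSE]
    h <- h[order(-h$score, h$chrom, h$start), , drop = FALSE]
    out[[q]] <- utils::head(h, top_n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# maximal-scoring contiguous segment constrained to contain [lo, hi]
best_segment_containing <- function(sc, lo, hi) {
  n <- length(sc)
  if (lo < 1L || hi > n) return(NULL)
  cs <- cumsum(sc)
  left <- c(0, cs)[seq_len(lo)]          # prefix sums before positions 1..lo
  from <- which.min(left)                # best left cut
  right <- cs[hi:n]
  to <- hi + which.max(right) - 1L
  score <- cs[to] - (if (from == 1L) 0 else cs[from - 1L])
  list(from = from, to = to, score = score)
}

empty_homologs <- function() {
  data.frame(query = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), score = numeric(),
             coverage = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Call MIRNA gains and losses between a tetraploid and its progenitors
#'
#' A progenitor locus is LOST when its precursor finds no retained homology
#' hit in the tetraploid genome. A tetraploid locus is GAINED when none of
#' its retained hits in either progenitor genome lies in a syntenic context
#' (microsynteny classes 1-3 against the flanking genes at the hit). A
#' progenitor locus whose best tetraploid hit lands on the non-corresponding
#' subgenome (A progenitor vs C subgenome or vice versa) is tallied as an
#' opposite-subgenome match.
#'
#' @param tet_loci,progA_loci,progC_loci locus tables with columns
#'   `locus_id`, `chrom`, `precursor_start`, `precursor_end` (and, for the
#'   progenitor tables, the progenitor's subgenome is implied by the table).
#' @param genomes named list with elements `tet`, `A`, `C` ([genome_set()]).
#' @param annotations named list with elements `tet`, `A`, `C` (gene
#'   annotations as from [read_gff3()], carrying `ortho_family`).
#' @param k flanking genes per side (default 10).
#' @param ... gates passed to [find_mirna_homologs()].
#' @return list with `lost` (data.frame of progenitor loci without hits),
#'   `gained` (data.frame of tetraploid loci without syntenic partners),
#'   `opposite_subgenome` (data.frame of progenitor loci whose best hit is
#'   on the other subgenome) and `synteny_calls` (per tetraploid locus/hit
#'   evidence table).
#' @export
call_gain_loss <- function(tet_loci, progA_loci, progC_loci, genomes,
                           annotations, k = 10L, ...) {
  prog_tabs <- list(A = progA_loci, C = progC_loci)
  locus_seq <- function(loci, genome) {
    stats::setNames(substring(genome$seqs[loci$chrom],
                              loci$precursor_start + 1L, loci$precursor_end),
                    loci$locus_id)
  }
  # progenitor -> tetraploid: losses and opposite-subgenome matches
  lost <- list(); opposite <- list()
  for (sg in c("A", "C")) {
    loci <- prog_tabs[[sg]]
    if (!nrow(loci)) next
    qs <- locus_seq(loci, genomes[[sg]])
    hits <- find_mirna_homologs(qs, genomes$tet, ...)
    for (i in seq_len(nrow(loci))) {
      h <- hits[hits$query == loci$locus_id[i], , drop = FALSE]
      if (!nrow(h)) {
        lost[[length(lost) + 1L]] <- data.frame(
          locus_id = loci$locus_id[i], progenitor = sg,
          chrom = loci$chrom[i], evidence = "no retained hit in tetraploid",
          stringsAsFactors = FALSE)
      } else {
        # opposite-subgenome only when the best hit is strictly better
        # than every hit on the corresponding subgenome (equal-score ties
        # resolve to the corresponding one)
        hit_sg <- assign_subgenome(h$chrom, genomes$tet)
        corr_best <- suppressWarnings(max(h$score[hit_sg == sg]))
        if (h$score[1] > corr_best) {
          best_sg <- hit_sg[1]
          if (best_sg != sg && best_sg != "unplaced")
            opposite[[length(opposite) + 1L]] <- data.frame(
              locus_id = loci$locus_id[i], progenitor = sg,
              best_hit_chrom = h$chrom[1], best_hit_subgenome = best_sg,
              score = h$score[1], stringsAsFactors = FALSE)
        }
      }
    }
  }
  # tetraploid -> progenitors: gains by absence of syntenic partners
  gained <- list(); calls <- list()
  if (nrow(tet_loci)) {
    qs <- locus_seq(tet_loci, genomes$tet)
    prog_hits <- list(A = find_mirna_homologs(qs, genomes$A, ...),
                      C = find_mirna_homologs(qs, genomes$C, ...))
    for (i in seq_len(nrow(tet_loci))) {
      lid <- tet_loci$locus_id[i]
      qctx <- extract_flanking_genes(tet_loci$chrom[i],
                                     tet_loci$precursor_start[i],
                                     tet_loci$precursor_end[i],
                                     annotations$tet, k = k)
      syntenic <- FALSE
      for (sg in c("A", "C")) {
        h <- prog_hits[[sg]]
        h <- h[h$query == lid, , drop = FALSE]
        for (j in seq_len(nrow(h))) {
          sctx <- extract_flanking_genes(h$chrom[j], h$start[j], h$end[j],
                                         annotations[[sg]], k = k)
          syn <- test_microsynteny(qctx, sctx)
          calls[[length(calls) + 1L]] <- data.frame(
            query = lid, progenitor = sg, hit_chrom = h$chrom[j],
            hit_start = h$start[j], shared_upstream = syn$shared_upstream,
            shared_downstream = syn$shared_downstream,
            set_class = syn$set_class, syntenic = syn$syntenic,
            stringsAsFactors = FALSE)
          if (syn$syntenic) syntenic <- TRUE
        }
      }
      if (!syntenic)
        gained[[length(gained) + 1L]] <- data.frame(
          locus_id = lid, chrom = tet_loci$chrom[i],
          evidence = "no syntenic progenitor partner (classes 1-3)",
          stringsAsFactors = FALSE)
    }
  }
  bindr <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(lost = bindr(lost, data.frame(locus_id = character(),
                                     progenitor = character(),
                                     chrom = character(),
                                     evidence = character())),
       gained = bindr(gained, data.frame(locus_id = character(),
                                         chrom = character(),
                                         evidence = character())),
       opposite_subgenome = bindr(opposite, data.frame(
         locus_id = character(), progenitor = character(),
         best_hit_chrom = character(), best_hit_subgenome = character(),
         score = numeric())),
       synteny_calls = bindr(calls, data.frame(
         query = character(), progenitor = character(),
         hit_chrom = character(), hit_start = integer(),
         shared_upstream = integer(), shared_downstream = integer(),
         set_class = integer(), syntenic = logical())))
}

#' Per-family copy-number table across genomes
#'
#' Rows are miRNA families, columns the locus counts in the tetraploid
#' subgenomes (`A_n`, `C_n`) and the two progenitors (`A_r`, `C_o`), with
#' `delta = (A_n + C_n) - (A_r + C_o)`. Sorted by |delta| descending, then
#' family name. Families absent everywhere are excluded.
#'
#' @param tet_loci tetraploid locus table with `family` and `subgenome`
#'   columns.
#' @param progA_loci,progC_loci progenitor locus tables with `family`.
#' @return data.frame with columns `family`, `A_n`, `C_n`, `A_r`, `C_o`,
#'   `delta`.
#' @export
family_copy_table <- function(tet_loci, progA_loci, progC_loci) {
  fam <- function(tab) tab$family[!is.na(tab$family)]
  fams <- sort(unique(c(fam(tet_loci), fam(progA_loci), fam(progC_loci))))
  cnt <- function(tab, f, sg = NULL) {
    sel <- !is.na(tab$family) & tab$family == f
    if (!is.null(sg)) sel <- sel & tab$subgenome == sg
    sum(sel)
  }
  out <- data.frame(
    family = fams,
    A_n = vapply(fams, function(f) cnt(tet_loci, f, "A"), numeric(1)),
    C_n = vapply(fams, function(f) cnt(tet_loci, f, "C"), numeric(1)),
    A_r = vapply(fams, function(f) cnt(progA_loci, f), numeric(1)),
    C_o = vapply(fams, function(f) cnt(progC_loci, f), numeric(1)),
    stringsAsFactors = FALSE)
  out$delta <- (out$A_n + out$C_n) - (out$A_r + out$C_o)
  out <- out[out$A_n + out$C_n + out$A_r + out$C_o > 0, , drop = FALSE]
  out <- out[order(-abs(out$delta), out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window MIRNA density track
#'
#' Counts loci in fixed windows along every chromosome; a plain TSV track
#' that substitutes for a circular ideogram rendering.
#'
#' @param loci locus table with `chrom` and `precursor_start`.
#' @param genome a [genome_set()].
#' @param window window size in nt (default 1 Mb).
#' @return data.frame `chrom`, `win_start`, `win_end`, `n_loci`.
#' @export
locus_density_track <- function(loci, genome, window = 1e6) {
  rows <- list()
  for (chrom in names(genome$seqs)) {
    len <- nchar(genome$seqs[[chrom]])
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    pos <- loci$precursor_start[loci$chrom == chrom]
    n <- vapply(seq_along(starts), function(i)
      sum(pos >= starts[i] & pos < ends[i]), numeric(1))
    rows[[chrom]] <- data.frame(chrom = chrom, win_start = starts,
                                win_end = ends, n_loci = n,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
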