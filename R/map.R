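#' Map collapsed reads to a genome by exact matching
#'
#' Every exact occurrence of every read is reported on both strands
#' (Aho-Corasick multi-pattern matching via Biostrings). `N` in the genome
#' never matches. `U` in reads is treated as `T`; any other non-ACGT
#' character is an error.
#'
#' @param library a [srna_library()], or a named integer vector of counts
#'   keyed by read sequence.
#' @param genome a [genome_set()].
#' @return data.frame with one row per alignment and columns `read`,
#'   `chrom`, `start` (0-based), `end` (exclusive), `strand`, `count`,
#'   ordered by (`chrom`, `start`, `strand`, `read`). Reads with no hits are
#'   returned in the `unmapped` attribute.
#' @export
map_reads_exact <- function(library, genome) {
  stopifnot(inherits(genome, "GenomeSet"))
  if (inherits(library, "SmallRNALibrary")) {
    counts <- library$reads
  } else {
    counts <- library
  }
  if (!length(counts)) return(empty_alignments())
  seqs <- chartr("U", "T", toupper(names(counts)))
  if (any(grepl("[^ACGT]", seqs)))
    stop("read with characters outside ACGTU: ",
         seqs[grepl("[^ACGT]", seqs)][1])
  names(counts) <- seqs
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- seqs
  hits <- list()
  subjects <- lapply(genome$seqs, Biostrings::DNAString)
  for (w in sort(unique(Biostrings::width(reads)))) {
    sub <- reads[Biostrings::width(reads) == w]
    pd_fwd <- Biostrings::PDict(sub)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(sub))
    for (chrom in names(subjects)) {
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_fwd else pd_rev
        m <- Biostrings::matchPDict(pd, subjects[[chrom]])
        n_per <- lengths(m)
        if (sum(n_per) == 0L) next
        ir <- unlist(m)
        hits[[length(hits) + 1L]] <- data.frame(
          read = rep(names(sub), n_per),
          chrom = chrom,
          start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir),
          strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else empty_alignments()
  if (nrow(out)) {
    out$count <- as.integer(counts[out$read])
    out <- out[order(out$chrom, out$start, out$strand, out$read), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unmapped") <- setdiff(seqs, unique(out$read))
  out
}

empty_alignments <- function() {
  data.frame(read = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), count = integer(),
             stringsAsFactors = FALSE)
}

#' Export alignments as 6-column BED
#'
#' @param alignments data.frame from [map_reads_exact()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
alignments_to_bed <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(alignments)) {
    writeLines(paste(alignments$chrom, alignments$start, alignments$end,
                     alignments$read, alignments$count, alignments$strand,
                     sep = "\t"), con)
  }
  invisible(path)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
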