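#' Score a miRNA against one target window
#'
#' Expectation score of the antiparallel duplex (miRNA 5'->3' vs target
#' 3'->5'): per aligned position 0 for a Watson-Crick pair, `gu_penalty`
#' for a G:U wobble and `mm_penalty` for a mismatch; every bulged target
#' nucleotide costs `bulge_penalty`. Penalties are multiplied by
#' `seed_mult` at miRNA positions `seed_from`..`seed_to`. At most one
#' target-side bulge is allowed, so the window may exceed the miRNA length
#' by up to 3 nt. Lower scores mean stronger predicted interactions.
#'
#' @param mirna mature miRNA sequence (5'->3').
#' @param window target site sequence (5'->3'), `length(mirna)` to
#'   `length(mirna) + 3` nt.
#' @param gu_penalty,mm_penalty,bulge_penalty,seed_from,seed_to,seed_mult
#'   scoring weights (defaults 0.5, 1, 2, positions 2-13, x2).
#' @return list with `expectation`, `alignment` (three-line character
#'   vector: miRNA 3'->5' on top-reversed layout, match line, target) and
#'   `bulge_after` (miRNA position preceding the target bulge, `NA` when
#'   none).
#' @export
score_target_site <- function(mirna, window, gu_penalty = 0.5,
                              mm_penalty = 1, bulge_penalty = 2,
                              seed_from = 2L, seed_to = 13L, seed_mult = 2) {
  if (!nzchar(mirna) || !nzchar(window)) stop("empty miRNA or target window")
  res <- .score_site_cpp(mirna, window, gu_penalty, mm_penalty,
                         bulge_penalty, seed_from, seed_to, seed_mult)
  b <- if (res$bulge_after < 0) NA_integer_ else res$bulge_after
  list(expectation = res$score,
       alignment = duplex_alignment(mirna, window, b),
       bulge_after = b)
}

duplex_alignment <- function(mirna, window, bulge_after) {
  m <- chartr("Uu", "Tt", toupper(mirna))
  w <- chartr("Uu", "Tt", toupper(window))
  rw <- paste(rev(strsplit(w, "")[[1]]), collapse = "") # target 3'->5'
  mlen <- nchar(m)
  d <- nchar(w) - mlen
  mi <- strsplit(m, "")[[1]]
  tg <- strsplit(rw, "")[[1]]
  if (d > 0 && !is.na(bulge_after)) {
    mi <- append(mi, rep("-", d), after = bulge_after)
  }
  match_line <- vapply(seq_along(mi), function(i) {
    a <- mi[i]; b <- tg[i]
    if (a == "-" || b == "-") " "
    else if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
             (a == "C" && b == "G") || (a == "G" && b == "C")) "|"
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) "o"
    else " "
  }, character(1))
  c(mirna = paste0("5' ", paste(mi, collapse = ""), " 3' (miRNA)"),
    match = paste0("   ", paste(match_line, collapse = "")),
    target = paste0("3' ", paste(tg, collapse = ""), " 5' (target)"))
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every window of every transcript is scored with [score_target_site()]'s
#' scheme; sites with expectation at or below `cutoff` are retained.
#' Overlapping windows of the same miRNA/transcript pair are collapsed to
#' the best-scoring one (ties: leftmost). The predicted cleavage position is
#' the transcript nucleotide paired with miRNA position 10 (AGO slicing
#' between positions 10 and 11).
#'
#' @param mirnas named character vector of mature sequences (names are
#'   miRNA ids).
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum retained expectation (default 3.0; sites scoring
#'   above this are considered disrupted).
#' @param max_bulge largest target bulge considered (default 3 nt).
#' @param ... scoring weights passed to the kernel.
#' @return data.frame of target interactions ordered by (miRNA id,
#'   transcript id, position): `mirna_id`, `transcript_id`, `start`, `end`
#'   (1-based inclusive site interval), `expectation`, `cleavage_pos`,
#'   `status` (`"unvalidated"`), `tag_support` (0).
#' @export
scan_transcriptome <- function(mirnas, transcripts, cutoff = 3.0,
                               max_bulge = 3L, ...) {
  if (!length(transcripts)) stop("transcripts must be non-empty")
  weights <- utils::modifyList(
    list(gu_penalty = 0.5, mm_penalty = 1, bulge_penalty = 2,
         seed_from = 2L, seed_to = 13L, seed_mult = 2), list(...))
  rows <- list()
  for (mid in sort(names(mirnas))) {
    m <- mirnas[[mid]]
    for (tid in sort(names(transcripts))) {
      hits <- .scan_transcript_cpp(m, transcripts[[tid]], cutoff, max_bulge,
                                   weights$gu_penalty, weights$mm_penalty,
                                   weights$bulge_penalty, weights$seed_from,
                                   weights$seed_to, weights$seed_mult)
      if (!nrow(hits)) next
      hits <- hits[order(hits$expectation, hits$start, hits$width), ,
                   drop = FALSE]
      kept <- hits[0, ]
      for (i in seq_len(nrow(hits))) {
        h <- hits[i, ]
        if (!nrow(kept) ||
            !any(h$start <= kept$start + kept$width - 1L &
                 h$start + h$width - 1L >= kept$start))
          kept <- rbind(kept, h)
      }
      mlen <- nchar(m)
      for (i in seq_len(nrow(kept))) {
        h <- kept[i, ]
        e <- h$start + h$width - 1L
        d <- h$width - mlen
        b <- h$bulge_after
        cleav <- if (d == 0L || (b >= 0L && b >= 10L)) e - 9L else e - 9L - d
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, transcript_id = tid, start = h$start, end = e,
          expectation = h$expectation, cleavage_pos = cleav,
          status = "unvalidated", tag_support = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    mirna_id = character(), transcript_id = character(), start = integer(),
    end = integer(), expectation = numeric(), cleavage_pos = integer(),
    status = character(), tag_support = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-transcript degradome profiles
#'
#' Each degradome tag is exact-matched to the transcripts (sense strand
#' only; tags derive from 3' cleavage fragments of the mRNA) and its count
#' accumulated at the 5'-most matched position. A tag matching several
#' transcripts is counted on every one of them.
#'
#' @param tags named integer vector of tag counts keyed by tag sequence, or
#'   a [srna_library()].
#' @param transcripts named character vector of transcript sequences.
#' @return named list mapping transcript id to a profile: an integer vector
#'   of counts named by 1-based 5'-end position (only positions with
#'   nonzero counts are present).
#' @export
build_degradome_profile <- function(tags, transcripts) {
  if (inherits(tags, "SmallRNALibrary")) tags <- tags$reads
  profiles <- stats::setNames(vector("list", length(transcripts)),
                              names(transcripts))
  for (tid in names(transcripts)) {
    subject <- Biostrings::DNAString(chartr("U", "T",
                                            toupper(transcripts[[tid]])))
    acc <- integer()
    for (tag in names(tags)) {
      mt <- Biostrings::matchPattern(chartr("U", "T", toupper(tag)), subject)
      for (s in Biostrings::start(mt)) {
        key <- as.character(s)
        acc[key] <- if (key %in% names(acc)) acc[[key]] + tags[[tag]]
                    else tags[[tag]]
      }
    }
    profiles[[tid]] <- acc[order(as.integer(names(acc)))]
  }
  profiles
}

#' Validate predicted cleavage with degradome evidence
#'
#' An interaction is validated when any degradome 5' end with nonzero count
#' lies within `window` nt of the predicted cleavage position (inclusive).
#' The supporting tag count is the profile sum over that window.
#'
#' @param interactions data.frame from [scan_transcriptome()].
#' @param profiles list from [build_degradome_profile()].
#' @param window maximum |offset| in nt (default 5).
#' @return `interactions` with `status` and `tag_support` updated.
#' @export
validate_cleavage <- function(interactions, profiles, window = 5L) {
  for (i in seq_len(nrow(interactions))) {
    tid <- interactions$transcript_id[i]
    prof <- profiles[[tid]]
    if (is.null(prof) || !length(prof)) next
    pos <- as.integer(names(prof))
    hit <- abs(pos - interactions$cleavage_pos[i]) <= window & prof > 0
    if (any(hit)) {
      interactions$status[i] <- "validated"
      interactions$tag_support[i] <- sum(prof[hit])
    }
  }
  interactions
}

#' Flag interactions whose targets belong to pathway gene lists
#'
#' @param interactions data.frame from [scan_transcriptome()].
#' @param gene_lists named list mapping pathway name to gene/transcript ids
#'   (building the lists is up to the user).
#' @return `interactions` with one logical column per pathway; the
#'   per-pathway summary (distinct miRNAs, distinct targets) is attached as
#'   attribute `"pathway_summary"`. Unknown ids in the lists produce a
#'   warning, not an error.
#' @export
annotate_pathway_targets <- function(interactions, gene_lists) {
  summaries <- list()
  for (pw in names(gene_lists)) {
    ids <- gene_lists[[pw]]
    unknown <- setdiff(ids, unique(interactions$transcript_id))
    if (length(unknown))
      warning("pathway '", pw, "': ", length(unknown),
              " gene id(s) not among targets")
    col <- paste0("pathway_", pw)
    interactions[[col]] <- interactions$transcript_id %in% ids
    summaries[[pw]] <- data.frame(
      pathway = pw,
      n_mirnas = length(unique(interactions$mirna_id[interactions[[col]]])),
      n_targets = length(unique(interactions$transcript_id[interactions[[col]]])),
      stringsAsFactors = FALSE)
  }
  attr(interactions, "pathway_summary") <- if (length(summaries))
    do.call(rbind, summaries) else NULL
  interactions
}

#' Export per-transcript T-plot data
#'
#' @param profiles list from [build_degradome_profile()].
#' @param path output TSV path (columns transcript, position, count).
#' @return `path`, invisibly.
#' @export
write_tplot_data <- function(profiles, path) {
  rows <- list()
  for (tid in names(profiles)) {
    prof <- profiles[[tid]]
    if (!length(prof)) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript = tid, position = as.integer(names(prof)),
      count = unname(prof), stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript = character(), position = integer(),
               count = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
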