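#' Construct a GenomeSet
#'
#' A GenomeSet holds labelled chromosome sequences together with their
#' subgenome assignment (`A`, `C` or `unplaced`) and is the coordinate frame
#' for every locus in the package. Allotetraploid genomes carry both `A` and
#' `C` chromosomes; progenitor genomes carry one of the two.
#'
#' @param seqs named character vector or `DNAStringSet` of chromosome
#'   sequences (alphabet ACGTN; stored uppercase).
#' @param subgenome_of named character vector mapping chromosome id to a
#'   label in `A`, `C`, `unplaced`. When `NULL`, labels are inferred from the
#'   leading letter of each chromosome id (`A01` -> `A`, `C01` -> `C`,
#'   anything else -> `unplaced`).
#' @return an object of class `GenomeSet` with elements `seqs` (named
#'   uppercase character vector) and `subgenome_of`.
#' @export
genome_set <- function(seqs, subgenome_of = NULL) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("chromosome ids must be present and unique")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("chromosome(s) with characters outside ACGTN: ",
         paste(names(seqs)[bad], collapse = ", "))
  if (is.null(subgenome_of)) subgenome_of <- infer_subgenome(names(seqs))
  if (!all(names(seqs) %in% names(subgenome_of)))
    stop("subgenome labels must cover all chromosome ids")
  subgenome_of <- subgenome_of[names(seqs)]
  if (!all(subgenome_of %in% c("A", "C", "unplaced")))
    stop("subgenome labels must be 'A', 'C' or 'unplaced'")
  structure(list(seqs = seqs, subgenome_of = subgenome_of),
            class = "GenomeSet")
}

#' Infer subgenome labels from chromosome ids
#'
#' @param ids character vector of chromosome ids.
#' @return named character vector of labels (`A`, `C`, `unplaced`).
#' @export
infer_subgenome <- function(ids) {
  lab <- ifelse(grepl("^A", ids), "A", ifelse(grepl("^C", ids), "C", "unplaced"))
  stats::setNames(lab, ids)
}

#' Total sequence length per subgenome
#'
#' @param genome a [genome_set()].
#' @return named numeric vector of nucleotide totals, one per label present.
#' @export
subgenome_lengths <- function(genome) {
  stopifnot(inherits(genome, "GenomeSet"))
  out <- tapply(nchar(genome$seqs), genome$subgenome_of, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' @export
print.GenomeSet <- function(x, ...) {
  cat("GenomeSet:", length(x$seqs), "chromosome(s),",
      sum(nchar(x$seqs)), "nt\n")
  tab <- table(x$subgenome_of)
  cat("  subgenomes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a collapsed small-RNA library
#'
#' Unique read sequences with copy numbers plus the library metadata used by
#' normalization (the clean-read total is the RPM denominator).
#'
#' @param reads named integer vector: names are read sequences (ACGT, U is
#'   converted to T), values are positive copy numbers.
#' @param id library identifier.
#' @param line line name (e.g. a cultivar or a derived line).
#' @param tissue tissue label.
#' @param environment environment tag (e.g. `"E1"`).
#' @param clean_total clean-read total; defaults to the sum of counts. Must
#'   be at least the sum of counts.
#' @return an object of class `SmallRNALibrary`.
#' @export
srna_library <- function(reads, id = "lib1", line = NA_character_,
                         tissue = NA_character_, environment = NA_character_,
                         clean_total = NULL) {
  if (length(reads) && (is.null(names(reads)) || any(names(reads) == "")))
    stop("reads must be a named vector (names are sequences)")
  seqs <- chartr("Uu", "Tt", toupper(names(reads)))
  if (any(grepl("[^ACGT]", seqs))) stop("read with characters outside ACGT/U")
  counts <- as.integer(reads)
  if (length(counts) && any(counts <= 0L)) stop("read counts must be positive")
  if (anyDuplicated(seqs)) {
    counts <- as.integer(tapply(counts, seqs, sum))
    seqs <- sort(unique(seqs))
  }
  names(counts) <- seqs
  if (is.null(clean_total)) clean_total <- sum(as.numeric(counts))
  if (length(counts) && clean_total < sum(as.numeric(counts)))
    stop("clean_total smaller than the sum of read counts")
  structure(list(id = id, line = line, tissue = tissue,
                 environment = environment, reads = counts,
                 clean_total = as.numeric(clean_total)),
            class = "SmallRNALibrary")
}

#' @export
print.SmallRNALibrary <- function(x, ...) {
  cat(sprintf("SmallRNALibrary '%s' (%s, %s): %d unique reads, %s total, clean total %s\n",
              x$id, x$line, x$environment, length(x$reads),
              format(sum(as.numeric(x$reads)), big.mark = ","),
              format(x$clean_total, big.mark = ",")))
  invisible(x)
}
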