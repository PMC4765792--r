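#' Read a FASTA file into a named character vector
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id: ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs))) stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a collapsed small-RNA FASTA into a SmallRNALibrary
#'
#' Collapsed-read headers follow the `>name_x<count>` dialect, where the
#' suffix after the final `_x` is the copy number of the unique read.
#'
#' @param path path to a collapsed FASTA file.
#' @param clean_total clean-read total; defaults to the sum of counts.
#' @inheritParams srna_library
#' @return a [srna_library()].
#' @export
read_srna_fasta <- function(path, id = basename(path), line = NA_character_,
                            tissue = NA_character_,
                            environment = NA_character_, clean_total = NULL) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  m <- regmatches(ids, regexpr("_x[0-9]+$", ids))
  bad <- which(lengths(regmatches(ids, gregexpr("_x[0-9]+$", ids))) == 0L)
  if (length(bad))
    stop("malformed collapsed-read header (no _x<count> suffix) at record ",
         bad[1], ": '", ids[bad[1]], "'")
  counts <- as.integer(sub("^_x", "", m))
  srna_library(stats::setNames(counts, unname(seqs)), id = id, line = line,
               tissue = tissue, environment = environment,
               clean_total = clean_total)
}

#' Write a SmallRNALibrary as collapsed FASTA
#'
#' Records are ordered by decreasing count then sequence, with headers
#' `>srr<i>_x<count>`.
#'
#' @param lib a [srna_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_srna_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "SmallRNALibrary"))
  ord <- order(-lib$reads, names(lib$reads))
  seqs <- names(lib$reads)[ord]
  counts <- lib$reads[ord]
  write_fasta(stats::setNames(seqs, sprintf("srr%d_x%d", seq_along(seqs), counts)),
              path)
}

#' Read a reference of known mature miRNAs (miRBase-like FASTA)
#'
#' Family names are derived from record ids by stripping a species prefix
#' (`xxx-`) and a trailing lowercase variant letter plus optional copy
#' suffix, so `ath-miR156a-5p`, `miR156a` and `miR156` all map to family
#' `miR156`.
#'
#' @param path FASTA of mature sequences.
#' @return named list mapping family name to a character vector of mature
#'   sequences (T alphabet).
#' @export
read_mature_reference <- function(path) {
  seqs <- chartr("U", "T", read_fasta(path))
  fam <- mature_family_name(names(seqs))
  split(unname(seqs), fam)
}

mature_family_name <- function(ids) {
  x <- sub("^[a-z]{3,4}-", "", ids)
  x <- sub("-[35]p$", "", x)
  x <- sub("[a-z]$", "", x)
  x
}

#' Read a GFF3 file
#'
#' Coordinates are converted from the file's 1-based inclusive convention to
#' the package's internal 0-based half-open convention. `ID`, `Parent` and
#' `ortho_family` attributes are extracted into columns; the raw attribute
#' string is preserved so that writing reproduces the table byte for byte.
#'
#' @param path path to a 9-column GFF3 file.
#' @return data.frame with columns `seqid`, `source`, `type`, `start`
#'   (0-based), `end` (exclusive), `score`, `strand`, `phase`,
#'   `attributes`, `ID`, `Parent`, `ortho_family`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(empty_gff())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L))
    stop("GFF3 line without 9 columns: line ", which(lengths(f) != 9L)[1])
  m <- do.call(rbind, f)
  start1 <- as.integer(m[, 4])
  end1 <- as.integer(m[, 5])
  if (any(is.na(start1)) || any(is.na(end1)))
    stop("non-numeric GFF3 coordinates")
  if (any(start1 > end1))
    stop("GFF3 feature with start > end at line ", which(start1 > end1)[1])
  if (!all(m[, 7] %in% c("+", "-", ".")))
    stop("unknown strand symbol: ",
         paste(unique(m[, 7][!m[, 7] %in% c("+", "-", ".")]), collapse = ", "))
  attr_field <- m[, 9]
  data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
             start = start1 - 1L, end = end1, score = m[, 6],
             strand = m[, 7], phase = m[, 8], attributes = attr_field,
             ID = gff_attr(attr_field, "ID"),
             Parent = gff_attr(attr_field, "Parent"),
             ortho_family = gff_attr(attr_field, "ortho_family"),
             stringsAsFactors = FALSE)
}

gff_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(attrs, regexpr(pat, attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs)
  out[hit] <- sub(pat, "\\1", regmatches(attrs, regexpr(pat, attrs)))
  out
}

empty_gff <- function() {
  data.frame(seqid = character(), source = character(), type = character(),
             start = integer(), end = integer(), score = character(),
             strand = character(), phase = character(),
             attributes = character(), ID = character(), Parent = character(),
             ortho_family = character(), stringsAsFactors = FALSE)
}

#' Write features as GFF3
#'
#' The inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive. The raw `attributes` column is written
#' verbatim.
#'
#' @param features data.frame as returned by [read_gff3()] (only the nine
#'   standard columns are used).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    writeLines(paste(features$seqid, features$source, features$type,
                     features$start + 1L, features$end, features$score,
                     features$strand, features$phase, features$attributes,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Build a GFF3 attribute string
#'
#' @param ... named scalar attribute values; `NA` entries are dropped.
#' @return a single `key=value;...` string.
#' @export
gff_attributes <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(x) is.null(x) || is.na(x), logical(1))]
  paste(paste0(names(kv), "=", unlist(kv)), collapse = ";")
}

#' Write a GenomeSet as FASTA
#'
#' @param genome a [genome_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "GenomeSet"))
  write_fasta(genome$seqs, path)
}

#' Read a genome FASTA into a GenomeSet
#'
#' @param path FASTA path.
#' @param subgenome_of optional explicit labels; inferred from ids otherwise.
#' @return a [genome_set()].
#' @export
read_genome_fasta <- function(path, subgenome_of = NULL) {
  genome_set(read_fasta(path), subgenome_of)
}
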