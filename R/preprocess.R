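#' Filter a library by read length
#'
#' Reads outside `[min_len, max_len]` are removed and the clean-read total
#' is recomputed as the sum of the retained counts (the "clean reads"
#' denominator used for RPM normalization downstream).
#'
#' @param library a [srna_library()].
#' @param min_len,max_len inclusive length bounds (defaults 18 and 44 nt,
#'   the raw-read range retained in small-RNA studies of this design).
#' @return a filtered [srna_library()].
#' @export
length_filter <- function(library, min_len = 18L, max_len = 44L) {
  stopifnot(inherits(library, "SmallRNALibrary"))
  if (min_len <= 0L || min_len > max_len)
    stop("need 0 < min_len <= max_len")
  len <- nchar(names(library$reads))
  keep <- len >= min_len & len <= max_len
  library$reads <- library$reads[keep]
  library$clean_total <- sum(as.numeric(library$reads))
  library
}

#' Remove reads matching annotated non-coding RNAs
#'
#' A read is removed when it is an exact substring of any reference sequence
#' on either strand (U and T equivalent). A read matching several classes is
#' removed once and tallied under the first matching class in the fixed
#' order snoRNA < tRNA < rRNA < rasiRNA. By default the clean-read total is
#' left untouched: "clean reads" is the post-length-filter, pre-ncRNA-filter
#' total.
#'
#' @param library a [srna_library()].
#' @param reference named list mapping class label to a character vector of
#'   reference sequences.
#' @param update_clean_total recompute the clean-read total after removal
#'   (default `FALSE`).
#' @return the filtered library; the removal report (class, unique reads
#'   removed, total count removed) is attached as attribute
#'   `"removal_report"`.
#' @export
filter_ncrna <- function(library, reference,
                         update_clean_total = FALSE) {
  stopifnot(inherits(library, "SmallRNALibrary"))
  class_order <- c("snoRNA", "tRNA", "rRNA", "rasiRNA")
  classes <- c(intersect(class_order, names(reference)),
               setdiff(names(reference), class_order))
  if (any(lengths(reference) == 0L) ||
      any(vapply(reference, function(x) any(!nzchar(x)), logical(1))))
    stop("reference class with empty sequences")
  reads <- names(library$reads)
  removed_class <- rep(NA_character_, length(reads))
  if (length(reads)) {
    for (cl in classes) {
      refs <- chartr("U", "T", toupper(reference[[cl]]))
      subjects <- c(refs, reverse_complement(refs))
      todo <- which(is.na(removed_class))
      if (!length(todo)) break
      hit <- vapply(reads[todo], function(r) {
        any(vapply(subjects, function(s) {
          length(Biostrings::matchPattern(r, s)) > 0L
        }, logical(1)))
      }, logical(1))
      removed_class[todo[hit]] <- cl
    }
  }
  report <- data.frame(
    class = classes,
    unique_removed = vapply(classes, function(cl)
      sum(removed_class == cl, na.rm = TRUE), integer(1)),
    count_removed = vapply(classes, function(cl)
      sum(library$reads[which(removed_class == cl)]), numeric(1)),
    stringsAsFactors = FALSE)
  library$reads <- library$reads[is.na(removed_class)]
  if (update_clean_total)
    library$clean_total <- sum(as.numeric(library$reads))
  attr(library, "removal_report") <- report
  library
}

#' Reads-per-million normalization
#'
#' RPM = read count / clean-read total x 10^6.
#'
#' @param count non-negative read count (vectorized).
#' @param clean_total positive clean-read total.
#' @return numeric RPM value(s).
#' @export
compute_rpm <- function(count, clean_total) {
  if (any(clean_total <= 0)) stop("clean_total must be positive")
  count / clean_total * 1e6
}

#' Write a per-class ncRNA removal report
#'
#' @param library a library returned by [filter_ncrna()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(library, path) {
  rep <- attr(library, "removal_report")
  if (is.null(rep)) stop("library carries no removal report")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
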