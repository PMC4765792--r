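#' Count small-RNA reads over mature miRNA spans
#'
#' A read contributes its full count to a mature miRNA when its alignment
#' lies within that mature's genomic span (with `slack` nt of tolerance at
#' each end, default 2). A read falling within mature spans on both the A
#' and the C subgenome contributes its full count to BOTH tallies (the
#' dual-subgenome read is counted twice).
#'
#' @param library a [srna_library()].
#' @param loci locus table with columns `locus_id`, `chrom`, `strand`,
#'   `mature_start`, `mature_end` (0-based half-open), `mature_seq`,
#'   `subgenome`.
#' @param alignments alignments of this library from [map_reads_exact()];
#'   computed on the fly when `NULL`.
#' @param genome needed only when `alignments` is `NULL`.
#' @param slack positional tolerance in nt (default 2).
#' @return data.frame with `locus_id`, `count` and `rpm` (one row per
#'   locus, in `loci` order).
#' @export
count_mature_reads <- function(library, loci, alignments = NULL,
                               genome = NULL, slack = 2L) {
  stopifnot(inherits(library, "SmallRNALibrary"))
  if (is.null(alignments)) {
    if (is.null(genome)) stop("provide alignments or a genome")
    alignments <- map_reads_exact(library, genome)
  }
  counts <- stats::setNames(numeric(nrow(loci)), loci$locus_id)
  if (nrow(alignments)) {
    for (chrom in unique(loci$chrom)) {
      li <- which(loci$chrom == chrom)
      ai <- which(alignments$chrom == chrom)
      if (!length(ai)) next
      spans <- IRanges::IRanges(start = loci$mature_start[li] + 1L - slack,
                                end = loci$mature_end[li] + slack)
      reads <- IRanges::IRanges(start = alignments$start[ai] + 1L,
                                end = alignments$end[ai])
      ov <- IRanges::findOverlaps(reads, spans, type = "within")
      if (!length(ov)) next
      same_strand <- alignments$strand[ai][S4Vectors_from(ov)] ==
        loci$strand[li][S4Vectors_to(ov)]
      add <- tapply(alignments$count[ai][S4Vectors_from(ov)][same_strand],
                    loci$locus_id[li][S4Vectors_to(ov)][same_strand], sum)
      counts[names(add)] <- counts[names(add)] + add
    }
  }
  data.frame(locus_id = loci$locus_id, count = unname(counts),
             rpm = compute_rpm(unname(counts), library$clean_total),
             stringsAsFactors = FALSE)
}

#' Build an expression matrix over libraries
#'
#' @param libraries list of [srna_library()] objects.
#' @param loci locus table (see [count_mature_reads()]).
#' @param genome a [genome_set()] (each library is mapped exactly).
#' @param slack positional tolerance in nt.
#' @return list of class `ExpressionMatrix`: `loci` (the annotation),
#'   `counts` and `rpm` (numeric matrices, rows = loci, columns =
#'   libraries), `libraries` (metadata data.frame with `id`, `line`,
#'   `tissue`, `environment`, `clean_total`).
#' @export
build_expression_matrix <- function(libraries, loci, genome, slack = 2L) {
  if (inherits(libraries, "SmallRNALibrary")) libraries <- list(libraries)
  ids <- vapply(libraries, function(l) l$id, character(1))
  counts <- matrix(0, nrow = nrow(loci), ncol = length(libraries),
                   dimnames = list(loci$locus_id, ids))
  rpm <- counts
  for (j in seq_along(libraries)) {
    col <- count_mature_reads(libraries[[j]], loci, genome = genome,
                              slack = slack)
    counts[, j] <- col$count
    rpm[, j] <- col$rpm
  }
  meta <- data.frame(
    id = ids,
    line = vapply(libraries, function(l) l$line, character(1)),
    tissue = vapply(libraries, function(l) l$tissue, character(1)),
    environment = vapply(libraries, function(l) l$environment, character(1)),
    clean_total = vapply(libraries, function(l) l$clean_total, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(loci = loci, counts = counts, rpm = rpm, libraries = meta),
            class = "ExpressionMatrix")
}

#' Subgenome expression partition test
#'
#' Compares miRNA expression between the A and C subgenomes over a set of
#' libraries. The per-mature statistic is the total RPM per unique mature
#' miRNA (mean RPM across the chosen libraries, summed per subgenome and
#' divided by the number of matures); the per-Mb statistic divides the
#' summed RPM by the subgenome length in Mb. The p-value is a two-sided
#' Wilcoxon rank-sum test on the per-mature RPM values of A vs C (exact
#' when both groups have at most `exact_max` matures).
#'
#' @param mat an [build_expression_matrix()] result.
#' @param library_ids libraries to use (default: all).
#' @param mode `"per_mature"` or `"per_mb"` for the reported statistic.
#' @param genome required for `"per_mb"` (subgenome lengths).
#' @param exact_max exact-permutation limit for the rank-sum test
#'   (default 10 per group).
#' @return list of class `PartitionResult`: `mean_A`, `mean_C`, `ratio`
#'   (C/A), `p_value`, `test`, `n_A`, `n_C`, `mode`, `library_ids`.
#' @export
subgenome_partition_test <- function(mat, library_ids = NULL,
                                     mode = c("per_mature", "per_mb"),
                                     genome = NULL, exact_max = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (is.null(library_ids)) library_ids <- mat$libraries$id
  rpm <- mat$rpm[, library_ids, drop = FALSE]
  expr <- rowMeans(rpm)
  a <- expr[mat$loci$subgenome == "A"]
  c_ <- expr[mat$loci$subgenome == "C"]
  if (length(a) < 2L || length(c_) < 2L)
    stop("need at least two mature miRNAs per subgenome")
  if (mode == "per_mature") {
    mean_a <- sum(a) / length(a)
    mean_c <- sum(c_) / length(c_)
  } else {
    if (is.null(genome)) stop("per_mb mode needs the genome")
    len <- subgenome_lengths(genome) / 1e6
    mean_a <- sum(a) / len[["A"]]
    mean_c <- sum(c_) / len[["C"]]
  }
  exact <- length(a) <= exact_max && length(c_) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(a, c_, exact = exact))
  list(mean_A = mean_a, mean_C = mean_c, ratio = mean_c / mean_a,
       p_value = wt$p.value,
       test = if (exact) "wilcoxon rank-sum (exact)" else
         "wilcoxon rank-sum (normal approximation)",
       n_A = length(a), n_C = length(c_), mode = mode,
       library_ids = library_ids)
}

#' MIRNA loci per Mb per subgenome
#'
#' @param loci locus table with `subgenome`.
#' @param genome a [genome_set()].
#' @return named numeric vector of loci per Mb for each subgenome present
#'   in the genome.
#' @export
mirna_density <- function(loci, genome) {
  len <- subgenome_lengths(genome)
  if (any(len == 0)) stop("zero-length subgenome")
  sgs <- names(len)
  stats::setNames(vapply(sgs, function(sg)
    sum(loci$subgenome == sg) / (len[[sg]] / 1e6), numeric(1)), sgs)
}

#' Differential expression between two library groups
#'
#' Fold change of mean RPM (with pseudo-count `eps` added to both means);
#' a miRNA is differentially expressed when the fold change is strictly
#' greater than `fold` or strictly smaller than `1/fold`.
#'
#' @param mat an [build_expression_matrix()] result.
#' @param group1,group2 library id vectors.
#' @param fold fold-change threshold (default 2).
#' @param eps pseudo-count in RPM (default 0.1).
#' @return data.frame `locus_id`, `mean1`, `mean2`, `fold_change`
#'   (group1/group2 on pseudo-counted means), `de` (logical), `direction`
#'   (`"up"` in group1, `"down"`, or `"ns"`).
#' @export
differential_expression <- function(mat, group1, group2, fold = 2,
                                    eps = 0.1) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  m1 <- rowMeans(mat$rpm[, group1, drop = FALSE])
  m2 <- rowMeans(mat$rpm[, group2, drop = FALSE])
  fc <- (m1 + eps) / (m2 + eps)
  de <- fc > fold | fc < 1 / fold
  data.frame(locus_id = mat$loci$locus_id, mean1 = m1, mean2 = m2,
             fold_change = fc, de = de,
             direction = ifelse(!de, "ns", ifelse(fc > fold, "up", "down")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Additive vs non-additive heredity of miRNA expression
#'
#' The mid-parent value (MPV) is the average of the two parental mean RPMs.
#' A miRNA is called non-additive when the derived-line mean deviates from
#' the MPV by at least `fold` in either direction (inclusive: a change of
#' at least two-fold), on pseudo-counted values.
#'
#' @param mat an [build_expression_matrix()] result.
#' @param parent1,parent2,derived library id vectors (all non-empty).
#' @param fold threshold (default 2).
#' @param eps pseudo-count in RPM substituted for zero means only, so that
#'   the inclusive two-fold boundary is exact on nonzero values
#'   (default 0.1).
#' @return data.frame `locus_id`, `mpv`, `derived_mean`, `log2_deviation`,
#'   `call` (`"additive"`/`"non-additive"`); summary counts and the
#'   non-additive:additive ratio attached as attribute `"summary"`.
#' @export
heredity_classification <- function(mat, parent1, parent2, derived,
                                    fold = 2, eps = 0.1) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!length(parent1) || !length(parent2) || !length(derived))
    stop("parent1, parent2 and derived library sets must be non-empty")
  p1 <- rowMeans(mat$rpm[, parent1, drop = FALSE])
  p2 <- rowMeans(mat$rpm[, parent2, drop = FALSE])
  dm <- rowMeans(mat$rpm[, derived, drop = FALSE])
  mpv <- (p1 + p2) / 2
  # eps substitutes for zeros only, so the inclusive two-fold boundary is
  # exact on nonzero values (a derived mean of exactly 2 x MPV is called)
  dev <- log2(ifelse(dm == 0, eps, dm) / ifelse(mpv == 0, eps, mpv))
  call <- ifelse(abs(dev) >= log2(fold), "non-additive", "additive")
  out <- data.frame(locus_id = mat$loci$locus_id, mpv = mpv,
                    derived_mean = dm, log2_deviation = dev, call = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  n_non <- sum(call == "non-additive")
  n_add <- sum(call == "additive")
  attr(out, "summary") <- list(n_additive = n_add, n_nonadditive = n_non,
                               ratio_nonadditive_additive =
                                 if (n_add > 0) n_non / n_add else Inf,
                               fraction_nonadditive = n_non / length(call))
  out
}

#' Write an expression matrix as TSV (counts and RPM)
#'
#' @param mat an [build_expression_matrix()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  tab <- data.frame(locus_id = mat$loci$locus_id,
                    subgenome = mat$loci$subgenome,
                    mature_seq = mat$loci$mature_seq,
                    stringsAsFactors = FALSE)
  for (id in colnames(mat$counts)) {
    tab[[paste0("count_", id)]] <- mat$counts[, id]
    tab[[paste0("rpm_", id)]] <- round(mat$rpm[, id], 4)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
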