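#' Fold a candidate precursor into its minimum-energy hairpin structure
#'
#' The default backend (`"nn"`) computes the minimum free energy nested
#' secondary structure under a simplified nearest-neighbor model: stacking
#' energies for Watson-Crick and G:U pairs from a shipped parameter table,
#' hairpin/bulge/interior loop length penalties with logarithmic
#' extrapolation, an affine multibranch term, minimum loop 3 and no
#' pseudoknots. The `"maxpair"` backend performs Nussinov base-pair
#' maximization (its `delta_g` is minus the pair count, not kcal/mol) and
#' exists mainly for structure-counting cross-checks.
#'
#' @param sequence RNA or DNA string (T is read as U); non-ACGU(T)
#'   characters are an error.
#' @param backend `"nn"` (default) or `"maxpair"`.
#' @param min_len,max_len accepted sequence length range (defaults 40 and
#'   700 nt).
#' @return an object of class `HairpinFold`: `sequence`, `structure`
#'   (dot-bracket), `delta_g` (kcal/mol for `"nn"`), `pair_table` (1-based
#'   partner per position, 0 = unpaired) and `backend`.
#' @export
fold_hairpin <- function(sequence, backend = c("nn", "maxpair"),
                         min_len = 40L, max_len = 700L) {
  backend <- match.arg(backend)
  n <- nchar(sequence)
  if (n < min_len || n > max_len)
    stop("sequence length ", n, " outside [", min_len, ", ", max_len, "]")
  res <- if (backend == "nn") .fold_nn_cpp(sequence) else
    .fold_maxpair_cpp(sequence)
  res$backend <- backend
  class(res) <- "HairpinFold"
  res
}

#' @export
print.HairpinFold <- function(x, ...) {
  cat("HairpinFold (", x$backend, "): ", nchar(x$sequence), " nt, dG = ",
      x$delta_g, if (x$backend == "nn") " kcal/mol" else " (-pairs)", "\n",
      sep = "")
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Count base pairs by Nussinov maximization
#'
#' Convenience wrapper around the `"maxpair"` backend without the precursor
#' length gate; used for oracle comparisons on short sequences.
#'
#' @param sequence RNA/DNA string.
#' @return integer maximum number of nested pairs (minimum loop 3,
#'   Watson-Crick + G:U).
#' @export
max_base_pairs <- function(sequence) {
  .fold_maxpair_cpp(sequence)$n_pairs
}

#' Evaluate the miRNA/miRNA* duplex of a folded hairpin
#'
#' Given the fold and the mature interval (1-based, inclusive, in precursor
#' coordinates), locates the star arm as the set of positions paired with
#' the mature, extended by a 2-nt 3' overhang (Dicer convention), and
#' computes the duplex acceptance metrics.
#'
#' @param fold a [fold_hairpin()] result.
#' @param mature_start,mature_end 1-based inclusive mature interval.
#' @return list with `ok` (logical), `reason` (when rejected), and on
#'   success `matched_nt` (paired mature positions, Watson-Crick or G:U),
#'   `bulge_nt` (unpaired nucleotides between miRNA and miRNA*, counted on
#'   both strands of the duplex: unpaired mature positions plus unpaired
#'   star-arm positions inside the partner span), `spacing_nt` (nt between
#'   the loop-proximal ends of mature and star), `star_start`, `star_end`,
#'   `arm` (`"5p"`/`"3p"`).
#' @export
evaluate_duplex <- function(fold, mature_start, mature_end) {
  stopifnot(inherits(fold, "HairpinFold"))
  n <- nchar(fold$sequence)
  if (mature_start < 1L || mature_end > n || mature_start > mature_end)
    stop("mature interval outside the precursor")
  idx <- mature_start:mature_end
  partners <- fold$pair_table[idx]
  paired <- partners > 0L
  if (!any(paired))
    return(list(ok = FALSE, reason = "mature entirely unpaired"))
  if (any(partners[paired] >= mature_start & partners[paired] <= mature_end))
    return(list(ok = FALSE,
                reason = "mature pairs with itself (spans the loop)"))
  p <- partners[paired]
  if (!(all(p > mature_end) || all(p < mature_start)))
    return(list(ok = FALSE,
                reason = "mature partners on both arms (spans the loop)"))
  arm <- if (all(p > mature_end)) "5p" else "3p"
  star_lo <- min(p)
  star_hi <- max(p)
  # bulges are counted on both strands of the duplex: unpaired mature
  # positions plus star-arm positions inside the partner span that are not
  # paired with the mature
  star_unpaired <- (star_hi - star_lo + 1L) - sum(paired)
  if (arm == "5p") {
    spacing <- star_lo - mature_end - 1L
    star_hi <- min(star_hi + 2L, n)
  } else {
    spacing <- mature_start - star_hi - 1L
    star_lo <- max(star_lo - 2L, 1L)
  }
  list(ok = TRUE, reason = NA_character_,
       matched_nt = sum(paired), bulge_nt = sum(!paired) + star_unpaired,
       spacing_nt = spacing, star_start = star_lo, star_end = star_hi,
       arm = arm)
}
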