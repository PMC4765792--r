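# Independent oracles used across the suite. These are deliberately naive
# implementations (recursion/enumeration) kept separate from the package's
# dynamic-programming code paths.

rc_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Nussinov base-pair maximization by memoized recursion (min loop 3,
# Watson-Crick + G:U), structured as "last base unpaired or paired with k"
# -- a different decomposition than the package kernel.
nussinov_oracle <- function(seq) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(s)
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  memo <- new.env()
  f <- function(i, j) {
    if (j - i < 4) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i, j - 1)
    for (k in i:(j - 4)) {
      if (can_pair(s[k], s[j])) {
        left <- if (k > i) f(i, k - 1) else 0L
        best <- max(best, left + 1L + f(k + 1, j - 1))
      }
    }
    memo[[key]] <- best
    best
  }
  f(1L, n)
}

# exhaustive target-site scoring: enumerates every placement of the single
# target-side bulge by plain loops over expanded character vectors
target_score_oracle <- function(mirna, window, gu = 0.5, mm = 1, bulge = 2,
                                seed_from = 2, seed_to = 13, mult = 2) {
  m <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  w <- rev(strsplit(chartr("U", "T", toupper(window)), "")[[1]])
  d <- length(w) - length(m)
  pos_pen <- function(a, b) {
    if (paste0(a, b) %in% c("AT", "TA", "CG", "GC")) 0
    else if (paste0(a, b) %in% c("GT", "TG")) gu
    else mm
  }
  seed_w <- function(k) if (k >= seed_from && k <= seed_to) mult else 1
  best <- Inf
  bs <- if (d == 0) 0 else 0:length(m)
  for (b in bs) {
    sc <- if (d > 0) d * bulge * seed_w(b + 1) else 0
    for (k in seq_along(m)) {
      t_idx <- if (d == 0 || k <= b) k else k + d
      sc <- sc + pos_pen(m[k], w[t_idx]) * seed_w(k)
    }
    best <- min(best, sc)
  }
  best
}

# exact two-sided rank-sum permutation test by enumeration of all
# assignments of the pooled values into the two groups
ranksum_permutation_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  p
}

# naive all-positions exact substring scan on both strands
naive_map_oracle <- function(read, genome_seqs) {
  out <- list()
  for (chrom in names(genome_seqs)) {
    g <- genome_seqs[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else rc_chr(read)
      L <- nchar(pat)
      for (s in seq_len(nchar(g) - L + 1)) {
        if (substr(g, s, s + L - 1) == pat)
          out[[length(out) + 1]] <- data.frame(
            chrom = chrom, start = s - 1L, end = s + L - 1L,
            strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character())
}

# tiny deterministic genome fixture: two homeologous chromosomes with a
# read planted verbatim on both
fixture_genome <- function(seed = 42, len = 400) {
  set.seed(seed)
  a <- rand_seq(len)
  c_ <- rand_seq(len)
  genome_set(c(A01 = a, C01 = c_))
}
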