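---
title: "Methods: miRNA discovery and subgenome evolution analysis in allopolyploids"
author: "polymir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery and subgenome evolution analysis in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`polymir` analyses small-RNA sequencing data from an allotetraploid plant
(two subgenomes, here labelled A and C) and its two progenitor species. It
covers five analysis stages — MIRNA locus discovery, conserved/novel
classification, target prediction with degradome validation, microsynteny
orthology with gain/loss calling, and subgenome expression genetics — plus a
synthetic-data generator that plants a fully known ground truth so every
stage can be scored end to end.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
emulate.

# MIRNA discovery

## Read handling

Collapsed small-RNA libraries (`>id_x<count>` FASTA headers) are mapped to
the genome by exact matching on both strands (Aho–Corasick multi-pattern
search via Biostrings). Exactness is a deliberate choice: collapsed reads
are already error-filtered in this kind of study, the mismatch allowance of
the original mapping step is not parameterized anywhere we could follow, and
exact matching makes every downstream count exactly reproducible. `N` bases
in the genome never match. Clean-read totals (the RPM denominator) are the
post-length-filter totals (18–44 nt by default); filtering against a
non-coding RNA reference (snoRNA/tRNA/rRNA/rasiRNA, exact substring on
either strand) removes reads but by default does not change the denominator,
mirroring the order of operations in the study design this package follows.

## Candidate excision and folding

Reads supported by at least 2 copies in some library are clustered by
overlap (per chromosome and strand); the most abundant read of a cluster
(ties: lexicographically smallest) is the candidate mature, and two windows
`[mature_start - 300, mature_end]` and `[mature_start, mature_end + 300]`
are excised, 300 nt being the maximum mature/star spacing accepted
downstream.

Windows are folded with a simplified nearest-neighbor energy model written
for this package (Rcpp): Watson–Crick and G:U stacking energies from a
shipped parameter table, hairpin/bulge/interior loop penalties with
logarithmic length extrapolation (loop sizes up to 30), minimum hairpin loop
3, no pseudoknots. Multibranch loops are intentionally **not** modelled:
every stem closes a stem-loop, and the external loop may chain several
stems. For a hairpin screen this loses nothing relevant — a miRNA precursor
is a stem-loop — and keeps the fold quadratic, so a 320-nt window folds in
well under a second. A `maxpair` backend (Nussinov base-pair maximization)
ships alongside for oracle testing; the energy model in use is recorded in
pipeline metadata, because an absolute ΔG gate is only meaningful relative
to its model.

## Acceptance gates

A candidate becomes a locus when all of the following hold (every one
exposed in `pipeline_config()` and defaulting to its quoted value):

* hairpin free energy strictly below −18 kcal/mol;
* strictly more than 16 mature positions paired (Watson–Crick or G:U);
* strictly fewer than 4 bulged nucleotides between miRNA and miRNA*,
  counted on **both** strands of the duplex (unpaired mature positions plus
  unpaired star-arm positions inside the partner span). The two-sided count
  is what a duplex criterion means: counting only the mature side admits
  candidates whose "star" is a dispersed 30–55-nt region of a large random
  stem, which no annotator would call a miRNA duplex;
* mature/star spacing strictly below 300 nt;
* at least 2 supporting reads in one library;
* the mature lies on a single arm (no self-pairing).

The star arm is delimited as the positions paired with the mature extended
by a 2-nt 3′ overhang (Dicer convention); the convention only affects the
reported star interval, not the gates.

## Classification

A mature is *conserved* when its minimum global edit distance (unit costs,
U≡T) to any known mature in the reference set is ≤ 2, and *novel*
otherwise. Edit distance rather than Hamming distance handles the 20–24-nt
length heterogeneity of plant matures; `utils::adist` provides it. Ties go
to the lexicographically smallest family. Novel miRNAs are numbered in
discovery order (`bna_novel_miRX1`, ...). Loci identical in position are
merged; the same mature at two genomic positions is two loci, because copy
numbers are counted per subgenome.

# Targets and degradome

Target sites are scored on the antiparallel duplex (miRNA 5′→3′ against the
target 3′→5′) with an Allen-style penalty scheme: 0 per Watson–Crick pair,
0.5 per G:U, 1 per mismatch, 2 per bulged target nucleotide, all doubled at
miRNA positions 2–13; at most one target-side bulge of up to 3 nt. The
scheme is a documented reimplementation — the original web service is not
versioned, so reproducibility wins over fidelity — and every weight is a
function argument. Sites with expectation ≤ 3.0 are retained; overlapping
windows of one miRNA/transcript pair collapse to the best-scoring one. The
predicted cleavage position is the transcript nucleotide paired with miRNA
position 10 (AGO slices between 10 and 11).

Degradome tags are exact-matched to transcripts (sense strand only — tags
are 3′ cleavage fragments), counts accumulated at the 5′ end. An
interaction is *validated* when any nonzero profile position lies within 5
nt of the predicted cleavage position, inclusive — the most permissive
literal reading of the 5-nt rule, stated in output metadata. No abundance
significance test is applied because none is normative for this design.

# Microsynteny and gain/loss

For every locus the 10 nearest protein-coding genes per side are retrieved,
keyed by `ortho_family` labels in the GFF3 (the synthetic generator writes
them; real data needs a user-supplied ortholog map — the "identical flanking
gene" notion presupposes a homology call that we refuse to hide inside this
package). Homologous copies of a precursor are found by a seed-and-extend
ungapped-core search (12-mer seeds, diagonal collapse, maximal-scoring
segment with +1/−2 scoring) gated on query coverage > 0.9 and a
Karlin–Altschul-style significance < 1e−5 (λ solved from the score scheme at
uniform composition, K fixed at 0.3 — an explicit, reproducible stand-in for
an unversioned BLASTN), keeping the top 5 hits. A pair is syntenic when it
shares ≥ 1 flanking ortho-family upstream or downstream; the four synteny
sets are: 1 both sides, 2 upstream only, 3 downstream only, 4 neither, with
1–3 counted as syntenic — a concrete interpretation, since the four-set
definition is cited but never restated in the sources this design follows.

A progenitor locus is **lost** when its precursor has no retained hit in the
tetraploid. A tetraploid locus is **gained** when no retained hit in either
progenitor lies in a syntenic context. Best hits landing on the
non-corresponding subgenome (A progenitor vs C subgenome or vice versa) are
tallied separately.

# Expression genetics

Reads are counted into a mature miRNA when their alignment lies within the
mature span (±2 nt slack — a literal reading of "within the length of the
mature sequence" with room for 1–2-nt end heterogeneity). A read falling in
mature spans on both subgenomes contributes its full count to both tallies.
The per-mature partition statistic is total RPM divided by the number of
unique matures per subgenome; the per-Mb statistic divides by subgenome
length. The test is a two-sided Wilcoxon rank-sum on per-mature RPM (exact
for ≤ 10 per group, normal approximation otherwise) — the source design
states only a p-value threshold, so a nonparametric default suits the
heavily skewed RPM distributions. Environments are never pooled.

Differential expression uses strict >2-fold on pseudo-counted means
(ε = 0.1 RPM added to both). Heredity compares the derived-line mean with
the mid-parent value (MPV): a deviation of **at least** two-fold either way
is non-additive. Because that boundary is inclusive, ε substitutes for zero
values only; adding it to both sides would silently exclude a derived mean
of exactly 2×MPV.

# The synthetic generator

The generator emulates the study design: two progenitor genomes carrying
homeologous MIRNA pairs, an allotetraploid with planted losses (in-place
disruption) and gains (duplication of a surviving locus into a new gene
neighbourhood), two parental lines and four DH lines sequenced in two
environments, a planted C:A expression bias, and 24-nt repeat-derived
background biased to the C subgenome.

Defaults are the study conditions: 100 loci per subgenome (2 chromosomes of
1 Mb each), library depth 10^6, background fraction 0.3, C:A expression
ratio 0.55, repeat background C:A ratio 10.3, 10 losses, 5 gains, 4 DH
lines, non-additive fraction 0.3 with scaling factors {4, 1/4} (safely
beyond the 2-fold call threshold, one factor per locus shared by all DH
lines), tetraploid divergence 0.002 substitutions/site (the allotetraploid
is evolutionarily very young). Per-locus expression is log-normal (meanlog
0, sdlog 1) — a free parameter of the generator, not a claim about any real
distribution; the C homeolog's expectation is ρ times its A partner's, so
the ratio estimator is nearly unbiased by construction. The second parent
and second environment receive independent log-normal perturbations (sdlog
0.3 and 0.2).

Design points worth calling out:

* **Hairpins are discoverable by construction.** Mature (21 nt, GC ≥ 0.4 —
  typical of plant matures, and necessary for a perfect stem to clear the
  −18 kcal/mol gate with margin) + loop (40–80 nt) + reverse complement
  with 1–3 planted G:U wobbles and at most one true mismatch. At
  `mutation_rate = 0` each planted locus is re-folded exactly as discovery
  will see it (precursor plus genomic flank) and regenerated if it fails
  the gates, so recovery tests measure the pipeline, not the generator's
  luck.
* **Homeolog matures differ by ≥ 1 substitution**, so exact mapping assigns
  every read to one subgenome and the planted ρ is identifiable. (If
  homeologs shared matures, the double-counting rule would pull every
  estimated ratio toward 1; subgenome-specific calls in real data are
  likewise restricted to unique matures.) The double-counting rule itself
  is exercised by dedicated fixtures.
* **Gains move only the locus sequence**, not its flanking genes: a gained
  copy inherits the resident genes at its insertion site as its new flank
  context. Duplicating the ortho-labelled neighbourhood too would make
  gains syntenic with their progenitor source and hence undetectable under
  the synteny definition — the planted event would contradict the truth
  ledger.
* **Decoy cleavage positions are certified signal-free.** The degradome's
  uniform positional noise is resampled away from ±5 nt of each recorded
  decoy; a decoy exists precisely to certify that no tag sits there, and a
  truth ledger that allowed noise inside that window would be false.
* **Gains land away from their source's gene neighbourhood** (the
  insertion gap must share no ortho-family with the source's ±10-gene
  context): a duplicate next to its source would be syntenic with the
  progenitor, contradicting its own "gained" truth label. Relatedly, a
  best homology match is tallied on the opposite subgenome only when it
  scores strictly above every corresponding-subgenome hit, so the
  equal-score tie created by an identical duplicated copy resolves to the
  corresponding subgenome.
* **The paired expression model makes the unpaired rank-sum test
  conservative under the null.** Homeolog pairs share their abundance
  scale (the C copy is ρ times its A partner), so with ρ = 1 the two
  per-mature RPM samples are far more similar than two independent samples
  of the same size and the test rejects almost never. Nominal-level
  calibration is therefore checked under independent per-locus abundances
  — the exchangeability the test actually assumes — while power and
  ratio-recovery checks use the paired design.
* **Repeat windows are unique sequence** annotated as repeats; background
  reads are drawn from them with the configured C:A ratio. True multi-copy
  repeat families (and transposon annotation generally) are out of scope,
  as are sequencing errors, quality scores, adapters, isomiRs and star-arm
  reads. Passing recovery tests therefore demonstrates correctness of the
  pipeline's logic under clean reads, not robustness to base-calling noise.

# Problem sizes and numerical choices

The shipped tests run the full discovery recovery at the study-design scale
(2+2 × 1 Mb chromosomes, 200 planted loci, depth 10^6, background 0.3),
gain/loss and degradome fixtures at 40 loci per subgenome, and the bias
recovery at 300 homeolog pairs — sizes chosen so the planted statistical
structure is measurable with comfortable margins. Ties are always broken
lexicographically or by coordinate; every stochastic step flows from a
single integer seed (sub-seeds are derived arithmetically per stage, kept
below 2^31); energies are handled internally in integer centi-kcal/mol, so
equality comparisons in tracebacks are exact. Degenerate inputs (empty
libraries, zero-length subgenomes, loci without annotated genes) raise
explicit errors naming the violated precondition.

# Known limitations

* The ΔG gate is model-relative; absolute agreement with other folding
  engines is not expected, only rank agreement on hairpin-vs-not decisions.
* The E-value is a Karlin–Altschul approximation with fixed K; it orders
  hits sensibly and gates random 12-mer diagonals, but is not calibrated
  against any particular aligner.
* Expression heredity uses plain fold-change calls (per the design it
  follows); no dispersion modelling or replicate-aware testing is applied.
* Gene order inside the generator is collinear by construction, so synteny
  recovery on synthetic data is easier than on rearranged real genomes.
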