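# polymir

Small-RNA discovery, target validation and subgenome evolution analysis for
allopolyploid genomes.

## The problem

Allopolyploid plants such as oilseed rape carry two complete subgenomes (A
and C) inherited from two progenitor species. After the hybridization that
created them, their MIRNA gene complement keeps evolving — loci are lost,
new copies arise by duplication — and the two subgenomes need not express
their miRNAs equally. Quantifying this requires a chain of analyses that
are usually scattered across ad-hoc scripts:

1. **Discovery** of MIRNA loci from collapsed small-RNA reads: candidate
   precursor windows are excised around read clusters, folded, and accepted
   when the hairpin satisfies ΔG < −18 kcal/mol, more than 16 matched
   nucleotides and fewer than 4 bulged nucleotides between miRNA and
   miRNA\*, mature/star spacing < 300 nt, and ≥ 2 supporting reads in a
   library.
2. **Classification** as conserved (≤ 2 mismatches to a known mature) or
   novel.
3. **Target prediction** by complementarity scoring (Allen-style penalties,
   seed doubling at positions 2–13, expectation ≤ 3.0) and **degradome
   validation**: a predicted slice site (opposite miRNA positions 10–11) is
   confirmed when a degradome tag 5′ end lies within 5 nt of it.
4. **Microsynteny orthology** between tetraploid and progenitor loci (10
   flanking protein-coding genes per side, top-5 homology hits at coverage
   > 90% and E < 1e−5, ≥ 1 shared flanking gene), from which locus **losses
   and gains** are called.
5. **Expression genetics**: RPM = count / clean reads × 10⁶; per-subgenome
   partition statistics (reads per unique mature miRNA, reads per Mb) with
   a rank-sum test; reads mapping to mature loci on both subgenomes are
   counted twice; additive vs non-additive heredity in derived lines by a
   ≥ 2-fold deviation from the mid-parent value.

`polymir` implements the full chain as a tested R package, plus a synthetic
data generator that plants a known truth (loci, losses, gains, expression
bias, cleavage sites) so that every stage can be scored.

## A worked example

```r
library(polymir)

cfg <- simulation_config(seed = 42, n_mirna_loci_per_subgenome = 12,
                         chromosome_length = 2.5e5,
                         n_protein_genes_per_chromosome = 40,
                         library_depth = 5e4, mutation_rate = 0,
                         n_repeat_windows_per_chromosome = 3)
sim <- simulate_genomes(cfg)          # progenitors + tetraploid + truth
sim <- simulate_srna_libraries(sim)   # 12 collapsed libraries

loci <- discover_mirnas(sim$libraries[c("T_E1", "N_E1")], sim$tetraploid,
                        reference = sim$reference)
head(loci[, c("locus_id", "chrom", "strand", "mature_seq", "delta_g",
              "matched_nt", "bulge_nt", "class", "family")], 3)
```

```
    locus_id chrom strand            mature_seq delta_g matched_nt bulge_nt
 pm-A01-0001   A01      + CGTAAGCGCCAACCCGCATTT  -89.89         20        2
 pm-A01-0002   A01      - GCGAAGTTCGACGTTGCCGAT -109.75         21        0
 pm-A02-0001   A02      + TAAGGGAGACGACATCATCGC  -98.00         20        2
 class          family
 novel bna_novel_miRX1
 novel bna_novel_miRX2
 novel bna_novel_miRX3
```

Each row is an accepted MIRNA locus with its hairpin metrics (free energy
in kcal/mol under the package's nearest-neighbor model, matched and bulged
nucleotides of the miRNA/miRNA\* duplex) and its conserved/novel call. On
this toy genome all 19 planted-and-surviving loci are recovered.

```r
mat <- build_expression_matrix(
  sim$libraries[c("T_E1", "N_E1")],
  sim$truth$loci[sim$truth$loci$present_in_tetraploid, ],
  sim$tetraploid)
subgenome_partition_test(mat, mode = "per_mature")
```

```
C/A expression ratio: 0.857 (p = 5.67e-01, wilcoxon rank-sum (exact))
```

With only 12 homeolog pairs the planted C:A bias of 0.55 is within noise;
at the package's default scale (hundreds of pairs, depth 10⁶) the estimate
lands within a few percent of the planted value and the test is highly
significant (see below).

`run_pipeline(pipeline_config(...))` chains all stages (simulate →
preprocess → discover → targets → degradome → synteny → express → report)
into a run directory with per-stage TSV/GFF3/JSON outputs, and
`inst/scripts/run_pipeline.R` wraps it for the shell.

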