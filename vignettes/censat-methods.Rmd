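---
title: "Methods: reference-free discovery of centromeric repeats from ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free discovery of centromeric repeats from ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censat)
```

## The problem

Centromeres of plants with large genomes are dominated by rapidly evolving
satellite DNA and retrotransposons. When no assembled reference genome
exists, the sequences occupying functional centromeres can still be
identified by combining two read sets:

* **ChIP reads**: short reads (36 nt) from chromatin immunoprecipitated
  with an antibody against the centromeric histone variant CenH3, so reads
  from centromeric chromatin are over-represented;
* **input reads**: reads from the same chromatin preparation without
  immunoprecipitation, representing the genome at large.

Together with a low-coverage (0.48x) whole-genome survey of longer reads
(100 nt, the *reference reads*), repeat families can be discovered, their
CenH3 association quantified, and their genomic abundance estimated —
all without a genome assembly. `censat` implements this analysis
end-to-end, plus a synthetic-data generator to validate it at desk scale.

## Enrichment model

For any unit \(u\) (a reference read or a cluster of reference reads), let
\(c_u\) of \(C\) ChIP reads and \(i_u\) of \(I\) input reads map to it.
The enrichment is the ratio of mapped-read proportions:

\[ E_u = \frac{c_u / C}{i_u / I} \]

Units with \(E_u \ge 10\) are called CenH3-enriched (the threshold is
inclusive). Two strategies are implemented:

* **Approach A** (`run_approach_a()`): cluster a random sample of reference
  reads first (default up to 2 million), keep the 1000 clusters with the
  highest genome representation, assign each ChIP/input read to a single
  cluster, and compute \(E\) per cluster. Each read is assigned to the
  cluster of its best match; when equally good matches hit several
  clusters, the cluster with the higher genome representation wins.
* **Approach B** (`run_approach_b()`): compute \(E\) per reference read
  (counting a read once for every reference read it matches), select the
  reads with \(E \ge 10\), and cluster only those. This recovers
  low-abundance enriched families that fall below approach A's
  top-cluster cut, at the cost of many spurious single-read "clusters"
  from sampling noise (zero input hits make \(E\) infinite); these are
  dropped from profiling by the `min_cluster_reads` floor (default 5).

When the input count is zero but the ChIP count is positive, \(E\) is
reported as `Inf` by default (`zero_policy = "infinite"`); a pseudocount
policy is available. \(0/0\) is undefined and reported as `NA`.

## Read matching

ChIP and input reads (31 nt after QC) are matched against reference reads
allowing **at most 2 difference events**, where one event is either a
single-base substitution or one insertion/deletion *run*, with at most 4
total inserted/deleted bases; `N` never matches. The query must match
end-to-end (globally), anywhere within the reference (locally); both
strands are searched.

The matcher is seed-based: every overlapping k-mer of the query is looked
up in a reference index. For the completeness of seeding under \(d\)
difference events with at most \(B\) indel bases, the query length \(L\)
must satisfy \(L \ge (k-1)(d+1) + B + d\); for \(d = 2, B = 4\) the
default \(k = 9\) is complete for all queries of at least 30 nt
(`match_reads()` warns below this bound). Candidate diagonals are then
verified by an exact case analysis over 0-, 1- and 2-gap alignments, which
is why `match_params()` caps `max_differences` at 2. The verifier is
validated against a brute-force dynamic-programming oracle in the test
suite.

Note that a simple pigeonhole argument over three non-overlapping 10-mers
is *not* complete under these semantics: two deletion runs can split a
31-nt query such that every clean segment is shorter than 10. The
overlapping-k-mer scheme with the bound above avoids this.

## Clustering reads into families

Reads are vertices of a similarity graph; an edge joins two reads when a
local alignment (either strand) reaches at least 90% identity over at
least 55% of the shorter read. Connected components of this graph are the
repeat families. A canonical 13-mer prefilter limits the alignment work to
plausible pairs. Genome proportion is `n_members / total_reads`, where the
denominator stays the full reference-read count even when only enriched
reads were clustered.

A geometric consequence worth knowing when simulating data: with 100-nt
reads and the 55% overlap floor, two same-family reads connect only when
their positions (monomer phases, for a satellite) differ by at most 45 bp.
A family's reads must therefore tile its monomer phase space densely or
the family will split into several clusters. Density alone is not
sufficient under approach B: per-read enrichment integrates ChIP/input
hits over a 70-bp phase window, so the enrichment estimate is
autocorrelated along the phase circle with a roughly 70-bp correlation
length, and when the expected enrichment sits near the threshold a single
downward sampling excursion silently removes a *contiguous* 50–90 bp block
of reference reads — a hole no raw density can fill. Scaled-down fixtures
must therefore also keep the expected enrichment comfortably above the
threshold, which caps the total annotated proportion (more annotated bp
dilutes enrichment). In a real survey experiment satellite families are
megabases in size and enrichment ratios are far from the threshold, so
neither constraint binds; in simulations the copy numbers must balance the
two (see `pea_like_families()`).

## Profiling a family

For each cluster with at least `min_cluster_reads` members:

1. **Representative contig** (`assemble_representative()`): greedy overlap
   extension from the member reads (minimum overlap 15 nt at 85%
   identity), extending right, then left on the reverse complement. The
   short overlap floor lets assembly step across local holes in a
   family's phase coverage of up to 85 bp; against a non-repetitive
   consensus a 15-nt anchor at 85% identity is still effectively unique.
2. **Monomer length** (`estimate_monomer_length()`): the sequence is
   compared to itself at every shift; the smallest shift whose identity is
   within 0.02 of the best (and at least 0.8) is the monomer length.
   Taking the *smallest* near-best shift avoids reporting a multiple of
   the true period.
3. **Tandem verification** (`verify_tandem_organization()`): occurrences
   of the putative monomer (up to 15% mismatches) must appear adjacently
   (start-to-start distance at most 1.1 monomers) on one strand.
4. **Classification** (`classify_cluster()`): if the contig matches a
   known retroelement library at >= 80% identity over >= 50% of its
   length, it is `ltr_retroelement` — this takes precedence because long
   terminal repeats mimic periodicity; otherwise a verified tandem
   structure makes it `satellite`; otherwise `unclassified`.
5. **AT content** and, via `genome_proportion_to_mbp()`, genomic abundance
   in Mbp (proportion / 100 x genome size, default 4300 Mbp, half-up
   rounding to 2 decimals).

`pairwise_identity()` computes identity between two sequences with a
global-local alignment (the shorter sequence must align end-to-end;
identity is matches over alignment columns, counting internal gaps) and
reports percent identity: `pairwise_identity("ACGT", "ACGA")` is exactly
75.

## Quality control

Raw 36-nt reads are trimmed to 31 nt (excess split 5'-heavy: 3 bases off
the 5' end, 2 off the 3' end, unless explicit `trim_5p`/`trim_3p` are
given), then reads with more than one base below Q20 are removed.
Qualities are Phred+33. Every read is accounted for:
`input = kept + dropped_short + dropped_quality`.

## Synthetic genomes

`build_genome()` plants satellite arrays (head-to-tail monomer copies with
per-base substitution divergence) and retroelement insertions (two
identical LTRs flanking an internal region) into a random background, on
random strands, with exact AT-content control (the consensus has exactly
`round(length x AT)` A/T bases — important for short monomers, where
binomial sampling would routinely miss a +-0.02 check). ChIP reads are
sampled with per-position weights equal to the fold enrichment of the
family covering the read midpoint; input reads are sampled uniformly. The
analytic expectation is

\[ E_f = \frac{w_f}{\sum_g p_g w_g + p_{bg}} \]

for family \(f\) with fold \(w_f\) and genome proportions \(p\), available
as `expected_enrichment()`.

Generator defaults mirror the study design they emulate: 0.48x coverage of
100-nt reference reads, 36-nt ChIP/input reads trimmed to 31 nt, enrichment
threshold 10.

## Scale-down choices and limitations

* Fixture genomes are 2–10 Mbp rather than 4300 Mbp so the full pipeline
  runs in minutes on one CPU. Family *copy numbers* are set so each
  family's reference reads tile its monomer phase space at a mean gap of
  about 4 bp (see the clustering note above); the real experiment's
  families exceed this by orders of magnitude.
* The matcher's "2 differences" reading counts an indel run as one event
  (with at most 4 indel bases total); other tools count per-base.
* Identity thresholds for clustering (90%/55%) follow the established
  graph-clustering convention for 100-nt reads.
* Enrichment of multi-mapping ChIP/input reads is counted once per
  matching reference read (`policy = "count_all"`); a fractional policy is
  available for sensitivity analysis.
* No genome assembly, no FISH/microscopy quantification, and no claims
  about centromere function: outputs are sequence statistics only.

## A minimal run

```{r example, eval = FALSE}
families <- dplyr::bind_rows(
  satellite_family("SAT-A", monomer_length = 50, at_content = 0.72,
                   n_loci = 2, copies_per_locus = 80, divergence = 0.02,
                   fold_enrichment = 50),
  retroelement_family("RTE-1", element_length = 400, ltr_length = 50,
                      n_insertions = 55, at_content = 0.60,
                      divergence = 0.02, fold_enrichment = 50))
genome <- build_genome(families, background_length = 6e5, seed = 1)
reference <- simulate_reference_reads(genome, seed = 2)
reads <- simulate_chip_and_input(genome, n_chip = 3e4, n_input = 3e4,
                                 seed = 3)
run <- run_approach_b(reads$chip, reads$input, reference,
                      censat_config(seed = 4),
                      retro_library = genome$consensus["RTE-1"])
tidy(run)
glance(run)
```
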