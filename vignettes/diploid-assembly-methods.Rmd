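---
title: "Haplotype-aware correction and diploid string-graph assembly: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-aware correction and diploid string-graph assembly: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diphase)
```

# The problem

Long noisy reads (PacBio CLR, Nanopore) carry 5--15% sequencing error,
well above the 0.1--1.5% divergence between the two haplotypes of a
diploid genome. A conventional correct-then-assemble pipeline therefore
treats heterozygous alleles as errors: the consensus across supporting
reads from *both* haplotypes erases or mixes them, and the assembler
cannot phase what the corrector destroyed. `diphase` implements a
correct-then-assemble pipeline that keeps haplotype information at every
stage:

1. **Haplotype-aware error correction.** Each read is corrected on a
   partial-order alignment (POA) graph built from its overlapping reads,
   but only supporting reads likely to come from the template's own
   haplotype are allowed to vote.
2. **Round-1 assembly.** A string graph over the corrected reads yields
   haplotype-collapsed contigs.
3. **Read-level SNP calling and grouping.** Heterozygous sites are called
   from the pileup of corrected reads on the collapsed contigs; each
   read's allele vector is verified and corrected by centroid-based
   clustering, and read pairs whose groups disagree are flagged as
   *inconsistent* (reads from different haplotypes or repeat copies).
4. **Round-2 assembly.** Inconsistent overlaps are removed from the
   candidate set, the graph is rebuilt, and two sets of contigs are
   emitted: primary/alternate, or a dual assembly with one contig set per
   haplotype.

A built-in diploid read simulator generates genomes, reads and truth
labels, so every stage is testable without external data.

# Haplotype-aware correction

## The POA graph

For a template read, every supporting read (candidate overlap partner) is
aligned to it base by base. Each alignment column becomes a node labelled
$(c, r, b)$: template position $c$, consecutive-insertion rank $r$ (0 for
match/mismatch/deletion), and base $b \in \{A,C,G,T,-\}$. Edges connect
consecutive columns of an alignment; each edge records how many
alignments traverse it (the template contributes a trivial
self-alignment). For each position, every path passes exactly one node of
the $(c, 0, \cdot)$ family.

## Important in-edges and locations

A heterozygous site shows up as *two dominant parallel branches*, while a
random error gives one dominant branch plus low-support noise. An in-edge
of the $(c,0,\cdot)$ family with support $s_i$ is *important* when

$$ s_i \ge \begin{cases}
 r_l\,S & S \le S_l\\
 \frac{r_h S_h - r_l S_l}{S_h - S_l}(S - S_l) + r_l S_l & S_l < S \le S_h\\
 r_h\,S & S > S_h
\end{cases} $$

with $S$ the family's total in-edge support and defaults
$r_l = 0.5,\ r_h = 0.2,\ S_l = 10,\ S_h = 200$: at low coverage a branch
must hold half the reads, at high coverage one fifth. A location is
*important* when (1) it is not inside a template homopolymer run
($\ge 3$ bases by default), (2) two or more important in-edges close a
bubble when walked backwards, (3) more than half of the reads through
each important in-edge follow that bubble path, and (4) the bubble paths
differ by substitution only. Condition (4) excludes length-changing
(indel) bubbles, whose alignment placement is ambiguous; condition (1)
excludes homopolymers for the same reason.

## Scoring, selection, weighting

Each supporting read scores $+1$ per important location where it takes
the template's important in-edge and $-1$ where it takes a different
one; the tally is divided by the number of important locations the read
covers (a read covering none scores 0). When supporting reads come from
both haplotypes, the score histogram is bimodal. The histogram (bin width
0.1, one-bin moving-average smoothing) is searched for peaks; plateaus
count as single peaks and adjacent peaks separated by a shallow valley
(above half the smaller peak) are merged, because sparse histograms
otherwise fragment one mode into several spurious peaks. With two or more
peaks, all reads above the valley separating the highest-score peak from
the next are selected — at desk-scale support counts the highest-score
peak's own bin plus its neighbours proved too narrow, selecting a
handful of reads and leaving the template essentially uncorrected. With
one peak the top half (ties included) is selected. Selected scores are
mapped linearly onto $[0.4, 0.8]$ as weights; unselected reads get 0.

## Weighted consensus

Edge weights are the summed weights of selected reads passing the edge.
Nodes are scored in topological order,
$S_v = \max_u\{S_u + W_{(u,v)} - P_v\}$, sources at 0, with the column
penalty

$$ P_v = \max(0.4^{\,r+1},\ 0.3)\; W_c , $$

where $W_c$ is the summed weight of selected reads spanning position
$c$. Match/deletion columns ($r = 0$) therefore pay $0.4\,W_c$ — the
descendant of the classical half-coverage penalty — and insertion
columns decay to the floor $0.3\,W_c$. Writing the penalty factor as
$0.4^{r}$ would make the $r=0$ penalty equal to the full column weight;
every step of the dynamic program would then be non-positive and the
best-scoring node would collapse to an early tie at zero, truncating the
consensus, so the attenuated form is used with the same published
constants. The template's own path carries an epsilon weight so that
regions without selected support follow the template rather than
drifting through unselected branches, and the consensus is trimmed to
the span covered by roughly four selected reads (ends below that support
level retain too many raw errors to be worth keeping).

Supporting alignments are overlap-mode (both sequences' flanks free):
with global or reference-only-free alignment, support overhangs smear
into the template ends and leave a band of junk insertions there.

# Overlap filtering and the string graph

Candidate overlaps come from shared canonical minimizers (majority
relative strand, dominant diagonal). Alignments are extended to the read
ends over the flanking segments only; an overlap is removed when a
residual inner overhang exceeds $\min(100,\ 0.01\,l)$ for PacBio or
$\min(300,\ 0.03\,l)$ for Nanopore on the read of length $l$ carrying
it. Reads covered end-to-end inside another read (within the same
tolerance) are contained: their overlaps are removed but the reads are
kept aside for dead-end repair. Per-read overlap coverage outside
a configurable band (default 3--400) also removes overlaps.

The string graph has two nodes per read (5' and 3' ends) and an edge
pair per dovetail overlap (an edge and its reverse-complement twin; all
status changes apply to both). Transitive edges are marked inactive when
a two-edge path reproduces their length within a 500-bp fuzz. Identities
are then computed by banded alignment *only for the active edges*, and
edges fall below the threshold

$$ \big( (m_1 - 6 \cdot 1.253\,\mathrm{MAD}_1) +
   2 (m_2 - 6 \cdot 1.4826\,\mathrm{MAD}_2) \big) / 3 $$

($m_1$/$\mathrm{MAD}_1$ mean and mean absolute deviation,
$m_2$/$\mathrm{MAD}_2$ median and median absolute deviation of the
active-edge identities). Dead ends left by that removal are repaired by
reactivating the longest-alignment transitive edge above the threshold,
then by adding dovetail edges through contained reads.

Best-overlap selection ranks each node side's edges by the score
$(n^+ w - n^-,\ l)$ — SNP-agreement counts from the phasing stage, then
overlap length ($w = 0.5$). The top edge is a candidate; further edges
join only when their read is inconsistent with every current candidate
*and* the score gap stays below $\max(C, s_i R_1)$ for $s_i \ge 0$ or
$\max(C, -s_i R_2)$ otherwise ($C = 4, R_1 = 2, R_2 = 0.66$). Edges
confirmed from both sides become best; sides without one keep their top
edge. In round 1 no SNP evidence exists, so this degrades to the
classical longest-overlap rule. Tips (up to 3 reads), spurious links
(below 30% of the sibling maximum) and — in round 1 only — bubbles are
then removed, and maximal unbranched paths become contigs (cycles break
at the lowest-identity edge; paths never revisit a read).

# SNP calling, read grouping, inconsistent overlaps

Corrected reads are mapped back to the round-1 contigs. Duplicate
round-1 fragments (the second haplotype's rendition of a region already
represented) are first removed by mapping shorter contigs onto longer
ones — phasing against a duplicated reference would separate the
haplotypes *spatially* and hide every heterozygous site from the
pileup. A site is heterozygous when its coverage lies in $[10, 1000]$
and the second-most common base reaches the same piecewise threshold
shape with $(r_l, r_h, c_l, c_h) = (0.4, 0.2, 10, 100)$. Each read's
allele $H_r(s)$ is 1 or 2 (first/second allele) or 0.

Reads sharing at least three SNP sites with a template form its group;
a centroid records per site the signed vote $v_s = v_s^+ - v_s^-$ and
total $n_s$. Verified sites require $|v_s| \ge \max(p_0 n_s, p_1)$, and
set algebra on verified signs yields the common (A), same-sign (S) and
opposite-sign (D) site sets between centroids. Groups are divided by a
modified bisecting k-means: the most distant read pair seeds two
centroids, reads far from both (overlap ratio $< p_2$ or distance ratio
$> p_3$ *for both centroids* — the printed rule leaves the quantifier
open, and requiring both keeps reads close to either centroid in play)
go to a separate subgroup, and the split iterates to a fixpoint. Leaves
satisfy $|G| \le 3$ or $\sum D / \sum A \le p_4$ and $\sum D \le p_5$.
Subgroups then re-combine around the template's leaf under the printed
closeness conditions ($p_6 \ldots p_9 = 0.66, 6, 4, 0.2$). Each read's
alleles are overwritten by its group centroid's verified signs; the
whole pass runs twice.

In the final pass, a query read $r$ with subgroup $L_r$ is inconsistent
with template $t$ (group $L_1$) when
$|D(L_r, L_1, p_6, p_7)| \ge \max(p_8, |A(L_r, L_1, p_6, p_7)|\,p_9)$
and the read-level differing alleles within the verified common sites
reach $\max(d_{\min}, |A \cap \cdot|\,p_9)$, with $d_{\min} = 8$ for
corrected-read evidence and 6 for the optional raw-read pass (external
VCF, or the package's own raw-read pileup caller via
`run_pipeline(raw_snp = TRUE)`). An overlap between an inconsistent pair
is removed only when the reads' relative direction matches their contig
layout and the 3'-end distances agree within 1 kb (corrected) or
$\max(2500, 0.05\,D_c)$ (raw) — pairs displaced by a repeat keep their
overlaps, which is what lets the clustering separate repeat copies
rather than shatter them.

# Round 2: two sets of contigs

Inconsistent overlaps are dropped from the candidate set and the
containment/coverage filter is re-run: a read contained only inside the
other haplotype becomes free again and can seed its own haplotype path —
without this the second round cannot represent both haplotypes at
desk-scale depths. The rebuilt graph keeps its bubbles; two-path bubbles
and alternate branches (two-branch junctions whose shorter, linear
branch is more than 30% inconsistent with the other) are identified.
Primary contigs traverse one side of each structure without breaking;
the other sides become alternates, and an independent contig whose reads
are more than 30% inconsistent with a longer contig is demoted to
alternate.

For the dual assembly, adjacent bubbles along a primary path are
connected by the pairing that minimises the distance between their path
read-group centroids (random under the run seed when no site is shared).
At SNP heterozygosity of about 0.5% and above with multi-kilobase reads,
every read carries enough heterozygous sites that the two haplotype
paths share no reads at all — the graph separates into parallel chains
and no bubbles remain to phase. Whole contigs are therefore also
two-coloured over the conflict graph induced by the inconsistent-pair
relation; conflict-free contigs stay in haplotype 1. Finally, within
each haplotype set, fragments mapping into longer contigs (junction
leftovers duplicating already-represented sequence) are dropped.

# The simulator and what passing tests mean

`sim_params()` defaults describe the study conditions used throughout
the tests: a 50-kb diploid genome at 1% SNP heterozygosity (the
benchmark species span 0.34--1.48%), 10% per-base read error (long noisy
reads carry 5--15%), 40-fold coverage per haplotype, and truncated-normal
read lengths of 4 kb ± 0.8 kb (minimum 500 bp) — a quarter-scale read
length matching the quarter-scale genome, chosen once for desk-scale
runtimes. Errors are split 50/25/25 between substitutions, insertions
and deletions; heterozygous variants are SNPs by default (an
`indel_het_fraction` hook adds 1--50-bp indels; the phasing stage uses
SNP alleles only). Repeats are embedded by replacing genome segments
with diverged copies of a unit. Truth tables record every variant
(0-based, haplotype-1 frame), each read's haplotype, interval and
strand.

The simulator emulates uniform coverage, independent per-base errors and
a flat quality profile. It does not model coverage waves, chimeric
reads beyond the tests' constructed fixtures, error clustering, or
structural variation beyond the repeat hook, so passing tests show the
algorithmic machinery behaves as designed under the stated error and
heterozygosity regime, not that the pipeline is production-ready for
arbitrary real datasets.

The repeat fixture uses a 26-kb genome with a 2-copy, 2-kb repeat at
0.5% divergence, 30-fold coverage and 1.3-kb reads: reads this short
cannot bridge the repeat, so round 1 collapses it, and the second round
separates the copies through the SNP-evidence best-overlap scores and
the loose raw-read pass (with 2-kb copies at 0.5% divergence a read
pair shares at most about ten diverged sites, so the strict
8-differing-allele rule alone cannot fire there).

# Numerical choices and degenerate inputs

* Alignment is banded edit distance with traceback (band
  $|n-m| + 4\sqrt{\max(n,m)} + 32$, widened once on implausible
  results); ties prefer diagonal, then query-gap, then reference-gap.
  Reference and/or query flanks can be free; all coordinates are 0-based
  half-open, minus-strand coordinates on the read's own forward frame.
* Minimizers: canonical k-mers, mixed 64-bit hash, window of 10 k-mers
  (k = 15 for corrected reads and mapping; k = 13, window 8 for raw
  reads, where the error rate makes long k-mers vanish).
* Ties in clustering break toward the first centroid; the seed pair for
  a split is the most distant pair over a capped random sample (2000
  pairs) for large groups.
* Zero-vote sites ($v_s = 0$) verify to nothing; a perfectly balanced
  group is its own leaf. Groups of three or fewer reads never split.
* Degenerate inputs: empty overlap sets give empty graphs and no
  contigs; a read with no supporting reads is returned unchanged and
  flagged; a heterozygosity-free run emits one contig set and warns that
  the dual assembly is a single haplotype.
* Fixed seeds make every stage byte-reproducible; the pipeline seed fans
  out to named substreams (simulation, dual-pairing fallback, sampling
  caps).

# Known limitations

* The contig sequence is a splice of read substrings; no consensus
  polishing is applied (the inconsistent-alignment filter for an
  external polisher is provided).
* All-vs-all overlap discovery is quadratic in read count and meant for
  desk-scale data (about $10^4$ reads).
* Indel heterozygosity is simulated but not phased; phasing uses SNP
  alleles only.
* Scaffolding, Hi-C/trio integration and quality-score-aware consensus
  are out of scope.
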