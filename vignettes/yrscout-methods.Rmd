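---
title: "Annotating tyrosine-recombinase retrotransposons with yrscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating tyrosine-recombinase retrotransposons with yrscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yrscout)
```

## The problem

Retrotransposons of the DIRS order integrate through a tyrosine recombinase
(YR) rather than an integrase or endonuclease, and their terminal repeats are
diagnostic of the superfamily: *DIRS-like* elements carry inverted terminal
repeats (ITRs, roughly 120 bp) plus an internal complementary region (ICR)
whose two halves are reverse-complementary to the element's own 5' and 3'
termini, and begin and end with a thymine trinucleotide (`TTT`); *Ngaro-like*
elements instead carry split direct repeats (SDRs) laid out as
A1 ... B1 A2 B2 with A1 = A2 and B1 = B2. Coding capacity is also
diagnostic: gag, reverse transcriptase (RT), RNase H (RH), an optional
DAM-methyltransferase (MT, DIRS-like only), the YR itself, and an SGNH
hydrolase (Ngaro-like only), in overlapping reading frames.

`yrscout` implements the complete desk workflow around these signatures:
structural diagnosis of single elements, homology-based copy retrieval and
genome masking with a consensus library, CpG-adjusted Kimura divergence
landscapes with molecular-clock dating, divergence-based family clustering
with majority-rule consensus building, and neighbor-joining trees of RT
domains with bootstrap support. Because the real inputs (curated element
libraries and multi-gigabase genomes) are large and external, the package
also ships a first-class synthetic-data generator that plants copies with
known truth, so every stage can be validated quantitatively.

## The synthetic-data generator

`family_spec()` + `make_consensus()` build single elements whose structural
features are exact by construction: the ITR pair is an exact reverse
complement, the ICR halves are reverse-complementary to the termini, SDR
blocks are identical, and ORFs are clean ATG-to-stop frames carrying fixed
30-aa marker peptides (invented stand-ins for the conserved domains, so
domain scanning needs no external database). Default element sizes are
4.2 kb (DIRS-like) and 4.8 kb (Ngaro-like), in the size range of real
elements; the default SDR blocks are 236 bp and 152 bp, the geometry
reported for the canonical *Xenopus* Ngaro-like element. Consecutive default
ORFs overlap by 29 nt in different frames. (An overlap that is a multiple
of 3 would force the two ORFs into the same frame, which cannot host two
independent clean reading frames, so 29 nt rather than a round 30 nt.)
One base just outside each planted repeat is chosen so that chance
complementarity does not extend the repeat, which keeps truth coordinates
exact; everything else is i.i.d. background at the configured GC content.

`mutate_copy()` applies independent site-wise substitutions under the
Kimura two-parameter model. With transition rate $\alpha$ and per-pathway
transversion rate $\beta$ ($\kappa = \alpha/\beta$, default 2), the
expected observable fractions after "time" $t$ are

$$P(t) = \tfrac14 - \tfrac12 e^{-2(\alpha+\beta)t} + \tfrac14 e^{-4\beta t},
\qquad Q(t) = \tfrac12 - \tfrac12 e^{-4\beta t},$$

and the parameters are chosen so $(\alpha + 2\beta)t = K$, the requested
divergence. The K2P estimator applied to the mutated copy is therefore a
consistent estimator of the target: over 20 replicates of a 10 kb sequence
the mean recovered $K$ is within 5% of the target for $K \le 0.3$.
Transitions at CpG dinucleotides of the source are accelerated by
`cpg_factor`; the default 10 emulates vertebrate CpG hypermutability and is
deliberately the inverse of the 0.1 weight used by the divergence
adjustment, so adjusted divergences center on the planted value. Indels are
off by default (geometric lengths, rate capped at a tenth of the
substitution rate, when enabled).

`build_genome()` plants mutated, optionally 5'/3'-truncated copies at
non-overlapping uniform positions on random strands, simulates EST reads as
lightly mutated consensus subsequences of at least 100 bp, and emits a
truth table (BED6 on disk, 0-based half-open; 1-based closed in memory,
the R convention). All randomness flows from one seed through named
substreams, so outputs are byte-identical across reruns.

What the generator does *not* emulate: nested insertions, segmental
duplications, low-complexity background, chromosome-scale heterogeneity,
and the allotetraploid subgenome structure (two separate configs can stand
in for subgenomes). Passing tests therefore demonstrate correctness of the
algorithms under clean, known conditions — not performance on real genomic
repeat landscapes.

## Terminal-repeat detection

`self_similarity_scan()` is the in-package analog of aligning an element
against itself with BLASTn at minimum word size: exact 11-mer seeds (both
orientations), chaining on common diagonals (gap tolerance 60 bp),
ungapped X-drop extension (match +1, mismatch -3, drop 6), trimming to
mismatch-free ends, then filters of at least 50 bp and at least 80%
identity. The detector is deliberately ungapped: real ITR pairs differ by
a few substitutions or short indels, and an indel simply splits a pair
into chained segments of which the longest survives the length filter. On
sequences up to a few kb the scan is checked against an exhaustive
run-length oracle that shares no code with it.

`find_itrs()` keeps the highest-scoring (identity × length, ties 5'-most)
inverted pair whose members fall in the terminal windows (outer 15% at
each end — the repeats of interest are terminal structures, but no
published length threshold exists, so the window is a package choice).
`find_icr()` anchors the left ICR half with a probe — the reverse
complement of the element's first 30 bp, allowing 6 mismatches — then
extends both halves base-by-base while complementarity to the respective
terminus holds. `find_sdrs()` assembles direct-repeat pairs into the
A1 ... B1 A2 B2 arrangement, requiring A1 in the 5' terminal window, and
maximizes summed identity × length over consistent arrangements.

`classify_superfamily()` calls DIRS-like iff an ITR pair is present and
Ngaro-like iff the SDR arrangement is present (or an SGNH-marker ORF
co-occurs with direct repeats); conflicting evidence yields `unclassified`
with a reason code rather than an arbitrary pick. Completeness is
`complete` only when all expected repeats *and* all expected coding
domains are intact, mirroring the usual complete/degenerate bookkeeping
for these elements.

## ORFs and domains

`find_orfs()` reports every maximal ATG-to-stop stretch of at least 75 nt
in all six frames, the standard ORF-finder convention with ATG-only starts;
the stop codon is counted in the length (a documented flag flips this).
`scan_domains()` slides each 30-aa marker along the protein and scores the
window by its BLOSUM62 sum; the acceptance threshold is calibrated per
marker as mean + 5 SD of the score against 1000 random windows (a fixed
internal seed makes the calibration deterministic). Five substitutions in
a marker still score far above this threshold; a reversed marker does not.

## Copy retrieval and masking

`translated_search()` mirrors a tBLASTn search: the genome is translated
in six frames, exact amino-acid 4-mers seed candidate loci, and each locus
is aligned locally to the query (BLOSUM62, gap open 11, extend 1). The top
10 hits (by default) are returned with 3 kb of flanking nucleotides,
clipped at sequence ends. On small genomes the seeded search reproduces
the score of a full Smith-Waterman pass over each complete frame.

`mask_genome()` mirrors a RepeatMasker run with alignment output: 11-mer
seeds on both strands, diagonal clustering (clusters below 5 seeds are
discarded as spurious), local alignment of each candidate locus against
the consensus (match +1, mismatch -1, gap open 5, extend 1), and
best-score-wins resolution of overlapping hits across families. A merged
window can contain several adjacent copies, so after each recorded hit the
flanking sub-windows are re-searched recursively. The gapped per-copy
alignments are retained — they are the input to the divergence stage, like
a RepeatMasker `.align` file.

## Divergence, ages and landscapes

`kimura2p()` excludes alignment columns with gaps or ambiguity codes and
evaluates $K = -\tfrac12\ln\big((1-2P-Q)\sqrt{1-2Q}\big)$; out-of-domain
arguments set a saturation flag instead of a number. `cpg_adjusted_kimura()`
follows the repeat-landscape convention for CpG hypermutability: a
transition at a consensus CpG position counts 0.1 of a transition, and two
transitions at the same CpG site count as one full transition; CpG sites
are read off the consensus strand (reverse-strand copies are oriented to
the consensus by the masking stage first). Ages use the molecular clock
$T = K/r$ with $r = 3.1\times10^{-9}$ substitutions per site per year, the
average rate estimated for *Xenopus* genomes; $K = 0.01$ dates to 3.2 My
and $K = 0.031$ to 10 My.

`build_landscape()` bins copies by $K$ (width 0.01, the common landscape
convention) and reports the percentage of the genome occupied per bin, per
family and per superfamily, with the age axis attached. Bin sums equal each
family's total masked proportion exactly; saturated records are dropped.
Note that a wave planted exactly on a bin edge scatters its copies across
the two adjacent bins, so wave recovery is assessed to within one bin.

## Families and consensus building

Family grouping follows the published 80%-divergence rule: sequences more
than 80% divergent form distinct families, implemented as single-linkage
connected components (chains of similar variants merge, which matches
curated-library practice; complete linkage is available). The divergence
*scale* matters more than the threshold: the optimal global alignment of
two completely unrelated sequences still pairs roughly half of their bases
by chance, so per-aligned-column divergence never reaches 80% and would
never split anything. Clustering therefore uses a homology-coverage scale,
$1 - \text{local-alignment matches}/\max(\text{lengths})$, under which
unrelated pairs measure above 0.9 and same-family copies (including 50%
fragments) stay well below 0.8 — the same spirit as the 80-80-80 family
rule used in repeat curation. The per-column measure remains available and
is what `pairwise_divergence()` reports by default.

Within each family a center-star progressive alignment (center = sequence
minimizing summed divergence; once-a-gap-always-a-gap merging) feeds the
50% majority consensus: per column, the most frequent residue if it is a
unique mode reaching half of the non-gap characters, otherwise the IUPAC
code of residues above 25%; gap-majority columns are dropped. Twenty
copies at 5% divergence reconstruct their ancestor to within 1%
divergence. Center-star alignment is adequate at these divergences; it is
not an iterative refinement aligner and is not intended for deep
divergences.

## Distance trees

RT-domain proteins are aligned, sequences under 70% alignment coverage are
excluded (boundary kept), and pairwise distances are p-distances with an
optional Poisson or gamma-Poisson correction (shape 1 by default). The
gamma-Poisson correction stands in for maximum-likelihood JTT distances:
at the divergences involved, the distances rather than the substitution
model drive the clustering, and the correction is available as a
configurable stand-in rather than a claim of model equivalence.

`neighbor_joining()` is the canonical Saitou–Nei agglomeration with the
Studier–Keppler criterion; negative branch lengths are clamped to zero
with the excess moved to the sister branch (the sum to the new node is
preserved). On additive matrices it recovers the generating topology and
branch lengths exactly; this is verified against 20 random 5–8 taxon trees
and cross-checked against an independent reference implementation.
`bootstrap_support()` resamples alignment columns, rebuilds the tree per
replicate, and reports the percentage of replicates containing each
bipartition of the full-data tree. Full analyses use 1000 replicates; the
packaged tests and pipeline default to 100, which is ample to certify a
clean bipartition.

## The pipeline

`run_full_analysis()` chains generate → annotate → mask → divergence +
landscape → family clustering → RT tree → EST evidence → summary, with
per-stage error tagging and every stochastic stage seeded from a named
substream of the single config seed. EST evidence uses the published
filters: identity above 85% and matched length above 100 bp, both strict.
The demo configuration (`demo_config()`) — two DIRS-like families and one
Ngaro-like family, recent ($K=0.02$) and ancient ($K=0.25$) waves in a
200 kb genome — runs in about two minutes on one core and recovers the
planted family count, superfamily densities within 10% relative, and wave
modes within one divergence bin.

Problem sizes throughout the test suite are deliberately modest (genomes
of 30–200 kb, 10 kb sequences for estimator checks, 20 replicates for
stochastic properties); they are chosen so each property is measured with
comfortable statistical margin while the whole suite stays quick.

## Known limitations

* Structural detection is ungapped; elements whose ITRs diverged mainly by
  long indels will be reported as shorter chained segments.
* The masking stage has no low-complexity filter (the synthetic background
  has none); on real genomes a RepeatMasker-style pre-filter would be
  needed.
* Center-star alignment and gamma-Poisson distances are pragmatic
  stand-ins adequate at tested divergences, not replacements for
  refinement aligners or ML distance estimation.
* The landscape uses per-fragment alignment records (each masked hit is
  one record), so a copy split by the aligner contributes multiple
  records, exactly as RepeatMasker `.align` fragments do.
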