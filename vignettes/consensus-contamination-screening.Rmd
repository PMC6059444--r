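---
title: "Consensus contamination screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus contamination screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(contamcheck)
```

## The problem

Prokaryotic genome assemblies — especially of organisms that are hard to
grow axenically, such as many cyanobacteria — often contain sequence from
co-cultured organisms. A contaminated assembly poisons every downstream
use: phylogenies acquire chimeric taxa, gene-content surveys report
enzymes the organism does not have, and once the assembly enters a
reference database it starts misclassifying other people's reads.

No single detector is both sensitive and specific for this problem, so
`contamcheck` implements six estimators with complementary failure modes
and aggregates them into a consensus ranking. Every estimate is expressed
relative to a *focal clade*: the taxon the assembly claims to belong to.
Sequence classified inside the clade is genuine (`FOCAL`), outside it is
`CONTAMINANT`, at a strict ancestor of the clade (say, the bacterial
root) it is classified-but-uninformative (`UNKNOWN`), and sequence with
no hit at all is `UNCLASSIFIED`. The `UNKNOWN` rule is structural —
"strict ancestor of the focal clade" — rather than a list of taxon
names, so it transfers to any taxonomy, including simulated ones. The
distinction matters: genuinely transferred genes tend to collapse to
high-ranking LCAs, so the unknown fraction is where real horizontal
transfer hides, and the package never counts it as contamination (nor
masks it).

## The six estimators

**SSU rRNA (16S) best hit.** SSU-like loci are detected by exact-word
seeding against the SSU reference panel followed by local nucleotide
alignment (match +2, mismatch −3, gap 5 + 2/base) on both strands;
calls need an aligned span of ≥ 300 nt at ≥ 70 % identity, overlapping
calls keep the best score, and a seed window is re-searched after
masking each accepted call so tandem copies are all found. Each locus
is labelled by its best-hit reference taxon. The estimate is
`100 · foreign / predicted`; an assembly with no predicted SSU gets a
missing value rather than a zero — absence of evidence.

**Ribosomal-protein top-3 LCA.** All six-frame ORF windows (≥ 30
residues between stops) are searched against the pooled references of
all protein marker families; a candidate belongs to the family of its
single best hit (a mutual-best screen against inter-family paralogues),
and overlapping candidates on a scaffold deduplicate to the best bit
score — requiring mutual overlap above half the shorter window, because
ORF windows of *adjacent* genes legitimately overlap across frames.
Each candidate is then labelled by the LCA of its three most similar
family references at ≥ 70 % identity over ≥ 30 aligned residues
(ties: longer alignment, then reference id). The estimate pools all
families, ignoring collocation: `100 · foreign / classified`.
Unclassified candidates are excluded from the denominator — by analogy
with the SSU formula, which divides by *predicted* genes — and
`UNKNOWN` labels count in the denominator but never as foreign.

**Single-copy redundancy.** Over a panel of `M` markers expected once
per genome with detected copy counts `c_m`: completeness is
`100 · |{m : c_m ≥ 1}| / M` and contamination is
`100 · Σ max(0, c_m − 1) / M`. One full extra marker set gives 100 %;
two give 200 % — the estimator is deliberately unbounded above, which
is exactly what flags multi-organism assemblies. An optional
collocation mode collapses hits within 5 kb into one countable unit,
reproducing the known underestimation of collocation-aware tools when
foreign markers arrive on one contiguous fragment; it is off by
default.

**Signature-kmer read classification.** Scaffolds are tiled into
250-nt pseudo-reads (0-based half-open coordinates; a trailing window
survives only if ≥ 21 nt — shorter windows contain no classifiable
kmer). The reference index maps every canonical 21-mer (lexicographic
minimum of kmer and reverse complement, encoded base-4 in doubles) to
the LCA of all reference taxa containing it. A read's candidate label
is the leaf-most taxon maximizing the summed hit count along its root
path, ties resolved by the LCA of the tied nodes; its *confidence* is
the fraction of the read's valid (ACGT-only) kmers falling inside the
clade rooted at the label — the denominator includes kmers with no
database hit, one of two readings of an ambiguous convention,
configurable. While confidence is below the threshold (default 0.04)
the label promotes to its parent; a read failing at the root stays
unclassified. Raising the threshold can therefore only move labels
rootward, which is the monotone sensitivity/precision trade-off the
threshold exists to tune. A kmer database that contains the query
genome is uninformative about it (its own kmers always match):
`kraken_na_mask()` flags such assemblies for an NA score in the
consensus, and the bundled analyses instead build the index without
the query hosts.

**MEGAN-like protein LCA.** The same pseudo-reads are translated in six
frames and searched against the reference proteome. The bundled search
engine is Smith–Waterman with affine gaps (BLOSUM62, 11/1), bit scores
from the published ungapped Karlin–Altschul constants
(λ = 0.3176, K = 0.134), and stops scored −4 against everything so
alignments never extend through one. A seed prefilter (exact 5-residue
words, by default ≥ 2 shared words and at most 16 candidate subjects
per frame) makes whole-assembly screening affordable; a pure
seed-free scan proved two orders of magnitude too slow at the scale the
package itself simulates, and the engine is in any case replaceable —
external tabular hits (12-column dialect plus genome/taxon columns)
drop into the same classifier. Per read: self-matches (hits to the
query's own genome) are removed, hits below 80 bits are removed, only
hits within 95 % of the best bit score vote, and the read is labelled
by the LCA of the voters. Self-exclusion makes the method valid even
when the query's own genome is part of the reference set; the package
tests that it is *exactly* equivalent to removing the genome from the
database.

**Composition binning.** Segments of 10 kb (a trailing remainder merges
into the previous segment; scaffolds shorter than 1 kb are dropped) are
described by canonical tetramer frequency vectors (136 classes,
pseudocount 1, log-transformed; invariant under reverse complement).
Vectors are centre-scaled and projected on leading principal
components, and a Gaussian mixture with hard assignment provides
groups; the estimate is `100 · (1 − largest group share)`, treating the
dominant composition cluster as the genuine genome. Three numerical
guards matter at the segment counts a single assembly provides (tens,
not the thousands of a metagenome):

* the 90 %-variance rule for picking dimensions is additionally
  screened by parallel analysis — only components whose eigenvalue
  beats column-permuted data survive — because at n ≈ 30 the variance
  rule alone retains pure noise and the mixture then hallucinates
  groups;
* centred vectors are rescaled by `sqrt(segment length / mean length)`:
  counting noise scales inversely with length, and without this the
  mixed 10–20-kb segments cluster by noise level rather than
  composition;
* the number of components (bounded by `max_clusters`, 400 by default,
  and by n/5) and the model are selected by ICL rather than BIC, over
  equal-variance (spherical/diagonal) models with a conjugate prior.
  ICL's entropy term merges overlapping components instead of
  splitting the homogeneous cloud of a clean genome — the behaviour a
  component-emptying variational mixture would show — and the prior
  keeps a near-noiseless feature (such as a two-level coverage track)
  from collapsing the diagonal models.

An optional per-segment coverage feature is appended after projection,
weighted like the leading composition axis; the default (no track)
corresponds to the dummy uniform-coverage convention. Tetramers are the
default for a reason the package can demonstrate: with hexamers the
largest-group share collapses and the statistic degrades, and the test
suite asserts only that κ = 4 beats κ = 6 on the same fixture.

## Consensus, categories, congruence

Each method's scores are ranked descending (rank 1 = most contaminated,
ties averaged, missing stays missing); an assembly's consensus score is
the mean of its non-missing ranks and the global rank orders that mean,
breaking exact ties by assembly id (the choice is unknowable from a
tie-free published table; any fixed rule does). Congruence is measured
by Spearman correlation with pairwise-complete observations, computed
as Pearson on averaged-tie ranks. Category bands follow the
conventional redundancy thresholds (0 / ≤5 / ≤10 / ≤15 / >15 %), the
ribosomal category counts how many of the two ribosomal methods found
anything, and the flagged-method count uses any positive score for the
three marker methods but a 1 % floor for the three genome-wide methods,
whose scores are noisy near zero (a translated search essentially never
returns exactly 0). These flag thresholds are configurable; nothing in
the consensus depends on them.

## The synthetic data generator

The generator is first-class code, not a fixture: it produces the
*study conditions* every test and the acceptance analysis run under.

* **Taxonomy**: root → domain-like node → 5 phyla → one genus each →
  two leaf genomes each; the first phylum is focal. The domain node
  exists so high-ranking LCAs land on a strict ancestor of the focal
  clade and exercise the `UNKNOWN` rule.
* **Composition**: per-phylum GC targets spread evenly over 35–65 %.
  Genomes are gene-dense mosaics (~85 % coding, as in real
  prokaryotes): orthologous protein families evolved along the tree by
  per-branch substitution (no indels, so identity thresholds are
  controlled by branch lengths: ~94 % amino-acid identity within a
  genus, 50–60 % between phyla), reverse-translated with a codon bias
  solved by bisection so realized GC lands within ±3 points of the
  phylum target, with order-3 Markov intergenic spacers whose GC
  compensates for what codon bias cannot reach. Gene density is not
  cosmetic: a translated search can only ever see coding sequence, so
  without it the protein-LCA method would be structurally blind.
* **Markers**: a 20-family single-copy ribosomal-protein panel plus an
  SSU-like 1500-nt family with invariant conserved blocks interleaved
  with variable regions (the conserved/variable architecture of real
  SSU genes, and what makes exact-word seeding reliable). All markers
  of a genome implant as one collocated operon-like cluster with
  stop-codon-bearing gaps, plus 1–4 SSU copies (extra copies at
  standalone loci); every locus is recorded in a registry.
* **Chimeras**: the host fragments into lognormal scaffolds (min 1 kb;
  breakpoints are moved off marker loci so marker ground truth stays
  well-defined), and contaminant bases totalling `f/(1−f)` of the host
  length arrive as contiguous blocks — by default drawn to include the
  contaminant's marker cluster, emulating a co-sequenced organism whose
  markers made it into the assembly — either as their own scaffolds or
  concatenated onto host scaffolds at the chimeric-scaffold rate (0.2).
  The realized fraction is exact by integer bookkeeping.
* **Reads**: uniform fragment sampling per source organism at 68× for
  the host and 26× for the contaminant (the depth contrast observed for
  a real contaminated assembly), substitution errors at a configurable
  rate, and an exactly accumulated depth track.

What the generator does **not** emulate: repeats, plasmids, indels,
real horizontal transfer, sequencing-error profiles, or real
cyanobacterial sequence. Passing tests show the estimators recover
planted signal under controlled composition contrast — they do not
certify performance on real assemblies, where reference databases are
incomplete and contaminants are not obligingly 15 GC points away.

## Known limitations worth stating plainly

* The protein-LCA path cannot classify RNA genes or reads with less
  than roughly 100 nt of coding overlap, so protein-label masking
  plateaus below ~95 % base recall (measured ~91 % on plain chimeras
  here, consistent with the sizeable unclassified fractions translated
  searches show on real data). Masking with kmer labels reaches ~100 %
  when the contaminant lineage is in the index; the decontamination
  function takes whichever labels you hand it.
* On these compact 300-kb genomes the SSU/marker cluster is a visible
  fraction of the assembly, and its genuinely atypical composition
  inflates the binning estimate of some *clean* genomes (up to ~30 %).
  This is the documented failure mode of largest-group statistics —
  atypical regions of the genuine organism masquerade as minor groups —
  amplified by small genomes; the consensus absorbs it, ranking every
  chimera above every clean assembly regardless.
* Redundancy estimates depend on the contaminant actually carrying
  markers; a marker-free contaminant is invisible to all three marker
  methods — the motivation for the genome-wide methods.

## Problem sizes used by the bundled analyses

The analysis scripts and the acceptance computation use the generator
defaults: ten 300-kb genomes, a ~5,200-protein reference proteome, a
~3-million-kmer index, ten chimera/clean pairs (~1,400 pseudo-reads
each), and five seeds per point on the contaminant-fraction grid
{0.05, 0.1, 0.2, 0.3}. One full six-method pass over an assembly takes
roughly 12 s on one core; the complete paired-query analysis runs in a
few minutes.

## Reproducing the numbers

`analysis/01...05` rerun the whole story (simulation → marker
estimates → genome-wide estimates → consensus → coverage validation and
masking) and write tables under `results/`. `scripts/acceptance.R`
recomputes the headline quantities from scratch for any seed; see the
README for how to run both.
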