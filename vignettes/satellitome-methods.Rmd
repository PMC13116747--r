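---
title: "Satellitome construction and characterization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellitome construction and characterization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Satellite DNA (satDNA) consists of non-coding monomers repeated in tandem
arrays. A *satellitome* is the complete catalogue of a genome's satDNA
families, each represented by a consensus monomer. This package builds such
a catalogue from a genome assembly and characterizes it with unassembled
short and long reads, because assemblies systematically compress or
misplace long tandem arrays while reads sample them without bias. The
workflow is: tandem-array detection on the assembly; consensus building and
quality filtering; redundancy removal; contamination screens; copy-number
estimation from both read types with cross-validation; per-read clustering
metrics; and per-chromosome specificity analysis.

All similarity decisions go through one engine: seeded Smith-Waterman local
alignment with affine gaps (match +1, mismatch −2, gap open 5, gap extend
2; a gap of length $L$ costs $open + L \cdot extend$) and Karlin-Altschul
E-values $E = K m n e^{-\lambda S}$. For this nucleotide scoring the
published ungapped constants are $\lambda = 1.33$, $K = 0.621$; the
protein-level coding screen uses the gapped BLOSUM62 constants
($\lambda = 0.267$, $K = 0.041$). The TE screen also uses the conservative
0.267/0.041 pair: it stands in for profile-HMM scanning, whose scores are
deliberately harder to reach, so a ~20 bp chance match does not count as
evidence of transposon origin while a genuine library-derived segment of a
few hundred bases far exceeds the threshold.

# Tandem detection

Arrays are found from the k-mer recurrence-distance profile: for every
position, the distance to the previous occurrence of the k-mer (k = 13)
starting there. Inside a tandem array these distances concentrate at the
monomer period. Maximal runs of supporting positions become array calls
when

* the modal distance has at least 5 *support events* — runs of consecutive
  supporting positions collapse into one event, so a single chance repeat
  (which always yields one short run) cannot mimic an array, while an
  array retains one event per intact k-mer stretch between mutations. A
  single run at least twice the period long (a perfect, mutation-free
  array) is accepted on its own;
* the event count is at least 3× the corresponding count in a shuffled
  copy of the same sequence (the empirical null);
* the called span covers at least two periods.

Detection runs in three rounds with period ranges (10–200), (150–1000) and
(800–3000) bp, hard-masking each round's calls with N before the next, so
long-period arrays are found without re-calling short-period structure.
The ranges span the monomer lengths observed in plant satellitomes
(roughly 30 bp to 3 kb).

Monomer units are cut at period boundaries, rotated to the rotation
minimizing Hamming distance to the first unit (tandem monomers are
rotation-ambiguous; indels otherwise shear the column frame), and
re-oriented by shared 7-mer count against the running profile of accepted
units; the first unit anchors the profile, and exact ties go to the
lexicographically smaller sequence. The consensus is the column-wise
majority over units aligned to the medoid unit; columns voted on by fewer
than half the panel (frame edges, partial units) are dropped instead of
being decided by a minority. The panel is capped (40 units, fewer for
monomers above ~700 bp where alignment cost grows quadratically); the
consensus quality score — the fraction of the full monomer pool's 7-mer
instances whose 7-mer occurs in the consensus — always uses the whole
pool. Candidates below 0.5 coverage are rejected; this operationalizes a
"well-assembled consensus" filter and is a declared definition, not a
reimplementation of any external tool's score.

# Curation

Deduplication is greedy centroid clustering, longest-first, merging at
≥80% rotation-invariant identity *and* ≥80% alignment coverage of the
shorter monomer, applied once within each assembly of origin and once
across assemblies/detectors. The coverage guard is implied by the
curation goal itself: without it a short monomer embedded at high local
identity inside an unrelated long one would be absorbed.

Remaining candidates (plus a known-satDNA library, whose entries are prior
knowledge, exempt from quality filters, and contribute provenance names)
form a similarity graph — edges at E ≤ 1e−5, identity ≥ 80%, coverage ≥
80% of the shorter, weighted by alignment bit score — clustered with a
Markov clustering implementation (expansion = squaring of the
column-normalized matrix, inflation 2.0, pruning 1e−6, convergence 1e−9;
self-loops at each node's maximum incident weight, the external tool's
default, to prevent oscillation). Each cluster keeps the member with the
highest short-read abundance, ties to the longer sequence.

Coverage profiles (per-position depth of short reads mapped to the
tandemized consensus, minus-strand intervals mirrored before folding
modulo the monomer length) support manual curation; a consensus is flagged
chimera-like when more than 25% of positions fall below 10% of the
upper-quartile depth.

# Contamination screens

The cascade order is fixed: coding → TE → organelle → rDNA; a candidate is
removed for exactly the first matching reason. The coding screen
translates the *doubled* candidate in six frames (rotation cannot split an
ORF) and removes it when a reference protein is hit at E ≤ 1e−5 with ≥50%
of the protein covered — the coverage is measured on the protein because
the screen targets gene content, not candidate content; the 50% value is a
declared choice. The TE screen removes at E ≤ 1e−3. The organelle and rDNA
screens remove at E ≤ 0.01 when the union of hit intervals on the
candidate (not the best single hit — fragmented hits to one reference
still indicate shared origin) covers ≥80% of its length.

# Copy number and abundance

Short-read abundance is the percentage of all reads whose best-scoring
local alignment (score ≥ 30, i.e. ≥ ~30 exactly matching bases) lands on a
family's tandemized consensus; each read counts for at most one family
(best-hit-only, matching read-count semantics). Copy number per diploid
genome follows

$$CN = \frac{2C_{bp} \times Abundance(\%)}{L_{monomer} \times 100},$$

with the exact algebraic inverse used to convert the final adjusted copy
number back to the percentage of the genome occupied.

Long-read copy number is the total count of thresholded (E ≤ 1e−5,
identity ≥ 70%, query coverage ≥ 70%), non-redundant hits of the consensus
across all reads. A raw hit count estimates copies per 2C only when the
read set totals about one 2C equivalent of bases; `pacbio_cn()` therefore
divides by the long-read fold coverage of 2C (default 1, the situation the
raw-count convention assumes). At any other depth the un-normalized count
would scale with coverage rather than copy number.

Cross-validation (CNCV) flags a family when its two estimates disagree by
more than one order of magnitude (|log10 ratio| > 1, a declared rule for
"significant discrepancy") and reports the squared Pearson correlation of
log10 copy numbers over the concordant families; log scale because copy
numbers span several orders of magnitude and a raw-scale correlation would
be dominated by the most abundant family. Flagged families are excluded
from the satellitome as putative consensus artifacts. The adjusted copy
number is the geometric mean $\exp((\ln a + \ln b)/2) = \sqrt{ab}$.

# Clustering metrics and chromosome specificity

For each family and long read: copy number (non-redundant hit count; two
same-strand hits overlapping by more than half the shorter collapse to the
higher-scoring one), total span (bases covered by the union of hit
intervals, so overlaps are never double-counted) and read coverage
fraction. Family-level MCNPR, MTSPR and MCOPR are the per-metric maxima
over reads — taken independently, so they may come from different reads. A
family is *clustered* when MTSPR strictly exceeds 10 kb ("above the
threshold" read as strict; exactly 10,000 bp is not clustered).

Per-chromosome hit counts (same thresholds; hits on scaffolds without the
chromosome name prefix count as unplaced and are excluded from the
analysis matrix) feed a correspondence analysis of $\ln(1+x)$-transformed
counts — the +1 handles zeros, the log damps multiplicative copy-number
differences between chromosomes. Standard CA via SVD of the standardized
residuals; two dimensions retained; sign fixed so the first nonzero row
coordinate of each dimension is positive, making runs bit-reproducible.
Chromosome specificity is the Mahalanobis distance of each family's
coordinates from the origin, with the covariance estimated from all row
coordinates (pseudo-inverse fallback if singular). Peak-copy-number (PCN)
chromosomes are those with at least 50% of the family's maximum
per-chromosome count — a declared rule, reported alongside raw counts so
users can re-call. Strict 1-/2-chromosome specificity is called from
positive counts alone; complete anchoring (no unplaced copies) is reported
separately, mirroring how the two facts differ.

# Synthetic data and the canonical study

The generator plants tandem arrays of mutated monomer copies (i.i.d.
substitutions plus geometric-length indels, the simplest model producing
the 70–95% identity spread the thresholds are designed around) on random
background chromosomes, with unplaced scaffolds named `scaffold_*` versus
`chr*`. Short reads are uniform with 150 bp length and i.i.d.
substitution errors (rate 0.002, typical of filtered Illumina data; the
read count is coverage × genome size / read length). Long-read lengths are
lognormal with the meanlog set so the untruncated mean is 25 kb (sdlog
0.5), resampled above a hard 10 kb floor; errors are 90% substitutions /
10% single-base indels at rate 0.01, HiFi-like. All generators run under
scoped seeds and are bit-reproducible.

The canonical study (`synthetic_study()`) plants five families chosen to
span the design space on a ~5 Mb, eight-chromosome genome: an abundant
377 bp subtelomere-like family on all chromosomes at 5% divergence (with
unplaced copies), a 40 bp family enriched 4:1 on one chromosome, a 2500 bp
family strictly confined to chromosome 1, a 750 bp family on two
chromosomes, and a dispersed 180 bp family planted as 4-copy mini-arrays
that can never reach the 10 kb clustering threshold. Four contaminant
arrays (organelle-, rDNA-, TE- and coding-derived) are planted so the
screening cascade is exercised end to end. Read sets are 10× short and 15×
long coverage; the genome is treated as one 2C equivalent so planted copy
counts are copies per 2C. These problem sizes keep a complete run in the
single-digit minutes on one core while leaving every stage's statistics
well-resolved (tens of thousands of long-read hits for the abundant
families). Cluster representatives are ranked using abundances estimated
on an evenly spaced 50,000-read subsample; the final satellitome
abundances always use the full read set.

What passing this study shows — and what it does not: the generator
produces uniform coverage, a single haplotype, homogeneous array-internal
divergence and no transposon nesting or higher-order repeat structure.
Recovery and accuracy under these conditions validate the algorithmic
chain, not performance on multi-gigabase genomes with GC-biased coverage,
diverged subfamilies or HOR structure.

# Numerical choices and degenerate inputs

* Alignment: all coordinates 1-based inclusive at the interface, 0-based
  half-open internally and in BED output. Empty sequences are input
  errors; N never matches.
* Seeded scanning: candidate regions need at least `max(2, L/250)` shared
  11-mers — one chance word in background must not trigger an alignment,
  while a copy at the 70% identity floor still shares about
  $0.7^{11} \approx 2\%$ of its k-mers. Within a region, seed diagonals
  (subject position minus query position) are clustered — one cluster per
  monomer copy — and each cluster is refined by a banded Smith-Waterman
  around its median diagonal (band half-width `2 * max(20, L/20)`, ample
  for the indel drift the mutation model or real HiFi reads produce).
  Aligning per diagonal rather than per sliding window both bounds the
  cost by the true copy count and prevents a strong copy from shadowing
  its neighbours in a shared window.
* MCL: non-convergence within 100 iterations is an error with
  diagnostics, not a silent result.
* CA: all-zero rows are dropped with a warning; rank < 2 after the
  transform is an error.
* CNCV: fewer than 3 concordant families with positive copy numbers is an
  error; a zero copy number on either platform flags the family rather
  than entering a log.
* `cn_from_abundance()` floors to whole copies for reporting; the exact
  value is available (`integer = FALSE`) and is what the round-trip
  identity uses.
* In-silico PCR requires ≥15 bp primers, reports the distance between the
  two primer 5' ends inclusive, and in circular mode searches the doubled
  template, discarding products longer than the template.

# Known limitations

Consensus length for very short monomers can carry a few bases of edge
noise when an array call extends slightly into flanking sequence; the
column-support rule suppresses most but not all of it. The detector does
not decompose higher-order repeats: a perfectly regular HOR would be
called at its fundamental period. Read mapping is best-hit-only, so
abundance of two families above ~80% mutual identity (which curation
normally prevents) would split arbitrarily. The E-value model uses fixed
published constants rather than per-composition estimation; only
threshold behaviour, not tail-exact p-values, should be read into it.
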