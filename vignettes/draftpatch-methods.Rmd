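---
title: "Methods: reference-guided draft patching, liftover and population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-guided draft patching, liftover and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draftpatch)
```

# The problem

Draft mammalian genome assemblies typically carry large numbers of
undetermined regions: runs of `N` inside scaffolds where the original read
data could not resolve the sequence. When a second, deeper sequencing effort
of the same species produces higher-quality contigs, those contigs can be
aligned back to the draft and used to (i) replace the draft sequence over
their aligned spans, (ii) fill gaps they bridge, and (iii) carry the
existing gene annotation onto the improved coordinates. draftpatch
implements this computation as a reusable, fully testable toolkit: gap
discovery and assembly statistics, patch planning and application with an
explicit coordinate chain, variant-based consensus correction (for the case
where the new contigs come from a different individual, making the merged
genome chimeric), annotation liftover and classification, clone-end
(BAC-end) pair validation, and allele-sharing-distance population structure.

Everything is exercised on synthetic fixtures drawn from a seeded truth
genome, so the whole pipeline is verifiable end to end without any external
data.

# Gap model and assembly statistics

A *gap* is a maximal run of `N` of length at least `min_run`. The default
`min_run = 1` is the conservative choice: every undetermined base counts,
and the counts are reproducible without a tuning parameter. When
`min_run > 1`, shorter N runs count as ordinary sequence for contig
splitting, and the statistics report both the filtered and the raw
(`min_run = 1`) gap counts so the knob stays self-consistent.

N50 is the largest length $L$ such that contigs of length $\ge L$ together
cover at least half the assembly. Ties are resolved with $\ge$, and the
comparison is computed as `2 * cumsum >= total` in exact integer arithmetic
rather than dividing by two. The test suite checks this implementation
against an independent brute-force oracle (sort descending, walk the
cumulative sum) on one thousand random length lists.

`gap_accounting()` subtracts a gap-fill ledger from a draft's totals. It
deliberately reports exact counts, never rounded ones, so downstream
comparisons of gap numbers are reproducible.

# Patch planning

Contig-to-draft alignments (PSL from BLAT, or a 12-column generic tab
dialect) are reduced to *placements*: the outer target interval from first
block start to last block end, an identity `matches / (matches +
mismatches)`, and the total aligned length. Selection is:

1. **One placement per contig.** Only a contig's best-scoring placement is
   eligible; the rest are rejected as `secondary`. This prevents one contig
   from being pasted into two places and duplicating sequence.
2. **Thresholds.** Identity $\ge 0.95$ and aligned length $\ge 500$ bp by
   default. These defaults describe "confidently mapped": 500 bp is half a
   typical short-read contig flank and well above the repeat-level spurious
   hit length, and 95% identity tolerates real polymorphism between two
   individuals of one species while excluding paralogous placements.
3. **Greedy non-overlap.** Candidates are accepted in descending
   `aligned_len * identity` order; a candidate whose target interval
   overlaps an accepted one is rejected (`overlap`). Ties break
   deterministically by contig id, then target start, so results are
   reproducible run to run.

The replacement granularity is the placement's *outer* interval: draft
bases from the first to the last aligned block are replaced by the contig
subsequence spanning the outer query interval (reverse-complemented for
minus-strand placements). Because the aligner cannot align through `N`, a
contig bridging a gap aligns as two flank blocks, and its unaligned
interior — the newly determined sequence — lands exactly over the gap.
Replacement and gap filling are therefore one mechanism.

A gap counts as *fillable* when a single accepted placement has one block
ending within `flank_tol` (default 1000 bp) upstream of the gap and another
starting within `flank_tol` downstream, with a non-empty contig interior
(or blocks abutting the gap exactly). Flanks from two different contigs
never fill a gap: with no single molecule bridging the gap, the interior
sequence would be a guess. After patching, ledger statuses are re-checked
against the patched sequence: if the filling contig carries `N` of its own,
those are kept and the gap is marked open again.

## Coordinate chains

Every patch emits a UCSC-chain-format map from draft to patched
coordinates. Within a placement, aligned blocks map block-wise; inter-block
gaps contribute source-only (`dSource`) and target-only (`dTarget`) bases;
untouched draft segments map as identity. The chain invariants (block sums
equal the declared source and target spans) are enforced on construction
and on every file read. Draft positions inside replaced-but-unaligned
segments (e.g. former gap bases) are unmapped by design — there is no
defensible image for a base that was `N`.

The tests verify the chain three ways: exhaustive per-position lifting on a
small fixture (each position maps at most once, strictly monotonically),
algebraic round trips through the inverted chain, and agreement with
`rtracklayer::liftOver()` on chains written to disk.

# Consensus correction

When the patching contigs come from a different animal than the draft, the
merged genome mixes haplotypes. The consensus step substitutes
externally-called variants back into the patched sequence. Variant
filtering keeps biallelic records with depth $\le 100$ (the depth cap
mirrors the `varFilter -D100` convention for excluding collapsed repeats);
map-quality filtering is a property of the upstream pileup and is carried
only as a recorded parameter, because the toolkit does not realign reads.

Indels are applied right-to-left per chromosome so earlier coordinates stay
valid without re-mapping. The emitted chain maps pre- to post-substitution
coordinates: length-preserving substitutions leave the map untouched; an
indel contributes a gap after the common ref/alt prefix. A chain cannot end
on a gap, so an indel consuming the final bases shortens the chain span to
the last mapped base.

`majority_call()` is a deliberately simple desk-scale caller over per-site
base counts (depth $\ge$ `min_depth`, majority non-reference fraction
$\ge$ `min_fraction`, defaults 5 and 0.8), sufficient to close the loop in
end-to-end tests: plant SNPs, simulate pileups, call, filter, apply,
recover the planted genome exactly. Heterozygous sites resolve to the
majority allele because the output is a single haploid consensus sequence;
that choice is recorded here as the package's documented policy.

# Annotation liftover and classification

Exons lift independently through the chain; a transcript is `full` when
every base of every exon maps, `failed` when none does (including a
chromosome with no chain), otherwise `partial`. Partial lifts keep their
per-exon fragments rather than being dropped — the verdict is
per-transcript but the information is per-base.

A fully lifted transcript is *completely filled* when its draft genomic
span (first exon start to last exon end, introns included) overlapped at
least one draft gap and its lifted span contains no `N`. Genomic-span
intersection is the default because gap-containing transcripts are defined
by their genomic extent; exon-only intersection is available behind a flag.

Novelty labelling of query alignments (e.g. cross-species cDNA hits) uses
single shared-base overlap, strand-ignorant by default since cDNA
alignments are frequently unstranded; strand-aware matching is a flag. A
query is additionally flagged `in_filled_gap` when it intersects the
patched-coordinate image of a ledger-filled gap.

# Clone-end pair validation

A clone-end pair is *proper* iff both ends map to the same chromosome, the
leftmost and rightmost placements are on opposite strands
(forward–reverse or reverse–forward), and the insert size is within the
library bound (350 kb by default, matching BAC insert libraries). Insert
size is the outermost span — fragment-length semantics, the quantity a
clone library's size distribution describes — not the inner distance. All
violated conditions are listed, so failure reasons partition cleanly.

Multi-hit ends keep the single best placement by matches with a leftmost
tie-break; an end whose best score is tied across different chromosomes is
ambiguous and the clone is set aside as `unpaired` rather than guessed.

# Population structure

Linkage-disequilibrium pruning uses the squared Pearson correlation of
dosage vectors (composite LD) over pairwise-complete entries. The pruning
pass runs left to right per chromosome with a 500-kb window and an
$r^2 > 0.2$ removal rule: a SNP is kept iff its $r^2$ against every
already-kept SNP within the window is at most the threshold. Keep-first
left-to-right is the package's documented resolution of which member of a
correlated pair to drop; the post-condition (no kept pair within a window
above threshold) is re-verified by exhaustive rescan in the tests.
Monomorphic SNPs, for which $r^2$ is undefined, are prune-ineligible: they
are kept and flagged rather than silently dropped, so SNP counts stay
auditable.

The allele-sharing distance between samples $i$ and $j$ over the $m_{ij}$
SNPs typed in both is

$$d(i,j) \;=\; 1 - \frac{1}{2\,m_{ij}} \sum_{s} \bigl(2 - |g_{is} - g_{js}|\bigr)
       \;=\; \frac{1}{2\,m_{ij}} \sum_s |g_{is} - g_{js}|,$$

one minus half the mean number of shared alleles (1 − IBS/2). It is
invariant under allele relabeling ($g \to 2-g$), symmetric, zero on the
diagonal, and bounded by \[0, 1\]; all four properties are asserted in the
tests.

"PCA on a distance matrix" is implemented as classical scaling (PCoA):
double-center $-\tfrac12 D \circ D$, eigendecompose (delegated to
`stats::cmdscale`), scale eigenvectors by the square root of their
eigenvalues. Negative eigenvalues — which arise whenever the distance is
not exactly Euclidean — are excluded both from the coordinates and from the
contribution-rate denominator, so contribution rates sum to at most 100%.
Eigenvalues are thresholded at $10^{-12}$ to keep numerical dust out of the
denominator. On Euclidean-derived input, the returned coordinates reproduce
the original distances to machine precision; the tests require $10^{-8}$.

# The synthetic-fixture generators

Every generator is a pure function of its configuration; the single seed
expands into per-generator substreams keyed by fixed labels, so adding a
generator never changes existing fixtures. The standard fixture is two
chromosomes of 100 kb with ten masked intervals of 200–2000 bp and 500 bp
of true flank per patch contig — large enough to exercise multi-gap,
multi-chromosome window logic, small enough for sub-second generation.
Masked intervals keep at least `2 * contig_flank + 10` bp between
neighbours and from chromosome ends so per-gap contigs never produce
overlapping placements; the truth-recovery property (the pipeline returns
the truth genome byte-exactly and reports every gap filled) is then exact,
not probabilistic.

Fixture annotations place gap-spanning transcripts with the gap inside an
intron and all exons on true sequence, so each lifts fully and exactly the
designated spanners classify as completely filled; background transcripts
avoid masked intervals entirely.

The clone-end fixture draws its own chromosome lengths (two of 1 Mb by
default) rather than reusing the 100-kb patching genome: planting
insert-size violations requires chromosomes longer than the 350-kb bound,
and megabase scale matches the BAC-library setting where inserts run
100–250 kb. Violations are planted with exact largest-remainder counts from
the configured mix (70% proper, 10% each violation class by default), so
summary counts can be compared to the planted truth exactly.

Genotypes follow the Balding–Nichols model: ancestral frequencies uniform
on (0.05, 0.95), population frequencies
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$ with
$F$ the divergence, dosages $\mathrm{Binomial}(2, p_k)$. The default panel
— 3 populations × 5 samples, 2000 SNPs, $F = 0.2$ — mimics the shape of a
small multi-colony resequencing panel: few samples, clear structure. The
generator does **not** simulate linkage (SNPs are independent given the
frequencies), sequencing error, or missingness patterns; LD pruning on
these fixtures therefore removes only structure-induced correlation, and a
passing pruning test says nothing about physically linked real data beyond
the window-rule logic itself.

## What the fixtures do not show

Synthetic truth genomes are uniform random sequence: no repeats, no
segmental duplication, no GC structure. Contig placement on real data must
contend with ambiguous multi-mappings that the greedy selection here only
sees in its `secondary`/`overlap` paths; alignment error itself is out of
scope (the aligner is external). Passing the truth-recovery test
demonstrates the bookkeeping — selection, splicing, chains, ledger,
liftover — is exact, not that any particular aligner's output is reliable.

# Numerical and degenerate-input choices

* Sequences are uppercased on read; IUPAC ambiguity codes other than `N`
  become `N` with a reported count, because the gap logic is defined on `N`
  only. Any other symbol is a hard error naming the record and offset.
* Internal coordinates are 0-based half-open everywhere; GTF and VCF keep
  their native 1-based conventions at the file boundary only.
* All-`N` sequences split into zero contigs with a warning; empty gap lists
  and empty verdict sets produce zero-filled reports, not errors.
* `compute_n50` on an empty list, a pair with zero shared SNPs, `k >= n`
  axes, and REF-mismatching or overlapping variants are hard errors — each
  names the offending object.
* Chain reading enforces the block-sum invariants, so a corrupted chain
  file fails at parse time rather than producing silently shifted
  coordinates.

# Problem sizes in the test suite

The suite runs the full pipeline on the standard 2 × 100 kb fixture, the
oracle comparisons on 1000 random length lists, a 1000-pair clone-end
fixture, 300–2000-SNP genotype panels, and 100-SNP consensus recovery at
simulated depth 30. These sizes were chosen so each property is exercised
at a scale where failures are interpretable, while the whole suite stays
fast enough to run on every change.
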