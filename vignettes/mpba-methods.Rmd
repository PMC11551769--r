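---
title: "MPBA occupancy and motif-interaction analysis: models and methods"
author: "mpba package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MPBA occupancy and motif-interaction analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpba)
```

## The assay and its readout

A massively parallel binding assay (MPBA) measures transcription-factor
(TF) binding to a designed library of regulatory-region variants inside
living cells. The TF is fused to micrococcal nuclease; after calcium
activation, plasmids bound by the fusion are cleaved and drop out of
the sequencing pool. The readout is therefore *depletion*: for each
variant, the log2 fold-change between an activated sample and its
paired pre-activation (timepoint 0) sample.

The library for a region with $n$ annotated motifs contains all $2^n$
combinations of intact/mutated motifs, each motif mutated at a single
position — the position with the highest information content in the
TF's in-vitro position probability matrix (PWM), since a mutation there
is most disruptive to binding. Variants are keyed by an $n$-bit 0/1
string in 5'→3' site order; the all-ones key is the wild type and the
all-zeros key is the fully mutated reference that carries no specific
binding site.

## From counts to occupancy

`normalizeCounts()` applies the normalization chain in a fixed order:

1. each sample's variant counts are scaled to reads per million of its
   assigned total (sequencing-depth correction);
2. technical repeats of the same (TF, timepoint, biological replicate)
   are averaged on the per-million scale;
3. values are log2-transformed after adding a pseudocount (default 1
   per-million unit);
4. each activated condition is normalized to the paired timepoint-0
   condition of the same biological replicate (log2 difference
   $\Delta$).

Biological replicates are kept as separate columns of the resulting
`DepletionTable` and averaged in log space by downstream summaries,
which also report the SEM across per-replicate values. The ordering
*average technical repeats, then log-transform* matters: averaging in
linear space before the log is deliberate and the package performs the
steps in exactly this order.

The pseudocount guards against zero counts, on which the data are
otherwise uninformative; it is applied after technical-repeat
averaging, together with the log. A fully mutated reference with zero
counts in any condition triggers a hard warning, because every
occupancy in that library is contrasted against it.

Occupancy converts the depletion contrast to a fraction of cells:

$$occ(v) = 1 - 0.5^{-(\Delta_v - \Delta_{fm})} = 1 - 2^{\Delta_v -
\Delta_{fm}}$$

with $\Delta_{fm}$ the fully mutated reference's depletion. The map is
strictly decreasing in $\Delta_v - \Delta_{fm}$, equals 0 at the
reference and tends to 1 under complete depletion. Because cleavage may
be incomplete, the value is a *lower bound* on the fraction of cells in
which the region is bound: the simulator (below) makes this explicit,
as the estimator converges on bound fraction × cleavage efficiency.

Occupancies can be negative when a variant is *less* depleted than the
reference. These are reported as-is by default; `occupancies(...,
clip = TRUE)` clips into $[0, 1]$ on request. Clipping silently would
bias the cooperativity null towards positive scores, which is why it is
opt-in.

## Cooperativity against the independence null

For a motif pair (A, B) in a library with $n$ sites, every assignment
of the other $n - 2$ sites defines a *context*. Within each context,
four variants differ only in A and B. Contrasting each single-intact
variant against the both-mutated variant of the same context gives the
single-motif occupancies $occ_A$, $occ_B$; under independent binding
the both-intact variant is expected at

$$E[occ_{AB}] = 1 - (1 - occ_A)(1 - occ_B),$$

the inclusion–exclusion union of two independent events. The
cooperativity score is the unweighted mean of (observed − expected)
over all $2^{n-2}$ contexts, with the SEM across contexts. The mean is
unweighted because each context is an equally designed measurement; a
depth-weighted variant can be composed from `contextOccupancy()` when
low-count contexts are a concern.

Two properties of the estimator are worth knowing, both verified
analytically in the test suite on noise-free data:

* an interaction that raises the joint bound fraction additively by $c$
  is recovered as exactly $c$ in the context where all other motifs are
  mutated, but as $c / (1 - b_{ref})$ in contexts whose reference
  (both-mutated) variant is itself bound with fraction $b_{ref}$ — the
  contrast is relative to what survives cleavage in that context;
* an interaction between sites (1, 2) leaks into the measured (1, 3)
  pair score through contexts where site 2 is intact (by
  $c \, p_3 / (1 - p_2)$ per such context). Pair scores in dense
  libraries are therefore correlated, not independent read-outs.

Per-context occupancies may be negative under noise; they propagate
into observed and expected without clipping (consistent with the
occupancy default), preserving the symmetry of the null. The default
report threshold for calling a pair cooperative is a score above 0.1 —
a 10% occupancy gain over independence — configurable in
`allPairCooperativity()`.

Motif distance follows the gap convention: distance 0 means the second
motif starts one base after the end of the first; overlapping spans
also report 0.

### Recruitment and self-motif occupancy

`recruitmentScore()` isolates what a non-canonical motif (a motif of a
*different* TF) contributes to the tested TF's occupancy on its own:
only sequences with every canonical ("self") site mutated enter, and
the non-canonical motif's intact vs mutated sets are contrasted,
averaging $\Delta$ in log space over the free sites' states.
`selfMotifOccupancy()` is the complementary contrast — all self sites
intact vs all mutated — and reduces to the single-motif occupancy when
the TF has one site and the library no others. Log-space averaging over
the remaining sites' states is used for both (and for the pair score's
key sets), matching the use of averaged log2 fold-changes throughout
the chain.

`tfPairCorrelation()` screens TF pairs measured on the same library for
shared drivers by Pearson correlation of their per-variant occupancy
vectors, flagging $r > 0.4$; fewer than 3 shared variants is an error
rather than a silent NA.

## Read assignment

Amplicon reads are matched directly against the library design rather
than through an external demultiplexing toolchain. A read is
**assigned** to a variant when:

1. it has exactly the region's length, and its last 6 bases (the 3'
   anchor) match the region's 3' end at the expected offset — any 1-bp
   insertion or deletion shifts the anchor and fails this test;
2. every variable-position base equals the site's wild-type or mutant
   base, which together spell the variant key;
3. the remaining scaffold carries at most 2 mismatches (sequencing
   errors).

Reads matching the scaffold but carrying a variable-position base that
is neither wild type nor mutant are **unassigned** — they describe
combinations absent from the library. Reads failing the 3' anchor
against every design are **filtered_indel**. Reads matching the spiked
poorly-bound control sequence (within the same mismatch budget) are
**control**. The four categories partition every input stream, a
conservation property the tests check on error-injected simulated
reads; the equal-length requirement guarantees that a 1-bp indel can
never be assigned to a wrong variant. The mismatch budget (2) and
anchor length (6) are arguments of `countReads()`; the published
pipeline does not state its tolerances, so these defaults are
deliberately conservative.

Sample QC (`qcFilterSamples()`) drops samples below a depth floor
(default 50,000 assigned reads) and samples whose log-scale profile
correlates below 0.7 (Pearson on $\log_2(c+1)$) with *every* sibling
technical repeat. Both thresholds are package defaults, stated here
because the source protocol names the criteria but not the cutoffs.

## Genome-signal utilities

`canonicalKmerIndex()` collapses each 7-mer with its reverse complement
onto one index (the smaller of the two base-4 encodings); for odd k
there are no palindromes, hence exactly $4^7/2 = 8192$ classes.
`kmerBindingScores()` scores each class by the mean signal in a 20 bp
window centred on each occurrence's central base, averaged over all
occurrences inside promoters. Two conventions had to be fixed where the
source description is ambiguous:

* the 20 bp window is the 20 bases from midpoint−10 to midpoint+9
  (midpoint included); occurrences whose window leaves the track are
  skipped and tallied in the result's `"skipped"` attribute;
* the enrichment denominator (`motifEnrichment()`) is the mean over the
  classes *observed* in promoters — classes with no occurrence have no
  score and cannot enter either side of the ratio.

Pattern matching for enrichment tests both the class representative and
its reverse complement against the IUPAC pattern (bracket sets like
`GAATG[CT]` are accepted), since the index is strand-collapsed.
`promoterZscoreTFCount()` z-scores each TF's per-promoter signal with
the population standard deviation and counts TFs strictly above the
threshold (default 3); zero-variance TFs are excluded with a warning.

PWMs of unequal length are compared (`pwmDistance()`) by sliding the
shorter over the longer and taking the minimum distance; padding with
uniform columns was rejected because it inflates distances between
otherwise identical cores. The variable-position tie rules are: maximal
information content, then closest to the motif midpoint, then leftmost;
the default mutant base is the minimum-probability base at that column,
preferring a transversion, then alphabetical order — an explicit
per-site override always wins.

## Nucleosome rescaling

`nucleosomeAnchor()` slides a library-sized (164 bp) window in 10 bp
steps over promoters, sums the MNase-seq signal per window, and takes
the 99th percentile (linear interpolation) of the window-sum
distribution as 100% nucleosome occupancy. A region's genomic occupancy
is its signal sum over that anchor, capped at 1.

For per-variant nucleosome occupancy, the published expression places
the genomic occupancy in the exponent,
$0.5^{\Delta_{wt} \cdot occ_{lib}}$. Read literally this is
dimensionally incoherent — with $occ_{lib} = 0$ every variant would
score occupancy 1 regardless of its data, and a wild-type-like variant
($\Delta_{wt}=0$) always scores 1 rather than the region's genomic
occupancy. `histoneOccupancy()` therefore implements fold-change ×
anchor, $2^{\Delta_{wt}} \times occ_{lib}$, under which a wild-type-like
variant scores exactly the genomic occupancy; the literal form remains
available via `literal = TRUE` for comparison.

## The generative simulator

`simulateCounts()` is the package's ground-truth oracle. Its model:

* each intact site $i$ is bound in a fraction $p_i$ of cells; a
  variant's bound fraction is the independence union
  $1 - \prod_{i\,intact}(1 - p_i)$ plus additive pairwise terms
  $c_{ij}$ for intact pairs, clamped to $[0,1]$ with a logged clamp
  count. The additive injection makes ground truth equal the
  cooperativity score's own definition in the all-mutated context by
  construction;
* a bound plasmid is cleaved by activation time $t$ with efficiency
  $e_t$, so the expected post/pre abundance ratio of a variant is
  $1 - bound \cdot e_t$ and the occupancy estimator converges on
  $bound \cdot e_t$;
* pre-activation abundances are drawn once per biological replicate
  from a symmetric Dirichlet (concentration 50 — a fairly even
  synthesis pool); technical replicates are independent
  gamma-multinomial draws (gamma shape 50, mild PCR jackpotting) from
  the same biological abundances;
* a poorly bound control — the region shuffled until no motif survives
  on either strand — is spiked at 5% of the pre-activation pool and
  never cleaved.

Defaults emulate the study design: 3 biological × 2 technical
replicates, 10^6 reads per sample, activation times of 60 and 180 s.
Cleavage efficiencies are not published; the defaults 0.5 (60 s) and
0.8 (180 s) encode the qualitative observation that occupancy grows
with activation time, and parameter-recovery validation uses $e = 1$ so
that the estimator's target equals the injected bound fraction rather
than an attenuated version of it. `simulateReads()` additionally
exercises the read matcher by expanding counts into reads with
configurable substitution and 1-bp indel rates.

What the simulator does *not* emulate: plasmid copy-number variation,
growth bottlenecks in library amplification, sequence-dependent PCR
bias, base-quality structure, and nucleosome positioning on the
plasmid. Passing parameter-recovery tests therefore demonstrates the
correctness of the estimators under the stated noise model, not
robustness to every artefact of the bench assay.

## Validation problem sizes

The shipped validation uses two- to seven-site toy libraries on 164 bp
regions: null-recovery runs 200 simulated experiments at depth 10^6
(mean pair score within ±0.01 of zero), signal recovery 25 experiments
with $c = 0.2$ (recovered within ±0.05), estimator consistency 10
experiments at bound fraction × efficiency = 0.9 (within ±0.02), and
the k-mer machinery is checked exhaustively over all 16,384 7-mers.
These sizes keep the whole suite under a minute while leaving the
statistical checks well-powered.

## Known limitations

* Occupancy is a relative measure anchored on the fully mutated
  variant; residual binding to the mutated motifs biases all
  occupancies downward.
* The cooperativity score inherits the estimator couplings described
  above; scores of overlapping pairs within a library are correlated.
* No significance testing beyond the per-pair SEM is provided, by
  design; the score is an effect size.
* Binding kinetics over activation time are not modelled; timepoints
  are analysed independently.
* The read matcher assumes full-length, forward-orientation amplicon
  reads after primer removal; paired-end merging and barcode
  demultiplexing are upstream concerns.
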