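---
title: "Methods: population analysis of centromeric LTR retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analysis of centromeric LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`retropop` analyses populations of centromere-specific LTR retrotransposons —
in wheat, the Gypsy families RLG_Cereba and RLG_Quinta, which make up roughly
half of the functional centromere — on genome assemblies. The pipeline has
five analysis stages plus a simulator:

1. **Discovery** (`find_full_length_copies`): full-length copies are found by
   scanning both strands for hits of the family LTR consensus, pairing
   same-strand hits whose span falls in a family size window, and validating
   the internal region against the internal consensus.
2. **Dating** (`estimate_ages`): the two LTRs of a copy are identical at
   insertion; their divergence, corrected with the Kimura two-parameter
   model, dates the insertion.
3. **Population genetics** (`call_variants`, `run_pca`,
   `pairwise_snp_distance`): every copy is aligned to a family consensus,
   variants are called into a VCF, and PCA reveals subfamily structure.
4. **ChIP hot spots** (`detect_hotspots`, `classify_hotspots`,
   `project_coverage`): segments of strong CENH3 enrichment are called from
   per-base coverage, classified to TE families, and per-copy coverage is
   projected onto consensus coordinates.
5. **Spatial analysis** (`mantel_test`): a Mantel test relates pairwise SNP
   distance to positional distance measured from the centromere midpoint.

Every stage is exercised end to end on synthetic chromosomes with known
ground truth (`simulate_population`, `simulate_chip_tracks`), which is how
the test suite and the acceptance script validate the implementation.

# Discovery

LTR hits are located by exact 12-mer seeding followed by local affine-gap
alignment (match +5, mismatch −4, gap open 10, extend 0.5) of the LTR
consensus against a window around each seed cluster. A hit must cover at
least `min_ltr_coverage = 0.8` of the consensus at identity
`min_ltr_identity = 0.8`; these thresholds are design choices (exposed in the
configuration) — the operational definition of a full-length copy is the
family *size window* (e.g. 7,700–8,000 bp for RLG_Cereba; 4,300–4,500 and
4,700–4,800 bp for RLG_Quinta), measured from the 5' LTR start to the 3' LTR
end. Because a local alignment trims mutated terminal bases, each hit is
extended to full consensus coverage; without this, boundary shifts of one or
two bases would corrupt the TSD windows downstream.

Candidate pairs at window distance are validated by aligning the internal
consensus against the enclosed region in ~1.5 kb anchored chunks (coverage
≥ 50 % of the internal consensus at ≥ 70 % identity), which discards chance
LTR pairs while keeping the dynamic program near-linear in element length.
Overlapping candidates are resolved greedily by descending combined LTR
score, ties to the leftmost start, so output is deterministic.

Target-site duplications are read as the `tsd_length` bases immediately
flanking the element *on the forward genomic strand* regardless of element
orientation (a TSD is a direct repeat). Copies whose TSDs differ at more
than 1 position are removed (`filter_by_tsd`), the rule used to exclude
recombinant or rearranged copies; flanks truncated by a contig edge give an
undefined mismatch count and are likewise removed.

# Dating

For each copy the two LTR sequences are aligned locally (gap open 10,
extend 0.5 — the EMBOSS `water` penalties; match/mismatch +5/−4, the EMBOSS
DNA defaults, since only the gap penalties are prescribed). Columns with a
base in both rows are counted; A↔G and C↔T are transitions, all other
differing pairs transversions; N-containing columns are excluded because the
pattern cannot be classified. The distance is the Kimura two-parameter
correction

$$ d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big), $$

with transition proportion $P$ and transversion proportion $Q$; "counting
transitions and transversions separately" is read as K2P, the standard
two-parameter model. Saturated inputs (log argument ≤ 0) raise an explicit
error rather than returning NaN. The age is $T = d / (2r)$ with
$r = 1.3\times10^{-8}$ substitutions/site/year, the rate proposed for
intergenic regions in grasses; both LTRs accumulate substitutions, hence the
factor 2. Copies whose LTR alignment covers less than half of the shorter
LTR are skipped with a warning (a partial alignment dates a fragment, not
the insertion). For display, `age_percentile_filter` drops ages above the
99th empirical percentile.

# Population genetics

A family consensus is built from 30 randomly sampled copies (seeded). The
built-in aligner is centre-star: the copy with the highest shared 8-mer
content is the centre, every other copy is globally aligned to it, and the
column-majority base is taken (ties alphabetical, majority-gap columns
dropped). Centre-star is a classical 2-approximation to multiple alignment
and needs no external binary; insertions relative to the centre are
discarded, which matches the downstream convention of ignoring insertions
relative to the consensus.

Variant calling aligns each copy locally to the consensus with gap open 50
and extend 0.1 — penalties that strongly discourage spurious gaps. Copy
bases in inserted (non-consensus) columns are discarded; consensus positions
deleted in a copy, or outside its aligned range, are missing for that copy.
A site is retained when, among non-missing calls, the second-most-common
allele has frequency ≥ `maf` (default 1 %) and the missing fraction is at
most `missing_cutoff` (default 90 %). Two open readings were settled as
follows: the missing cutoff is applied **per site** (sites more than 90 %
missing are dropped), and the MAF rule is folded (the site must be
polymorphic among the copies at ≥ 1 %); alternate alleles individually rarer
than the threshold are recoded missing. Multi-allelic sites are kept and
encoded by allele index, which matches VCF semantics; copies are haploid
samples in the emitted VCF 4.2, with the consensus as the contig.

PCA encodes allele indices numerically, mean-imputes missing calls per site
(standard practice for genotype PCA), centres, and decomposes by SVD;
coordinates are deterministic up to component sign. Identical copies give a
zero-variance matrix and an explicit degenerate-input error. Pairwise SNP
distance counts sites where both calls are non-missing and differ, the
`dist.gene`-style pairwise count.

# ChIP-seq hot spots and consensus projection

Coverage tracks are per-base integer read depths. The hot-spot rule is: a
maximal run of at least `min_len = 100` bases, inside the search regions,
where experimental depth is at least `fold = 5` times the regional baseline
**and** at least 5 times the summed control/mock depth at that base. The
baseline is the average experimental coverage over the region set, computed
separately per region set (centromeres vs a control arm), mirroring the
two-average procedure. Runs are strict maximal runs — no sub-threshold gaps
are tolerated (the simplest reading; an optional `max_len` accommodates the
80–300 bp display definition but is off by default). Zero baseline is a
degenerate-track error.

Peaks classify to a TE family when the best local alignment against the
family library spans ≥ 90 columns at ≥ 70 % identity (the blastn-style
rule); a seeded local aligner replaces blastn since the contract is the
thresholds, not the tool. Ties go to higher identity, then alphabetical
family. Per-family counts are normalised to peaks per annotated megabase.

Projection transfers the genomic depth at each aligned copy base to its
consensus column, omitting insertions in the copy; deleted consensus columns
receive nothing, and minus-strand copies are projected in consensus
orientation. The summed projected depth therefore equals the genomic depth
over the copy minus the depth over insertion bases — an identity the tests
assert exactly. Profiles sum per-position depth over copies per experiment;
the CENH3/mock ratio uses a pseudocount of 1 on the denominator to avoid
division by zero (the handling was unstated; a pseudocount of 1 on integer
counts is the conventional minimal choice).

# Spatial analysis

The position of a copy is its interval midpoint (which coordinate to use was
unstated; the midpoint is symmetric and stable under small boundary error).
The positional difference of two copies is
$\big||p_i - m| - |p_j - m|\big|$ in Mb for centromere midpoint $m$ — two
copies equidistant from the midpoint on opposite sides have difference 0.
The Mantel test computes the Spearman correlation between the off-diagonal
entries of the genetic and positional distance matrices and permutes
rows/columns of one matrix jointly (9,999 permutations by default). The
p-value uses the add-one correction $p = (1 + \#\{r_\pi \ge r\})/(B+1)$, so
it is never exactly zero, and the test is one-sided for positive
association, matching the hypothesis (young copies concentrate at the
functional centromere) and the default of the reference R implementation.
`filter_region_age` retains copies whose midpoint lies in a given interval
with age at most a cutoff — the rule used to ask which copies inserted into
a newly formed neocentromere (e.g. 281.1–284 Mb, ≤ 100,000 years).

# The synthetic-data generator

`simulate_population` builds an i.i.d.-uniform random chromosome (discovery
operates on consensus similarity, not composition, so base composition is
not modelled) and implants elements with known ground truth:

* **Families.** Defaults mirror the real families' scales: 7,850 bp elements
  (500 bp LTRs) in a 7,700–8,000 bp window, and 4,400 bp elements (400 bp
  LTRs) with 4,300–4,500/4,700–4,800 bp windows.
* **TSDs.** Each implant is flanked by an identical 5 bp duplication. The
  true TSD length for these families is not established; 5 bp is the
  canonical value for Gypsy integrases and is configurable.
* **Ages and LTR divergence.** Ages are uniform over `age_range`
  (default 10⁴–2×10⁶ years). Each LTR of a copy is independently mutated
  from its template; the per-site mutation probability is solved
  analytically so that the *expected observed* pairwise difference
  proportion between the two LTRs equals exactly $2 r T$, accounting for
  coincident hits at the same site (with transition probability
  $t = R/(R+1)$ for transition:transversion ratio $R$, two mutated copies of
  a site coincide with probability $t^2 + (1-t)^2/2$). Substitution
  positions are uniform; transitions are drawn per event with probability
  $R/(R+1)$ (default $R = 2$), matching the site-pattern assumptions of the
  dating model.
* **Wave templates (master-copy model).** Subfamilies are temporal waves:
  copies are assigned to subfamilies by age rank, each wave carries fixed
  diagnostic SNPs, and wave templates derive from a master lineage that
  drifts at the substitution rate between wave mean ages. This reflects how
  retrotransposon bursts amplify from contemporary source copies, and it is
  what couples pairwise SNP distance to insertion-time difference. Without
  shared lineage drift, copy-to-copy distances at full element length are
  dominated by private post-insertion mutations (≈ proportional to
  $T_i + T_j$), and the age–position association would be undetectable even
  though every per-copy quantity is correct. LTR dating is unaffected: both
  LTRs share the template state at insertion.
* **Positions.** Non-decoy copies are placed uniformly inside the
  centromere interval; with `age_position_gradient` on, ages are assigned
  by distance rank from the centromere midpoint, so age increases with
  distance — emulating the outward displacement of older copies. Decoys
  (solo LTRs, 5'-truncated copies, and full-length copies with ≥ 2-mismatch
  TSDs) are placed anywhere. Requested implants that cannot fit raise an
  explicit overflow error rather than silently truncating.
* **ChIP tracks.** Depth is per-base Poisson — the simplest model meeting
  the caller's contracts — with the experimental mean elevated by
  `chip_enrichment_fold` inside enrichment segments (the LTR intervals of
  the enriched family's non-decoy copies) and flat background controls and
  mocks. The default fold is 30: a hot spot must exceed both five times the
  regional baseline and five times the *summed* control depth at every base
  of a ≥ 100 bp run, and with independent per-base noise an enrichment near
  the detection threshold is split by single-base dips; strong pileup is
  also what the real CENH3 hot spots show. The fold is a direct parameter
  for null (fold = 1) and mean-coverage checks.

What the generator does **not** emulate: read sequences and mapping
ambiguity (coverage is consumed, not produced), nested insertions, indel
mutations within elements, local base composition, and recombination
between lineages. Passing tests therefore demonstrate correctness of the
algorithms under substitution-only divergence and clean coverage; they do
not certify performance on real assemblies with segmental duplications,
nesting or mapping artefacts.

# Numerical and interface conventions

* Internal coordinates are 1-based inclusive (`IRanges`/`GRanges`, the
  native R/Bioconductor convention); GFF3 and VCF are emitted 1-based per
  their standards, BED/bedGraph 0-based half-open at the boundary (via
  `rtracklayer`). Round-trips are asserted lossless in the tests.
* All randomness flows through explicit seeds; every simulator and pipeline
  output is byte-reproducible for a fixed seed, and the pipeline writes a
  JSON manifest of versions, seeds, thresholds and per-stage counts.
* Deterministic tie-breaks throughout: alphabetical base in consensus ties,
  leftmost start in candidate ties, higher identity then alphabetical
  family in classification ties.
* Degenerate inputs fail loudly: empty genomes, saturated distances,
  zero-baseline tracks, zero-variance PCA and Mantel inputs all raise
  informative errors.

# Problem sizes

The bundled checks run at desk scale, chosen so the full suite completes in
a few minutes on one core: discovery on a 5 Mb chromosome with 100 implants
plus 30 decoys at real element sizes; age recovery on 150–2,000 copies per
true age at 10⁴, 10⁵ and 10⁶ years with 1 kb LTRs; variant calling on up to
200 copies; Mantel calibration on 500 null replicates of 30 copies. The
algorithms themselves have no scale assumptions beyond memory for
per-chromosome depth vectors.

# Limitations

Discovery assumes two recognisable LTR hits; heavily nested or truncated
elements are out of scope by design (decoys are rejected, not catalogued).
Dating assumes a single substitution rate and no gene conversion between
LTRs, which in real data biases ages downward when conversion homogenises
LTR pairs. The built-in centre-star consensus is adequate for
substitution-dominated populations; for indel-rich families an external
multiple aligner can be substituted when building the consensus. The Mantel
test inherits the usual caveats of distance-matrix permutation tests
(non-independence of pairs; the p-value is calibrated, but the statistic is
not an effect size on the copy level).
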