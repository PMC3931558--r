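---
title: "Methods: simulating and mapping suppressor screens by pooled sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping suppressor screens by pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supmapr)
```

## The problem

One-step mapping-by-sequencing identifies the molecular lesion behind a
mutant phenotype in a single experiment: the mutant (isolated in the
reference strain, "A"/N2-like) is crossed to a genetically divergent wild
isolate (the polymorphic mapping strain, "B"/Hawaiian-like), recombinant
F2 progeny carrying the phenotype are selected and pooled, and the pool
is sequenced. Away from the causal locus the pool is an even mix of both
parental genomes, so the polymorphic strain's diagnostic SNPs sit near
50% frequency; around the causal locus, selection removes B haplotypes
and the B-SNP frequency collapses. The depleted region is the mapping
interval, and the same pool, scanned for novel mutations, yields the
candidate lesions.

Suppressor mutations are a hard case for this strategy: they have no
phenotype of their own — only the ability to rescue another mutation —
and they can be dominant, semi-dominant or recessive, which changes both
the selection regime and the expected pool frequency of the causal
allele. `supmapr` implements the whole protocol as a simulation plus
analysis pipeline so that every stage — cross design, selection
arithmetic, pooled read sampling, interval calling, candidate filtering —
is executable and testable at desk scale.

## The genetic model

**Genome and markers.** Six chromosomes (default lengths 15, 15, 14,
17.5, 21, 18 Mb, the first and fourth fixed by the linkage groups whose
sizes the screen's introgression gaps are quoted against). Markers are
biallelic strain-diagnostic SNPs placed uniformly at 20/Mb by default
(about 2,000 genome-wide). Real inter-strain SNP catalogues are roughly
an order of magnitude denser; the default is a desk-scale thinning and is
a single knob (`marker_density`).

**Meiosis.** Each chromosome undergoes exactly one obligate crossover per
meiosis at a position uniform in base pairs, and one of the two
reciprocal products is transmitted. This matches the ~50 cM genetic
length and near-complete crossover interference of holocentric nematode
chromosomes. A Poisson(1) crossover-count alternative is available
(`crossover_model = "poisson"`). Under the obligate model, two loci a
physical fraction *d/L* apart recombine with probability *d/L*, which the
meiosis tests verify by brute-force simulation.

**Selection.** A `selection_model` maps the suppressor genotype
(`sup/sup`, `sup/+`, `+/+`) to a survival probability and a relative
brood size. Recessive mode: only homozygotes propagate (heterozygous
survival is 0 by definition). Semi-dominant mode: heterozygotes survive
with, by default, half-size broods ("fewer progeny as heterozygotes");
dominant mode gives them full broods. Everything survives at the
permissive temperature. Viability is a probability table, not a
mechanism — no temperature-shift kinetics or developmental biology is
modelled.

**En-masse propagation.** After F2 selection the pool selfs for two
further generations. Each generation the plate is refilled to a constant
`f2_pool_size` animals: a parent is drawn with probability proportional
to its brood multiplier (among parents that can produce viable
offspring), then a viable selfed offspring of that parent is accepted by
rejection sampling. Dead embryos therefore do not reduce a surviving
parent's representation — hermaphrodites lay far more embryos than a
food-limited plate propagates. Under this model the heterozygote fraction
of a semi-dominant pool shrinks by exactly 2/3 per generation, giving the
closed-form recursion the tests use as an oracle: allele frequency 2/3 at
F2 and 23/27 ≈ 0.852 two generations later. Propagating at the raw
survivor count instead (an earlier design) exaggerates drift and
occasionally fakes depleted windows on unlinked chromosomes; the
constant-size model is both more faithful to an en-masse culture and
statistically better behaved.

**The mapping strain and its gaps.** The strain used for the cross is the
target-gene mutant introgressed into the polymorphic background.
Empirically such strains retain reference-genome regions that resist
introgression — around the target gene itself (linkage) and around the
paternal-effect incompatibility locus on LG I. `simulate_screen()`
constructs the strain directly from its *measured* description: B origin
everywhere except the configured gaps (LG I 1.5–12.8 Mb and LG IV
0–15.8 Mb by default), which stay A-type. Building the strain this way
keeps the gap annotation written to disk exactly equal to the strain's
true A-type regions, the situation of a strain whose gaps have been
mapped by sequencing before use. Simulating the introgression cross
itself (available via `backcross_series()` with `force_a_regions`)
leaves stochastic linkage drag beyond any fixed annotation — precisely
the failure mode that makes unannotated gaps masquerade as mapping
signals, and the reason sequencing the mapping strain beforehand is the
recommended practice.

**Incompatibility locus.** The paternal-effect incompatibility (B/B
zygotes sired by heterozygous fathers die) is implemented and tested, with
a default placement at 2.3 Mb on LG I — inside the LG I gap, which is why
it is disabled in default mapping runs: the gap already removes the locus
from the mapping cross.

**EMS mutagenesis.** `mutagenize()` adds one causal variant (in the
configured suppressor gene's CDS, with a configurable truth effect class,
missense by default) plus `n_passenger_ems` passengers (default 300) at
random non-marker positions, all heterozygous. The substitution spectrum
is 87% G:C→A:T transitions by default — the canonical EMS signature; the
published screen reports dose (0.04 M, 4 h) but not spectrum, so the
fraction is a knob. Four backcross rounds to the unmutagenized parent
reduce unlinked passenger heterozygosity by 1/2 per round in expectation
(verified against the (1/2)^4 closed form).

## Sequencing model

The pool's true per-site frequencies are converted to read evidence
site-by-site: depth is Poisson with mean 18 (the per-library fold
coverage of the protocol being emulated; a fixed-depth mode exists for
deterministic tests), and the alt count is binomial with success
probability `f(1-e) + (1-f)e/3`, folding strand and mapping error into a
single per-read miscall probability `e` (default 0.001) with uniform
erroneous-base choice. No read-level simulation, alignment or genotype
likelihood is attempted — upstream read processing is out of scope.
Markers and novel variants are emitted in one VCF 4.2 file with `AD`/`DP`
per-sample fields, markers flagged `MARKER` in INFO, because the same
pool serves both the mapping scan and the candidate scan.

## Mapping algorithm

The published interval definition was visual ("absence" of polymorphic
SNPs for recessive suppressors, "reduction" for dominant ones, inspected
along the chromosome). The package's codification:

1. **Track**: per-marker B frequency `alt/(ref+alt)`, markers under
   `min_depth` (4 reads) dropped and counted in a coverage report.
2. **Windows**: 500 kb tiles; unweighted mean frequency (each marker one
   vote, matching the dot-per-SNP presentation of the original plots);
   windows with fewer than 5 markers are uninformative.
3. **Calling**: informative windows with mean ≤ 0.10 (absence, recessive)
   or ≤ 0.30 (reduction, dominant/semi-dominant) qualify; maximal runs
   merged across ≤ 1 non-qualifying window become intervals. Bounds snap
   to the outermost sub-threshold marker positions, extending outward
   while consecutive flanking markers stay sub-threshold (so a depleted
   marker stranded in a marker-sparse window still bounds the interval).
   Intervals under 500 kb are discarded.
4. **Gap subtraction**: intervals fully inside the known introgression
   gaps are flagged non-unique; partial overlaps are trimmed to their
   residual and kept only if the residual spans 500 kb.
5. **Outcome**: exactly one unique interval → `extragenic_mapped`; none,
   but a qualifying new variant inside the target gene →
   `linked_to_target` (intragenic suppressors hide inside the LG IV gap);
   neither → `unmapped`; several → `ambiguous`, reported with all
   intervals listed rather than silently resolved.

The reduction cutoff (0.30) is this package's default and must not be
read as a published value — the source protocol never states one. The
display rule (plot only frequencies > 20%) is implemented as a pure
plotting view and never feeds interval calling. The caller is verified
against an exhaustive-scan oracle on random tracks of up to 50 windows,
and lowering the absence threshold provably never enlarges an interval.

## Candidate identification

Pipeline order: parental subtraction (anything present in the parental
strain's library, including the original lethal allele), cross-strain
background removal (variants in ≥ 2 sequenced pools; "multiple" is not
defined in the source and is a knob), effect classification, then
interval restriction and the frequency/effect filter. Thresholds are
strict inequalities — frequency > 0.85 for recessive suppressors, > 0.67
for semi-dominant ones — and only missense, nonsense and splice-site
changes qualify. Whether background removal ran before or after interval
restriction in the original analysis is not stated; the order here is
recorded in the report metadata. Parental subtraction and background
removal commute (tested on random inputs), so the choice only affects
logging, not results.

Effect classification translates the affected codon through the standard
genetic code on the coding strand of the single supplied transcript (toy
gene models have one transcript; no isoform arbitration). Splice sites
are the first/last two intronic bases of every intron. Start-codon and
stop-codon losses are grouped with missense (nonsynonymous,
non-truncating); indels are out of scope throughout, consistent with the
EMS point-mutation spectrum. The classifier is checked against a
brute-force oracle that rebuilds and translates the entire mutant CDS
with Biostrings on a two-gene toy genome (both strands), with the
initiator-codon special case of `Biostrings::translate` disabled in the
oracle so both routes implement the same plain genetic code.

## Homozygote preselection

For a dominant suppressor the selected pool keeps heterozygotes, the
causal-allele frequency plateaus near 85% instead of 100%, and the
depleted region is shallow and wide. The protocol's counter-measure is
simulated by `preselect_homozygotes()`: F2s are "plated singly" and kept
when their selfed brood exceeds 60% survivors. With heterozygous brood
survival near 50%, the kept set is dominated by the homozygous quarter.
At the desk-scale brood of 50 scored progeny, heterozygotes leak through
the screen in the binomial tail (about 6% of them) — the original
protocol screened full broods and still retested eight F3s per kept F2 to
confirm homozygosity. Pooling 26 preselected homozygotes and mapping in
absence mode yields systematically narrower intervals than pooling
unselected semi-dominant survivors in reduction mode; the acceptance
suite asserts this direction on seed-paired replicate screens (the same
comparison the original study made for its hardest suppressor: one
suppressor line, two pooling strategies).

## Synthetic data: what it does and does not emulate

The generator writes a complete truth bundle — genome FASTA, gene-model
GFF3, marker TSV, gaps BED, parental and pooled VCFs, truth JSON — all
deterministic given one seed. Chromosome sequences are N-filled except
where the simulation needs real bases (gene bodies, marker sites, variant
sites): a sparse synthetic reference that keeps full-length coordinates
at desk-scale memory cost. Gene models are toy single-transcript genes
with ATG...stop CDSs free of internal stops, placed on both strands.

Passing tests on this substrate demonstrate the *analysis logic* —
selection arithmetic, frequency tracks, interval calling, filtering — not
robustness to real sequencing data: there are no alignment artifacts,
no repeat-induced mis-mapping, no indels, no copy-number variation, no
non-uniform coverage along the genome, and marker density is ~10× below a
real inter-strain SNP catalogue. The per-read error model is a single
folded miscall probability, far simpler than real base-quality
structure.

## Numerical and design choices

- **Problem sizes**: unit tests run on a 2-chromosome × 2 Mb fixture
  (40 markers); the acceptance suite runs 20 full-genome recessive
  screens, 16 paired semi-dominant screens and the recursion/meiosis
  checks, all with pool sizes 120–250 — the study-scale conditions —
  chosen so the whole suite completes in minutes on one CPU.
- **Stochastic assertions** fix their seeds and size replicate counts so
  each tolerance sits at ≥ 3σ of sampling noise; tolerances themselves
  come from the claims being checked (e.g. 25% ± 1.5% for the Mendelian
  quarter, ± 0.04 for the 23/27 recursion match).
- **Coordinates**: VCF/GFF3/marker TSV and all internal computation are
  1-based inclusive; BED files are 0-based half-open; conversion is
  isolated in the readers/writers.
- **Config serialization** uses JSON (`write_run_config()`): the
  configuration nests tables (gap lists, chromosome lengths), which a
  flat key-value format would force into ad-hoc encodings; JSON
  round-trips them losslessly through a standard parser.
- **Preselection sampling entry point**: whether the singled F2s are
  drawn before or after viability selection is ambiguous in the source
  protocol; both are supported (`preselect_before_selection`), default
  before (the plated F2s are unselected recombinants).
- **Degenerate inputs**: empty marker maps are valid; zero-depth sites
  are emitted and read back with undefined frequency; extinct pools
  (all genotypes inviable) return empty, warning-flagged pools, modelling
  the suppressor lines for which no survivors were recovered; an empty
  interval set plus no target-gene hit is a well-formed `unmapped`
  report.

## Known limitations

- Genotype-level truth only: no read simulation, so aligner- or
  caller-induced biases cannot be studied.
- The obligate-crossover model ignores chromosome-arm recombination-rate
  structure; physical and genetic distance are proportional.
- Selection acts on a single biallelic suppressor locus; no epistasis,
  no multi-locus suppression, no incomplete penetrance.
- The semi-dominant brood penalty is a single multiplier; real brood
  kinetics (timing, clutch structure) are not modelled.
- Interval calling is a windowed threshold scan by design; smoothing or
  HMM segmentation alternatives are out of scope.
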