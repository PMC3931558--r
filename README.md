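# supmapr

Simulated suppressor screens and one-step mapping-by-sequencing for a
selfing nematode.

## The problem

Genetic suppressors — second-site mutations that rescue the phenotype of
another mutation — are powerful probes of pathway structure, but they are
hard to clone: they have no phenotype of their own and may be dominant,
semi-dominant or recessive. One-step WGS/SNP mapping solves this in a
single experiment: cross the suppressed mutant to a polymorphic mapping
strain (a Hawaiian-like wild isolate), select F2 recombinants that retain
suppression, grow them en masse under selection for two more generations,
and sequence the survivors as one pool. Away from the suppressor the pool
carries polymorphic-strain SNPs at ~50% frequency; around it, selection
strips them out. The depleted interval maps the suppressor, and the same
pool, scanned for novel EMS-induced mutations, names the candidates.

`supmapr` implements the full protocol as testable code:

- **Cross simulation** (`simulate_screen()`): EMS mutagenesis with a
  configurable G:C→A:T transition spectrum, backcrossing, an introgressed
  mapping strain with its characteristic marker gaps (LG I 1.5–12.8 Mb,
  LG IV 0–15.8 Mb), obligate-crossover meiosis, F1/F2 generation,
  genotype-dependent selection (recessive / semi-dominant / dominant),
  optional paternal-effect incompatibility, en-masse propagation, and an
  optional homozygote-preselection step (plate F2s singly, keep broods
  with > 60% survivors).
- **Pooled sequencing** (`sample_site_counts()`, `emit_pool_vcf()`):
  per-site Poisson depth at 18× with binomial allele counts and a folded
  per-read error rate, emitted as VCF 4.2 with `AD`/`DP` fields.
- **Mapping** (`marker_frequencies()`, `window_stats()`,
  `call_intervals()`, `subtract_known_gaps()`, `classify_outcome()`):
  windowed B-allele frequency scan; absence mode (≤ 0.10, recessive) or
  reduction mode (≤ 0.30, dominant); introgression-gap subtraction;
  outcomes `extragenic_mapped` / `linked_to_target` / `unmapped` /
  `ambiguous`.
- **Candidates** (`subtract_parental()`, `remove_background()`,
  `classify_effect()`, `filter_candidates()`, `detect_intragenic()`):
  parental subtraction, cross-strain background removal, codon-level
  effect classification against gene models, and the strict > 85%
  (recessive) / > 67% (semi-dominant) pool-frequency filters restricted
  to missense / nonsense / splice-site changes.

For the population model behind the selection arithmetic (why a
semi-dominant pool reaches allele frequency 2/3 at F2 and 23/27 ≈ 85%
two selfing generations later), see the methods vignette in
`vignettes/suppressor-mapping-methods.Rmd`.

## Worked example

Simulate a recessive suppressor screen at the protocol's scale (six
chromosomes, ~2,000 markers, 250 F2 recombinants, two further selfing
generations, 18× pooled coverage), then map and scan it from the files
the simulation wrote:

```r
library(supmapr)

cfg <- screen_config(seed = 11)          # mode = "recessive" by default
bundle <- simulate_screen(cfg)
print(bundle)
#> <screen_truth> 1 line(s), mode=recessive, seed=11
#>   line1: causal II:6500017 T>C (missense), true freq 1.000

res <- run_e2e(cfg, "screen_out")        # simulate -> map -> candidates
r <- res$line1
r$report$outcome
#> [1] "extragenic_mapped"
r$report$unique_intervals[, c("chrom", "start", "end", "span",
                              "mean_freq", "n_markers")]
#>   chrom   start     end    span  mean_freq n_markers
#> 2    II 4896352 8488123 3591771 0.02700225        67
r$report$candidates
#>   chrom     pos ref alt freq gene_id   effect inside_interval
#> 1    II 6500017   T   C    1   sup-1 missense            TRUE
```

Reading the output: selection fixed the causal suppressor allele in the
pool (true frequency 1.000), the marker scan found a single unique
depleted interval of 3.6 Mb on LG II (mean Hawaiian-SNP frequency 2.7%
across its 67 markers — "absence" by the recessive criterion) while the
known introgression gaps on LG I and LG IV were recognized and set aside,
and the candidate scan inside that interval returned exactly one
qualifying mutation: the simulated causal missense change in `sup-1` at
pool frequency 1.0, well past the > 85% recessive threshold. The filter
log (`pool=70 after_parental=19 ... candidates=1`) shows 70 observed
variant sites shrinking to one candidate through parental subtraction and
the interval/effect/frequency filters.

A command-line wrapper with the same stages lives at
`inst/cli/supmap.R` (`simulate`, `map`, `candidates`, `e2e`); its exit
status encodes the outcome (0 mapped, 3 linked to the target gene,
4 unmapped, 2 input error, 5 ambiguous) so batch runs can be triaged.

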