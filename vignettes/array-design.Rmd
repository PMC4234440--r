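---
title: "Designing and evaluating a SNP genotyping array with arrayforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a SNP genotyping array with arrayforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayforge)
```

## The problem

Fixed-content SNP arrays genotype hundreds of thousands of loci cheaply and
reproducibly, but only the loci that were printed on the array. Designing
one is therefore a one-shot filtering and packing problem: start from
millions of candidate SNPs discovered by re-sequencing several strains of
the target species, discard every candidate whose probe context would
genotype unreliably, and then pack a fixed budget of markers as evenly as
possible across the genome while honouring priorities between functional
classes of SNPs. After manufacture, the array is validated by genotyping
large panels: markers are classified by cluster quality, accuracy is
estimated from parent–offspring trios, and the data are put to first
scientific use through linkage-disequilibrium (LD) decay profiles and
identity-by-state (IBS) clustering of the sampled populations.

`arrayforge` implements this whole workflow at desk scale — the design
cascade, the spacing selection, and the evaluation suite — together with a
synthetic-data generator that produces genomes, candidate pools and
structured genotype matrices with known ground truth, so every stage is
testable without any external download. The defaults throughout are the
parameter values used to design a published 250,000-SNP array for common
carp (*Cyprinus carpio*), a tetraploidized cyprinid with a large genome and
many domesticated strains; the shipped reference tables
(`design_reference_tables()`) carry that design's printed per-stage counts.

## The candidate-reduction cascade

Candidates enter as biallelic SNPs with call statistics and leave, greatly
thinned, as probe-worthy loci. `run_filter_cascade()` applies the stages in
a fixed order, each producing a conserved input/output/removed accounting
row:

1. **Primary call filters** (`filter_primary()`): SNP quality $\ge 20$,
   read depth $\ge 10$, minor allele count $\ge 2$, minor allele frequency
   $\ge 5\%$. These mirror the thresholds applied at variant calling;
   mapping and base quality live upstream of this package.
2. **Probe context extraction** (`extract_flank()`): 35 bp either side of
   the SNP, a 71-bp context whose centre must equal the reference allele.
   Loci too close to a sequence end cannot be probed and count as removed
   at the next stage.
3. **Homopolymer/N screen** (`flank_run_filter()`): any `N`, more than
   four consecutive `G` or `C`, or more than six consecutive `A` or `T`
   fails. We read "consecutive G or C" as a run of one repeated base (the
   standard homopolymer semantics in probe design); the alternative
   reading — a run drawn from the set $\{G,C\}$ — is available as
   `run_mode = "base_class"` because the source description is ambiguous.
   The reported reason is the left-most rule violation.
4. **GC screen** (`gc_filter()`): GC fraction of the 71-mer within the
   closed interval $[0.30, 0.70]$; "below 30% or above 70% removed"
   makes the bounds themselves acceptable.
5. **Uniqueness** (`uniqueness_filter()`): the 71-mer must occur exactly
   once in the genome, counting both strands (the locus itself is that one
   hit). We use exact k-mer matching (Biostrings `PDict`) rather than a
   mismatch-tolerant aligner: it is deterministic, dependency-free at desk
   scale, and the original mapping tool and its mismatch tolerance are not
   specified anywhere we could follow.
6. **Proximity** (`proximity_filter()`): neighbouring variants interfere
   with hybridisation, so *both* members of any pair $\le 10$ bp apart are
   removed (the rule is "removed", not "thinned"), as is every variant in
   any 35-bp window holding more than two variants. Window occupancy is
   counted over the full set entering the stage — a variant already doomed
   by the pair rule still crowds its neighbours. Two readings the source
   leaves open are exposed as options: `pair_rule = "lt"` for a strict
   10-bp inequality, and proximity is computed over the merged pool of all
   strains (interference is physical, not per-strain).
7. **Probe conversion score** (`pconvert_filter()`): platform-predicted
   conversion probabilities for the forward and reverse probe are consumed
   as an input table; a SNP qualifies when the better of the two reaches
   0.58 (inclusive). Whether one or both probes had to qualify is not
   stated in the source, so `pconvert_mode = "both"` is available; the
   default is `"any"` (`max()`), which matches the high qualification rate
   reported (91.8% of submitted SNPs). The predictor itself (a platform
   random-forest model over probe thermodynamics) is out of scope — only
   the threshold is applied here.

Each stage is a pure per-record predicate or a pure function of positions,
so every filter is idempotent, and the first two flank screens commute
(asserted in the tests).

## Category-prioritised spacing selection

`greedy_select()` packs the array. A `selection_plan()` is an ordered list
of `category_spec(category, priority, t, quota)` rows; the default plan
reproduces the published design order:

| priority | category | spacing $t$ |
|---|---|---|
| 1–3 | non-synonymous, 3'UTR, 5'UTR | 100 bp |
| 4 | other transcript SNPs | 1.8 kb |
| 5 | strain-shared re-sequencing SNPs | 10 kb |
| 6 | strain-specific SNPs | 17 kb |

Within a category candidates are visited best-quality-first (ties broken
by chromosome, then position; a `position_sweep` strategy is also offered
because the source describes the ordering only as "quality scores and
spacing"). A candidate is accepted when, for every already-selected SNP on
the same chromosome, the distance is at least
$\max(t_{\text{candidate}}, t_{\text{selected}})$. The literal rule
"distance $\ge$ the candidate's own $t$" is equivalent whenever $t$ is
non-decreasing in priority order — true of the design plan above — but it
cannot guarantee the advertised final-set property (every marker at least
its *own* $t$ from everything else) for plans where a later category has a
smaller $t$; the symmetric `max` rule guarantees it for every plan, which
is why we enforce it. Spacing is checked across categories (the
strain-specific clause "from any other SNP on the array" indicates
cross-category checking); inter-chromosomal markers never conflict.

The selection is deterministic, quota- and budget-capped, and greedy-
maximal: since the selected set only grows, any rejected candidate remains
in conflict with the final set. Tests verify spacing, determinism,
maximality and priority dominance against an $O(n^2)$ checker on 10,000
random candidates.

`interval_histogram()` reports adjacent within-chromosome intervals (the
published design averaged 6.6 kb between 250,000 markers);
`density_report()` reports sites/Mb per chromosome, concatenating
unassembled scaffolds into a pseudo-chromosome `"P"` as the published
density figure did. `design_summary()` performs the stage-by-category
accounting and validates that attrition is monotone.

## Evaluating a manufactured array

`snp_performance()` classifies each marker from its call rate and genotype
class counts, in the order used by the platform's analysis suite: external
OTV flag, call-rate threshold (default 0.95, with 0.80 the conventional
setting for cross-species panels; a rate exactly at the threshold passes),
monomorphic, no-minor-homozygote, polymorphic-high-resolution, `Other`.
Off-target variants cannot be recognised from dosage calls — they are an
intensity-space phenomenon — so OTV is only ever assigned from an external
flag. A marker showing only heterozygotes falls into `Other`; the
platform's exact tie-breaking for `Other` is proprietary, and our rule set
is an operational stand-in that is total and exhaustively tested against a
decision-table oracle. Markers on the array but absent from genotyping
output (manufacturing failures) are accounted as `Other` so class counts
always sum to the array total. `eval_summary()` adds the MAF spectrum
(strict cutoffs, denominator = markers passing the call-rate threshold).

`family_accuracy()` estimates genotyping accuracy from a two-parent family
as $1 - \sum \text{errors} / \sum \text{tested}$, counting a Mendelian
inconsistency once per (marker, offspring) pair and skipping any trio with
a missing call. `exclude_discordant()` drops offspring whose error rate
exceeds a user-chosen cutoff (sample swaps produce error rates two orders
of magnitude above the genotyping-error floor, so any reasonable cutoff
finds them); the cutoff has no default because the analogous published
exclusion was done by inspection.

`pairwise_r2()` computes genotype-dosage $r^2$ (the PLINK `--r2` default;
no phasing) for same-chromosome pairs within 100 kb with both MAFs above
0.05, and `bin_decay()` averages it in 1-kb bins labelled by their upper
edge. `ibs_matrix()` computes allele-sharing similarity
$\mathrm{mean}(2 - |d_i - d_j|)/2$ over jointly called markers and
`mds_ibs()` embeds $1 - \mathrm{similarity}$ by classical Torgerson
scaling (via `stats::cmdscale`), with each axis's sign fixed by forcing
its first nonzero loading positive. Embeddings are compared through
inter-point distances, never raw coordinates. The published clustering
applied additional relatedness pre-filters before IBS; we compute IBS on
all retained pairs.

## The synthetic-data generator

The generator emulates the *structure* of the study, not its scale or its
population-genetic realism:

* `gen_genome()` draws independent bases at a target GC fraction (default
  0.37, a typical teleost value). Real genomes have repeats,
  isochores and assembly gaps; the only repeat structure here is what
  `plant_variants()` injects deliberately.
* `plant_variants()` places candidates at least 100 bp apart and verifies
  at planting time that "clean" candidates pass the homopolymer, GC,
  uniqueness and proximity rules, then plants labelled violations:
  injected homopolymer runs, AT-rich probe contexts, duplicated 101-bp
  blocks with a twin SNP at the copy, and close pairs/triples. The truth
  table alone — never re-derived logic — predicts the fate of every record
  in downstream tests.
* `gen_genotypes()` draws ancestral frequencies from Beta(2, 2) and
  perturbs them per population by a Balding–Nichols Beta with variance set
  by the `divergence` parameter (one interpretable knob; default 0.1,
  with 0.3 representing the strong between-species divergence that
  produces clearly separated clusters). LD is induced by a shared-uniform
  copy chain: a latent uniform is retained between adjacent markers with
  probability $\rho^{d_{kb}}$, else redrawn, and the allele is
  $1[u < p]$. Marginals are exact for any frequency, and when frequencies
  are equal the dosage correlation at distance $D$ kb is exactly
  $\rho^{D}$, so $r^2 = \rho^{2D}$ and the decay parameter is recoverable
  by a log-linear fit (with unequal frequencies the decay is attenuated
  but stays monotone — sufficient for what the estimator tests need). A
  coalescent simulator would be more realistic and much heavier; this
  artifact tests LD *estimation*, not demography.
* Families add two fresh parents per family and build offspring by
  per-marker gamete sampling (no recombination map; irrelevant for
  Mendelian accounting). Genotyping errors default to symmetric
  single-step dosage perturbations at rate 0.004 — chosen to mirror the
  ~99.6%-accuracy regime of a validated array — followed by missingness
  at 2%. Because a symmetric error is sometimes Mendel-consistent (a
  planted $0 \to 1$ with a heterozygous parent is legal), recovery of the
  planted rate from trio checks alone is only possible when errors are
  forced to be pedigree-visible; `error_mode = "mendel_visible"` does
  exactly that (avoiding both-parents-heterozygous markers, which admit no
  inconsistent child) and is what the calibration runs use. The symmetric
  default instead supports an exact test: observed Mendelian errors equal
  the enumerated detectable subset of the planted ones.

Everything is deterministic under a seed. What passing tests on this
generator do **not** show: behaviour on repetitive real genomes (the
uniqueness filter faces far harder inputs there), intensity-space
artefacts (OTV, cluster splitting), or realistic haplotype structure.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script were chosen so the
whole suite runs in well under a minute of compute per module: 1,000+
random 71-mers and 500-position sets against brute-force oracles, 10,000
candidates over 10 chromosomes for selection, 10,000 markers × 40
offspring for accuracy recovery, 200 samples × 150 markers for LD decay,
and 3 × 30 samples × 400 markers for clustering. Distances are integer
base pairs; $r^2$ uses pairwise-complete observations and skips
zero-variance markers; MDS refuses more dimensions than positive
eigenvalues; the PED reader orients dosage by the lexicographically later
observed allele, which means truly monomorphic markers need an explicit
allele table to round-trip (the writer accepts one).

## Limitations

The probe conversion predictor, intensity-based OTV detection, alignment-
based (mismatch-tolerant) uniqueness, haplotype phasing and LD-block
calling, and pedigree reconstruction are all out of scope. The performance
classes reproduce the platform's published categories operationally, not
its proprietary cluster-geometry rules.
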