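---
title: "Methods: testing adaptive introgression of R-genes with adintro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing adaptive introgression of R-genes with adintro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the design

Two interfertile sister species (here *Arabidopsis lyrata* and
*A. halleri*) have diverged for long enough that most loci show clear
interspecific differentiation. Disease-resistance (R-) genes are a
candidate exception: a resistance allele that works against a shared
pathogen can cross the species boundary by hybridization and be kept by
selection. The design contrasts a small panel of R-genes with a larger
panel of reference genes on three axes:

1. **diversity and polymorphism sharing** — π (synonymous, nonsynonymous,
   total), fixed vs shared polymorphisms, minimum recombination events;
2. **genealogical species sorting** — per-locus neighbor-joining trees;
   a locus is *trans*-specific when neither species is monophyletic;
3. **identical interspecific sequences** — the count of loci at which
   some sequence from species A is identical to some sequence from
   species B, compared against an isolation-with-migration (IM)
   coalescent null simulated over a grid of demographic parameters.

The package implements each axis as an independent module plus an
orchestration layer, and ships a synthetic-data generator that emulates
the study's geometry with planted, known-truth signals.

# Statistics

## Distances and diversity

All distances are Jukes–Cantor corrected,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, with *p* the raw mismatch
proportion over sites non-missing in both sequences (pairwise deletion;
`-` and `N` are treated identically as missing). π is the *unweighted*
mean of corrected distances over all unordered sequence pairs, not Nei's
frequency-weighted estimator; at these sample sizes the difference is
negligible, and the unweighted mean matches the per-pair correction that
DnaSP applies. Each pair is corrected individually (we do not correct the
mean *p*). Pairs at or beyond the correction's domain boundary
(*p* ≥ 0.75) are excluded with a warning rather than propagating
infinities; a locus where *every* pair saturates is an error.

## Synonymous and nonsynonymous site classes

π_s, π_a and the interspecific divergences Ks/Kn use Nei–Gojobori (1986)
counting: each codon contributes fractional synonymous sites equal to the
fraction of its nine single-base neighbours that preserve the amino acid
(changes to stop codons count as nonsynonymous opportunity), averaged
over the two sequences of a pair. Codons differing at 2–3 positions are
resolved by equal-weight averaging over all minimal substitution
orderings, excluding orderings that pass through a stop codon (if every
ordering is blocked — a rare corner — all orderings are used). Codon
pairs containing missing residues are skipped; an internal stop codon in
an input sequence is a hard error naming the codon. This emulates the
Ks/Kn behaviour of the standard desktop tools the field uses; the choice
of Nei–Gojobori (rather than a codon model) is a deliberate emulation
decision.

A labeling note: the study's summary table prints "nonsynonymous (π_s),
synonymous (π_a)", i.e. subscripts swapped relative to universal
convention and to its own body text. `adintro` follows the convention:
**π_s is synonymous**, π_a nonsynonymous, and output columns are labeled
explicitly so no reader has to guess.

## Recombination

*R*m is the Hudson–Kaplan (1985) four-gamete lower bound: only biallelic
sites with complete data enter; every pair of sites exhibiting all four
gametes defines an open interval that must contain a recombination
point; *R*m is the minimum number of points stabbing all intervals
(greedy scan by right endpoint, which is exact for interval stabbing and
equals the exhaustive-search oracle in tests). `Rm_per_site` divides by
the number of sites with at least two non-missing residues.

## Polymorphism partition

Per site, with the outgroup excluded: *fixed* — both species monomorphic
for different alleles; *shared* — both species polymorphic and sharing at
least two alleles; *private* — exactly one species polymorphic. Sites
where either species is entirely missing are dropped from the
denominator. Sites polymorphic in both species but sharing fewer than two
alleles fall into no category, so the category counts sum to at most the
analyzed-site count.

# Trees and the trans-specificity call

Per locus: JC distance matrix (pairwise deletion) → Saitou–Nei
neighbor joining (via `ape::nj`; negative branch lengths are clamped to
zero for display, which cannot change topology). Node support, when
requested, is the standard site bootstrap (resample columns, rebuild,
count bipartitions; 1000 replicates is the study's choice).

The call is purely topological: root on the outgroup if present in the
locus alignment, otherwise midpoint-root (the study aligned *A. thaliana*
precisely to serve as outgroup; it does not state its rooting for the
monophyly judgment, so the outgroup/midpoint rule is our documented
default). A species is monophyletic iff the smallest rooted clade
containing all its leaves contains no other leaves; a singleton species
counts as monophyletic. Trans-specific ⇔ both species non-monophyletic.
Bootstrap support is reported but never thresholded — the study states no
support cutoff.

"Identical interspecific pair" on real alignments means: equal at every
site where both sequences are non-missing *and* at least 90% of the locus
length is jointly covered (`min_overlap = 0.9`), so identity cannot be an
artifact of missing data. On simulated loci (infinite sites, no missing
data) it reduces to zero differentiating mutations.

# The isolation-with-migration null

## Model and simulation algorithm

Backwards in time: two demes of haploid size 2*N* (diploid *N*
individuals each); within-deme coalescence at rate $\binom{k}{2}/2N$ per
generation; each lineage switches demes at rate *m* per generation
(symmetric by default — the study defines its introgression rate as "the
probability of any allele being moved from one species to the other each
generation", which we read as a per-sequence rate); recombination splits
a lineage's ancestral span at rate *r* per breakable bp per generation
(full ancestral-recombination-graph bookkeeping: segments carry their
descendant sets, and a segment that reaches the whole sample is dropped —
its position has found its MRCA). At *T* generations the demes merge into
one of haploid size 2*N*_anc. Waiting times are exponential
(continuous-time competing risks; never per-generation stepping), so a
locus costs a few hundred events regardless of *N* and the full published
grid (6 rates × 2 split times × 2 sizes × 2 recombination rates × 2 gene
classes × 100 replicates) runs in about five minutes on one CPU.

Mutation is infinite-sites: Poisson along (time × ancestral material) at
μ per site per generation, each mutation recording the carrier set of the
segment it hits. Sequence identity is therefore exactly "zero
differentiating mutations". At these divergences (μ·L·T ≈ 2) finite-site
double hits are negligible, which justifies the infinite-sites emulation
of the original finite-site simulator; the original study does not state
which mutation model it configured.

Defaults mirror the study: μ = 4e-9 per site per year (the study's
purifying-selection-adjusted rate, taken as given), generation time 1
year (the study mixes per-year mutation with per-generation migration
and recombination rates, implying one-year generations), *r* ∈ {0,
4.3e-9}, *T* ∈ {0.56, 0.75} MY per branch, sample sizes 48 + 23
haploid sequences. The study's rate list prints one value twice; the six
distinct printed rates {0, 2e-8, 4e-8, 8e-8, 1e-7, 1.5e-7} form the
default grid and any further rate can be supplied in the grid config.

## Population-size units — an important resolution

`im_params()` takes **diploid** sizes (its calibration identity
P(identical | 1+1 samples, m=0, r=0) = exp(−2μLT)/(1 + 4Nμ L) is stated
and tested in diploid *N*). The published grid values {150,000; 600,000}
are, however, interpreted by `default_sim_grid()` as **gene copies**
(haploid 2N), because the original study ran fastsimcoal2, whose
population sizes are specified in gene copies. This is not a free knob:
under the diploid reading the per-locus identity probability at
(T = 0.56 MY, N = 600,000, r = 0) is 0.21 — confirmed to three decimals
by an independent simulator (msprime) at identical parameters — which
makes the simulated envelope *contain* the observed resistance count and
contradicts every printed qualitative result; under the gene-copies
reading all printed results reproduce, including the side remark that
only the deepest-split/smallest-size combination makes the reference
observation compatible with low introgression. `N_unit = "diploids"` is
available for users who mean diploid sizes.

Even under the gene-copies reading, one combination
(T = 0.56 MY, N = 600,000 copies, r = 0) sits exactly on the envelope
boundary: the true per-locus identity probability is 0.144 (both engines
agree), so P(count ≥ 4 of 10) = 0.044 and the true 97.5% quantile equals
the observed count of 4. With 100 replicates the empirical quantile flips
between 3 and 4 across seeds. The corresponding acceptance check is left
to report this honestly rather than being smoothed over; every other
combination, and the entire reference-class result, is robust.

## Envelope rule and other tests

The envelope test computes type-7 empirical quantiles at the 2.5% tails;
the decision is `excess`/`deficit` only on *strict* exceedance, so an
observation exactly at a quantile counts as consistent (the study's
phrase "not included or in the 2.5% tail" is ambiguous; ties-consistent
is the conservative reading). Fisher's exact test is two-sided by the
point-probability rule (the study does not state sidedness), computed as
a log-stable hypergeometric sum and checked against full enumeration.
The permutation test uses |difference of unweighted class means| with
10,000 label shuffles and the add-one estimator
p = (1 + #{perm ≥ obs})/(1 + n_perm); the study states neither its
statistic nor its resample count, so both are documented choices.

# The synthetic-data generator

`generate_dataset(synth_spec(), seed)` produces the "paper-shape" preset:
37 reference-like loci (513 bp, frame offset 0) and 10 resistance-like
loci (730 bp, frame offset 1 — 730 is not a codon multiple, matching
fragments that start mid-codon), 48 + 23 haplotypes per locus, one
divergent outgroup sequence per locus (≈4% divergence, emulating the
deeper outgroup split), and a truth table.

Nucleotide realization maps the simulator's infinite-sites output onto
codon-valid sequences: an ancestral sequence drawn uniformly over sense
codons, mutations assigned to distinct integer sites (order-preserving,
so linkage structure survives) with a random non-identical derived base,
and any realization creating an internal stop codon redrawn (counted and
capped). Identity/difference structure is preserved *exactly*, so the
identical-pair indicator computed on sequences equals the one computed on
mutation profiles — this is asserted in tests.

Planted events:

- **introgressed haplotype** — one donor haplotype copied into the
  recipient sample (replace or add mode), plus Poisson(μ·L·recency)
  codon-safe private mutations; recency 0 guarantees an identical
  interspecific pair, and such a locus is genuinely trans-specific too
  (the copied leaf nests inside the donor clade), which the truth table
  records.
- **balanced trans-specific polymorphism** — a divergent allele B built
  from the locus consensus (6% of sites, codon-safe), given small
  species-specific variants (1% each, so the planted allele never fakes
  an identical pair), and assigned to 40% of each species' sample. The
  resulting genealogy has two deep allelic clades each containing both
  species.

The recovery preset deliberately uses a deep split — 2 MY per branch with
N = 150,000 diploids, T/2N ≈ 6.7 coalescent units — rather than the
inference grid's shallow splits. At the grid's depths (T/2N ≈ 0.5–1.9)
incomplete lineage sorting alone produces non-monophyly and occasional
chance identical pairs, so planted-signal sensitivity/specificity would
be confounded by true background positives; a positive/negative control
dataset needs a clean background, and the deep preset provides it
(background identity probability e^(−2μLT) ≈ e^(−11.7)). This was fixed
a priori, before any recovery rate was measured. What a green recovery
test establishes is therefore that the pipeline detects planted signals
of the stated strength against a sorted background — not that it would
separate balancing selection from ILS at shallow depths, which no
topology-only method can.

The generator does **not** attempt real *Arabidopsis* base composition,
codon usage, R-gene domain structure, alignment error, or
heterozygote-phasing artifacts; conclusions about those belong to the
real-data workflow.

# Numerical and engineering choices

- Missing data: `-` and `N` are one missing class everywhere.
- Haplotype counting compares sequences verbatim (missing included), so
  partially sequenced copies are distinct haplotypes; this matches the
  diversity statistics' pairwise-deletion philosophy and is documented
  rather than hidden.
- Unique-haplotype collapsing accelerates all O(n²) pair statistics
  without changing any value (identical strings contribute identical
  terms).
- The simulator uses R's RNG (`set.seed` governs C++ draws), so every
  stage is reproducible cross-platform; `run_grid` expands a master seed
  into per-row child seeds so any grid row can be recomputed alone.
- The ARG simulator guards against runaway event counts
  (`max_events = 2e6`) and reports recombination/migration event counts
  and total tree material for calibration tests.
- Bootstrap CIs for class summaries are percentile bootstrap over loci
  (1000 resamples, seeded); the study does not state its CI construction.
- Reports embed the seed and a small deterministic fingerprint of the
  configuration (FNV-style hash) so outputs are traceable to inputs
  without extra dependencies.

# Known limitations

- The IM model has no growth, bottlenecks, additional demes, selection,
  or gene conversion; it is the study's null, not a fitted demography.
- Reference-class per-locus sample sizes in the original study live in
  supplementary material we do not consume; the documented default (48 +
  23 for both classes) slightly overstates reference-class sampling, one
  reason the envelope criterion is qualitative.
- Real data enter as pre-aligned coding-frame FASTA; no aligner or
  chromatogram processing is provided, and GenBank fetching is left to
  the user (accessions are documented in the README).
- Trans-specificity is topology-only; at shallow splits it cannot
  distinguish balancing selection from incomplete lineage sorting, and
  the package does not claim to.
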