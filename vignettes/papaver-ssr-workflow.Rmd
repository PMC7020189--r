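---
title: "EST-SSR marker development and cultivar genotyping with PapaverSSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EST-SSR marker development and cultivar genotyping with PapaverSSR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PapaverSSR)
```

## The problem

Opium poppy (*Papaver somniferum* L.) is an autogamous diploid: varieties
are pure lines stabilised by repeated self-pollination, so a cultivar
panel consists of highly homozygous, often closely related accessions.
Distinguishing such varieties — for breeding, gene-bank curation, seed
certification or forensic provenance — needs codominant, single-locus,
reproducible markers, and a quantitative account of how well a given
marker panel resolves the material. PapaverSSR implements that account
end to end: from mining candidate microsatellites out of sequence
collections, through allele calling and binning, to diversity, identity,
error-rate, transferability and multivariate analyses, plus a seeded
simulator that generates panels with exactly the structure the analyses
assume.

## Mining trinucleotide repeats

`findSSRs()` reports **maximal perfect repeats** of a fixed unit length
(default 3 bp) with at least `minRepeats` copies (default 10). The
choices behind the scanner:

* *Perfect repeats only.* Compound or interrupted repeats are not merged;
  marker design targets clean repeat tracts, and a single mismatch breaks
  slippage-based polymorphism into separately scored tracts.
* *Trinucleotide units.* Length-3 units are the workhorse class for genic
  SSRs: length variants preserve reading frame, so they survive in
  expressed sequence. Units reducible to a shorter period (AAA, CCC, …)
  are mononucleotide runs in disguise and are excluded.
* *Greedy leftmost-longest, non-overlapping.* Within one periodic
  stretch, the leftmost phase carries the most complete units; later
  overlapping candidates are absorbed. This makes output deterministic
  and matches common SSR-miner behaviour. `N` bases break runs.
* *Coordinates are 0-based half-open*, so `end - start` is exactly
  `3 * n_repeats`; FASTA ids are taken up to the first whitespace.

`mineFasta()` adds flank extraction, amplicon feasibility (repeat ≤ 300
bp and repeat plus available flanks ≥ 100 bp, the conventional
fragment-analysis design window) and deduplication. Uniqueness is **exact
string equality of the flanking sequence** at `flankLen` (default 50 bp)
on both sides: mined sequence collections contain near-identical
transcripts, and two loci with identical flanks would amplify with the
same primers. Fuzzy flank clustering was deliberately not attempted — it
buys little for marker triage and costs determinism.

## Genotype data model

`GenotypeMatrix` stores accessions × loci unordered diploid allele pairs
(S4, with validity checks). Conventions worth stating explicitly:

* **Single peak ⇒ homozygote.** Fragment analysis cannot see null
  alleles; a one-peak profile is recorded as two copies of that allele.
  Three or more peaks mean co-amplification and yield no genotype at all
  (the sample is flagged for marker QC).
* **Missing is `"0"` in files, `NA` in memory**, always in both allele
  columns; missing calls never enter frequency denominators.
* **Allele labels are nominal fragment sizes in bp**, not repeat counts —
  allelic-ladder nomenclature is size-based, and sizes are what two
  laboratories can reconcile.

`buildLadder()` turns observed sizes into ladder rungs by single-linkage
1-D clustering with a gap threshold of half the repeat step (1.5 bp for
trinucleotides); each rung's nominal size is the median of its members,
rounded to 0.01 bp. `binSize()` assigns an observed size to the nearest
rung within a tolerance (default 1.0 bp, safely below half the step so
bins cannot overlap); an exact midpoint tie goes to the lower rung
(documented, arbitrary, deterministic), and anything farther than the
tolerance from every rung returns the explicit `OFF_LADDER` sentinel —
new or artifact alleles must be examined, never auto-assigned. Binning a
nominal size returns its own label, so binning is idempotent. Two labs'
data stay as two `GenotypeMatrix` objects; binning both against the
shared ladder *is* the cross-instrument calibration, and no further size
recalibration is attempted.

## Diversity and identity statistics

Per locus and accession group, `locusSummary()` reports the allele count
*k*, observed heterozygosity *Ho* (heterozygous / typed), expected
heterozygosity $He = 1 - \sum p_i^2$ and the polymorphic information
content in the Botstein form used by the Cervus genealogy software:

$$PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2 .$$

PIC ≤ He always, with equality only in degenerate cases; both are 0 iff
*k* = 1 (property-tested on random frequency vectors).

`identityAnalysis()` compares every accession pair locus by locus; the
per-locus building block is the multiset mismatch
`2 − |intersection|` of the two unordered pairs. A pair *matches at
allowance t* when its summed mismatch is ≤ *t* over loci typed in both
members, provided at least `minSharedLoci` loci are comparable (default
10 of 17; pairs below that are reported as incomparable rather than
matched — a profile missing half its loci should not be declared
identical to anything). Match counts are monotone non-decreasing in *t*
by construction, and accessions matching no one at *t* = 0 carry unique
profiles.

`pIdentity()` gives the Hardy–Weinberg probability that two random
individuals share a multilocus genotype,
$pID = \prod_l \left( \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2 \right)$,
and the sibling variant
$pID_{sib} = \prod_l \left( 0.25 + 0.5 S_2 + 0.5 S_2^2 - 0.25 S_4 \right)$
(with $S_m = \sum_i p_i^m$). Both are exposed because cultivar panels are
anything but random-mating populations: related varieties share genome
segments, so the naive pID wildly overstates resolution and the sibling
variant is the honest lower bound. Interpreting either for bred material
requires caution — they are reported, not relied upon.

## Error rates and transferability

`errorRates()` follows the per-allele / per-locus convention of Pompanon
et al.: $e_a = m_a / 2nt$ and $e_l = m_l / nt$ over *n* genotypes typed
*t* times. The accounting decision that matters: a genotype **typed in
one dataset but missing in the other counts as a full locus error**
(`m_l += 1`, `m_a += 2`), because amplification failure is the dominant
error mode in cross-species replication and silently dropping failures
would make unreliable markers look reproducible. Genotypes missing in
both datasets are excluded from *n*. Means over loci are unweighted.
The identity $e_l/2 \le e_a \le e_l$ holds for every report.

`transferabilitySummary()` applies the conservative two-laboratory AND
rule — a marker transfers to a species only when *both* labs amplified
it — then reports per-species amplifying-marker counts and the
percentage of markers amplifying in all focal congeners, all but one, at
least two, at least one, and across genera (at least one species of
every genus in the genera map). `referenceTransferability()` packages a
count-faithful synthetic reconstruction of the published 17-marker
amplification pattern (the full marker-by-species table is not public;
the reconstruction reproduces the per-species counts 13/10/9/8/2 and the
all-congeners and cross-genera counts exactly).

`markerQC()` codifies the three marker-rejection rules for inbred
material: MULTIPEAK (≥ 3 peaks in any sample), LOW_POLYMORPHISM
(*k* < 3 in the focal group) and IMPLAUSIBLE_HET (heterozygote fraction
above 0.5 in varieties that should be near-fully homozygous — such loci
almost certainly co-amplify two loci whose fragments mimic constant
heterozygosity).

## Multivariate analysis

`encodeBinary()` produces the presence/absence allele matrix;
`diceDistance()` the Dice/Sørensen distance $1 - 2a/(2a+b+c)$, undefined
(an error, naming the accessions) only when two rows are all-absent.
`clusterAccessions()` wraps standard agglomerative linkage (single,
complete, UPGMA, WPGMA) with node heights equal to the inter-cluster
distance at each merge, so cophenetic distances are on the scale of the
input. `selectLinkage()` scores each candidate by the cophenetic
correlation CC and Mather's goodness of fit
$\delta_q = \sqrt{\sum (d^q - c^q)^2 / \sum d^{2q}}$ for
$q \in \{0.5, 1\}$, choosing the highest CC with ties broken by smaller
$\delta_1$; a residual exact tie (ultrametric input fits every linkage
perfectly) goes to UPGMA, the conventional default for allele-sharing
distances.

`bootstrapSupports()` resamples **loci** (not allele columns — columns
of one locus are strongly dependent, and resampling them would fabricate
support) with replacement, rebuilds encoding → Dice → tree per
replicate, and scores each original clade by the percentage of
replicates containing the same leaf set. Everything is seeded; the rare
replicate in which some accession loses all its presence calls (possible
only with missing data) is skipped and the denominator adjusted.

`trinaryPCA()` takes the 0 / 0.5 / 1 encoding (heterozygote alleles at
0.5, so each locus block sums to 1), column-centres **without scaling**
— allele columns are already commensurable frequencies, and scaling
would inflate rare alleles — and eigendecomposes the covariance. Score
signs are fixed by requiring each component's largest-magnitude loading
to be positive, making output reproducible across platforms.

## The synthetic generator

`simulationConfig()` fixes the study conditions the simulator emulates;
these defaults are chosen once from the biology and are not tuning
knobs:

| parameter | default | rationale |
|---|---|---|
| `nLoci` | 17 | size of the characterised marker panel |
| `alleleCounts` | published per-locus k values (10, 9, 5, …, 9; 118 total) | keeps simulated summaries on the real panel's scale |
| `alpha` | 1 | symmetric Dirichlet, uniform over the frequency simplex; produces the broad PIC spread (≈ 0.25–0.78) real panels show |
| `piHomo` | 0.71 | fraction of varieties homozygous at *all* loci in inbred poppy panels |
| `hetLociProbs` | 0.6 / 0.4 for 1 / 2 loci | residual heterozygotes carry heterozygous calls at only one or two markers |
| `nIsolinePairs` | 3 | pairs with exactly identical profiles (isolines / duplicated varieties), as a 47-accession panel produced |
| `sizeRange`, `step` | 100–300 bp, 3 bp | fragment-analysis design window, trinucleotide spacing |

Heterozygosity is modelled **at the accession level** — a minority of
accessions are heterozygous at a few loci — rather than independently
per locus under Hardy–Weinberg. This is deliberate: observed
heterozygosity in inbred panels concentrates in a few off-type
accessions, and locus-independent Ho would essentially never produce the
observed ~71 % of fully homozygous accessions. A consequence worth
knowing: simulated *Ho* is controlled by (`piHomo`, `hetLociProbs`), not
by allele frequencies.

`injectErrors()` builds replicate datasets (per-genotype failure rate,
per-allele substitution rate, drawing substitutes uniformly from the
locus's allele pool); `shiftPanel()` offsets allele pools to emulate
species divergence, which is what makes the PCA species-separation and
two-cluster bootstrap properties testable. `simulateTransferability()`
draws two-lab panels with a configurable lab-discordance probability to
exercise the AND consensus.

What the simulator does **not** emulate: electrophoretic stutter and
size-calling noise, null alleles, linkage between loci, pedigree
structure among varieties, and locus-specific mutation models. Passing
tests therefore demonstrate the correctness of the statistical machinery
under the stated model, not the field behaviour of any real marker
panel.

## Numerical and design choices, collected

* Ladder rung = median of cluster members rounded to 0.01 bp; binning
  tolerance 1.0 bp < step/2; midpoint ties to the lower rung.
* Allele pairs stored sorted with numeric-aware comparison, so multiset
  operations reduce to componentwise ones.
* Medians in summary tables are plain order statistics (`stats::median`);
  with 17 loci (odd) this is the middle value.
* Identity analysis: `minSharedLoci = 10` of 17 by default.
* Bootstrap unit = locus; replicates with undefined Dice distances are
  skipped, not imputed.
* Linkage tie-break order: CC, then $\delta_1$, then
  UPGMA > WPGMA > complete > single.
* PCA sign convention: largest-|loading| positive per component.
* Every stochastic function requires an explicit seed and is a pure
  function of (inputs, seed).

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
brute-force scanning over every (start, phase) pair for the SSR miner
(200+ random sequences up to 1 kb); all-pairs comparison for
deduplication and identity analysis (20+ accessions); exhaustive
enumeration over genotypes for PIC and pID (k ≤ 6); a naive O(n³)
UPGMA agglomerator for cophenetic distances (8 × 8 random matrices);
direct SVD for PCA. Parameter-recovery checks run at n = 500 accessions
for error injection (ε ∈ {0.01, 0.05}, 3 Monte-Carlo SE) and n = 10 000
for the homozygosity fraction (3 binomial SE). These sizes give the
property tests comfortable statistical power while keeping the default
suite fast.

## Known limitations

* Mining handles perfect repeats only; interrupted/compound SSRs are
  reported as separate tracts.
* The flank-identity dedup criterion is exact string match; paralogous
  loci with slightly diverged flanks are not collapsed.
* pID estimators assume Hardy–Weinberg and locus independence; both are
  violated in cultivar panels, which is why identity analysis (direct
  pairwise comparison) is the primary resolution statistic.
* The reference transferability pattern is a reconstruction from
  published counts, not the original table; per-marker assignments
  beyond the constrained ones are arbitrary within those counts.
* The published summary rows for Ho and PIC are not recomputable from
  their own per-locus columns (the printed k columns are, and are the
  ones asserted); this package reproduces the k-column arithmetic and
  treats the printed Ho/PIC summary rows as unverifiable.
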