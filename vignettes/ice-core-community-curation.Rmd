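---
title: "Curating ice-core sequence surveys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating ice-core sequence surveys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryocurate)
```

## The problem

Deep ice cores — glacial ice, deformed basal ice at the glacier/bedrock
interface, and accretion ice frozen onto the underside of a glacier from
subglacial lake water — carry minute, heavily multiplexed nucleic-acid
loads. A typical survey amplifies DNA and cDNA with sample-specific
multiplex identifiers (MIDs), sequences everything in a pooled run, matches
reads against a nucleotide database, and then relies on an exacting chain
of in-silico curation before any ecological statement can be made: reads
must be demultiplexed and stripped of adapter decoration, weak matches
discarded, anything shared with a sterile-water control removed, duplicate
database identifiers collapsed, and read frequencies tallied. The biology
sits at the very end of that chain: habitat-source and physiology tallies
per sample, diversity indices, cross-sample overlap, and a regression of
species counts on geochemistry.

`cryocurate` implements that chain as composable, tested R functions, with
a seeded synthetic-community generator standing in for deposited reads so
that every stage can be validated against planted ground truth.

## The read model and demultiplexing

Each simulated read is `ADAPTER + MID + LINKER + insert`: a 30-nt
sequencing-platform A-adapter, a sample-specific 10-mer MID, the 19-nt
EcoRI/NotI linker used during library construction, and an insert excised
from the source taxon's reference sequence. The packaged manifest
(`vostok_mid_manifest()`) carries the five MIDs of the Lake Vostok survey
design: four ice-core samples and a sterile-water control.

Demultiplexing (`assign_by_mid()`) scans the first 45 bases of each read
for each MID, tolerating `max_mismatch` substitutions (default 0). Two
rules matter:

* **Best, unique match wins.** A read matched by two MIDs at the same
  mismatch level goes to `unassigned`. Given that a single cross-assigned
  read becomes a spurious "shared taxon" in downstream overlap counts, we
  prefer losing a read to mislabelling it.
* **The window is generous.** 45 bases admits the 30-nt platform adapter
  plus drift, but stops the MID being found deep inside an insert.

Clipping (`clip_decoration()`) removes everything through the matched MID
(and the linker when it directly follows), then truncates at any 3'
occurrence of the linker or P1 adapter on either strand. The retained bases
are always a contiguous substring of the input — clipping can never
fabricate sequence. Reads clipped to nothing are routed to a discard list;
reads shorter than 50 bp after clipping are dropped (`filter_min_length()`,
boundary inclusive: a 50-bp read survives).

The generator's insert lengths are uniform on [50, 1000] bp by default.
The lower bound sits exactly on the length-filter boundary on purpose;
tests that need to see discards (and the boundary behaviour) draw from
ranges extending below 50.

The error model is substitution-only, applied uniformly at a configurable
per-base rate (default 0). Indels, chimeras, homopolymer artifacts and
quality-score structure are deliberately out of scope: substitutions are
sufficient to exercise identity thresholds and mismatch-tolerant MID
matching, which is all the curation chain is sensitive to. Consequently, a
green test suite says nothing about adapter-discovery or
quality-trimming behaviour on real instrument output — those steps are
upstream of this package's contract. An optional mean-quality filter exists
nowhere in the default path for the same reason: the input contract is
"high-quality reads".

## Hit curation

Hit tables are the 11-field comma-separated tabular layout
(`qseqid sacc sgi length sstart send pident evalue staxid sskingdom
ssciname`), headerless, with no embedded commas in the scientific name.
The curation order is fixed and enforced by `curate_profile()`:

1. **Thresholds** (`apply_thresholds()`): keep `pident >= 97` (inclusive)
   and `evalue < 1e-6` (strict). The asymmetry is deliberate and encoded
   exactly as the conventions are usually printed; both cutoffs are
   parameters.
2. **Control subtraction** (`subtract_control()`): any GI present in the
   negative control at >= 97% identity is removed from the sample wholesale.
   The sample-side identity is not re-examined — membership is keyed on the
   GI alone, which is the most conservative literal reading of
   control-based decontamination.
3. **Read enumeration** (`enumerate_reads()`): distinct query reads per
   accession (or GI, or scientific name). A read with several HSP rows
   against one subject counts once; the alternative silently double-counts
   fragmented alignments.
4. **Best-hit deduplication** (`dedupe_best_hit()`): one row per GI —
   lowest e-value, then highest identity, then longest alignment, then
   first-seen. The two leading keys are the field convention; the trailing
   two are ours, chosen purely so the operation is deterministic and
   idempotent on any input.

The curation report exposes the **no-hit fraction**,
`1 − (reads with any hit) / (reads searched)`, computed on the raw hit
table before thresholding (surveys of deep-ice samples report roughly a
third of reads returning nothing; the synthetic generator plants that rate
by default). Whether such a fraction "should" be computed before or after
decontamination is unresolvable from convention alone; computing it before
makes it a property of the search, not of the control, which is the more
interpretable quantity.

Molecule classes (rRNA / mRNA / other) come from a declarative accession →
class map; unknown accessions fall back to `other` with a warning rather
than an error, because decoy accessions are expected in real searches.

## Trait annotation

The literature lookup that normally assigns ecology to species is replaced
by a declarative TSV (one row per species; set-valued cells comma-joined).
Joins are by exact scientific name — species/strain exclusivity means no
genus-level fallback — and are total: taxa without entries stay in the
profile unlabelled. Entries flagged `ambiguous` keep their taxon in the
profile (it still counts toward domain/phylum breakdowns) but contribute to
no source or physiology tally.

Category tallies use **set semantics**: a taxon isolated from both marine
and freshwater sources increments both categories. The alternative
(forcing one label per taxon) discards exactly the information the
figures-by-category are meant to show; the package flags this as a
convention the user should know when comparing against single-label
tallies.

The process-by-group capability matrix (`build_metabolic_matrix()`) maps
phyla to the standard short codes (Ac, αP, Ar, As, Ba, Bd, βP, Cb, Ch, Cy,
DT, δP, εP, Fi, γP, Pl — extended with Ad for Acidobacteria, which carbon
fixation capability sets require) and renders undetected cells as `"nd"`.
The packaged reference matrix (`reference_metabolic_matrix()`) is a
transcription of the published capability sets for Lake Vostok basal and
accretion ice; cells whose printed content is a free-text marker ("many",
"other heterotrophs") rather than a code set are carried verbatim but
excluded from code-level comparisons. The carbon-fixation block of the
printed table collapses four pathways into one physical row; the
transcription separates them (reductive PP, reductive TCA, reductive
acetyl-CoA, 3-hydroxypropionate), assigning each sub-cell by the
accompanying text's description of which groups carry which pathway.

## Diversity and overlap

`shannon_weaver()` computes `H = −Σ p_i ln p_i` over read counts and
evenness `H / ln S`. The natural log is the default; the base is exposed
because published values do not always state theirs, and evenness is
base-invariant so the choice only rescales `H`. All components (`H`,
`S`, total reads, base) are reported so any convention can be reproduced
downstream. One-taxon communities get `H = 0` and an **undefined** (not
zero) evenness — zero would wrongly suggest maximal unevenness.

`taxon_overlap()` computes, over unique taxon keys, the sample-exclusive
counts, all pairwise intersection sizes, and the exhaustive disjoint-region
counts (every nonempty sample subset), which always sum to the union size.
Accession keys are the default; scientific-name keys are available since
"same organism" is often the intended equivalence.

## The count–geochemistry model

Species counts per habitat category and depth are overdispersed; the
package fits

\[
y \sim \mathrm{NB}_2(\mu, \theta), \qquad
\log \mu = \beta_0 + \textstyle\sum_i \beta_i z_i + u_{\mathrm{habitat}},
\qquad u \sim N(0, \sigma_u^2)
\]

with NB2 variance `μ + μ²/θ` (the standard parameterization for ecological
counts), habitat as a random intercept (habitats are repeatedly sampled
across depths), Laplace approximation of the marginal likelihood (via
glmmTMB), and Wald two-tailed p-values at α = 0.05. Covariates — Na⁺, K⁺,
Ca²⁺, Mg²⁺, Cl⁻, SO₄²⁻ in µmol/L; NPOC and total amino acids in mol/L —
span five orders of magnitude, so they are z-scored internally;
coefficients are reported both per standard deviation (`estimate`) and per
original unit (`estimate_raw`). The synthetic generator applies its betas
on the standardized scale for the same reason: an effect of 0.5 means "0.5
log-units per covariate SD" regardless of units.

Boundary behaviour: when the random-intercept variance is truly zero the
mixed fit reduces to a plain NB regression (verified against
`MASS::glm.nb` to 1e-3 relative in the tests); single-habitat data trigger
an automatic fixed-effects-only fallback with a warning; non-convergence
returns an explicit failed-fit object carrying the optimizer diagnostics,
never silent coefficients.

The directional claims this layer can support on synthetic data are
structural only — a generator with positive β yields positive fitted signs
with calibrated error rates. Reproducing any published coefficient would
require the original covariate and count tables, which are external.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately desk-sized
scales, chosen as the smallest sizes at which each check is decisive:
10,000 reads for demultiplexing fidelity (binary outcomes, no sampling
noise), 100 random communities for decontamination (set-equality, exact),
1,000 random tables for deduplication against brute force (exact), and 200
replicates of n = 600 for the regression calibration — at which the
binomial standard error on a 5% rejection rate is ±1.5%, comfortably
inside the accepted [1%, 10%] band, and the power check (standardized
β = 0.5) is essentially saturated. Stochastic tests fix their seeds; a 3-SD
binomial/multinomial band is used wherever a sampled proportion is compared
with its target.

All randomness passes through a single integer seed per generator call;
sub-seeds for references, reads, hit tables, traits and geochemistry are
derived arithmetically from it (kept within 32-bit range), so a
`community_spec` plus its seed reproduces every byte of every output. The
pipeline writes no timestamps or environment data into its outputs for the
same reason: identical config and inputs give byte-identical runs.

## Known limitations

* The generator does not emulate indels, chimeras, strand-flipped MIDs,
  quality degradation, or real database identifiers; conclusions about
  those failure modes cannot be drawn from its tests.
* Control subtraction keys on GI identity only. Contamination that appears
  in the control under a *different* database record than in the sample is
  not removed — a real limitation of GI-keyed decontamination itself, not
  just of this implementation.
* The trait layer is only as good as its TSV: it validates vocabulary and
  uniqueness, not biology.
* `prepare_association_table()` builds one row per (habitat × depth) from
  unique-taxon tallies; other units of analysis (e.g. per-phylum counts)
  require assembling the table yourself, which `fit_count_association()`
  accepts unchanged.
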