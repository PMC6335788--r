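---
title: "Characterizing a bZIP transcription-factor family with bzipkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a bZIP transcription-factor family with bzipkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzipkit)
```

## The biological model

Basic leucine zipper (bZIP) transcription factors carry a compact,
two-part DNA-binding module: a highly conserved **basic region** of 16
residues that contacts DNA, a short **hinge**, and a **leucine zipper**
of heptad repeats that mediates homo- and heterodimerization. The basic
region carries an invariant motif, an asparagine followed seven residues
later by an arginine or lysine (N-x7-R/K), and the first zipper leucine
sits exactly nine residues C-terminal of that R/K.

bzipkit fixes a single position convention for the whole package (there
is no position 0):

* basic region: domain positions −25..−10 (16 residues), with the
  invariant Asn at **−18** and R/K at **−10**;
* hinge: −9..−1 (9 residues);
* zipper: +1 onward, leucines expected at +1, +8, +15, ...

With a 1-based anchor index `a` for the Asn, the −10 residue is at
`a + 8` and the first zipper residue at `a + 18`. This is the only
arithmetic consistent with all of the positions the convention names
(−18, −10, a hinge intron at −5, a basic intron at −20, and the
nine-residue offset between R/K and the first leucine).

## Domain scanning

`scan_domain()` reports every index satisfying the motif: `N` at the
anchor, `R`/`K` at +8 (optionally `I` under `relaxed = TRUE`, admitting
the rare binding-incompetent isoleucine substitution), `L` at +18, and at
least `min_heptads − 1` further leucines spaced seven apart. Defaults:
`min_heptads = 2` (a single leucine is not evidence of a zipper),
`max_heptads = 8` (the motif itself does not delimit the zipper's
C-terminal end, so the reported span is capped at a configurable eight
heptads). `X` never matches a motif position — conservative matching.
All hits are reported in N-terminal order; downstream helpers default to
the first when one domain per protein is assumed.
`classify_binding_variant()` is total over all residue pairs:
`canonical_R` (N/R), `variant_K` (N/K), `variant_I` (any/−10 = I), else
`noncanonical`.

## Intron phases and the a–d patterns

`build_cds_map()` produces the bijection between CDS nucleotides and
genomic positions (minus-strand exons are walked high-to-low), and
`locate_introns()` computes each intron's CDS offset and splicing phase
`offset mod 3` — P0 between codons, P1 after the first nucleotide, P2
after the second. Phase attributes present in a GFF3 are ignored and
recomputed from exon lengths, so a file's self-description can never
contradict the analysis.

Intron position labelling follows one rule: a P0 intron between codon *p*
and codon *p+1* is labelled *p* (the N-terminal residue); P1/P2 introns
are labelled with the residue whose codon they interrupt. Within the
domain window, four configurations of basic+hinge introns are
distinguished by `classify_pattern()`:

* **a** — one P0 intron at hinge −5;
* **b** — two P0 introns, one basic, one hinge;
* **c** — one P2 intron at basic −20;
* **d** — no intron in the window.

Pattern *a* requires phase 0 because a junction "between two amino
acids" is by definition inter-codon. Matching is strict, with an
explicit `other` class rather than forcing a label: real gene families
are not guaranteed to exhaust the four canonical classes, and a count of
`other` genes is itself a result.

## Heptad registers and dimerization statistics

`assign_register()` anchors the first zipper residue (+1, a leucine in
canonical domains) at slot **d** of heptad 1 and continues cyclically
(`e f g a b c d ...`); heptad 1's a–c slots are absent by construction
and a trailing partial heptad keeps its slots. The anchor choice is the
conventional one — leucines define d positions — but it is exposed as
`register_offset` because conventions for numbering the first heptad
differ between curated alignments; when reproducing an externally
curated register table (`read_heptad_alignment()`), that table's own
annotation is authoritative.

Three statistics summarize dimerization properties:

* `composition_by_position()` — residue frequencies at the interface
  slots a, d, e, g, pooled over all heptads of all proteins (`X` and
  absent slots excluded from denominators). Residue-pooled frequencies
  are used rather than per-protein majorities; the latter can be
  recovered from the returned denominators if wanted.
* `asn_a_by_heptad()` — per-heptad percentage of asparagine at `a`,
  computed on exact integer counts and rounded to two decimals only for
  reporting.
* `classify_ge_pairs()` / `aggregate_ge()` — the g residue of heptad *n*
  against the e residue of heptad *n+1* of the *same* sequence, a
  homodimer self-pairing proxy (per-protein pair statistics cannot see a
  partner helix; this is the standard surrogate in bZIP surveys).
  Charge classes use basic = {R, K} and acidic = {D, E}; histidine is
  treated as uncharged. Frequencies default to per-heptad denominators
  (`per_heptad = FALSE` pools all pairs), since per-heptad
  concentration of attractive pairs is the quantity of interest.

## Duplication and molecular evolution

`find_tandem_clusters()` grows clusters greedily left-to-right within a
chromosome: the next gene joins if it is similar (e-value strictly below
`1e-20`) to at least one current member and at most one non-member
intervenes. The one-gene tolerance is applied **per gap** by default —
the most literal reading of "one unrelated gene among cluster members
was tolerated" — with `per_cluster = TRUE` for the stricter total
budget. Clusters never span chromosomes and only maximal clusters are
returned; the output is invariant to edge-list order.

`kaks_ng86()` implements Nei–Gojobori (1986) counting with Jukes–Cantor
correction. Site counting uses, at each codon position, the fraction of
synonymous changes among non-stop single-nucleotide changes, so that
S + N = 3 × codons exactly — an invariant the test suite checks
pair-by-pair. Codons differing at two or three positions are resolved by
averaging over all substitution orderings with equal weight, skipping
orderings that pass through a stop codon (with an all-orderings fallback
should every ordering be blocked). Saturation (`p ≥ 3/4`) yields `NA`
with a flag rather than a number. A deliberately simple, fully specified
estimator was preferred over maximum-likelihood codon models
(YN00-style): every quantity it produces can be verified against an
exhaustive enumeration oracle to 1e−12, and the downstream uses — a
Ka/Ks < 0.5 purifying-selection census (`purifying_summary()`, strict
`<`) and a binned Ks distribution — do not require transition/
transversion or codon-frequency corrections. Ks values from different
estimators differ mildly in absolute scale, which is a documented
limitation when comparing against results computed with other tools.

`ks_histogram()` bins half-open `[k·0.05, (k+1)·0.05)` with the default
0.05 width; the peak is the maximal bin, ties broken toward the lower
bin, and `ks_local_maxima()` exposes multi-modal structure (ortholog
vs whole-genome-duplication modes).

## Expression profiles and qPCR

Three-stage seed FPKM profiles (20/40/60 days after flowering) are
classified by `classify_profile()`: `not_expressed` when all stages are
below a floor of 1 FPKM; group **I** when DAF20 is at least 2-fold above
both later stages; **II** when DAF40 is 2-fold above its flanks; **III**
when DAF40 is 2-fold below its flanks; **IV** otherwise (expressed
without such a pivot, including high-and-flat profiles). Verbal
descriptions of such groups never pin down thresholds; the floor/fold
rule is this package's explicit operationalization, both parameters are
arguments, and any result sensitive to them should be reported together
with the values used. The label priority (not_expressed, then I, II,
III) only matters on measure-zero boundary triples.

`relative_expression_ddct()` implements 2^−ΔΔCt with an internal
control gene: per-replicate ΔCt, ΔΔCt as difference of condition means,
fold = 2^−ΔΔCt, SE over per-replicate folds, and a two-sided t test on
the ΔCt values — not on folds, because ΔCt is the approximately normal
scale. Student's equal-variance test is the default to match the named
method; `welch = TRUE` switches. `de_time_course_summary()` counts
significant up/down genes per time point without multiple-testing
correction by default (matching per-gene qPCR practice), with any
`p.adjust` method available via `adjust = "BH"` etc. Constant-replicate
degenerate cells return `NA` p-values rather than an error.

## The synthetic-data generators

Every stage is testable against planted truth without genome downloads:

* `make_domain_protein()` assembles flank + basic(16) + hinge(9) +
  zipper + flank. Random content (via `random_domain_spec()`) excludes
  asparagine outside the planted anchor, so recovery tests can assert
  *exactly one* hit — flanks are motif-free by construction.
* `make_gene_model()` reverse-translates with a seeded uniform codon
  choice (codon identity only matters where divergence is controlled
  explicitly), cuts the CDS at planted positions/phases, and inserts
  random introns of 60–200 nt with canonical `GT..AG` ends — phase
  arithmetic depends only on exon lengths, so intron content is
  unconstrained. The concatenated exons always retranslate to the input
  protein.
* `evolve_pair()` plants Poisson numbers of synonymous and
  nonsynonymous events (half per lineage) drawn uniformly over the
  currently available changes of each class, rejecting stops. Repeated
  hits are allowed; the Jukes–Cantor correction in the estimator is what
  undoes them, which is exactly the property the recovery tests probe.
* `make_gene_order_table()` plants within-cluster e-values strictly
  below 1e−20 and background e-values at or above it.
* `make_expression_data()` uses multiplicative log-normal noise with a
  configured CV (mean-preserving), group means at `base_fpkm` and
  `fold × base_fpkm` (default fold 5 — comfortably above the 2-fold
  classification rule, as planted effects in a recovery experiment
  should be), silent genes at 0.1 FPKM; Ct tables use a control gene at
  Ct ≈ 20, baseline ΔCt 5, and replicate noise SD 0.15 cycles, typical
  of technical qPCR spread.

All generators route randomness through a seed and restore the caller's
RNG state, so outputs are byte-identical per seed.

What the generators deliberately do **not** emulate: genomic background
(the proteins outside the planted domain are uniform random, not
homologous families), alignment error (Ka/Ks inputs are gap-free and
codon-aligned by construction), compositional bias and selection
heterogeneity along the sequence, RNA-seq count noise (FPKM noise is
log-normal, not negative-binomial), or amplification failure in qPCR.
Passing recovery tests therefore demonstrates correctness of the
computations under their stated assumptions, not robustness to real
annotation or alignment artefacts.

## Problem sizes and determinism

The shipped verification cohorts are 1000 proteins for domain-scan
recovery, 500 gene models for phase/pattern recovery, 60 zippers with
exact planted compositions, the full 61 × 61 sense-codon grid against
the enumeration oracle, divergence recovery on 10,000 codons over 10
seeds (±10% on planted dS = 0.3; ±15% at the deeper dS = 0.9 regime),
1000 random gene-order tables for cluster invariants, and a
1200-gene null qPCR simulation whose type-I error is checked against
α = 0.05 within binomial error. These sizes give sampling error well
inside the asserted tolerances while keeping the whole suite fast on a
single CPU.

## Known limitations

* The scanner is a motif scanner, not a profile HMM: it will not find
  genuinely degenerate domains that family-level HMMs recover, and it
  deliberately reports nothing when the invariant residues are absent.
* The zipper's C-terminal end is capped, not inferred; coiled-coil
  probability scoring is out of scope.
* NG86/JC Ks values are not numerically interchangeable with
  ML-estimator Ks values at high divergence.
* Collinearity (segmental/WGD block) detection is out of scope;
  duplicated pairs are accepted as externally computed lists, as is
  standard with dedicated collinearity tools.
* Group I–IV profile membership depends on the floor/fold
  operationalization; there is no ground truth for the thresholds in
  verbal group descriptions.

## A worked mini-pipeline

```{r example, eval = FALSE}
spec <- random_domain_spec(seed = 42, max_flank = 40)
prot <- make_domain_protein(spec, id = "demo")
ann <- scan_domain(prot$sequence, id = "demo")
gm <- make_gene_model(prot$sequence, intron_plan(-5, 0), seed = 1,
                      annotation = ann)
introns <- annotate_domain_positions(locate_introns(gm$model), ann)
classify_pattern(introns)                       # "a"
reg <- assign_register(ann, prot$sequence)
aggregate_ge(reg)
pair <- evolve_pair(gm$cds, target_dS = 0.3, target_dN = 0.05, seed = 2)
kaks_ng86(pair$cds_a, pair$cds_b)
```
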