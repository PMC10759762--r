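---
title: "Identifying reciprocal natural hybrids from karyotypes and plastomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying reciprocal natural hybrids from karyotypes and plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyohybrid)
```

## The inference problem

When two plant species with distinct karyotypes hybridize in the wild, the
F1 carries a diagnostic signature on two independent genomes. On the
nuclear side, regular meiosis gives each gamete one chromosome of every
homolog pair, so the hybrid complement should be the *union of one balanced
gamete from each parent*: per centromere-type counts halved and summed. On
the organellar side, the chloroplast genome is transmitted (in most
angiosperms) only by the seed parent, so the hybrid's plastome identifies
the maternal species. Together these resolve not just *whether* two taxa
are the parents but *which direction* the cross went — and reciprocal
hybrids (the same pair crossed both ways) show the same nuclear complement
with different plastomes. `karyohybrid` implements both evidence chains and
their combination, plus a seeded simulator so the whole pipeline is
testable without external sequence data.

## Karyotype statistics

Arm measurements arrive as one row per chromosome per metaphase cell
(`taxon`, `cell`, `chrom`, `short_um`, `long_um`, µm). Measurements with
short arm recorded longer than the long arm are auto-swapped with a
warning. Centromere classes follow the conventional arm-ratio (long/short)
bands: `T` terminal point (no short arm, ratio infinite), `t` > 7.00, `st`
3.01–7.00, `sm` 1.71–3.00, `m` 1.01–1.70, `M` median point (ratio 1.00).
Two numerical choices matter here:

* band edges are applied at two-decimal precision (`M` up to 1.005, the
  `sm`/`st` cut at 3.005, `st` inclusive of 7.00, `t` strictly above), so
  ratios that would print inside a band classify into it;
* the `sm` band is not used by the reference taxa but kept so the
  classifier is total; hitting it warns rather than errs.

Aggregation across cells averages arms position-wise, keyed by the
chromosome index when all cells share one index set (the layout of
published per-chromosome tables), falling back to (type, length-rank)
alignment otherwise. Complement statistics are then: TCL, the mean over
cells of half the summed complement length (µm); L/S, the mean
longest/shortest ratio; A2, the coefficient of variation (sample sd over
mean) of the averaged chromosome lengths; and A1 = 1 − mean(b/B) over
homolog pairs, where pairs are formed within type by descending length and
`b/B` is 0 for T pairs. A hybrid complement with odd per-type counts has no
true homolog pairs, so A1 falls back to averaging short/long over
individual chromosomes — identical to the pair version whenever homologs
are near-copies. The Stebbins class combines the proportion of arm ratios
above 2 (digit: 0 → 1; ≤ 0.5 → 2; < 1 → 3; 1 → 4) with the L/S ratio
(letter: < 2 → A; [2, 4] → B; > 4 → C); boundary placement (B closed on
both sides) is fixed by published typings with L/S 2.45 → B and 4.31 → C.

## The additivity model

`balanced_gamete()` halves per-type counts and refuses odd ones — only
euploid, reduced gametes are modelled, because the argument the test
formalizes uses strict halving; aneuploid or unreduced gametes would need a
different model. `predict_f1()` sums two gametes (commutative, conserves
(2nₐ + 2n_b)/2); `additivity_test()` compares an observed complement per
type and is consistent exactly when all residuals vanish. Type classes are
matched exactly (`m` ≠ `sm`) since the argument operates at type-count
resolution. `screen_parent_pairs()` evaluates every unordered pair
(including self-pairs) of a candidate panel; karyotype additivity cannot
orient a cross, so orientation is left to the plastome evidence.

## Plastome structure

`detect_inverted_repeat()` finds the maximal pair of disjoint exact
reverse-complement repeats: 25-mer seeds shared between the sequence and
its reverse complement group on anti-diagonals (i + partner-end constant),
and each candidate diagonal is scanned base-wise for its longest run.
Circularity is handled by retrying at four origin rotations — the origin
cannot fall inside both IR copies at all four offsets for IRs shorter than
a quarter genome. IRs are required to be *exact* repeats: plastome IR
copies are homogenized in real genomes, and exactness keeps the planted
ground truth sharp. The longer single-copy gap is the LSC; coordinates are
rotated so it starts at base 1, and IRb is the copy that follows it.
Strand orientation is canonicalized so that an annotated *rps19* copy
straddles (or failing that, is nearest to) the LSC–IRb junction, matching
the conventional junction layout; without features the lexicographically
smaller strand is chosen. All coordinates are 1-based closed (GenBank
convention), and features — including `join()` multi-part genes — are
remapped through the same rotation/flip.

`junction_genes()` reports, per junction, the gene copy spanning it with
base counts on each side (a gene ending exactly on the border counts as
spanning with a zero side), or otherwise the nearest gene on each side
within a 1000 bp window with its distance. Gene *copies* are tracked by
feature entry, not by name, because IR genes such as *rps19* legitimately
occur twice.

## Plastome variation

`call_variants()` assumes near-identical, collinear genomes in a common
rotation (run structure detection first; the pipeline does). Anchors are
31-mers unique in both sequences; the longest chain increasing in both
coordinates forms exact-match blocks, and inter-block segments are aligned
globally (match +1, mismatch −1, `N` scored 0, gap of length L costing
3 + L). Two normalization details make shared-site counting well-defined:
indels are left-aligned against the reference with insertions anchored to
the base they follow, and adjacent blocks that overlap after an indel in
repetitive context are trimmed before segment extraction. Edits closer
than about 2k bp may merge into one gap segment; at the divergence levels
this workflow targets (on the order of 150 substitutions across a 158 kb
plastome) that limitation is immaterial, and the simulator spaces its
edits accordingly. `shared_snp_sites()` counts substitutions identical in
(position, reference allele, alternate allele); `maternal_assignment()`
ranks candidates by that count with the symmetric difference of full
variant sets as tie-break, and the margin between the top two is the
discriminability measure. Confidence in `infer_cross()` is the boolean
"karyotype additive AND margin positive" — deliberately not a probability,
as no statistical model of shared-site counts is attempted.

The SSR scanner reports maximal perfect tandem repeats of primitive 1–6 bp
motifs meeting per-unit minimum repeat counts, defaulting to 10/5/4/3/3/3
with a 100 bp compound gap — thresholds chosen to admit the mononucleotide
(A)₁₀ and pentanucleotide (GGAAA)₃ loci typical of published plastome
catalogues, and fully configurable because scanner settings vary between
studies. Motifs are reported as observed rather than cycle-canonicalized,
matching how catalogue entries are printed.

## Phenetics

Trait matrices are standardized per column (z-scores with the n−1 standard
deviation; constant columns map to zero with a warning). The default
distance is the *average Euclidean* distance, the root-mean-square trait
difference `sqrt(mean((xᵢ − xⱼ)²))`; plain Euclidean is available behind a
flag because a printed dissimilarity range alone cannot fix the scaling
convention. UPGMA uses average linkage with node heights at half the merge
distance, giving an ultrametric tree; the implementation rides on
`stats::hclust`, and the test suite checks it against an independent naive
O(n³) implementation. Flower-colour variables are accepted as
user-supplied numeric encodings (ordinal stage scores in the bundled
fixture); no claim is made to reproduce any particular colorimetric
encoding, which is why absolute dissimilarity values from the fixture are
not comparable to published ones — only the clustering structure is.

## The synthetic generator

The generator mirrors the statistical structure the analyses assume, at
sizes that keep the full pipeline in seconds:

* **Karyotypes** — per-homolog-pair target arms with pair totals spaced
  geometrically to hit a target L/S ratio and TCL; per-cell measurements
  are targets times independent log-normal noise (multiplicative, because
  cytological measurement error scales with length), default CV 0.05 over
  5 cells, the usual minimum cell count for published karyotypes. Arm-ratio
  targets sit inside their classification bands (t 8–12, st 3.5–6.5,
  m 1.05–1.55) so noiseless data invert exactly; under default noise a
  band-edge chromosome still misclassifies occasionally (a few per
  thousand), which is why formula recovery is asserted as ≥ 99 % of
  chromosomes rather than per-run exactness.
* **Plastomes** — random sequence per region assembled as LSC + IRb + SSC +
  revcomp(IRb), default 3000/1000/800 bp (~5.8 kb; a `lycoris` preset uses
  86597/26733/18342 bp for stress tests). Junction gene stubs reproduce the
  conventional layout (rps19 176/34 bp across LSC–IRb, ndhF 107 bp into the
  IRb, ycf1 41 bp into the IRa, psbA 86 bp into the LSC, an rps19 copy
  ending 3 bp before the IRa–LSC border), SSR plants get repeat-breaking
  flanks, and single-copy termini are fixed so the planted IR is exactly
  maximal.
* **Trios** — both parents derive from a shared reference (12 substitutions
  + 2 indels each, scaled from ~150 SNPs per 158 kb to the reduced genome)
  and the hybrid from the designated maternal parent (3 + 1 private edits),
  with edits confined to single-copy interiors ≥ 100 bp apart so IRs stay
  exact and every edit is recoverable.

What the simulator does *not* emulate: chromosome-level measurement biases
(condensation gradients, rosette artefacts), IR boundary shifts between
taxa, heteroplasmy or paternal plastome leakage, and SSR mutation models —
so passing tests demonstrate correctness of the inference machinery under
its stated assumptions, not robustness to those real-data effects.

## Problem sizes and determinism

All stochastic tests fix seeds. The suite exercises: the printed parental
and hybrid formulas; 100-seed planted-IR recovery and 50-seed
planted-variant recovery at the reduced plastome scale; SSR-scanner
equivalence with a brute-force oracle on 100 random 2 kb strings; UPGMA
oracle equivalence for up to six taxa; and 100 seeded maternal-trio
pipelines covering both reciprocal directions. These sizes were chosen so
the whole suite runs in a few minutes on one core while still giving each
property enough random instances to be meaningful.

## Known limitations

* Additivity is tested at type-count resolution; structural rearrangements
  preserving type counts are invisible to it.
* The variant caller is for near-identical collinear genomes only — it
  refuses (with an informative error) inputs without enough shared unique
  anchors, and it is not a substitute for read-based genotyping.
* Maternal inheritance is assumed strict; a leaky or biparental system
  would need the margin to be interpreted differently.
* IR detection requires exact repeat copies; genomes with diverged IRs
  need the mismatch-free assumption relaxed upstream.
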