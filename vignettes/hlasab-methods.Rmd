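---
title: "Methods: models, cutoffs and design choices in hlasab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, cutoffs and design choices in hlasab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlasab)
```

This vignette records how each stage of the pipeline is defined, which
parameters matter, and where the design was genuinely open — so that a
maintainer can tell a convention from a constraint.

## Normalization and positivity

The raw readout per bead is a trimmed-mean fluorescence (MFI). Normalized
MFI subtracts three backgrounds in sequence: the buffer-only (PBS) reading,
the negative-control (NC) bead reading, and the mean of the negative-sera
means supplied with the two vendors' kits:

$$\mathrm{MFI}_{norm} = ((\mathrm{trim} - \mathrm{PBS}) - \mathrm{NC}) -
\tfrac{1}{2}(\mathrm{NGS}_{LS} + \mathrm{NGS}_{LC}).$$

The formula is applied literally; whether the NC term was itself
PBS-corrected upstream is not knowable from the data files, so no further
adjustment is attempted. Negative values are retained (clamping would
destroy the linearity property that tests rely on). Corrections are
per-bead when a per-bead controls table is available, scalar otherwise.

**Positivity cutoff: 500 MFI at 1/10 serum dilution, at-or-above.** Source
material for this kind of assay mixes "above 500" and "at or above 500"
phrasings; the package standardizes on `>= 500` everywhere because the
unacceptable-antigen listing rule — the operative downstream consumer — is
an at-or-above rule. The same convention applies to the variant cutoff
(1000) and the "strong reaction" cutoff (1000) in group classification.

## Conformational-variant classification

Three monoclonal antibodies dissect the class I antigen's state on a bead:
W6/32 requires the intact HC–β2M–peptide trimer, HC-10 binds peptide-free
β2M-associated heavy chain, TFL-006 binds β2M-free heavy chain. A flag is
set when the corresponding normalized MFI is `>= 1000`. A missing reading
yields an *unknown* (`NA`) flag, never `FALSE`: the bundled
characterisation table carries only the TFL-006 columns, so intact and
peptide-free flags are exercisable only on synthetic data, and the bundled
fixture must not silently report "no intact antigen" for beads that were
simply not assayed. An `N/A` cell in the bundled table means the allele is
absent from that vendor's panel, not that binding was zero.

### Fixture conflicts, kept verbatim

The two bundled tables disagree in places: B\*82:01 and B\*82:02 appear
with swapped vendor membership between the characterisation table and the
vendor-unique lists, B\*15:11 is present in one and absent from the other,
and one DP bead label appears in both vendors' "unique" columns. The
fixtures store both tables exactly as printed and the package never
"fixes" them: panel membership (hence the 28/43/13 common counts) is
always derived from the characterisation table's presence/absence, and the
12/12 and 34/34 unique counts from the unique lists, which reproduces all
printed totals either way.

## Common-antigen restriction and concordance

All cross-vendor comparisons are restricted to beads carrying identical
antigen content (`common_alleles()`), since a count difference on
vendor-unique beads is uninterpretable. Per serum the four conditions
(LS/LC × FcMonoIgG/IgHPolyFab) are held in a `condition_quartet`.

**Reactivity groups.** The published description of groups 1A–2C is a
pattern language, not an algorithm; the package operationalizes it and
exposes the knobs. Let $H(v)$ be the number of common antigens on vendor
$v$ whose normalized MFI (maximum over the two secondaries) is at or above
`high_cutoff` (default 1000):

* letter **C**: $H(LS) \ge 2$ and $H(LC) \ge 2$;
* letter **B**: exactly one vendor has $H \ge 2$;
* letter **A**: positives exist but neither vendor reaches two strong beads;
* number **1** when the maximal per-condition positive count is `>= 5`,
  **2** otherwise.

The boundary is `>= 5` (not `> 5`) because the described group-1 breadth
range starts at 5; with `< 5` the endpoint would belong to neither group.
Both thresholds are arguments, not constants.

**Paired tests.** The source analyses report nonparametric paired p-values
without naming the test; the package provides both the exact sign test and
the exact Wilcoxon signed-rank test and defaults to reporting both. The
signed-rank test is implemented in-package because the conventional
treatment of ties (drop zero differences, mid-rank equal absolute
differences) is incompatible with the tabulated exact distribution that
`stats::wilcox.test` relies on — it falls back to a normal approximation
whenever ties occur. Here, for $n \le 25$ the null distribution of the
positive-rank sum is built by exact convolution over all $2^n$ sign
assignments (mid-ranks doubled to integers), so exact p-values survive
ties; beyond 25 a tie-corrected, continuity-corrected normal approximation
is used. The two-sided p is the null mass at least as far from the mean as
observed (the null is symmetric). `stats::wilcox.test` and
`stats::binom.test` serve as independent cross-checks in the test suite on
tie-free inputs; a literal brute-force enumerator is the oracle elsewhere.

## Unacceptable antigens and cPRA

Listing rules: each positive bead contributes its allele-level label
(`A0203`) *and* its serologic base group (`A2`); positive DRB3/4/5 beads
contribute DR52/DR53/DR51; DQB1 is listable; DQA1-, DPA1- and DPB1-chain
reactivities cannot be listed and are recorded under `excluded` — an
unmapped allele at a listable locus is a hard error so that mapping gaps
cannot silently shrink a patient's list. The allele→base-group table is
shipped as editable data (standard serologic split equivalences covering
the bundled panels), not code.

Two engines bracket standard practice, since the exact registry formula is
not public:

* **Haplotype / Hardy–Weinberg**: per population,
  $P(\text{acceptable}) = \left(\sum_{h \in \text{acceptable}} f_h\right)^2$,
  and $\mathrm{cPRA} = 1 - \sum_{pop} w_{pop} P_{pop}(\text{acceptable})$.
  Haplotypes are written as base antigens, so allele-level entries match
  through their base group (which expansion always includes when mapped).
* **Per-locus / linkage equilibrium**:
  $P(\text{acceptable}) = \prod_l (1 - F_l)^2$ with $F_l$ the summed
  unacceptable-antigen frequency at locus $l$.

A Monte Carlo donor-sampling oracle (draw a population by weight, then two
haplotypes or per-locus genotypes i.i.d.) validates both engines; the test
suite requires agreement within three binomial standard errors on
randomized tables. Registry frequency tables are versioned external data
and are deliberately not bundled; the shipped table is synthetic and named
accordingly.

## The synthetic-data generator

The generator is a mechanistic model of the full 2×2 experiment, not a
noise generator around target outputs.

**Bead composition.** Each bead carries fractions
(native, peptide-free, β2M-free) summing to at most 1. Per vendor:
LS draws native ∈ U(0.40, 0.60) with the remainder split into a
peptide-free share U(0.10, 0.35) and, for 85% of beads, a β2M-free share
U(0.30, 0.60); LC draws native ∈ U(0.70, 0.95), a small peptide-free share
U(0.02, 0.15), and β2M-free ≡ 0. These emulate the characterised contrast
between the vendors (free heavy chain widespread on one panel, absent on
the other; less peptide-free heterodimer on the cleaner panel).

**Sera.** A serum is a set of IgG clones: *native* clones bind the native
fraction of their target allele's bead; *shared-epitope* clones
(peptide-free or β2M-free class) bind the corresponding variant fraction
across a breadth set of alleles, reflecting public epitopes exposed on
disrupted heavy chains. Bound density is additive mass action:
$D = \sum_{\text{clones}} c \cdot f_{\text{matching fraction}}$.

**Detection.** Mean signal is $\mathrm{background} + \alpha\, g(D)\, D$
with multiplicative lognormal noise (CV 0.15 — the conventional error
model for fluorescence data) clipped at zero. The monoclonal secondary has
$g \equiv 1$; the polyclonal secondary has
$g(D) = 1 + (A - 1)e^{-D/D_0}$, strictly decreasing with $g(0) = A$ and
$g(\infty) = 1$. This law is an invented concretization of a qualitative
hypothesis (multi-epitope binding on sparse surfaces, crowding/aggregation
at high density) and is configuration-replaceable. No quantitative
amplification factor is published; the defaults $A = 4$ and $D_0 = 1000$
density units (with $\alpha = 1$ MFI per unit) are one-time calibration
choices placing the mono/poly crossover near the 3000–5000 MFI regime in
which the two secondaries are described as reading comparably. Background
is 90 MFI, decomposed 20 (PBS) + 25 (NC) + 45 (NGS) so that the
normalization formula centres blank beads at zero.

**Default study conditions.** `default_sim_config()` fixes four serum
archetypes: an anti-denatured serum (one β2M-free-class clone, breadth 20
class-I alleles, 500 binding units — low-titer), a strong dual-reactive
serum (native clones on 8 common antigens at 12 000 units — high-titer), a
weak native serum (3 antigens at 1500 units) and a zero-clone serum. The
concentrations were chosen once so that the archetypes land in the assay
regimes of interest (sub-1000-MFI LS-only reactivity; >5000-MFI
dual-platform reactivity) and were not revisited.

**What the generator does not emulate.** Kinetic binding, prozone/
complement interference, IgM, titration series, lot-to-lot drift, and any
class II variant chemistry (no characterisation protocol exists for class
II; its "denatured" behaviour is generator-only truth). Passing recovery
tests therefore shows the pipeline recovers *this* mechanism's patterns,
not that real sera behave this simply.

## Numerical choices and degenerate inputs

* Exact-test enumeration is $O(n \cdot \sum 2r)$ dynamic programming, not
  $O(2^n)$; the brute-force $2^n$ enumerator lives only in the test suite.
* All-tied input to the signed-rank or sign test is an error, not p = 1.
* A profile with no positive bead has an *undefined* median positive MFI
  (`NA`), never 0.
* Monte Carlo seeds: every generator function that draws takes an explicit
  seed (or inherits the caller's RNG stream) and restores the global RNG
  state afterwards; identical config + seed reproduces byte-identical
  output.
* Problem sizes in the shipped checks — 50 randomized cPRA tables at
  $10^5$ donor draws, 20 simulation replicates of 4 sera × 2 panels × 2
  secondaries on the ~100-bead class-I panels — were chosen to make the
  3-standard-error and ≥90%-recovery margins statistically meaningful at
  interactive runtimes.

## Known limitations

* The allele→base-antigen table covers the bundled panels only; other
  panels require extending the CSV (missing entries fail loudly).
* Group classification letters depend on the `H >= 2` operationalization;
  sera near the boundary can flip letter with the cutoff. The thresholds
  are exposed as arguments for sensitivity analysis.
* The per-locus cPRA engine ignores linkage disequilibrium by
  construction; with real haplotype structure it can under- or
  over-estimate relative to the haplotype engine.
* Class II variant flags exist only in simulation truth, mirroring the
  absence of a wet-lab protocol.
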