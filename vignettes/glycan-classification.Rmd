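---
title: "Compositional classification and enrichment of released N-glycans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional classification and enrichment of released N-glycans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomine)
```

## The problem

MALDI mass spectrometry imaging of tissue sections detects released
N-glycans as accurate masses, which annotation platforms convert into
*compositions*: residue counts such as `Hex:5 HexNAc:4 dHex:1`. A
composition does not resolve linkage or branching — many isomers share it —
but because N-glycan biosynthesis is strongly canonical (all N-glycans grow
from the Hex:3 HexNAc:2 chitobiose core), residue counts alone already
imply a great deal of structure. glycomine turns compositional annotations
into structural class calls, ontology-style term sets, enrichment
statistics, and region-level class-frequency profiles.

## Mass arithmetic

Residue monoisotopic masses are fixed to the standard values
(Hex 162.052824, HexNAc 203.079373, dHex 146.057909, NeuAc 291.095417,
NeuGc 307.090331, Pent 132.042259 Da). A released glycan carries a free
reducing end, so the neutral mass adds one water (18.0105647 Da), and a
singly charged adduct ion is

$$ m/z\,[\mathrm{M+X}]^{+} = M + m_X - m_{e^-} $$

with the cation's atomic mass and one electron subtracted. The electron
term (0.00055 Da) is not cosmetic: it is needed to match 4-decimal
annotation and lock-mass values on high-resolution instruments.

```{r}
adduct_mz("Hex:5 HexNAc:4 dHex:1", "Na")  # a classic lock mass
adduct_mz("Hex:7 HexNAc:2", "Na")
```

Two spellings of annotations occur in the wild — delimited
(`"Hex:5 HexNAc:4"`) and concatenated (`"Hex5HexNAc4"`) — and the parser
accepts both, case-insensitively for known symbols. Peak matching
(`match_mz()`) defaults to 2 ppm, the accuracy class of 7 T
magnetic-resonance instruments; it is a plain tolerance, configurable per
call. Note that published figure captions occasionally pair a composition
with an m/z that standard monoisotopic arithmetic does not reproduce
(transcription slips of one residue are common); this package treats the
arithmetic, not any single printed value, as ground truth, and the
reference values it tests against are those that reproduce exactly.

## The classification rules

With H = Hex, N = HexNAc, F = dHex, S = NeuAc counts, the *type class* is
the first match of:

| type | rule | reading |
|---|---|---|
| high-mannose | H > 3, N ≤ 2, F = 0, S = 0 | only hexoses beyond a full or partial core |
| pauci-mannose | H < 4, N < 3, S = 0 | truncated core; fucose permitted |
| hybrid | N = 3, H ≥ 4 | one antenna on a mannose-extended core |
| complex | N ≥ 4 | two core + ≥2 antenna HexNAc |
| unclassified | otherwise | fallback, never an error |

Hybrid and complex glycans are then screened for decorations:
fucosylated (F = 1), multifucosylated (F > 1), sialylated (S ≥ 1),
polylactosamine (N > 6 and H > 7, repeating Hex-HexNAc units), bisecting
(N = H and N = 5 or N > 6), and tetra-antennary (N ≥ 6). The single
composition H = 6, N = 6 is consistent with either a bisecting or a
tetra-antennary structure; rather than guessing, the classifier emits the
dedicated label `BISECTING_OR_TETRA_ANTENNARY` and sets an `ambiguous`
flag.

```{r}
classify("Hex:8 HexNAc:8 dHex:2")
classify("Hex:6 HexNAc:6")
```

Design choices worth knowing:

* **The hybrid rule is a package convention.** Compositional criteria for
  high-mannose, pauci-mannose, complex and the decorations follow standard
  database-validated cut-offs; no equally standard compositional rule
  exists for hybrid glycans. N = 3 with H ≥ 4 (exactly one antenna HexNAc
  on a mannose-extended core) is the natural reading and is deliberately
  kept adjacent to (not overlapping) the high-mannose bound N ≤ 2.
* **Pauci-mannose excludes sialylation** (S = 0): only fucose occurs on
  truncated cores.
* **Bisecting at N = H = 5 is called as printed.** A composition such as
  Hex:5 HexNAc:5 dHex:4 receives the bisecting label even though curated
  assignments sometimes prefer plain "complex multifucose" for it; the rule
  system is kept exact rather than special-cased.
* **Unknown residues never block typing.** Symbols outside
  Hex/HexNAc/dHex/NeuAc (e.g. NeuGc, Pent, user extensions) are ignored by
  the rules with a warning, so registry extensions cannot silently change
  class calls.
* Decorations are evaluated for hybrid and complex glycans; for
  pauci-mannose the fucosylation state is surfaced as metadata
  (`$fucosylation`) but kept out of the display name, matching how the
  class vocabulary is conventionally applied.

The whole rule system is pure arithmetic on counts, so it is testable by
brute force: the suite re-evaluates an independently written decision
chain over every composition with H ≤ 12, N ≤ 12, F ≤ 4, S ≤ 4 (4224
cases) and requires exact agreement.

## Ontology terms and enrichment

`ontology_terms()` maps each glycan to its term set (type class plus
decorations; the ambiguous label is a term of its own) and builds the
inverted index used by `term_enrichment()`. Four over-representation
statistics are computed per term, all one-sided in keeping with
enrichment convention:

* **Fisher**: hypergeometric tail \(P(X \ge k)\);
* **EASE**: the same tail after discarding one observed hit
  (\(k \to \max(k-1, 0)\)), a deliberately conservative variant — it is
  provably never more significant than Fisher;
* **binomial**: \(P(X \ge k)\) for \(X \sim \mathrm{Bin}(n, K/N)\), the
  with-replacement approximation;
* **Kolmogorov–Smirnov** on ranks: two-sample members vs non-members by
  default (a one-sample test of member ranks against uniform is available
  via `ks_mode = "uniform"`), asymptotic p-values, ties broken by stable
  ordering on the identifier. Terms with no member or no non-member are
  flagged untestable rather than erroring.

Multiset queries are collapsed to sets (with a message) before testing.
Benjamini–Hochberg is the default adjustment, Bonferroni selectable. The
choice of universe matters and is deliberately explicit: the natural
default for imaging experiments is the set of glycans detected in the
section, not an external database.

```{r}
ont <- ontology_terms(c(a = "Hex:7 HexNAc:2", b = "Hex:3 HexNAc:6",
                        c = "Hex:5 HexNAc:4 dHex:1", d = "Hex:3 HexNAc:2"))
term_enrichment(c("a", "b"), c("a", "b", "c", "d"), ont$index)[, 1:7]
```

## Regions and co-localization

`summarize_regions()` produces the region × class surfaces used for
glycome profiling: per-region counts, within-region percentages (the
denominator is the region's distinct-glycan total, so multi-labelled
decorations can sum past 100%), and totals. Three views are tabulated:
mutually exclusive type classes (which partition the total), marginal
decoration terms plus an explicit "complex (no decorations)" bucket, and
exact display-name combinations — published class axes mix marginal and
combination levels, so both are provided.

The spatial path is deliberately light: `colocalize()` is the cosine
similarity between an ion image and a binary region mask, and
`assign_regions()` thresholds it (default 0.5). This is a transparent
stand-in for platform-internal co-localization measures, not a
re-implementation of any of them; reproducing a specific platform's
region lists is out of scope.

## Synthetic fixtures: what they emulate, and what not

`generate_fixture_compositions()` samples compositions from the
H ≤ 12, N ≤ 12, F ≤ 4, S ≤ 4 grid to hit a requested class mix, using
constructive structural predicates written independently of `classify()` —
so the emitted `intended_class` column is a genuine oracle for round-trip
tests. Infeasible requests (e.g. pauci-mannose constrained to carry
NeuAc) fail naming the class. The pipeline default mix (20% complex
fucosylated, 15% plain complex, 15% high-mannose, 10% each hybrid,
multifucosylated, sialylated, tetra-antennary, 5% pauci-mannose) mirrors
the composition balance reported for healthy lung tissue, where complex
fucosylated species dominate; it is a realism choice, not a fit.

`generate_fixture_images()` renders each glycan's ion image as the union
of its intended region masks plus clipped Gaussian noise. With equal-area
non-overlapping masks a union of k regions scores \(1/\sqrt{k}\) against
each member mask, so at the default threshold 0.5 a noise-free fixture
with ≤ 4 regions per glycan is recovered exactly — that closed form is
what the recovery tests assert.

What the fixtures do **not** emulate: real ion images have correlated,
heteroscedastic noise, partial-volume mixing at region boundaries, and
region masks that overlap anatomically; real annotation carries FDR-
controlled uncertainty; and real glycan class frequencies are not uniform
within a class's feasible grid cell. Passing fixture tests therefore
demonstrates correctness of the algorithms, not performance on tissue
data.

## Numerical choices and degenerate inputs

* Exact tails come from `phyper`/`pbinom`; the suite cross-checks them
  against direct binomial-coefficient enumeration on every table with
  N ≤ 25 and checks null calibration (2,000 random-term replicates,
  universe 60, query 15) — exact tests are conservative, so the empirical
  type-I error sits below the nominal 5%.
* Odds ratios use the Haldane 0.5 correction only when a cell of the 2×2
  table is zero, and only for display; p-values never use it.
* `assign_regions()` compares scores to the threshold with a 1e-9 guard so
  an image identical to its mask survives threshold 1.0 despite float
  round-off.
* Empty compositions (`Hex:0 HexNAc:0`), malformed tokens, duplicate
  symbols, unknown adducts, zero tolerances, and empty universes all fail
  fast with messages naming the offending input; `UNCLASSIFIED` (not an
  error) is the classifier's fallback, so every glycan always carries at
  least one ontology term.
* All randomness (fixtures, the pipeline's simulated spatial experiment)
  flows from explicit seeds; `run_pipeline()` reruns byte-identically
  under a fixed seed. Test and verification problem sizes — the 4224-case
  grid, 10^4-table sweeps, 2,000 null replicates, 200-row fixtures — were
  chosen to exercise every rule branch while keeping the whole suite in
  the tens of seconds.

## Limitations

The classifier is compositional: it cannot distinguish isomers, cannot
see linkage (e.g. core vs antenna fucosylation, α2,3 vs α2,6 sialylation),
and its hybrid rule is a convention rather than a database-derived
criterion. The ambiguous H = 6, N = 6 call is honest uncertainty —
resolving it requires orthogonal structural data. The cosine
co-localization path is a toy for testing plumbing, not an image-analysis
method.
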