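---
title: "Classifying ASV origin in low-biomass subsurface surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ASV origin in low-biomass subsurface surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvorigin)
```

## The problem

Amplicon surveys of very low-biomass habitats — subseafloor sediment and
crust recovered by drilling, deep aquifers, glacial ice — operate near the
noise floor of molecular biology.  With 10–10^4 cells per cm^3 in the
sample, reagent contaminants, drilling-fluid organisms and seawater
carryover can contribute a substantial share of the reads, and a naive
community profile describes the laboratory more than the habitat.  The
standard defences are (i) sequencing no-template controls (NTCs) and
environmental control material such as drilling fluid ("grease") and
station seawater, and (ii) tracking a perfluorocarbon (PFC) tracer added to
the drilling fluid, whose concentration in a core sample indexes physical
contamination.

`asvorigin` turns the screening judgement usually performed by hand into a
deterministic decision procedure over those evidence sources, so that a
survey's decontamination is reproducible, auditable (every call carries its
evidence trail) and testable against synthetic ground truth.

## The classifier

Every ASV receives exactly one of four categories — `subsurface`,
`possibly_subsurface`, `likely_contaminant`, `contaminant` — from three
inputs:

* **Control identity**: the maximum pairwise identity between the ASV and
  the NTC, drilling-fluid and seawater control collections, thresholded at
  `identity_threshold` (default 0.99).
* **Whitelist membership**: an independently established "likely
  indigenous" ASV set.  Membership exempts an ASV from the hard
  `contaminant` call — the survey that established the whitelist has
  positive evidence the taxon lives in the habitat — but not from
  `likely_contaminant`.
* **Environment class**: the free-text environment of the ASV's closest
  database match, mapped to `subsurface_like` / `contaminant_like` /
  `ambiguous` by a keyword list (`environment_map()`).  This replaces a
  manual curation step; the keyword lists are deliberately short, fully
  user-configurable, and contaminant keywords win when both classes match,
  because the screening stance is to discard on doubt.

The cascade (R1–R3) is documented on `classify_asv()`.  Two branches are
policy parameters rather than fixed rules, because the evidence there is
genuinely ambiguous:

* a whitelisted, control-matching ASV with no usable environment evidence
  defaults to `likely_contaminant` (`unknown_env_policy_matched`) —
  conservative, since the control match is affirmative contamination
  evidence;
* a non-matching ASV with no evidence at all defaults to
  `possibly_subsurface` (`unknown_env_policy_unmatched`) — the bulk of
  minor taxa land here, and claiming them as firmly `subsurface` would
  overstate what is known.

A design choice worth stating: in R3 (no control match), whitelist
membership alone yields `subsurface`.  We read "likely indigenous" status
from a companion survey as affirmative habitat evidence on par with a
subsurface-like database match; users who prefer a weaker reading can
whitelist nothing and rely on environment evidence only.

### The abundance gate

Manual screening workflows often BLAST only abundant taxa (e.g. taxa with
more than 5,000 reads) as a labour constraint.  `abundance_gate_reads`
reproduces that behaviour: when set, ASVs at or below the gate take the
ambiguous/absent branch of their rule.  The default is off — with
machine-computed environment classes there is no labour to save, and
classifying everything is strictly more informative.

## Sequence identity

"99% similar" is the conventional screening criterion, but it
underdetermines the computation: the aligner, the gap treatment and the
denominator all matter.  The choices here, all surfaced in
`identity_params()`:

* **Alignment**: Needleman–Wunsch global alignment with free end gaps
  (Biostrings `pairwiseAlignment`, type `"overlap"`), match +1, mismatch −1,
  gap −2 per column.  Ambiguity codes, including N, score as mismatches:
  an uncalled base is not evidence of identity.
* **Denominator** (`denominator = "global"`, the default): matched columns
  divided by *all* columns of the full-span alignment, terminal overhangs
  included.  Under the alternative `"overlap"` denominator a short exact
  fragment of a longer control would score 1.0 over the overlap alone; for
  amplicons of one primer set the two definitions agree (lengths are nearly
  equal), and the default is the safer reading when they do not.
* **Symmetry**: each pair is canonically ordered (lexicographically smaller
  string as alignment pattern) before aligning.  When the optimal alignment
  is not unique, traceback tie-breaking could otherwise make
  `identity(a, b)` differ from `identity(b, a)` in the last decimal; the
  canonical ordering makes symmetry exact by construction.
* **Tie-breaking in `best_control_match()`**: highest identity first, then
  control-type precedence NTC > drilling fluid > seawater (an NTC match is
  the strongest contamination evidence), then lexicographic control id —
  fully deterministic.
* **k-mer prescreen** (`kmer_k = 8`): pairs sharing no 8-mer are skipped
  without alignment.  At any threshold ≥ 0.9 a true match shares many
  8-mers, so the prescreen is an optimisation only; the test suite asserts
  equivalence with exhaustive all-pairs alignment on a 200-sequence set.
* **Degenerate inputs**: empty sequences are hard errors; the identity of a
  sequence with itself is exactly 1.

## Tracer comparison

The biological expectation is qualitative: samples dominated by indigenous
reads should carry little drilling-fluid tracer.  `tracer_comparison()`
therefore uses a rank correlation (Spearman) between the per-sample
indigenous read fraction (`subsurface + possibly_subsurface`, reads-weighted
— the read-weighted choice matches how category profiles are plotted) and
the interior PFC concentration, with an exact two-sided permutation p-value
when at most 8 samples are usable (8! = 40,320 orderings; beyond that the
asymptotic approximation is used).  Sentinel tracer values (below detection
limit, not determined) are excluded by default rather than imputed as zero
(`bdl_policy = "zero"` is available): the sentinel mixture in real sample
tables makes any single imputation arbitrary, and with n this small the
correlation should not hinge on it.  Fewer than 3 usable samples yields an
explicit `insufficient_data` report, never a correlation.

## Sentinel handling in sample tables

Sample overview tables mix numbers with typed sentinels: `BDL`/`ADL`
(below/above detection limit), `BMQL (4.4)` (below minimum quantification
limit, with the limit), `n.d.`, `n.a.`, and `n.c.` (no cells detected) in
the PCR column, plus occasional numeric ranges (`5-16`).  `read_sample_table()`
maps each to a typed flag beside an `NA` numeric — sentinels never silently
become zeros — and parses ranges to a flagged midpoint that downstream
arithmetic never consumes.  Unknown tokens are hard errors: a typo in a
sentinel must not silently become a missing value.

## Functional profiling

Pathway completeness of a partial genome is
`|defining KOs present| / |defining KOs|` — presence/absence semantics, so
copy number never inflates completeness, and every value lies exactly on
the grid k/|defining set|.  Marker-gene entries are summed copy numbers
over each marker's KO list.  The packaged pathway and marker definitions
(`default_pathway_file()`, `default_marker_file()`) cover the common
carbon-fixation, heterotrophy, nitrogen, sulfur, CO-oxidation, hydrogenase
and cytochrome-oxidase pathways as *editable data*: KO-to-pathway mappings
are a curation product, not an algorithm, and surveys routinely adapt them.
A few marker KO assignments (e.g. the [NiFeSe] hydrogenase) are best-effort
defaults and should be reviewed before use on real annotations.

## The synthetic-data generator

`make_community()` emulates the structure of a contaminated low-biomass
survey, not its biology:

* indigenous and contaminant ASV pools of uniform random DNA, with
  rejection sampling enforcing pairwise identity < 0.97 within and between
  pools (no phylogenetic realism — the classifier only consumes identities);
* contaminant ASVs copied **verbatim** into exactly one control set each,
  with the NTC weighted so two taxa dominate (110 and 21 reads of a
  147-read control, the canonical reagent signature);
* optional near-threshold variants at a stated substitution count (3
  substitutions over 370 nt gives identity 367/370 ≈ 0.9919, just above the
  0.99 threshold);
* a whitelist drawn from the indigenous pool, plus optional contaminant
  decoys;
* environment descriptions consistent with truth, at a configurable hit
  rate (default 0.75 — real minor taxa often lack a usable hit);
* per-sample multinomial read counts: the planted contaminant fraction of
  probability mass split uniformly over contaminants, the remainder over
  indigenous ASVs with log-normal relative abundances (σ = 1, a standard
  rank-abundance shape);
* a tracer that is a strictly increasing function of the planted
  contaminant fraction (`10^(1 + 4f)`, spanning the 10–10^5 pg cm^-3 range
  of real PFC measurements), with optional log-scale noise.

Before writing truth, the generator *certifies* separability by exhaustive
pairwise alignment and errors if the guarantees fail, so downstream
precision/recall tests cannot pass vacuously.  Default conditions — 20
indigenous + 10 contaminant ASVs of 370 nt, 8 samples at 50,000 reads,
planted fractions spanning 0 to 1 — are the reference regime used by the
test suite (20 seeds of it run in well under two minutes; property suites
use 80–150 nt sequences to keep hundreds of random cases fast).

What passing these tests shows — and does not.  In the separable regime the
classifier must recover truth exactly; this validates the decision logic,
the identity computation and the plumbing.  It does *not* show that real
contaminants are verbatim copies of control reads (they are not: sequencing
error, chimeras and index hopping blur the boundary), nor that the 0.99
threshold is optimal for any particular dataset.  The near-threshold
variant machinery exists precisely to probe that boundary.

## Numerical conventions

* Displayed percentages are rounded half-up (`round_half_up()`), at one
  decimal place in reports and to the nearest integer for the screening
  efficiency; internal computation is always full precision.
* Category profiles of zero-read samples are `NA` and flagged, never 0/0.
* Family composition collapses families below 0.1% relative abundance in
  every sample into `"other family"`; ASVs unresolved at family level get
  "(p) Phylum"-style labels at their deepest resolved rank; ASVs missing
  from the taxonomy go to an `"unknown bacteria"` bucket with a warning.
* All output files are written atomically (temp file + rename), and every
  pipeline stage writes a manifest with package version, resolved
  parameters, seed and input checksums.

## Known limitations

* The classifier is identity-based only; it does not model read frequencies
  across controls and samples (prevalence-style statistical decontamination
  is a complementary, not competing, approach and is out of scope).
* Chimera detection and index-hopping correction are upstream concerns.
* Whether screening identity should be computed ASV-to-ASV or
  ASV-to-raw-control-reads is a genuine open question; this implementation
  compares ASV representatives to control sequence sets as provided.
* The single-best-hit retention rule in `read_blast_tab()` (max bitscore,
  lexicographic tie-break) is a determinism choice; workflows that retain
  multiple hits per query need to reduce them before import.
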