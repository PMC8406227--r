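# asvorigin

Contamination screening and origin classification for **low-biomass
microbiome surveys** — subseafloor sediment and crust, deep aquifers, and any
other habitat where the organisms of interest are so sparse that reagent,
drilling-fluid and seawater contamination can dominate a 16S rRNA amplicon
library.

In such surveys every amplicon sequence variant (ASV) has to be interrogated
before it can be believed.  `asvorigin` codifies that interrogation as a
deterministic, reproducible classifier, and surrounds it with the summaries a
survey paper needs: decontaminated community composition, drilling-tracer
comparison, screening-success accounting, and KEGG Orthology (KO) based
functional profiles of partial genomes (MAGs and SAGs).

## The classifier

Each ASV receives exactly one of four origin categories —
**subsurface**, **possibly subsurface**, **likely contaminant**,
**contaminant** — from a rule cascade over three evidence sources:

1. **Control identity.** Global, end-gap-free pairwise identity between the
   ASV and every sequence in the no-template-control (NTC), drilling-fluid
   and seawater control collections.  Identity is
   `matches / alignment columns` (terminal overhangs included by default),
   with match +1, mismatch −1 (ambiguity codes count as mismatches) and gap
   −2.  An ASV with identity ≥ *t* (default *t* = 0.99) to any control is
   control-matched.
2. **Whitelist.** A "likely indigenous" set of ASVs established
   independently (e.g. by differential-abundance analysis in a companion
   survey).  Whitelisted ASVs are exempt from the hard `contaminant` call.
3. **Environment of the closest database match.** The free-text environment
   of each ASV's best BLAST hit, classed as subsurface-like or
   contaminant-like by a configurable keyword map.

The cascade:

| Rule | Condition | Category |
|------|-----------|----------|
| R1 | control match, not whitelisted | contaminant |
| R2 | control match, whitelisted | possibly subsurface / likely contaminant by environment (policy default when ambiguous) |
| R3 | no control match | likely contaminant if environment is contaminant-like; subsurface if subsurface-like or whitelisted; policy default otherwise |

ASVs called `contaminant` or `likely_contaminant` are removed before any
community-level summary.

A seeded synthetic-community generator (`make_community()`,
`sample_counts()`, `make_tracer()`, `make_genomes()`) produces every input
the pipeline consumes together with recorded ground truth, and certifies by
exhaustive pairwise alignment that its contaminant/indigenous pools are
separable — so classifier precision and recall are exactly measurable.

## Worked example

Screening accounting over the packaged 29-sample drilling-expedition
overview (lithology, cell density, PCR and sequencing status per sample):

```r
library(asvorigin)
samples <- read_sample_table(atlantis_sample_file())
str(summarize_screening(samples))
#> List of 8
#>  $ n_screened                : int 29
#>  $ n_cells_detected          : int 18
#>  $ n_pcr_positive            : int 9
#>  $ n_sequenced               : int 8
#>  $ n_sequenced_sediment      : int 3
#>  $ n_sequenced_crust         : int 5
#>  $ efficiency_percent        : num 27.6
#>  $ efficiency_percent_rounded: num 28
```

Of 29 samples screened, 18 yielded cell-like particles, 9 gave a positive
PCR, and 8 (3 sediment, 5 crust) were successfully sequenced — a 28%
end-to-end screening efficiency.

Classification of a small synthetic community (6 indigenous + 4 contaminant
ASVs, 4 samples with planted contaminant read fractions 0, 1/3, 2/3, 1):

```r
p <- generator_params(n_indigenous = 6, n_contaminant = 4, asv_length = 120,
                      n_samples = 4, read_depth = 2000, seed = 7)
cm    <- make_community(p)
drawn <- sample_counts(cm, p)
calls <- classify_table(drawn$counts, cm$seqs, cm$controls, cm$whitelist, cm$blast)
table(calls$category)
#>         contaminant possibly_subsurface          subsurface
#>                   4                   1                   5

filter_contaminants(drawn$counts, calls)$report
#>   sample_id reads_before reads_after fraction_removed fully_excluded
#> 1       S01         2000        2000           0.0000          FALSE
#> 2       S02         2000        1319           0.3405          FALSE
#> 3       S03         2000         667           0.6665          FALSE
#> 4       S04         2000           0           1.0000           TRUE
```

All four planted contaminants are recovered as `contaminant` (precision and
recall 1 in this separable regime), the removed-read fraction per sample
tracks the planted contamination level, and the fully contaminated sample is
flagged as excluded outright.

The same stages are available from a shell via `exec/asvorigin`
(`simulate`, `classify`, `summarize`, `profile` subcommands) or as the
`run_simulate()` / `run_classify()` / `run_summarize()` / `run_profile()`
functions, which write TSV/JSON outputs plus a manifest recording package
version, parameters, seed and input checksums.

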