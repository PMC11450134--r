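---
title: "Methods: N-terminome annotation and cleavage-site concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: N-terminome annotation and cleavage-site concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntermscope)
```

## Scope and model

`ntermscope` annotates protein N-terminomes measured with TAILS-style
enrichment: free alpha- and epsilon-amines are dimethylated in vitro with
isotopic formaldehyde before digestion, so that the N-terminal mass shift of
an enriched peptide encodes the in-vivo state of that N-terminus. The
package consumes post-search identification tables (it does not re-score
spectra), a proteome FASTA with reversed-sequence decoys, and TargetP2-style
targeting-peptide predictions, and produces proteoform-level annotations:

1. **Filtering.** PSMs are accepted at protein probability &ge; 0.99 (with
   &ge; 1 peptide), peptide probability &ge; 0.95, and ion score &ge; 40 —
   inclusive bounds. The decoy FDR is reported at peptide level (keys:
   peptide sequence + N-terminal shift) and protein level (keys: protein
   groups, decoy iff every member is a decoy) as the simple ratio
   decoys/targets. The corrected estimator 2D/(T+D) is a
   one-line swap in `compute_decoy_fdr()`; the simple ratio was chosen
   because it matches the convention of the identification software whose
   reports the pipeline mirrors.
2. **Proteoform enumeration.** Each accepted N-terminal peptide is located
   in each matched protein; the observation key is
   `(accession, start_index, state)`. A position identified both acetylated
   and free therefore yields **two** proteoforms ("dual state") — this
   keying is required for state-stratified percentages at confirmed
   cleavage sites, and it propagates to the termini-per-protein table.
   Peptides that do not occur, or occur more than once (overlapping
   occurrences included), are dropped and counted. Ile/Leu are treated as
   distinct letters because search engines emit database-resolved
   sequences.
3. **State classification.** The shift is matched within an absolute
   tolerance (default 0.005 Da) against acetyl (+42.010565), the chemistry's
   dimethyl shift (free), its hybrid-methylation shift (in-vivo
   monomethyl), and pyroGlu (−17.026549, first residue Gln only). The four
   windows are validated pairwise non-overlapping at start-up for the
   chemistry in use, so classification is a partition. pyroGlu is accepted
   only when the preceding residue is outside the protease specificity set
   (trypsin {K,R}; GluC {E,D}; chymotrypsin {F,Y,W,L,M}); a rejected
   pyroGlu, any unmatched shift, and an absent shift all classify as
   `other`. The tight absolute window (rather than the instrument's ppm
   tolerance) is appropriate because export tables carry canonical
   modification masses, not measured ones.
4. **Concordance.** For each protein with a predicted targeting-peptide
   cleavage site, `dif = start_index − p1_prime`, kept when |dif| &le; 5.
   Sign convention: positive dif means the observed terminus lies
   C-terminal of the predicted P1′, i.e. further trimming after import;
   this makes the post-processing tail positive and cumulative curves read
   left to right. Concordance tables count distinct
   `(accession, dif, state)` proteoforms and also report the protein-level
   tally per dif, since both views are informative when dual states exist.
   A protein is *confirmed* for its class when &ge; 1 observation is
   in-window; state breakdowns divide per-class proteoform counts by the
   per-class confirmed protein count, so dual-state proteins contribute to
   several states and fractions may sum above 1 by design.
5. **Sequence context.** Windows are aligned at the identified N-terminal
   residue: one preceding (P1) residue — `-` at the protein start — plus
   `width` mature residues (default 10, wide enough to show the P2
   proline/lysine context relevant to N-terminal methyltransferase
   specificity), right-padded with `-`. Non-redundancy (`dedupe = TRUE`)
   applies to the extracted window string, the convention for logo inputs.
   Gaps are excluded from column sums; both the P1-included matrix and any
   narrower slice can be taken from the output. Information-content scaling
   is left to plotting tools.
6. **Triage.** Acetylated N-termini at mitochondrial presequence sites are
   classified by a total, deterministic rule order: alternative translation
   initiation (preceding Met, Kozak similarity &ge; 0.7 when context data
   exist) &gt; splice variant (a variant protein starts within &plusmn;1 of
   the observed residue, compared over the first 10 residues after optional
   initiator-Met stripping) &gt; dual targeting (external
   ambiguous-targeting call) &gt; unclear. The precedence encodes the
   biological reading that a Met-preceded acetylated Ala/Ser/Thr most
   parsimoniously marks a co-translationally acetylated shorter isoform.
   When no Kozak context is supplied, a preceding Met alone is accepted as
   alt-TIS evidence — the preceding Met *is* the candidate downstream
   initiator; supplying contexts makes the rule strictly stricter.

### The Kozak similarity score

Translation-initiation-site predictors are typically external web services;
the package instead scores a fixed 12-nt window (6 upstream, AUG, 3
downstream) against a position-probability matrix as the mean per-position
probability normalized by the position maxima, so the consensus scores
exactly 1 and the usual threshold semantics (&ge; 0.7) carry over. The
bundled matrix is a soft plant initiation-context consensus; any PWM of the
same shape can be substituted, and external predictor calls can be supplied
instead of contexts. This is a transparent stand-in with matching range and
threshold, not a re-implementation of the external service.

## The synthetic-data generator

`generator_params()` fixes the study conditions; the generator is the
ground-truth oracle for every end-to-end test.

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 1000 | large enough for 3-sigma binomial checks on a 1% state |
| `class_fractions` | cTP 0.20, mTP 0.10, luTP 0.02, SP 0.05, noTP 0.63 | organellar-heavy mix mirroring the confirmed-cleavage ratios of plant N-terminome data (allocated as an exact partition, largest-remainder rule) |
| `tp_length_range` | 20–80 | typical cleavable targeting-peptide lengths |
| `trim_geometric_p`, `max_trim` | 0.5, 5 | trimming offsets drawn from a geometric law truncated to 0..5: the simplest named decaying distribution consistent with "one to five residues with decreasing frequency", and swappable |
| `state_probs` | free 0.71, acetyl 0.25, monomethyl 0.03, pyroGlu 0.01 | the modification-state mix the analysis assumes |
| `mature_aa_bias` | 4 | Ala/Ser enrichment at mature N-termini, so logo tests have a planted modal residue |
| `chemistries` | DS1 = ¹³C,D₂; DS2 = D₂ | two datasets, one per formaldehyde isotopologue, so both labeling chemistries are exercised |
| `p1_jitter` | 0 | predictions equal planted truth; set &gt; 0 to probe window robustness |
| `decoy_pass_rate`, `low_score_rate` | 0.002, 0.05 | a few decoys pass thresholds (non-trivial empirical FDR), some target rows fail them (filtering is consequential) |

Planted constraints make every state recoverable: pyroGlu termini get a Gln
first residue and an Ala preceder (outside every supported specificity
set); untargeted proteins start at index 1 (30%), 2 (30%, Met excision) or
an internal position 3–100 (40%). Peptides run from the planted start to
the next protease-specific residue and are extended until they occur
uniquely in their protein, so mapping recovery is exact. All output files
are reproducible byte-for-byte from the seed, which is recorded in a header
comment of every TSV/prediction file.

**What the generator does not emulate:** spectra and retention times,
search-engine score distributions (scores are threshold-passing scalars),
shared peptides across proteins, multiple N-termini per protein,
protein-abundance structure, and predictor error (unless jitter is
enabled). Passing recovery tests therefore validates the annotation logic
and bookkeeping, not robustness to search-engine idiosyncrasies of real
data.

## Numerical and degenerate-input choices

* Mass deltas are written with six decimals (the precision of canonical
  modification masses); probabilities and scores with `%.10g`, so TSV
  round-trips are exact at double precision.
* FDR with zero targets reports 0 and a `degenerate` flag instead of
  dividing.
* Empty observation sets yield empty histogram/PFM/concordance outputs with
  no division by zero; a PFM over an empty selection has `n = 0` and
  all-zero counts.
* The truncated-geometric trimming parameter is fitted by maximizing the
  exact likelihood on (0, 1) with `stats::optimize()`; an all-zero offset
  sample drives the estimate to the upper boundary rather than failing.
  Confidence intervals are percentile bootstrap (default 200 replicates).
* Ties in the largest-remainder class allocation break by parameter order —
  irrelevant at the defaults, deterministic always.

## Validation problem sizes

The shipped test-suite runs brute-force all-pairs oracles on fixtures of up
to 50 proteins, exhaustive delta grids (70k points per chemistry/protease
combination) for the classification partition and pyroGlu-filter
completeness, a 12-case planted triage panel, and a full end-to-end
1000-protein synthetic study in which state fractions must fall within
3-sigma binomial bounds, confirmed-cleavage counts must equal the planted
truth exactly, and the bootstrap CI of the trimming parameter must cover
0.5. These sizes give stable statistical checks while keeping the whole
suite in the seconds range.

## Known limitations

* Real supplementary workbooks (XLSX observation/prediction tables) are not
  parsed; the TSV dialect is an information-equivalent. An adapter would be
  a thin conversion layer in front of `read_psm_table()`.
* The pipeline consumes one prediction per protein; disagreeing prediction
  files should be analyzed per file, never merged.
* Probability models behind peptide/protein scores are consumed, not
  re-derived; the FDR is only as meaningful as the upstream decoy search.
* Triage quality is bounded by its inputs: without splice-variant sequences,
  Kozak contexts or ambiguous-targeting calls, the rules can only reach
  alt-TIS (via preceding Met) or unclear.
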