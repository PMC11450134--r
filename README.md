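# ntermscope

Annotation of protein N-terminomes from TAILS-style dimethyl-labeling
proteomics, with cleavage-site concordance against predicted organellar
targeting peptides.

## The problem

N-terminomics experiments enrich the N-terminal peptide of every protein in
a sample. Before proteolysis, all free amines are blocked in vitro by
reductive dimethylation with isotopic formaldehyde, so the mass shift
observed on a peptide's N-terminus reports what the N-terminus looked like
*in vivo*:

| observed N-terminal shift (Da) | in-vivo state |
|---|---|
| +42.010565 | N&alpha;-acetylated |
| +34.063117 (¹³C,D₂) / +32.056407 (D₂) | free (fully dimethylated in vitro) |
| +31.047208 (¹³C,D₂) / +30.043854 (D₂) | monomethylated (hybrid label) |
| −17.026549 on Gln | pyroglutamate |

Because pyroglutamate also forms artifactually after in-vitro digestion, it
is only accepted when the preceding (P1) residue does **not** match the
protease specificity (e.g. no K/R preceders in tryptic digests).

Mapping each accepted N-terminal peptide back to its protein gives a
*proteoform start index*; comparing start indices with predicted cleavage
sites of chloroplast transit peptides (cTP), thylakoid-lumen transfer
peptides (luTP), mitochondrial presequences (mTP) and secretory signal
peptides (SP) — within a ±5-residue window around the predicted first
mature residue P1′ — confirms targeting-peptide cleavage and exposes
post-import trimming: the signed offset

```
dif = start_index − P1′,   |dif| ≤ 5
```

is 0 at exact agreement and positive when residues beyond the predicted
site were removed. The package covers the full chain: decoy-FDR filtering of
peptide-spectrum matches (PSMs), proteoform enumeration,
modification-state classification, concordance and confirmed-cleavage
tables, modification-stratified position-frequency matrices (sequence-logo
inputs), and a rule-based triage of acetylated N-termini at mTP sites
(alternative translation initiation vs splice variant vs dual targeting,
using a Kozak-similarity score with threshold 0.7). A seeded synthetic-data
generator with planted ground truth makes every stage testable offline.

## Worked example

```r
library(ntermscope)

params <- generator_params(n_proteins = 300, seed = 11)
paths  <- write_synthetic_study(params, "demo")          # FASTA + predictions + PSMs + truth
cfg <- run_config(paths$proteome, paths$psms, paths$predictions,
                  "demo/out", chemistry_by_dataset = params$chemistries)
run <- run_pipeline(cfg)
run
#> N-terminome pipeline run
#>   PSMs: 377 total, 359 accepted (peptide FDR 0.333%, protein FDR 0.333%)
#>   N-termini: 300 proteoforms at 300 positions in 300 proteins
#>   states: free 70.3%, acetyl 25.7%, monomethyl 3.0%, pyroGlu 1.0%, other 0.0%
#>   confirmed cleavages: cTP 60, mTP 30, luTP 6, SP 15
#>   outputs: demo/out

run$confirmed
#>   signal_class n_proteins
#> 1          cTP         60
#> 2          mTP         30
#> 3         luTP          6
#> 4           SP         15

fit_trim_geometric(run$records$dif)   # trimming-law parameter (planted: 0.5)
#> [1] 0.5272685
```

The 377 simulated PSMs include planted below-threshold and decoy rows; 359
pass the acceptance thresholds (protein probability ≥ 0.99, peptide
probability ≥ 0.95, ion score ≥ 40), giving the quoted decoy FDRs. All 300
planted proteoform N-termini are recovered; the per-class confirmed counts
equal the planted class allocation because every planted trim offset lies
within the ±5 window. Stage tables (`observations.tsv`,
`offset_records.tsv`, `concordance_by_class.tsv`,
`confirmed_cleavages.tsv`, `state_breakdown.tsv`, `pfm_*.tsv`,
`triage_calls.tsv`) and `summary.json` are written to `demo/out`.

A thin CLI wrapper is installed at `inst/scripts/ntermscope`
(`ntermscope simulate --seed 17 --n-proteins 1000 --out DIR`,
`ntermscope run --config cfg.yaml`).

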