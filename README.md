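# castscan

Read-level characterization of CRISPR-associated transposase (CAST)
integration products.

CASTs couple a nuclease-deficient, RNA-guided targeting complex to Tn7-like
transposition proteins and insert kilobase-scale cargos at a programmed
genomic site. `castscan` provides the sequencing-side analyses used to
characterize such systems, together with a deterministic synthetic-read
generator with ground-truth manifests so that every stage can be validated
end to end:

* **Junction analysis** — detect transposon-end/genome junctions in
  amplicon reads; report the signed distance *d* between the target 3' end
  and the first transposon-joined genomic base (modal *d* ≈ 49 bp for the
  modeled Type I-F system), the T-RL/T-LR orientation mixture, and the
  target-site duplication (TSD) length inferred from paired junctions as
  `p_L − p_R + 1`.
* **Product purity** — indel frequency in a 40-bp window centered on the
  predicted insertion site of unintegrated reads; substitution rate within
  the 5-bp TSD; read-level integration fraction; simple-insertion vs
  cointegrate classification of long reads (cointegrates carry donor
  backbone or an extra end copy).
* **Off-target mapping (UDiTaS-style)** — UMI extraction, unidirectional
  flank mapping, site clustering with single-linkage Hamming-1 UMI
  deduplication, on/off-target labeling, target-homology scanning against a
  shuffled null, replicate overlap, and the on-target fraction of
  deduplicated UMIs.
* **Pipeline** — one seeded YAML configuration drives
  simulate → junctions → purity → offtarget and emits a metrics bundle
  (JSON) with TSV/BED sidecars; `compare_conditions()` reports fold changes
  between runs.

Internals use Biostrings for all sequence matching and alignment; matching
is edit-bounded (default: 20-bp anchors, ≤ 2 edits) and every read is
accounted to exactly one outcome category.

## Worked example

```r
library(castscan)

ref   <- make_reference(100000, gc = 0.41, seed = 1)
site  <- target_site(ref, 50000, 50032, "+")
donor <- make_donor(seed = 2)

ev  <- simulate_events(ref, site, n = 200, seed = 3)
amp <- emit_amplicon_reads(ref, site, donor, ev, depth = 5,
                           unintegrated_fraction = 0.3,
                           junction_side = "both", seed = 4)

jx <- call_junctions(amp, ref, site, donor)
jx$counts
#> junction_called    unintegrated       ambiguous        multimap       too_short
#>            2000             857               0               0               0
#>       unmatched
#>               0

distance_profile(jx)$mode            # modal insertion distance: 49 bp
classify_orientation_bulk(jx)$t_rl   # T-RL fraction: 0.935
infer_tsd(jx)$tsd_len                # inferred TSD length: 5 bp
integration_fraction(jx)$fraction    # integration fraction: 0.700
```

Every read was junction-called or recognized as unintegrated amplicon
(2000 + 857 = all input reads). The junction caller recovers the
generator's 49-bp insertion offset as the modal distance, the orientation
mixture (95% T-RL drawn, 0.935 observed among 2000 calls), the 5-bp
duplication from paired upstream/downstream junction coordinates, and the
read-level integration fraction implied by the 30% unintegrated mix.

The full pipeline runs from one configuration:

```r
bundle <- run_pipeline(default_config(seed = 1), out_dir = "out")
bundle$metrics$on_target_fraction
```

A thin command-line wrapper is installed with the package
(`inst/scripts/castscan`): `castscan run --config cfg.yaml --seed 1 --out
dir/`, plus `simulate`, `compare`, and `offtarget-compare` subcommands.

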