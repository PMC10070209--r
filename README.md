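# mnoxstate

Predicts per-ion **manganese oxidation states** (II / III / IV) directly
from atomic coordinates, and assigns the Kok-cycle **S-state** of the
photosystem II oxygen-evolving complex (OEC) from the four predicted Mn
charges.

## Who this is for

Structural biologists and bioinorganic chemists who have a PDB/mmCIF
structure containing octahedrally coordinated Mn — a small-molecule
complex, a metalloenzyme, or a photosystem II deposition — and want a fast,
reproducible estimate of each Mn centre's oxidation state, e.g. to assess
the catalytic state of an OEC structure or to quantify radiation-induced
photoreduction.

## The model

Mn–ligand bonds contract with oxidation, and high-spin d⁴ Mn(III)
octahedra show a Jahn–Teller axial elongation. Each six-coordinate Mn site
is therefore reduced to two features

- *E* — mean equatorial Mn–ligand bond length (Å, mean of 4),
- *A* — mean axial bond length (Å, mean of 2),

after matching the six ligands into three antipodal pairs (exhaustive
search over all 15 matchings, angular objective) and taking the longest
pair as axial. In (*E*, *A*) space the three oxidation classes cluster
around (2.18, 2.28), (1.95, 2.26) and (1.91, 2.05) Å for Mn(II), Mn(III),
Mn(IV). Training labels are corrected by k = 3 K-means clustering before
fitting either a Gaussian naive Bayes or an entropy decision-tree
classifier. For an OEC monomer, the S index follows the total Mn charge:

```
s_index = (q_Mn1 + q_Mn2 + q_Mn3 + q_Mn4) − 13     (S0..S3 ↔ 13..16)
```

with negative indices (down to S₋₅) marking over-reduced, damaged
clusters. An independent cross-check computes bond-valence sums
`v = Σᵢ exp((R₀ − Rᵢ)/B)` under each candidate state's published R₀ and
assigns the state minimizing |v − state|.

## Worked example

```r
library(mnoxstate)

## a feature table shaped like the curated small-molecule reference set
## (class counts 1734/835/107, 10% label noise), then K-means correction
tab <- gen_feature_table(mislabel_rate = 0.1, seed = 1)
rl  <- kmeans_relabel(tab, seed = 1)
round(rl$model$centers, 2)
#>        E    A
#> II  2.18 2.28
#> III 1.95 2.26
#> IV  1.91 2.05

pre  <- evaluate("dt", tab,      holdout_scheme(0.25), seed = 1)$accuracy
post <- evaluate("dt", rl$table, holdout_scheme(0.25), seed = 1)$accuracy
#> DT accuracy before relabeling: 0.82; after: 1.00

model <- fit_dt(rl$table)
head(export_dt_rules(model, digits = 4), 5)
#> if E <= 2.056:
#>   if A <= 2.152:
#>     predict IV
#>   else:
#>     predict III

## a two-monomer synthetic OEC built at the Mn(III,IV,IV,III) centres —
## the dark-adapted S1 pattern — then the full prediction pipeline
pdb <- tempfile(fileext = ".pdb")
gen_oec_file(pdb, labels = c("III", "IV", "IV", "III"), monomers = 2, seed = 1)
for (st in predict_oec(load_structure(pdb), model)) print(st)
#> <s_state> S1  Mn(III,IV,IV,III)  total charge 14
#> <s_state> S1  Mn(III,IV,IV,III)  total charge 14

## bond-valence cross-check on the first Mn site (a Mn(III) centre)
assign_bvs_oxidation(find_mn_sites(load_structure(pdb))[[1]])
#> <bvs_assignment> assigned Mn(III)
#>   state      v deviation
#> 1    II 3.3819    1.3819
#> 2   III 3.1885    0.1885
#> 3    IV 3.0978    0.9022
```

The recovered cluster centres match the class centres to 0.01 Å, label
correction lifts held-out decision-tree accuracy from 0.82 (10% label
noise) to 1.00, both monomers of the synthetic dark-state cluster come
back as S₁ with the Mn(III,IV,IV,III) pattern, and the bond-valence sum
independently lands on Mn(III) for a site built at the Mn(III) geometry.

## Command line

```sh
Rscript -e 'quit(status = mnoxstate::run_cli())' simulate --type features --out train.csv --seed 7 --mislabel-rate 0.1
Rscript -e 'quit(status = mnoxstate::run_cli())' train    --in train.csv --kind dt --out model.json --seed 7
Rscript -e 'quit(status = mnoxstate::run_cli())' simulate --type oec --out oec.pdb --labels III,IV,IV,III --monomers 2 --seed 7
Rscript -e 'quit(status = mnoxstate::run_cli())' predict  --in oec.pdb --model model.json --out report.csv
Rscript -e 'quit(status = mnoxstate::run_cli())' evaluate --in train.csv --kind gnb --scheme kfold:10 --seed 7
Rscript -e 'quit(status = mnoxstate::run_cli())' bvs      --in oec.pdb
```

Every output starts with `#` provenance lines (package version,
subcommand, options, seed) and identical invocations are byte-identical.

## Package data

- `inst/extdata/psii_sstate_predictions.csv` — reported vs predicted
  S-states for 38 photosystem II structures (2 monomers each), used by the
  report module's tests.
- `inst/extdata/bvs_params.tsv` — bond-valence R₀/B parameters for
  Mn(II/III/IV)–O/N (published literature values; editable).

See `vignettes/mnoxstate-methods.Rmd` for the full methods description,
parameter rationale, and known limitations.
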