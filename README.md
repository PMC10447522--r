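# shbligand

Detection and classification of **short hydrogen bonds (SHBs)** between
amino-acid side chains and small-molecule ligands in protein structures.

A hydrogen bond is identified by three geometric criteria — O/N
heteroatoms, donor–acceptor distance 2.3 Å ≤ R ≤ 3.2 Å, and
donor–H–acceptor angle θ ≥ 135° — and classified by distance: **SHB** for
R ≤ 2.7 Å (heteroatoms >0.3 Å closer than their van der Waals sum, where
the interaction gains covalent character), **NHB** for R ≥ 2.8 Å, with the
2.7–2.8 Å gap reported as ambiguous. Because SHBs can only be observed
directly at atomic resolution, the package also ships a predictive model:
each protein–ligand bond is described by 14 chemical and sequence features
(amino-acid charge/residue/heteroatom; ligand group charge, functional
group, pKa, pKb, logP; the 3 sequence neighbors on each side), and an
**ensemble of 10 gradient-boosted tree models**, each trained on a
class-balanced undersample with exponential loss (5000 trees, shrinkage
0.01, interaction depth chosen by 10-fold CV over 1–12), averages its
members' probabilities. A bond is called SHB when the averaged probability
is ≥ 0.870.

The audience is structural biologists and method developers who want to
flag likely SHBs in refined or predicted structures, and anyone needing a
reproducible reference implementation of the undersampling-boosting
pipeline with planted-truth synthetic benchmarks.

## Worked example

Plant three contacts of known geometry in a synthetic complex, detect and
featurize them, and score them with an ensemble trained on a synthetic
table whose SHB propensity is driven by the ligand functional group:

```r
library(shbligand)

specs <- list(plant_spec(2.50, 170),                          # hydroxyl SHB
              plant_spec(2.64, 165, lig_group = "phosphate"), # phosphate SHB
              plant_spec(3.00, 160, lig_group = "phenol"))    # phenol NHB
out <- synth_complex(specs, seed = 42, path = "demo.pdb")
s   <- place_polar_hydrogens(out$structure)
hb  <- detect_hbonds(s)
hb[, c("donor_atom", "acceptor_resname", "R", "theta", "distance_class")]
#>   donor_atom acceptor_resname    R theta distance_class
#> 1         OG              L01 2.50   170            SHB
#> 2         OG              L02 2.64   165            SHB
#> 3         OG              L03 3.00   160            NHB

ft <- build_feature_table(hb, s)
tb <- synth_feature_table(table_spec(n = 2000,
        odds_ratios = list(lig_functional_group = 9), seed = 1))
m  <- train_ensemble(tb, shb_config(n_members = 10, n_trees = 500,
                                    depth_candidates = 3, rng_seed = 1))
data.frame(group = ft$lig_functional_group,
           prob = round(predict_proba(m, ft), 3),
           class = classify(predict_proba(m, ft)))
#>            group  prob class
#> 1 alkyl_hydroxyl 0.883   SHB
#> 2      phosphate 0.636   NHB
#> 3         phenol 0.850   NHB
```

The detected geometry reproduces the planted values exactly. The
classifier's calls follow the training signal, not the geometry — the
generator made hydroxyls/phenols SHB-prone and phosphates NHB-prone, and a
probability must reach the deliberately precision-oriented 0.870 threshold
to be called SHB. Held-out evaluation of the same model:

```r
te <- synth_feature_table(table_spec(n = 2000,
        odds_ratios = list(lig_functional_group = 9), seed = 2))
evaluate_model(m, te, group_below = 1)
#> shb_evaluation: AUC 0.909
#> at threshold 0.870: precision 79.8, recall 48.2
#> top features:
#>               feature importance
#>  lig_functional_group  68.059487
#>            lig_charge  23.523060
#>                seq_p1   1.780945
#>                 Other   6.636508
```

The planted functional-group association dominates the importance table
(its correlate, the group charge, picks up the remainder), and importances
sum to 100%.

Real structures go through the same calls
(`read_structure("file.pdb")`, then select/detect/featurize), or through
the command line: `inst/cli/shbligand` provides `detect`, `featurize`,
`train`, `predict`, `evaluate`, `stats` and `simulate` subcommands.

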