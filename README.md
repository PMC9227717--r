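# mntox

Statistical toolkit for two-by-two factorial transcriptome studies of
metal toxicity, modelled on experiments in which embryos from a
heterozygous incross of a manganese-transporter mutant are split into
unexposed and MnCl₂-exposed groups, individually genotyped and profiled
by 3′-tag counting. Wild-type and heterozygous individuals are pooled as
*siblings*, homozygous mutants form the *mutant* group, giving four
conditions: sibling/mutant × unexposed/exposed.

The package is aimed at analysts who want the complete statistical chain
of such a study — differential expression, effect-type classification,
ontology enrichment and whole-brain activity mapping — as tested,
scriptable R functions that can be exercised end-to-end on synthetic
data with known ground truth.

## The model

Counts for gene *i* in sample *j* are modelled as negative binomial,

```
K_ij ~ NB(mean = s_j * q_ij,  variance = mu + alpha_i * mu^2)
log2(q_ij) = beta0_i + betaG_i * G_j + betaT_i * T_j + betaGT_i * G_j * T_j
```

with genotype indicator `G` (mutant = 1), treatment indicator `T`
(exposed = 1), median-of-ratios size factors `s_j`, and per-gene
dispersions `alpha_i` estimated by Cox–Reid adjusted maximum likelihood,
smoothed by an `a0 + a1/mu` mean–dispersion trend and shrunk towards it
under a log-normal prior. Four Wald contrasts are tested per gene, with
Benjamini–Hochberg adjustment per contrast:

| contrast         | linear combination           | comparison                           |
|------------------|------------------------------|--------------------------------------|
| `toxicity`       | `betaT`                      | exposed vs unexposed siblings        |
| `mutant_exposed` | `betaG + betaT + betaGT`     | exposed mutants vs unexposed siblings|
| `mutant`         | `betaG`                      | unexposed mutants vs unexposed siblings |
| `interaction`    | `betaGT`                     | genotype × treatment                 |

Genes are then classified into three (non-exclusive) groups:

* **Group 1, toxicity** — significant in `toxicity`;
* **Group 2, increased sensitivity** — significant in `mutant_exposed`
  but in neither single comparison; split into *synergistic* (the
  interaction is itself significant with the same sign as the total
  effect) and *additive*;
* **Group 3, mutant effect** — significant in `mutant`; split into
  *rescued* (no longer different in exposed mutants — the signature of a
  concurrent metal deficiency) and *persistent*, with
  persistent ∩ group 1 flagged as the most sensitive toxicity targets.

Companion modules provide ontology enrichment (right-sided
hypergeometric term-for-term with Holm–Bonferroni, and parent-child-union
with Bonferroni, on OBO ontologies with true-path propagation),
voxel-wise permutation mapping of registered 3D image stacks (3D median
filter, exact or Monte-Carlo label permutation, BH/FDR masks, summaries
over anatomical region atlases), 2^−ΔΔCt qPCR quantification, and
synthetic-data generators for all three data types with machine-readable
truth tables.

## Worked example

```r
library(mntox)

cfg <- sim_config(n_genes = 800, n_per_condition = 8, seed = 42,
                  class_fractions = c(null = 0.8, toxicity = 0.05,
                                      sensitivity_synergistic = 0.05,
                                      mutant_rescued = 0.05,
                                      mutant_persistent = 0.05))
sim <- simulate_counts(cfg)
de  <- run_de(sim$counts, sim$samples)
out <- classify_all(de$results, q = 0.05)
str(out$summary[c("n_group1_toxicity", "n_group2_sensitivity",
                  "n_group3_mutant", "n_rescued", "frac_rescued")])
```

```
List of 5
 $ n_group1_toxicity   : int 41
 $ n_group2_sensitivity: int 46
 $ n_group3_mutant     : int 84
 $ n_rescued           : int 44
 $ frac_rescued        : num 0.524
```

Of the 800 simulated genes, 40 carried each planted effect class: the
engine recovers 41 toxicity genes (Group 1), 46 increased-sensitivity
genes (Group 2), and 84 mutant-effect genes (Group 3, the planted
rescued plus persistent classes); 44 of the Group 3 genes are called
rescued, i.e. their expression is no longer distinguishable from
unexposed siblings once the mutants are exposed.

The same chain is available as a config-driven pipeline
(`run_de_pipeline()`, `run_voxel_pipeline()`) that writes TSV/JSON
artefacts with a checksummed manifest, and as a thin command-line
wrapper in `inst/scripts/mntox-pipeline.R`.

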