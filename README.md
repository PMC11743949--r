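# wpinjury

Hypergraph-based analysis of injury patterns in elite women's water polo.

When a national women's water polo squad introduces male-assisted female
training (MAFT) — sparring against male partners to raise confrontational
intensity — its injury profile shifts: shoulder and elbow/wrist injuries
rise with the heavier confrontational load, knee and ankle injuries fall
with reduced time treading water. `wpinjury` packages the analysis pipeline
for studying such shifts when the cohort is small (n = 26 athletes) and the
interactions are many-to-many:

* **Epidemiology.** Per-site injury proportions by training regime and
  Fisher's exact test for the regime comparison, reproducing the squad's
  published injury table exactly.
* **Hypergraphs.** Athletes are vertices; training groups (or k-nearest-
  neighbour sets in feature space) are hyperedges. The package provides the
  incidence matrix `H` with `h(v,e) = 1` iff `v ∈ e`, vertex/hyperedge
  degrees `Dv`, `De`, the clique-expansion adjacency
  `A[i,j] = Σ_e w_e h(i,e) h(j,e) / De(e)`, and the vertex-space Laplacian
  `L = D_A − A` with the smoothness functional `½·tr(XᵀLX)`.
* **Pattern analysis.** A hypergraph neural network (per-node embedding
  layer + hypergraph convolution) trained jointly with an MLP decoder under
  the reconstruction loss `Σ_j ‖a_j − p_j‖²` over hyperedge embeddings,
  with Adam (lr 0.001), early stopping (patience 10), 2-D principal-
  component visualisation and quantitative compactness statistics
  (within-group distance, silhouette).
* **Classification (rHGNN).** A graph-regularised hypergraph classifier for
  per-site injury labels, trained transductively by SGD (lr 0.01, step
  decay) on

  `J = CE(logits, y) + λ·( ½·tr(XᵀLX) + Ω(X) )`,
  `Ω(X) = α·Σ_ij A_ij‖X_i−X_j‖² + β·Σ_i‖X_i‖²`,

  with defaults λ = 0.2, α = 0.03, β = 0.005, plus MLP and RBF-SVM
  baselines, repeated stratified cross-validation (ACC/PPV/NPV/SEN/SPEC as
  mean ± sd) and the standard single-parameter ablation grid.
* **Synthetic cohorts.** Because the athlete data are confidential, a
  seeded generator emulates the study design: 26 athletes (3 centers, 3
  defensive centers, 15 perimeter players, 5 goalkeepers), 320-dimensional
  standardised features, two regimes, nine injury sites with configurable
  prevalences, class separation, regime compactness ratio and latent
  within-regime training groups.

## Worked example

```r
library(wpinjury)

# -- the squad's published injury table ------------------------------------
compare_modes(table1_fixture())
#>   site              traditional  maft pct_traditional pct_maft p_value significant
#> 1 neck                        2     1             7.7      3.8   1     FALSE
#> 2 shoulder                    9    11            34.6     42.3   0.776 FALSE
#> 3 elbow_wrist                 2     7             7.7     26.9   0.140 FALSE
#> 4 chest_back                  1     1             3.8      3.8   1     FALSE
#> 5 lumbar_sacral_hip           7     9            26.9     34.6   0.764 FALSE
#> 6 knee                       11     6            42.3     23.1   0.237 FALSE
#> 7 ankle                       4     3            15.4     11.5   1     FALSE
#> 8 forearm_ulnar               0     1             0        3.8   1     FALSE
#> 9 sternoclavicular            0     1             0        3.8   1     FALSE
```

The shoulder leads both regimes (34.6% of athletes under traditional
training, 42.3% under MAFT) and elbow/wrist injuries more than triple
(7.7% → 26.9%); at 26 athletes per regime no single site reaches two-tailed
significance at 0.05 — the p-values quantify how small this cohort is, which
is exactly why the classifier below is regularised.

```r
# -- synthetic cohort, pattern compactness, classification -----------------
cohort <- generate_cohort(simulation_config(seed = 3))
cohort
#> # Athlete cohort: 26 athletes, 320 features, 9 injury sites, 9 training groups

pat <- train_pattern_model(cohort, settings = train_settings(seed = 3))
compactness_stats(project_2d(pat$embeddings), cohort$regime)
#>   group           n mean_within_distance silhouette
#> 1 maft           13                0.816     0.781
#> 2 traditional    13                3.74     -0.0266

cross_validate(cohort, "rhgnn", seed = 3)$acc   #> "0.79690±0.0322"
cross_validate(cohort, "hgnn",  seed = 3)$acc   #> "0.77738±0.0845"
```

The MAFT group projects more compactly than the traditional group
(within-group distance 0.82 vs 3.74), mirroring the tighter, more organised
post-MAFT feature distributions the method is designed to surface, and the
structural regulariser lifts cross-validated accuracy over the
unregularised hypergraph network on the same folds.

A command-line interface wraps the same functions
(`inst/cli/wpinjury simulate|build-hypergraph|train-pattern|classify|ablate|stats`);
see `?run_cli`.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic cohorts | `simulation_config()`, `generate_cohort()`, `table1_fixture()`, `sample_injury_counts()` |
| Hypergraph core | `hypergraph()`, `build_knn_hypergraph()`, `hypergraph_degrees()`, `hypergraph_laplacian()`, `smoothness()`, `edge_space_laplacian()` |
| Network layers | `layer_params()`, `embed_nodes()`, `hyperconv_layer()`, `hgnn_forward()` |
| Pattern pipeline | `train_pattern_model()`, `aggregate_hyperedge()`, `reconstruction_loss()`, `project_2d()`, `compactness_stats()`, `structure_report()` |
| Classifier | `regularizer_config()`, `omega()`, `total_objective()`, `train_classifier()`, `cross_validate()`, `ablation_grid()` |
| Epidemiology | `confusion_metrics()`, `injury_proportions()`, `fisher_exact()`, `compare_modes()` |
| I/O and CLI | `read_cohort()`/`write_cohort()`, `read_hypergraph_json()`/`write_hypergraph_json()`, `read_injury_counts()`, `run_cli()` |

Fitted objects follow tidyverse conventions: `tidy()` returns loss traces,
`glance()` one-row fit summaries, and `autoplot()` draws loss curves,
proportion bars and metric comparisons.
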