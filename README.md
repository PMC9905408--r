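# scarscape

Quantifying the spatiotemporal architecture of the spinal cord glial scar
from spot-based spatial transcriptomics.

After spinal cord injury the lesion matures into a concentric scar: a
fibrotic core (preceded by a macrophage infiltrate in the first days)
wrapped by a microglial ring, then an astrocytic ring, inside
oligodendrocyte white matter and neuronal gray matter. Spot arrays (55-µm
spots, 100-µm hexagonal pitch, ~1–6 cells per spot) resolve this
architecture, but turning spot × gene count matrices into statements about
scar geometry and boundary signaling takes a pipeline. `scarscape` is that
pipeline, for computational biologists analyzing lesion-centered spatial
transcriptomics — together with a synthetic lesion generator with full
ground truth, so every stage is tested against planted structure.

## What it computes

* **Synthetic lesions** — hexagonal spot lattices (the default 78 × 64
  array holds 4,992 spots); time-resolved concentric domain scenes
  (3/7/14/28 dpi) with 1–6 cells per spot; negative-binomial counts with
  cell-type marker programs, planted ligand–receptor pairs and planted
  co-expression blocks.
* **Preprocessing** — spot QC (total UMI ≥ 163), log normalization
  *Ei* = log(UMI + 1), top-*n* highly-variable genes by variance, and a
  PCA + k-means domain labeler (external label tables are first-class).
* **Scar geometry** — lattice neighbor graphs; scar center (centroid of
  scar spots) and radius in µm and in spots (1.2 mm at 100-µm pitch = 12
  spots); equal-width layer bands; interface regions two spots wide along
  domain boundaries (lattice-graph BFS distance ≤ 2); cell-type
  spot-count/fraction time courses.
* **Gene-set scoring** — expression-bin-matched module scores
  (signature mean minus matched-control mean) for cell-type assignment;
  rank-based single-sample pathway activity in [−1, 1]; layer profiles of
  scores versus signed spot distance from the scar center.
* **Boundary ligand–receptor testing** — for each ordered pair of adjacent
  domains: expression-fraction filter (> 0.1 on both sides of the
  interface), mean-of-averages interaction score
  (mean ligand *Ei* in source + mean receptor *Ei* in target)/2, and a
  label-permutation p-value (proportion of permuted scores ≥ observed).
* **Co-expression modules** — Pearson correlation of HVGs, k-means on
  correlation rows (default k = 18), spatiotemporal module maps, and
  average-linkage submodules on 1 − *r* distance.

## Worked example

The `analysis/` scripts run the whole study on a simulated 30 × 30-spot
lesion, one scene per time point (`Rscript analysis/01_simulate.R` through
`analysis/06_coexpression.R`; outputs land under `results/`). Labeling the
domains and measuring the scar (`02`, `03`) prints:

```
dpi  3: 863/900 spots pass QC, 6 clusters -> 5 cell types, 99.2% agree with truth
dpi  7: 884/900 spots pass QC, 6 clusters -> 5 cell types, 98.3% agree with truth
...
scar center and radius per time point:
 time_dpi center_x_um center_y_um radius_um radius_spots
        3      1477.7      1259.0    1306.9           14
        7      1465.6      1257.6    1308.7           14
       14      1474.3      1258.4    1152.7           12
       28      1478.6      1248.1    1012.0           11
```

The called scar boundary sits ~12–14 spots from the scar center and
contracts from 7 to 28 dpi, and the fraction table shows fibroblasts
holding the shrinking core while astrocytes and microglia make up the
rings. The boundary ligand–receptor screen (`05`) recovers the five
planted pairs at their planted boundaries as the top hits among 50 decoy
pairs:

```
     pair_name source_cluster target_cluster mean_score p_value
 Sema4d_Plxnb2      astrocyte      microglia   3.177404       0
    Ptn_Plxnb2      astrocyte      microglia   3.152745       0
     Spp1_Cd44      microglia      astrocyte   2.832357       0
  Grn_Tnfrsf1b     fibroblast      microglia   2.759161       0
  Psap_Gpr37l1     fibroblast      microglia   2.746000       0
```

and the co-expression stage (`06`) isolates the planted fibrotic program:

```
8 modules over 150 HVGs; sizes: 93, 11, 10, 10, 8, 8, 8, 2
fibroblast markers concentrate in module 4 (8 of 8 markers)
module 4 mean expression by dpi: 14=0.79, 28=0.71, 3=0.58, 7=0.92
```

The same stages are available as one call, `run_pipeline(run_config(...),
out_dir)`, which writes every artifact plus a manifest (config hash, seed,
stage outputs) and is byte-reproducible from `(config, seed)`.

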