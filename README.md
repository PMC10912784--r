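# popcontext

Quantifying how a cell's **population context** — whether it sits alone, at
the edge of an epithelial colony, or embedded in its center — shapes its
response to interferon (IFN) stimulation and its protection from viral
infection.

Polarized epithelial cells keep their IFN receptors on the basolateral
membrane. A cell in the middle of a colony exposes only its apical surface
to the medium, so apically applied IFN barely reaches its receptors; an
isolated cell or a colony-edge cell stays accessible and responsive. The
package turns that biology into a reproducible analysis pipeline for
high-content imaging and surface-proteomics data, aimed at groups studying
single-cell heterogeneity in epithelial monolayers, micropatterned colonies
and related systems.

## What it computes

* **Spatial annotation** of segmented cell centroids: DBSCAN clustering,
  an angular-gap edge test, and an integer **edge degree** assigned by
  iterative peeling — degree 0 = single cell (no neighbors within the
  annotation radius `eps`), degree 1 = colony border, degree ≥ 2 = embedded.
  Formally, a core cell has ≥ `minPts − 1` neighbors within `eps`; a
  clustered cell is *edge* when the largest angular gap between bearings to
  its within-`eps` neighbors exceeds θ (default 120°); edge cells get the
  current degree *d*, are removed, and the remainder is re-examined with
  *d* + 1.
* **Responder classification** against mock-treated cells (threshold =
  99th percentile of matched mock reporter intensity), per-well
  percent-positive summaries by edge degree or position class, and the
  midrank Spearman correlation ρ between edge degree and percent-positive.
* **Radial profiles of circular micropatterns**: 14 µm rings counted
  inward from the pattern edge (6 rings + center for a 100 µm radius),
  ring-by-ring mock normalization, and a 28 µm edge-versus-center split.
* **Infected-cell counting** from a control-derived virus-channel threshold.
* **Surface-proteome polarity**: background and replicate/annotation-term
  filtering of label-free quantification (LFQ) tables, Welch t statistics
  with sample-randomization FDR, log2 apical/basolateral ratios, and the
  **apical index** AI = A / (A + B) on linear-scale side means.
* **ΔΔCt qPCR fold changes** normalized to a housekeeping gene and to the
  per-timepoint mock.
* A **synthetic-data generator** (colony fields, micropattern disks,
  degree-dependent responder labels, infection labels, LFQ tables) with
  complete ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(popcontext)

cfg <- generator_config(n_colonies = 3, n_singles = 15,
                        field_width_um = 1200, field_height_um = 1200,
                        seed = 7)
field <- generate_colony_field(cfg)
truth <- reference_annotation(field$cells, eps = 22.5)  # ground-truth degrees

treated <- assign_response_intensities(field, cfg, truth$edge_degree)
mock_cfg <- cfg; mock_cfg$seed <- cfg$seed + 7919L
mock <- assign_response_intensities(field, mock_cfg, truth$edge_degree,
                                    condition = "mock")

ann <- annotate_cells(treated$cells, annotation_params(eps = 22.5))
ann
#> Spatial annotation of 150 cells (eps = 22.50 um, min_pts = 4, theta = 120 deg)
#> position_class
#> center   edge single
#>     77     58     15

thr <- responder_threshold(mock$cells$reporter)   # 99th pct of mock: 246.9
percent_positive_by_group(treated$cells, ann, thr)
#>   well_id edge_degree n_cells n_positive percent_positive mean_intensity low_confidence
#> 1   well1           0      15         12             80.0           1003          FALSE
#> 2   well1           1      58         31             53.4            694          FALSE
#> 3   well1           2      43         26             60.5            876          FALSE
#> 4   well1           3      25          7             28.0            377          FALSE
#> 5   well1           4       9          0              0.0            105           TRUE

spearman_degree_correlation(percent_positive_by_group(treated$cells, ann, thr))
#> Spearman rank correlation (midranks, two-sided)
#>   rho = -0.9000 (|rho| = 0.9000), p = 0.0833, n = 5
```

Reading of the output: isolated cells (edge degree 0) respond most (80%
positive here, matching the generator's 0.80 calibration), and
responsiveness falls with embedding depth — the negative rank correlation.
The degree-4 bin holds only 9 cells and is flagged `low_confidence` rather
than dropped. On a single small field the correlation is noisy; the
full-scale multi-well analysis is what the acceptance script runs.

A configured end-to-end run (generate → annotate → classify → summarize,
with a manifest for reproducibility) is available via
`run_pipeline("inst/extdata/demo_config.yaml")`, or from a shell through
`Rscript inst/scripts/popcontext.R run --config <yaml>`.

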