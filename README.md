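# osteolcn

Automated segmentation and connectomics of the osteocyte
lacunar-canalicular network (LCN) in 2D confocal-style microscopy.

Osteocytes — the most abundant, mechanosensitive cells in bone — sit in
lacunae and communicate through dendritic processes running in thin
canaliculi. The integrity of this network degrades with age (fewer cells,
fewer and shorter connections, more blunted "dead-end" processes), but
quantifying it from confocal scans has traditionally required slow manual
segmentation. `osteolcn` implements the full analysis chain as a tested R
library with a thin command-line front end:

* **Thresholding segmentation** — two pipelines with shared pre/post
  stages (Gaussian pre-filter σ = 2; binary split at 70 into osteocyte and
  dendrite candidates; second noise threshold; Otsu core restricted to
  [80, 255] or Canny core with hysteresis 70/220; 3×3 closing; elementwise
  subtraction), producing a 3-class label: background 0, osteocyte 1,
  dendrite 2.
* **Evaluation** — Dice score `DSC = 2|P∩G| / (|P|+|G|)` and Jaccard index
  `IoU = |P∩G| / |P∪G|`, per class and averaged.
* **Training machinery** for pluggable per-pixel classifiers — masked
  DiceCE loss computed only over annotated pixels (partial labels),
  dendrite-label dilation, a connected-component fragmentation penalty
  (`Σ size^(-penalty_factor) × weight`), AdamW with cosine annealing and
  gradient clipping, per-class model merging, and a compact reference
  backbone (softmax head over multi-scale convolutional features).
* **Connectomics** — label mask → osteocyte graph (4×4 ellipse / 2×2 cross
  merging dilation, 8-connected components, overlap-based edges), with
  node counts, dead ends per node, connections per node = 2|E|/|V|,
  per-connection length (skeleton geodesics, √2 diagonals) and thickness
  (area / skeleton length), network diameter, and mean shortest path.
* **Group comparison** — per-metric two-sided pooled Student's t-tests at
  α = 1e-4, reported as mean ± SD.
* **Synthetic ground truth** — a seeded generator of LCN-like scenes
  (elliptical somas, curved 1.5–3 px dendrites, noise, illumination ramp,
  young vs aged topology regimes) whose planted graphs validate the whole
  chain end to end.

## Worked example

```r
library(osteolcn)

cfg   <- scene_config(seed = 42)          # 320x320 px field, 16 osteocytes
scene <- generate_scene(cfg)
scene
#> <lcn_scene> 320x320 px, 16 somas, 23 connections, 18 dead ends

label <- segment_lcn(scene$image, method = "otsu")
evaluate_label(label, scene$mask)
#> DSC 0.785 | mIoU 0.584 | osteocyte IoU 0.866 | dendrite IoU 0.303

graph <- label_to_graph(scene$mask, um_per_px = cfg$um_per_px)
network_metrics(graph)
#> Connectomics report
#>   Average nodes:                 16.00
#>   Average dead ends per node:    1.12
#>   Average connections per node:  2.88
#>   Average length of connections: 12.92 um
#>   Average diameter of connections: 0.686 um
#>   Average diameter of network:   0.670 um
#>   Mean shortest path (hops):     2.73
```

The generated scene plants 16 somas, 23 connections and 18 dead-end
stubs. The Otsu pipeline recovers osteocytes well (IoU 0.87) and thin
dendrites partially (IoU 0.30) — fixed thresholds inevitably lose the
thinnest processes, the known weakness of threshold pipelines on this
tissue. Graph extraction from the ground-truth mask recovers the planted
topology exactly (16 nodes, 2·23/16 = 2.88 connections per node); lengths
and diameters are in micrometres at the configured 0.284 µm/px.

A typical phenotype study trains the reference backbone on a few labelled
fields, segments young and aged cohorts, and compares their per-field
network metrics:

```r
aged_cfg <- degrade_to_aged(cfg, severity = 0.7)
fit <- train_backbone(feature_backbone(), training_items,
                      train_config(learning_rate = 0.1, epochs = 40))
lab <- suppress_soma_halo(predict_label(fit$backbone, fit$params, img))
compare_groups(young_reports, aged_reports, alpha = 1e-4)
```

## Command line

A thin front end over the same functions ships in `inst/scripts/lcn`:

```sh
lcn generate   --out scene --seed 7 [--aged 0.7]
lcn segment    --in scene_image.tif --method otsu --out label.png
lcn evaluate   --pred label.png --truth scene_mask.png
lcn connectome --label label.png --um-per-px 0.284 --out-report report.csv
lcn compare    --a young.csv --b aged.csv --alpha 0.0001
```

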