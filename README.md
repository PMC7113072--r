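# histocompress

Digital pathology increasingly ships whole-slide images across networks —
telepathology — and increasingly analyses them with convolutional networks.
Both pressures meet at lossy compression: how small can an image get before a
segmentation or detection model trained on pristine tissue stops working, and
before the nuclear-architecture features that downstream prognostic models
consume become unreliable?

`histocompress` implements that experiment as a reusable, fully seeded R
pipeline. Because the question is about *relative* degradation rather than
absolute scores, it runs on synthetic histology-like scenes with exact ground
truth — no slide archives required — and everything fits one CPU.

The pipeline is train-on-clean / test-on-compressed:

* **Scenes** — `generate_scene()` renders textured elliptical nuclei (plus
  stromal clutter and uneven illumination) over an eosin-like background for
  three tasks: nuclei segmentation, lymphocyte detection, tumour-region
  segmentation. Object counts are Poisson in the cell density; every scene is
  a deterministic function of its seed. `write_scene()`/`read_scene()` store
  scenes losslessly (PNG / 16-bit TIFF / CSV / JSON manifest).
* **Codecs** — JPEG via quality scores; JPEG2000 via PSNR targeting:
  `compress_to_target_psnr()` bisects the codec's rate parameter until the
  round-trip PSNR = `10·log10(255²/MSE)` lands within ±0.5 dB of the target
  (100 dB = bit-exact lossless). Ratios are `compressed bytes / (H·W·3)`.
* **Classifier** — a compact patch CNN (two conv+pool blocks, ~17k
  parameters) trained with dihedral augmentation; dense inference produces a
  per-pixel probability map.
* **Metrics** — pixel F1, pixel AUC (Mann–Whitney pair statistic), and
  detection F1 over a one-to-one Hungarian matching of predicted to true
  centres within a radius.
* **Features** — 77 first-order statistics of nuclear architecture over five
  families (Voronoi 12, Delaunay 8, MST 4, nuclear morphology/neighbourhood
  27, cell-cluster subgraph 26), plus a compression-level × feature
  stability matrix of max-normalised relative differences in [0, 1].
* **Orchestration** — `run_sweep()` runs the whole protocol from one config
  and seed, returns tidy tibbles (`tidy()`, `glance()`) and ggplot2 figures
  (`autoplot()`), and writes CSV/JSON/PNG artifacts.

JPEG2000 encoding/decoding runs through a bundled helper script over the
OpenJPEG bindings of the Python imaging library (`python` with Pillow must be
on the PATH); there is no R-native JPEG2000 codec.

## A worked example

```r
library(histocompress)

cfg <- sweep_config(
  task = "nuclei", n_train = 8, n_test = 3,
  scene = scene_params(width = 128, height = 128),
  ladder = c(18, 20, 22, 25, 30, 35, 40, 100),
  train = train_config(epochs = 6, patches_per_scene = 200),
  seed = 1)
res <- run_sweep(cfg)
glance(res)
#> # A tibble: 2 × 5
#>   metric    clean_value most_compressed_value spearman_psnr_ratio task
#>   <chr>           <dbl>                 <dbl>               <dbl> <chr>
#> 1 pixel_auc       0.991                 0.938               0.990 nuclei
#> 2 pixel_f1        0.901                 0.639               0.990 nuclei
```

Reading: on clean test scenes the model segments nuclei at F1 0.90; after
compressing the same test images to the 18 dB PSNR floor (fractions of a
percent of the raw byte size) the F1 collapses to 0.64, while ratio and PSNR
are almost perfectly rank-correlated across the ladder. The per-level curves
(`res$curves`, `autoplot(res)`) show the shape: F1 is nearly flat from
lossless down to ~22 dB, then drops sharply — compression is close to free
until it suddenly is not. `autoplot(res$stability)` draws the feature
heat map: cell-cluster subgraph statistics destabilise at moderate
compression while Voronoi/Delaunay/MST summaries stay comparatively stable.

Single pieces are usable on their own:

```r
sc  <- generate_scene(scene_params(width = 256, height = 256, seed = 7))
enc <- compress_to_target_psnr(sc$image, target = 30)   # ± 0.5 dB
enc$record
#> # A tibble: 1 × 7
#>   codec    control achieved_psnr compressed_bytes raw_bytes ratio converged
#>   <chr>      <dbl>         <dbl>            <dbl>     <dbl> <dbl> <lgl>
#> 1 jpeg2000      30          29.6            22400    196608 0.114 TRUE
```

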