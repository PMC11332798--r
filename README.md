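# wbcnet

Four-class white-blood-cell (leukocyte) image classification in R, built
for auditability: every stage — cell extraction, network, training,
metrics, and explanation — is implemented in plain, testable code.

Differential white-cell counts rest on recognizing eosinophils,
lymphocytes, monocytes and neutrophils in stained blood smears, which
differ chiefly in nuclear morphology (bilobed; large and round; kidney
shaped; 2–5 lobes). `wbcnet` provides:

* **Cell extraction** (`run_pipeline()`): pad → color-band threshold →
  binary erosion → dilation → largest-contour selection → contour masking
  → crop and bilinear resize to 120×120. The threshold keeps pixels whose
  channels lie in the band (80, 80, 180)–(180, 170, 245); morphology uses
  a 3×3 elliptical structuring element with 2+2 iterations, and every knob
  is a `pipeline_config()` field.
* **Classifier** (`network_spec()`, `build_network()`, `train_network()`):
  a declarative six-block CNN — two standard 16-filter convolutions, then
  five depthwise-separable blocks with batch normalization — and a
  512/128/64 tanh head with dropout 0.7/0.5/0.3 under a 4-way softmax.
  Weights are Glorot uniform, `W ~ U(±√(6/(n_in+n_out)))`; training is
  mini-batch Nadam,
  `θ ← θ − η/(√v̂+ε)·(β₁m̂ + (1−β₁)g/(1−β₁ᵗ))`,
  with the full-scale regime η = 1e-5, batch 64, 30 epochs. Forward and
  backward passes are hand-implemented on BLAS and checked against finite
  differences.
* **Evaluation** (`compute_metrics()`, `roc_auc()`): confusion matrix,
  per-class and macro precision/recall/F1 (`P = TP/(TP+FP)`,
  `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`), and one-vs-rest ROC-AUC whose
  trapezoid sweep equals the midrank Mann–Whitney statistic.
* **Explainability** (`grad_cam()`, `grad_cam_pp()`, `lime_explain()`,
  `kernel_shap()`, `render_overlay()`): from-scratch Grad-CAM and
  Grad-CAM++, a LIME image explainer over superpixels with a weighted
  ridge surrogate, and Kernel SHAP with the exact efficiency identity
  (exact Shapley values up to 12 segments).
* **Synthetic data** (`smear_spec()`, `render_smear()`,
  `generate_dataset()`): seeded blood-smear-like images with the four
  nuclear morphologies and exact ground-truth masks, so the whole stack is
  testable without downloading any dataset.

## Worked example

```r
library(wbcnet)

# one synthetic lymphocyte, extracted by the full chain
sm  <- render_smear(1, smear_spec(seed = 42))
seg <- run_pipeline(sm$image)
seg
#> <wbc_segmentation> status: ok  crop: 120x120  bbox: [74, 75, 167, 168)
bbox_iou(seg$bbox, sm$truth$nucleus_bbox + 10)
#> [1] 0.797

# desk-scale experiment: 100 images/class, 48 px crops, 3-block network
ds  <- synthetic_cell_dataset(100, smear_spec(image_size = 120),
                              pipeline_config(target_size = 48), seed = 7)
man <- data.frame(idx = seq_along(ds$y), label = ds$y)
spl <- stratified_split(man, split_plan(seed = 7))
net <- build_network(scaled_network_spec(48), seed = 7)
fit <- train_network(net, ds$x[,,,spl$train$idx], ds$y[spl$train$idx],
                     ds$x[,,,spl$val$idx],   ds$y[spl$val$idx],
                     training_params(learning_rate = 1e-3, batch_size = 32,
                                     epochs = 15, seed = 7))
fit
#> <wbc_net> trained 15 epochs; best val acc 1.000 (epoch 9)
#> <wbc_network> 3 blocks, input 48x48x3, 4 classes, 75276 parameters

evaluate_network(fit, ds$x[,,,spl$test$idx], ds$y[spl$test$idx])
#> confusion matrix (rows = actual, columns = predicted):
#>             predicted
#> actual       EOSINOPHIL LYMPHOCYTE MONOCYTE NEUTROPHIL
#>   EOSINOPHIL         15          0        0          0
#>   LYMPHOCYTE          0         15        0          0
#>   MONOCYTE            0          0       15          0
#>   NEUTROPHIL          0          0        0         15
#> accuracy 1.0000 | macro P 1.0000 R 1.0000 F1 1.0000
#> per-class AUC: EOSINOPHIL 1.0000, LYMPHOCYTE 1.0000, MONOCYTE 1.0000, NEUTROPHIL 1.0000
#> macro-average AUC: 1.0000

# why did it decide that? saliency for one test image
img <- ds$x[,,,spl$test$idx[1]]
att <- grad_cam(fit, img, ds$y[spl$test$idx[1]])
att
#> <wbc_attribution> method gradcam, class 0, 48x48 map in [0.00, 1.00]
heat <- render_overlay(img, att)        # jet heat blended over the cell
```

The IoU line scores how well the detected crop box matches the known
nucleus box (1 is perfect agreement); the evaluation report shows the
classifier separating all four synthetic morphologies, and the final
attribution is a 48×48 importance map over the crop, warm where the
network's evidence for the predicted class concentrates.

A command-line front end over the same functions ships in
`inst/scripts/wbcnet.R`
(`generate` / `preprocess` / `split` / `train` / `evaluate` / `explain` /
`all`), and `run_end_to_end()` drives the whole flow into one directory
with a provenance file.

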