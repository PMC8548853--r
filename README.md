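# poreclass

Raw-signal nanopore read classification and Read-Until throughput
modelling in R.

## The problem

Nanopore sequencers report a raw ionic-current time series (a
"squiggle") while each DNA molecule translocates the pore. Deciding
*what* a molecule is — host or microbe, target locus or background —
normally requires basecalling and alignment against a reference
database. But the sequencer can also *reject* a molecule mid-read
(Read-Until adaptive sampling): reversing the pore voltage ejects it and
frees the pore for another capture. A classifier that decides from the
first second of raw signal, with no basecaller and no reference,
turns a standard flow cell into a targeted-sequencing instrument — for
example depleting host DNA from a metagenomic sample or enriching a
repeat family.

`poreclass` implements that classifier and everything needed to study
it end to end without access to a sequencer:

* **signal I/O** — single- and multi-read FAST5 (HDF5) containers, DAC →
  picoampere calibration (`(raw + offset) · range / digitisation`),
  TSV label manifests;
* **preprocessing** — skip the adapter-dominated prefix (1500 samples
  for training, 1000 at inference), keep a 3000-sample window (≈ 300
  bases at 450 bp/s and 4 kHz), replace extreme samples with a modified
  z-score above 3.5 (`0.6745·|x − x̃| / MAD`), then normalize by the
  window's median and median absolute deviation;
* **the classifier** — a compact 1D residual bottleneck network: a
  20-channel stem convolution (kernel 19, stride 3), four layers of two
  bottleneck blocks with ×1.5 channel growth (20/30/45/68) and stride 2
  per block, global average pooling, and a softmax head. The default
  model stores **174.4 KB** of 32-bit parameters — small enough for the
  published 304 KB footprint bound with half the budget to spare.
  Forward, backprop and Adam are implemented in the package (BLAS
  matmul + C++ kernels); training follows the published recipe
  (cross-entropy, Adam, lr 1e-3, Kaiming initialisation, batch norm in
  every block);
* **attribution** — integrated gradients along a straight baseline path
  against the pre-softmax score, satisfying the completeness axiom;
* **a seeded squiggle simulator** — k-mer pore models (levels 60–120 pA,
  per-k-mer noise 0.5–3 pA), geometric dwells averaging
  `sampling_rate/speed` ≈ 8.9 samples per base, an adapter-like noisy
  prefix of 1000–1500 samples, per-read gain/offset distortion and DAC
  quantisation. Classes can differ by template sequences, GC skew, or a
  methylation-like level shift Δ on a k-mer subset (default: CG-containing
  k-mers, Δ in robust z-units of the level table);
* **the Read-Until throughput model** — closed-form expected bases and
  wall time to collect a fixed number of target reads with and without
  classifier-driven ejection, a parameter-grid sweep, and a Monte-Carlo
  oracle with standard errors.

## The throughput model at a glance

For mean target read length $\bar z$, mean non-target length $\bar h$,
target concentration $c$, classifier rates TPR/TNR, and decision-point
bases $b_d = \text{speed}\cdot(t_{signal}+t_{decide})$:

$$B_{\text{without}} = \frac{N}{c}\left(c\,\bar z + (1-c)\,\bar h\right),\qquad
B_{\text{with}} = \frac{N}{c\,\mathrm{TPR}}\Big(c\,[\mathrm{TPR}\,\bar z + (1-\mathrm{TPR})\,b_d] + (1-c)\,[(1-\mathrm{TNR})\,\bar h + \mathrm{TNR}\,b_d]\Big)$$

Times divide bases across `speed × pores`, and the Read-Until arm
additionally pays `t_eject` per ejected read and `t_decide` per read.
At $\bar h/\bar z = 20$, $c = 0.1$, TPR = TNR = 0.9, 450 bp/s, 500
pores, $t_{signal} = 1$ s, $t_{decide} = 0.8$ s the model predicts a
**7.7× base-pair** and **7.1× time** gain.

## Worked example

```r
library(poreclass)

## simulate a labelled two-class corpus (methylation-like level shift)
cfg <- sim_config(n_per_class = 300, delta = 1.0, seed = 42)
sim <- simulate_squiggles(cfg)
sim$squiggles[[1]]
#> <squiggle> background_00001: 13208 samples @ 4000 Hz, label=background

## fixed-length normalized windows: skip adapter, take 3000 samples
pp <- preprocess_squiggles(sim$squiggles, skip = 1500, length = 3000)
dim(pp$windows)
#> [1]  600 3000

## stratified split and model fit
sp  <- make_splits(data.frame(read_id = rownames(pp$windows),
                              label = pp$labels), seed = 1)
ix  <- function(m) match(m$read_id, rownames(pp$windows))
fit <- porenet(pp$windows[ix(sp$train), ], pp$labels[ix(sp$train)],
               control = train_control(batch_size = 16, epochs = 3, seed = 1),
               x_val = pp$windows[ix(sp$val), ], y_val = pp$labels[ix(sp$val)])
fit
#> Raw-signal read classifier (background vs target)
#>   trained 3 epoch(s), lr 0.001, batch 16; best epoch 3 (val accuracy 0.900)
#>   174.4 KB of parameters; input 3000 samples

## held-out metrics
pred <- data.frame(read_id = sp$test$read_id,
                   p_target = predict(fit, pp$windows[ix(sp$test), ])[, "target"],
                   pred  = as.character(predict(fit, pp$windows[ix(sp$test), ],
                                                type = "class")),
                   truth = pp$labels[ix(sp$test)])
compute_metrics(pred, positive_class = "target")
#> Classification metrics (positive class: target)
#>   accuracy 0.9333 | TPR 0.9000 | TNR 0.9667 | precision 0.9643 | AUROC 0.9589
#>   TP 27  FP 1  TN 29  FN 3

## expected Read-Until enrichment at this operating point
expected_totals(throughput_params(tpr = 0.9, tnr = 0.9))
#> Read-Until throughput model (zbar 3000 bp, hbar 60000 bp, c 0.1, TPR 0.9, TNR 0.9, t_eject 0.5 s)
#>   bases: 5.430e+08 without vs 7.038e+07 with  -> gain 7.72x
#>   time:  2.413e+03 s without vs 3.397e+02 s with -> gain 7.10x
```

The held-out accuracy here comes from a deliberately small corpus (300
reads per class, three epochs); the full-scale study conditions — 2000
reads per class — are exercised by the acceptance suite and reach the
0.95 accuracy bound, with a label-permuted refit staying at chance.

A thin command-line front end wrapping the same functions ships in
`inst/cli/poreclass.R`, with subcommands `sim`, `preprocess`, `train`,
`classify` and `throughput`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/poreclass.R", package = "poreclass"))')
Rscript $CLI sim --out toy.fast5 --n-per-class 100 --seed 3
Rscript $CLI preprocess --in toy.fast5 --out windows.h5 --skip 1500 --length 3000
Rscript $CLI train --windows windows.h5 --manifest toy.fast5.manifest.tsv \
        --out model.rds --epochs 3 --batch-size 16
Rscript $CLI classify --model model.rds --in toy.fast5 --out preds.tsv
Rscript $CLI throughput --ratio 10,20 --c 0.05,0.1
```

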