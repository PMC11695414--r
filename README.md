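# eegfuse

Cross-modal attention fusion of EEG and video for sequence
classification, in pure R.

## What this is for

Experiments that record a subject simultaneously with multichannel EEG
(a `T x d` matrix of scalp potentials) and a synchronized camera (a
`T x h x w x c` frame stack) and need a per-time-step class label —
an action, a movement phase, a cognitive state.  Neither stream
suffices alone, so the package implements a two-stream attention
classifier plus everything required to test it end-to-end on synthetic
data with planted signal: generators, training loop, metrics, ablation
harness, EDF/CSV/dense-array I/O and a CLI.

## The model

For hidden states `H` (from a temporal convolution over the EEG, and
from per-pixel spatial attention pooling over each video frame),
scaled dot-product attention produces per-step context vectors
`c_t = sum_j alpha_{t,j} h_j` with
`alpha_{t,j} = softmax_j(q_t . k_j / sqrt(k))`.  The two context
streams are projected to a shared width `d_f` and fused by a
cross-modal attention block,

    alpha_cross[t, j] = softmax_j( c_eeg[t] . c_vid[j] )
    c_cross[t]        = sum_j alpha_cross[t, j] * (c_eeg[j] + c_vid[j])

followed by a softmax head and per-step cross-entropy.  Training uses
Adam with decoupled weight decay, a cosine cyclic learning rate with
warm restarts, global gradient-norm clipping (`g / max(1, ||g||/tau)`)
and early stopping.  All backpropagation is analytic and verified
against numerical gradients.  Ablation builders remove the cross-modal
block, the adaptive attention, or the entire EEG stream.

## Worked example

```r
library(eegfuse)

spec  <- synth_spec(n_sequences = 120, T = 32, d = 8, h = 16, w = 16,
                    n_classes = 2, regime = "redundant", snr = 2, seed = 42)
data  <- generate_synthetic(spec)
split <- holdout_split(data, c(0.7, 0.15, 0.15), seed = 42)   # 84 / 18 / 18

model <- build_model(tiny_config(T = 32), "full", seed = 42)
model
#> <eegfuse_model> variant=full, 8194 parameters

fit <- train_model(model, data, split, tiny_train_config(seed = 42,
                                                         max_epochs = 25))
rep <- evaluate_model(fit$model, data, split$test)
rep
#> <metric_report> (macro averaging) acc=0.9444 recall=0.9444 f1=0.9443 auc=1.0000
```

On 120 synthetic sequences whose class is planted redundantly in both
streams (EEG carrier 4 vs 30 Hz at amplitude 2 over unit noise; a
bright blob heading right vs left), 25 epochs reach 94% held-out
accuracy with 8,194 parameters and ~554k MACs per forward pass
(`count_parameters()` / `estimate_flops()` report both).

The same pipeline from the command line:

```sh
Rscript -e 'eegfuse::cli()' simulate --spec spec.json --out data/ --seed 1
Rscript -e 'eegfuse::cli()' train    --data data/ --config run.json --out run/ --seed 1
Rscript -e 'eegfuse::cli()' evaluate --checkpoint run/checkpoint.json --data data/ --out eval/
Rscript -e 'eegfuse::cli()' ablate   --spec spec.json --config run.json --seeds 5 --out abl/
```

Every output directory receives a `manifest.json` (config snapshot,
seed, input MD5s, package version); re-running `train` from the same
manifest reproduces `record.csv` and `checkpoint.json` byte-for-byte.

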