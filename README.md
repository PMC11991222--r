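# habitminer

Activity recognition and habit mining from ambient smart-home sensor
streams, for researchers in digital health and ambient assisted living.

A single resident's home emits a stream of timestamped binary-sensor
events (motion ON/OFF, doors OPEN/CLOSE, periodic temperature readings) in
the CASAS text dialect. `habitminer` answers two questions about that
stream:

1. **What is the resident doing right now?** Events are tokenized
   (`"M011ON"`), frequency-index encoded, and cut into sliding
   sensor-event windows (SEW) of the `W` most recent events; a
   1-D U-Net over learned 64-d token embeddings labels every window with
   an activity of daily living (FCN and LSTM baselines included, each
   with a one-hot ablation variant). Scoring uses weighted F1 and
   balanced accuracy under a stratified 70/30 split with 3-fold
   cross-validation and early stopping.
2. **What are their habits?** Classified windows collapse into behavior
   instances, itemized as (activity, hour bin) in one transaction per
   day. A from-scratch FP-Growth mines frequent itemsets
   (support(X→Y) = |T(X∪Y)|/|D|), rules are kept at
   confidence(X→Y) = |T(X∪Y)|/|T(X)| ≥ min_conf, and a **temporal gap
   filter** then discards rules whose antecedent and consequent are
   separated by a median gap above `max_gap` (default 30 min):
   behaviors that co-occur daily but hours apart are frequent itemsets,
   not habits. Mined habits are scored by precision = TP/(TP+FP) against
   planted ground truth.

A deterministic synthetic smart-home simulator (five ADLs, eight sensors,
planted short-gap habits and long-gap decoy pairs, noise) generates
CASAS-format logs with per-event ground truth, so every stage is testable
without external data. Real CASAS logs are read by the same I/O layer.

## A worked example

```r
library(habitminer)
cfg <- pipeline_config(out_dir = "run1", seed = 1)   # default 60-day scenario
res <- run_pipeline(cfg)

res$eval_report
#> eval_report: weighted F1 99.20, balanced accuracy 98.94 (n = 3769)

nrow(res$rules); nrow(res$habits)
#> [1] 286
#> [1] 27

res$rule_eval_before$precision; res$rule_eval_after$precision
#> [1] 0.01048951
#> [1] 0.1111111
```

Reading: the depth-scaled U-Net labels held-out windows almost perfectly;
mining the classified stream at support/confidence 0.8 yields ~300 rules
(every split of every frequent itemset over a day's co-occurring
activities); the 30-minute gap filter keeps ~27, including all three
planted habits (sleep→toilet, meal-prep→eating, relax→toilet) while
rejecting both long-gap decoys, so precision rises by an order of
magnitude with no true positive lost. Absolute precision stays modest by
construction — exact-match scoring counts every multi-item side-rule as a
false positive; the filter's job is the direction of the change.

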