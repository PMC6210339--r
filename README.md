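# cavr — dictionary-of-motions classification for activities with variations

`cavr` classifies complex, heterogeneous human activities — eating, mopping,
making a phone call — recorded as quaternion body-pose time series, in the
presence of wide within-class variation (left vs right hand, optional steps,
different order, speed and duration). It is aimed at wearable/motion-capture
activity-recognition researchers who need a classifier that generalizes to
*unseen variants* of an activity after training on only a few.

## The method

A pose is nine body-segment orientations as unit quaternions (a
36-dimensional vector per frame); an activity example is a pose sequence.
Training:

1. segment every example with windows of 0.5/1/1.5/2 s, tiled at start
   offsets of 0%, 25% and 50% of the window size, all resampled to a common
   base length;
2. cluster each activity's windows with Euclidean k-means; drop clusters
   with ≤ 5 windows; resolve overlaps longest-first within each recording;
3. cluster all surviving centers again into a **motion dictionary** (distinct
   motions with IDs, radii and provenance);
4. represent each example by a log-normalized tf-idf motion histogram (stop
   list: top 5% most frequent motions) and a smoothed first-order transition
   matrix.

Inference encodes an observation by greedy longest-first matching against
the dictionary (match ⇔ distance ≤ τ · motion radius) and scores it against
every training example with

    cost = histDiff / seqProb,
    seqProb = Pr(m1) · Π Pr(m_i | m_(i-1)),

where histDiff is the Euclidean distance between tf-idf histograms. The
label with the lowest example-averaged cost wins.

The package also provides the dataset-profiling metrics **Complexity** (sum
of distances between a recording and its whole-second circular shifts) and
**Variation** (mean pairwise distance between length-normalized examples),
evaluation protocols (leave-one-out, repeated subject holdout,
variation-narrowed split), a deterministic synthetic pose-data generator
with planted motion primitives, and a `cav` command-line interface
(`simulate`, `metrics`, `train`, `infer`, `eval`).

## Worked example

```r
library(cavr)

gen <- generate_dataset(n_activities = 4, n_subjects = 6,
                        variation_level = 0.2, frame_rate = 10, seed = 42)
cfg <- cav_config(base_len = 8L, n_init = 2L, seed = 1L)
model <- train_model(gen$dataset, cfg)
model
#> <cav_model> 60 motions, 24 training examples, 4 activities

classify(gen$dataset$recordings[[1]], model)$predicted_label
#> [1] "activity1"

cm <- evaluate_loocv(gen$dataset, cfg)
cm
#> <cav_confusion> overall accuracy 79.17% (3.17-times chance for 4 classes)
#>            predicted
#> truth       activity1 activity2 activity3 activity4
#>   activity1    100.00         0      0.00      0.00
#>   activity2     33.33        50      0.00     16.67
#>   activity3      0.00         0     66.67     33.33
#>   activity4      0.00         0      0.00    100.00
```

On this tiny six-subject demo the classifier confuses the classes that
share motions (activity2 with its neighbor activity1), which is exactly
the failure mode the method predicts; accuracy rises with more subjects —
the full-scale acceptance run (8 activities x 15 subjects) reaches 84% in
leave-one-out at low variation.

(Printed numbers are from this exact script; `generate_dataset` is fully
reproducible from its seed.) The confusion matrix rows are true activities,
columns predictions, in row-normalized percent; `overall_accuracy` is the
diagonal mass, and the chance ratio divides it by 100/K for K classes.

The same pipeline from the shell:

```sh
cav simulate --out data/ --seed 42
cav metrics  --dataset data/manifest.json
cav train    --dataset data/manifest.json --config run.yaml --out model.json
cav infer    --model model.json --dataset data/manifest.json --out pred.csv
cav eval loocv --dataset data/manifest.json --out report.json
```

(`cav` is installed under `<library>/cavr/exec/cav`.)

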