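# chidt

Donor splice-site prediction from short GT-anchored sequence windows,
using a decision table built from chi-square-compressed contingency
tables.

## The problem

Canonical introns start with the dinucleotide GT (the GT–AG rule), but
decoy GTs vastly outnumber true donor sites: a genome scan yields
hundreds of false candidates per true one, and labeled benchmarks
inherit the same skew (thousands of true sites against hundreds of
thousands of false ones). Most classifiers trained on such data buy
specificity by sacrificing nearly all sensitivity. `chidt` is for
computational biologists who need a donor-site predictor that (a) works
from a very short context — an 11-bp window, 3 nt upstream and 8 nt
downstream of the GT, the GT excluded — and (b) stays sensitive when
trained on extremely imbalanced data, with no tuning parameters beyond a
single significance threshold.

## The method

Every window is encoded as 27 features: 11 positional features (the base
at each offset, written P-3..P-1, P+1..P+8) and 16 compositional
features (the count of each dinucleotide in the window, 0..10).

1. **Compression.** For a feature within any subset of the data, a 2 × r
   contingency table counts positives and negatives per status value.
   Candidate column merges are scored by the Pearson statistic of the
   merged table; the best merge is kept only if a local 2 × 2 chi-square
   test finds the two columns class-indistinguishable (p ≥ α, default
   0.01), otherwise compression stops. Ordinal (count) features may only
   merge adjacent values.
2. **Feature introduction.** Starting from one cell, features are
   introduced iteratively: candidates must retain ≥ 2 status groups in
   some cell after compression; among candidates with information gain
   above the candidates' mean, the highest gain ratio
   (Gain(D, X) / IV(X)) wins; its per-cell groups split the cells. The
   surviving cells are conjunctive rules such as
   `(P+3=A)&(P-1=ACT)&(GT=012)`.
3. **Balancing.** The rules' negative counts b_k are multiplied by
   θ = N+/N−, equalizing the class mass of the two rows of the decision
   table.
4. **The ±1 decision.** A new window matches exactly one rule k; the
   whole-table Pearson statistic is computed once with a_k + 1 and once
   with b_k + 1, and the window is called positive iff
   χ²₊ > χ²₋. The difference χ²₊ − χ²₋ is a continuous score for
   ROC/PR analysis.

Evaluation utilities cover SN = TP/(TP+FN), SP = TN/(TN+FP), MCC, the
class-skew-invariant Q9 index, and ROC / precision–recall curves with
the nonlinear (count-space) PR interpolation. A seeded synthetic-data
generator produces benchmark-shaped records (140 nt, GT at 71–72) from a
donor-consensus positional model, plus a 1% indel mutator for
sequencing-error robustness experiments, so the whole pipeline is
testable offline.

## Worked example

The package reproduces the classic two-feature worked example: 87
positive and 1687 negative training samples partitioned by position −1
(groups {A,C,T}, {G}) and position +3 (groups {A,T}, {G,C}) into four
rules with positives (38, 12, 26, 11) and negatives
(184, 1026, 289, 188). A true donor with G at both positions matches
rule 4:

```r
library(chidt)
fx <- worked_fixtures()
part <- tibble::tibble(
  rule = 1:4,
  conditions = list(list(`P-1` = c("A","C","T"), `P+3` = c("A","T")),
                    list(`P-1` = c("A","C","T"), `P+3` = c("G","C")),
                    list(`P-1` = "G",            `P+3` = c("A","T")),
                    list(`P-1` = "G",            `P+3` = c("G","C"))),
  pos = fx$table_imbalanced[1, ], neg = fx$table_imbalanced[2, ])
sample4 <- tibble::tibble(`P-1` = "G", `P+3` = "C")

classify_samples(sample4, build_decision_table(part, balanced = FALSE))
#> # A tibble: 1 × 5
#>    rule chi2_pos chi2_neg  score label
#>   <int>    <dbl>    <dbl>  <dbl> <chr>
#> 1     4     109.     110. -0.838 negative

classify_samples(sample4, build_decision_table(part, balanced = TRUE))
#> # A tibble: 1 × 5
#>    rule chi2_pos chi2_neg score label
#>   <int>    <dbl>    <dbl> <dbl> <chr>
#> 1     4     46.2     45.9 0.241 positive
```

On the raw (imbalanced) table the true site is wrongly rejected
(χ²₊ = 109.2 < χ²₋ = 110.1); after θ = 87/1687 reweighting the same
site is correctly accepted (46.2 > 45.9). This is the entire point of
the balanced table.

An end-to-end run on synthetic data — simulate a 1:10 training set and a
balanced test set, fit, predict, score:

```r
pl <- run_pipeline(n_pos = 200, n_neg = 2000, n_test = 300, seed = 42)
pl$model
#> <chidt_model: 52 rules from 19 introduced features (balanced table)>
#>   window: -3..+8 (GT excluded), alpha = 0.01
#>   training: 200 positive / 2000 negative, theta = 0.1
dplyr::select(pl$metrics, sn, sp, mcc, q9, auc_roc, auc_pr)
#> # A tibble: 1 × 6
#>      sn    sp   mcc    q9 auc_roc auc_pr
#>   <dbl> <dbl> <dbl> <dbl>   <dbl>  <dbl>
#> 1 0.733 0.953 0.704 0.809    0.93  0.933
```

Here `sn`/`sp` are the fractions of true/false donor sites called
correctly on the held-out balanced set, `q9` the skew-invariant global
accuracy, and the AUCs the areas under the ROC and precision–recall
curves of the continuous score. (At this deliberately small training
size sensitivity is modest; it climbs above 0.9 with a few thousand
training positives and a stronger motif, as the test suite's property
checks demonstrate.) `tidy(pl$model)` lists the fitted rules;
`autoplot(pl$model)` plots per-rule class mass;
`predict(pl$model, newdata)` classifies new windows, and
`scan_sequences()` applies the model to every GT candidate in genomic
FASTA.

A thin command-line front end over these functions ships in
`inst/exec/chidt` (subcommands `simulate`, `mutate`, `train`, `predict`,
`scan`, `evaluate`, `inspect`).

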