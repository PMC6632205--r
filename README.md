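# picrf — precursor-induced CRFs for clinical named entity recognition

Clinical narratives describe related events: a *test* is ordered because
of a *problem*, a *treatment* follows the test.  The entities carrying
this structure are usually separated by several non-entity words, so a
first-order linear-chain CRF — the workhorse of named entity recognition
(NER) — never sees the dependency between them: from a label sequence
`[A, O, …, O, B]` it learns only the adjacent transitions `(A, O)`,
`(O, O)`, `(O, B)`.

`picrf` implements the **precursor-induced CRF (pi-CRF)**: a first-order
chain whose non-entity states remember the class of the most recent
preceding entity.  A deterministic label induction rewrites each outside
label `O` as `c[O]+` (precursor class `c`) or `O[O]+` (no precursor
yet), so `[A, O, …, O, B]` becomes `[A, A[O]+, …, A[O]+, B]` and the
ordinary first-order transition `(A[O]+, B)` *is* the long-distance
dependency, propagated across the gap one step at a time.  With the
usual CRF

$$p(y\mid x) = \frac{1}{Z(x)}\prod_{t=1}^{T}
  \exp\Big\{\sum_k \theta_k f_k(y_t,y_{t-1},x_t)\Big\}$$

nothing else changes: training (L-BFGS, l2 penalty
$-\sum_k \theta_k^2/2\sigma^2$) and Viterbi decoding run unmodified on
the expanded state set.  To avoid the sparsity the induction would
create, all outside states share one observation parameter per symbol
(many-to-one binding), so the pi-CRF has exactly as many observation
parameters as the plain first-order model while adding only one state
per entity class (8 → 11 states for three IOB2 classes, versus 64 for a
second-order CRF).

The package provides:

* `crf_fit()` — one fitting front end for four variants: `"first"`
  (first-order baseline), `"pi"`, `"first_induced"` (the no-sharing
  ablation), `"second"` (pair-expanded second-order baseline); with
  `predict`, `summary`, `coef`, `logLik` and `plot` methods;
* CoNLL token-per-line corpus I/O (`read_conll`, `write_conll`), inline
  bracket-annotation parsing (`parse_bracketed`), IOB2 repair and span
  extraction;
* entity-level exact-match evaluation on whole and multi-entity
  ("distanced") sentences, inter-entity gap profiling and cumulative
  recall-by-distance curves;
* a synthetic clinical-corpus generator (`synth_corpus`) with separated
  entities, precursor-dependent entity classes and ambiguous surface
  vocabulary, so everything is testable without restricted clinical
  data;
* a command-line driver (`inst/cli/picrf.R`) with `synth`, `train`,
  `predict`, `eval` and `profile` subcommands.

## Worked example

Parse an annotated sentence, measure the inter-entity gap, then fit and
score models on synthetic data:

```r
library(picrf)

sch <- label_scheme(c("problem", "test", "treatment"))
s <- parse_bracketed(
  "With [intravenous hydration]_treatment_ [the BUN]_test_ and", sch)
gap_distances(s)
#>   precursor     class gap
#> 1    single treatment  NA
#> 2 treatment      test   0
```

The first entity has no precursor ("single"); the second follows it at
gap 0 (no non-entity token between them).

```r
cfg <- synth_config()                      # 3 classes, 200 sentences,
train <- synth_corpus(cfg, seed = 1)       # median gap 3, ambiguous
test  <- synth_corpus(cfg, sentences = 100, seed = 2)   # entity surfaces

m <- crf_fit(train, variant = "pi")
summary(m)
#> precursor-induced CRF
#>   entity classes : problem, test, treatment
#>   states         : 11 (start included)
#>   parameters     : 2985 (50 transition + 2935 observation; 1874 symbols)
#>   sigma          : 10
#>   training       : 200 sentences, 309 evaluations, converged
#>   penalized LL   : -29.4394

ner_score(test, predict(m, test))
#> Entity-level evaluation (whole instances)
#>           gold expected correct precision recall    f1
#> problem     92       84      59     70.24  64.13 67.05
#> test        93       94      55     58.51  59.14 58.82
#> treatment   82       80      48     60.00  58.54 59.26
#> micro      267      258     162     62.79  60.67 61.71
```

Entities are counted correct only on an exact match of class, start and
end; `gold`/`expected`/`correct` are the match counts behind the
precision/recall/F1 columns (0–100 scale).  The same fit with
`variant = "first"` scores about 3 F1 points lower on this data: the
ambiguous entity surfaces can only be classified from the precursor,
which the first-order chain cannot see.  The generator's structure can
be inspected directly:

```r
distance_profile(train)
#> Inter-entity distance profile
#>   entities: 557 (200 without precursor); precursor ratio 0.641
#>   gap: median 3, mean 4.38
#>   ...
```

## Command-line use

```sh
Rscript inst/cli/picrf.R synth --out train.conll --sentences 200 --seed 1
Rscript inst/cli/picrf.R train --corpus train.conll --variant pi --out model.rds
Rscript inst/cli/picrf.R predict --model model.rds --corpus test.conll --out pred.conll
Rscript inst/cli/picrf.R eval --gold test.conll --pred pred.conll --distanced-only
```

See the vignette (`vignettes/precursor-induced-crf.Rmd`) for the model,
its assumptions, the design choices behind the synthetic generator, and
what the synthetic experiments do and do not demonstrate about real
clinical text.
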