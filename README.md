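# picopipe

Two-step PICO extraction from randomized controlled trial (RCT)
abstracts, for people building evidence-synthesis and literature-triage
tooling: first classify each sentence of an abstract into a rhetorical
section (background, methods, results, conclusions), then run a BIO
named-entity tagger for the four PICO classes — **P**opulation,
**I**ntervention, **C**omparison/Control, **O**utcome — over only the
title and the methods sentences, where nearly all *unique* PICO mentions
live. The package bundles the complete measurement stack for such a
system (token-level and entity-level exact/partial scoring,
micro-averaging, end-to-end evaluation, confusion matrices, Cohen's
kappa, document-level cross-validation), a section-coverage analysis,
readers/writers for MEDLINE-style text, a PubMed-XML subset, CoNLL and
standoff-JSON formats, and a deterministic synthetic-corpus generator so
everything is testable without external data.

## The method in brief

For a document whose sentences $x_1,\dots,x_n$ receive section labels
$\hat{s}_i \in \{\mathrm{BG},\mathrm{MT},\mathrm{RS},\mathrm{CC}\}$, the
tagger decodes, for the title and every sentence with
$\hat{s}_i = \mathrm{MT}$, the BIO label path

$$\hat{y} = \arg\max_y \sum_t \big[ w^\top \phi(x, t, y_t) + A_{y_{t-1}, y_t} \big]$$

by Viterbi, where $\phi$ are sparse token features, $w$ is trained with
the averaged structured perceptron, and the transition matrix $A$ hard-masks
invalid BIO bigrams ($A = -\infty$ for `O → I-c` and cross-class
`I` transitions), so every decoded sequence is a valid flat span set.
Spans are scored per class with precision, recall and F1 from summed
TP/FP/FN (micro-averaging pools counts across classes), at three
granularities: per token with Outside-agreement excluded, per entity by
exact span match, and per entity by greedy one-to-one partial
(overlap ≥ 1 token) match.

The coverage statistic motivating the section filter: for unique
per-class mention counts $c_{ks}$ in section $s$ and class totals $T_k$,

$$\mathrm{coverage}(s) = \frac{\sum_k c_{ks}}{\sum_k T_k}.$$

## Worked example

```r
library(picopipe)

# a synthetic corpus with known gold sections and gold PICO spans
corp  <- generate_separable_corpus(synth_config(n_docs = 120, seed = 7))
train <- as_corpus(unclass(corp)[1:90])
test  <- as_corpus(unclass(corp)[91:120])

cls    <- train_classifier(train, seed = 7)
tagger <- train_tagger(train, config = list(epochs = 5), seed = 7)

out <- run_pipeline(cls, tagger, test)
print(out$records[[1]])
#> <pico_record> synth0091: 9 unique elements (9 spans)
#>   P: adults with obesity; participants with anemia
#>   I: adjunctive gabapentin; high-dose donepezil; high-dose liraglutide; intravenous metoprolol; intravenous montelukast; low-dose sertraline
#>   O: pain score
```

The record lists, per document, the deduplicated (case-folded,
whitespace-collapsed) entity strings the pipeline extracted from the
title and the predicted-methods sentences, each backed by its source
spans. End-to-end scoring compares these predictions against gold over
*all* sentences, so misrouted sentences cost recall and misclassified
ones cost precision:

```r
print(end_to_end_eval(test, out$corpus, "entity_exact"))
#> <pico_eval_report> granularity: entity_exact
#>   P        P/R/F1 = 1.000/1.000/1.000  (TP=61 FP=0 FN=0)
#>   I        P/R/F1 = 1.000/1.000/1.000  (TP=108 FP=0 FN=0)
#>   C        P/R/F1 = 1.000/1.000/1.000  (TP=10 FP=0 FN=0)
#>   O        P/R/F1 = 1.000/1.000/1.000  (TP=74 FP=0 FN=0)
#>   Overall  P/R/F1 = 1.000/1.000/1.000
```

(The separable corpus is constructed so a consistent learner can solve
it; it validates the machinery, not real-world difficulty.)

The packaged 30-abstract unique-mention count table reproduces the
section-coverage analysis that justifies tagging only title + methods —
the methods column alone covers 95.2% of unique mentions:

```r
tab <- read_section_counts()
print(compute_coverage_from_counts(tab$counts, tab$totals))
#>   TT BG MT RS CC Total
#> P 30 30 28  5 26    30
#> I 30 30 30 30 30    30
#> C  5  0 10 11  8    12
#> O  6  4 72 71 10    75
#> Coverage  TT=0.483  BG=0.435  MT=0.952  RS=0.796  CC=0.503
```

A thin command-line front end over the same functions ships at
`inst/cli/picopipe.R` (subcommands `synth`, `convert`,
`train-classifier`, `classify`, `train-ner`, `tag`, `pipeline`,
`evaluate`, `coverage`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/picopipe.R", package = "picopipe"))')
Rscript $CLI synth --n-docs 50 --seed 1 --out corpus.json
Rscript $CLI coverage --in corpus.json
```

See `vignettes/picopipe-methods.Rmd` for the full account of the models,
evaluation conventions, generator design and known limitations.

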