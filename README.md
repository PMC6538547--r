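# collabotag

Collaborating BiLSTM-CRF taggers for biomedical named entity recognition.

## The problem

Biomedical NER gold standards each annotate a single entity type: a disease
corpus tags diseases, a gene corpus tags genes. A model trained on one of
them never sees a labeled example of the *other* types, so polysemous names
— *VHL* is a disease in one sentence and a gene in another — get tagged as
the model's own type whenever they look entity-like. These *bio-entity
errors* (an entity of another type recognized as the target type) are the
false positives that matter most downstream, because they propagate wrong
facts rather than merely missing one.

`collabotag` implements the CollaboNet scheme: one single-task expert model
per corpus, trained in phases during which each expert in turn is the
*target* (trained for one epoch on its own data) while the frozen
*collaborators* supply their BiLSTM encoder outputs as extra input features,
aggregated by weighted max pooling with trainable scalar weights α. The gene
expert can thereby tell the disease expert "this token is mine", vetoing the
false positive.

## The model

Each expert is a BiLSTM-CRF over BIOES tags. Token `w_t` is represented as
`x̂_t = [x_t, x^c_t]`: a word embedding `x_t` (word2vec text format
supported) concatenated with a CNN character-level word embedding

    [x^c_t]_j = max_{1<=i<=M} [ W_char C_i^t + b_char ]_j ,

the coordinate-wise max over the word's character windows `C_i^t` (window
sizes 3/5/7 by default). A bidirectional LSTM encodes
`[x̂_t ; s_t]` — `s_t` is the collaborator-feature slot, zero outside
collaboration — into `h_t = [h^f_t, h^b_t]`. Emission scores are
`z_t = W_y h_t + b_y`, and training minimizes

    Loss = L_LSTM + L_CRF ,

the per-position softmax cross entropy plus the CRF negative sentence-level
log likelihood over the learned transition matrix `A`. Decoding is Viterbi;
structurally invalid BIOES output is repaired by a deterministic
post-processing step before exact-match span evaluation
(`P = C/M`, `R = C/N`, `F1 = 2PR/(P+R)`).

During phase `n ≥ 1` the target `d` trains on

    Ŝ_d = max_k ( α_k · M_k^{n-1}([S_d ; 0]) ) ,     k ≠ d,

collaborators frozen at the phase boundary, α initialized to 1 and trained
through the pooling. The numerical core (char-CNN, BiLSTM, CRF forward
algorithm and full backpropagation, AdaGrad with per-epoch learning-rate
decay) is implemented in RcppArmadillo.

Because full-scale corpora and pretrained embeddings are not shipped, the
package includes a seeded synthetic-corpus generator that reproduces the
structural problem: single-type annotation per corpus over a shared
vocabulary, with planted polysemous tokens whose gold type is determined by
the nearest preceding context cue. See the vignette
(`vignettes/collaborative-ner.Rmd`) for the full model and design account.

## Worked example

The two-type polysemy benchmark: two corpora (disease, gene) of 800/200/200
sentences each, five polysemous tokens.

```r
library(collabotag)

spec <- polysemy_benchmark_spec(seed = 11)
corpora <- generate_corpora(spec)
describe_corpora(corpora)
#>    corpus split sentences entities polysemous_mentions
#> 1 disease train       800      887                 284
#> 2 disease   dev       200      230                  61
#> 3 disease  test       200      222                  63
#> 4    gene train       800      903                 277
#> 5    gene   dev       200      221                  64
#> 6    gene  test       200      223                  66

set.seed(11)
state <- collabo_init(corpora, stm_config("desk"), seed = 11)
state <- run_preparation_phase(state)   # independent convergence, dev-F1 patience
# phase-0 baseline (independent experts):
#> disease  F1 0.9978  bio-entity errors 1
#> gene     F1 0.9612  bio-entity errors 18

for (i in 1:3) state <- run_phase(state)
# after 3 collaboration phases:
#> disease  F1 1.0000  bio-entity errors 0
#> gene     F1 1.0000  bio-entity errors 0

state$alphas
#> $disease
#>      gene
#> 0.9814237
#>
#> $gene
#>  disease
#> 1.080892
```

The lone gene expert mistags disease-context polysemous tokens as genes (18
bio-entity errors on the test split); after three collaboration phases the
disease expert's features veto them all, and the aggregation weights have
moved off their unit initialization. Per-dataset F1 here is exact-match
entity-level F1; `classify_errors()` / `error_summary()` produce the error
taxonomy (bio-entity / span / spurious / missed).

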