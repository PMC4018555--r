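# esnlang

Echo state network models of grammatical construction learning: sentence
comprehension (commands → predicate-argument actions) and sentence
production (coded meanings → descriptions), with corpus tooling and the
learnability / leave-one-out evaluation protocols.

## The problem

How can a system with almost no built-in linguistic knowledge learn the
mapping between a sentence's *form* and its *meaning* — who did what to
whom, and in which order? The working hypothesis is the construction
grammar one: thematic roles are carried by the ordered pattern of
closed-class (function) words, so "put the **trumpet** on the **left**" and
"on the **left** put the **trumpet**" can be recognized as two
constructions assigning the same roles to their content words. This package
is for computational (neuro)linguists and developmental-robotics
researchers who want a trainable, inspectable model of that hypothesis:
train it on `<sentence, meaning>` pairs, query it with new sentences or new
meanings, and measure what a corpus lets it learn and generalize.

## The model

Both directions use a leaky echo state network: a fixed random recurrent
reservoir and a trained linear readout,

    x(t+1) = (1 − α) x(t) + α tanh(W_res x(t) + W_in u(t+1)),
    y(t)   = W_out [x(t); 1],

with `W_res` rescaled to a prescribed spectral radius, dense `W_in` entries
±(input scaling), and `W_out` fitted by pseudo-inverse linear regression
over all time steps of all training sequences.

* **Comprehension** (action-performing task): the sentence is reduced to
  its grammatical form — every open-class word becomes a generic `SW`
  marker and is pushed onto a FIFO working memory — and fed one-hot, one
  word per time step. The readout learns a 6 × 3 × 2 meaning grid (six
  content words × {predicate, agent, location} × two actions in execution
  order), clamped from sentence onset so the trajectory is an anytime
  estimate of the meaning. Defaults: 100 units, α = 1/6, spectral radius 1,
  input scaling 0.75, threshold 0.5.
* **Production** (scene-description task): the same grid, plus a
  canonical / non-canonical choice folded into four construction patterns
  (`SW2(SW1,SW3)`, `SW1(SW3,SW2)`, and double-relation variants with a
  shared agent), is presented as a constant input; the readout traces the
  word sequence as 5-step square waves which are decoded back into tokens
  and re-bound to the FIFO words. Defaults: 500 units, α = 0.75, spectral
  radius 2, input scaling 0.01.

Evaluation follows the two corpus protocols: *learnability* (train = test;
what the corpus lets the model even memorize) and *leave-one-out*
generalization, aggregated over model instances with mean ± sd and the
"best" (common-failure) statistic, plus per-category breakdowns by sentence
style and action count.

## Worked example

```r
library(esnlang)

# a seeded synthetic command corpus: 2 subjects x 12 behaviors x 2 styles
corp <- generate_ap_corpus(generator_params(n_subjects = 2, n_single = 4,
                                            n_double = 8, seed = 42))
length(corp)
#> [1] 48
corp[[15]]
#> [ap0015/AP/simple] "put the triangle on the middle"  ->  put(triangle,middle)

model <- train_comprehension(corp, n_units = 300, seed = 1)

# novel content words in a trained inverted construction: "before ... please"
# means the second surface action is executed first
comprehend(model, "before you grasp the cross please touch the trumpet")$meaning
#> touch(trumpet); grasp(cross)

# anaphoric "it" binds the shared object into both predications
comprehend(model, "put the guitar on the left and then touch it")$meaning
#> put(guitar,left); touch(guitar)

leave_one_out(corp, eval_config(n_units = 300, n_instances = 2, base_seed = 0))
#> Leave-one-out generalization test: 48 pairs, 2 instance(s), 300 units
#>   mean error 0.0% (sd 0.0%)   best (common failures) 0.0% (0 pairs)
#>   per category (n, mean fail, best fail):
#>     elaborate     x 1 action(s):   8     0.0 (0.0%)     0 (0.0%)
#>     elaborate     x 2 action(s):  16     0.0 (0.0%)     0 (0.0%)
#>     simple        x 1 action(s):   8     0.0 (0.0%)     0 (0.0%)
#>     simple        x 2 action(s):  16     0.0 (0.0%)     0 (0.0%)

# the inverse task: meaning -> sentence, in either form
sdc <- generate_sd_corpus(seed = 2)
pm <- train_production(sdc, seed = 1)
produce(pm, "right(trumpet,guitar)", "non_canonical")$sentence
#> [1] "to the right of the guitar is the trumpet"
produce(pm, "left(drums,toy)", "canonical")$sentence
#> [1] "the drums is to the left of the toy"
```

Every decoded meaning above is read off the readout's final time step; the
full trajectory is in `$outputs` (comprehension) / `$trace` (production)
and can be plotted with the `plot()` methods or exported with
`write_trajectory()`. A zero leave-one-out error on a clean template corpus
is the expected study condition: each construction recurs, and the model
never sees content-word identity, so known constructions transfer exactly.

A command-line front end over the same functions is installed at
`exec/esnlang` (subcommands `generate`, `train`, `comprehend`, `produce`,
`learnability`, `loo`, `demo`); trained models round-trip through portable
text archives via `write_esn_model()` / `read_esn_model()`.

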