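# morphrep

Component-based construction of great-ape gestural repertoires from coded
gesture-token tables, with a calibrated synthetic data generator for
end-to-end testing.

## The problem

Field studies of ape gestural communication code each observed gesture use
as a *token* of a *gesture action* (Push, Reach, Chest beat, ...), together
with four categorical *modifiers* describing how the action was expressed:
body part, contact with the recipient, lateral use, and repetition. Two
repertoire questions follow:

1. **Gesture-action repertoire** — which actions belong to the population's
   repertoire (inclusion threshold: observed ≥ 3 times), how unevenly are
   they used (token-contribution table, repertoire of regular use covering
   ~70 % of tokens), and has sampling saturated (detection-asymptote
   curve)?
2. **Morph repertoire** — within each sufficiently sampled action (≥ 10
   clear tokens), are there consistent configurations of modifier levels
   (*morphs*)? Morphs are detected as latent classes of a multinomial
   mixture over the modifiers: for token *i* of an action, the model is

   `P(x_i) = Σ_k π_k Π_m p_{k,m,x_im}`

   fitted by EM (20 random restarts, relative tolerance 1e-8), with the
   number of classes *k* chosen by BIC
   (`BIC = −2·LL + d·log n`, `d = (k−1) + k·Σ_m(L_m−1)`, ties to the
   smaller *k*). Hard-assigned classes with ≥ 5 tokens are morphs; actions
   resolve to *unimorphic* (1 morph), *polymorphic* (≥ 2), or remain
   *unspecified* (3–9 tokens, excluded from the LCA).

The package also computes individual repertoire sizes (IRS_1, IRS_3) and
gesturing rates (IGR_obs per follow-hour, IGR_vid per video-hour) by
maturation/sex class (infant, juvenile, subadult/blackback/nulliparous,
adult), the behavioural-context distribution of communications, and
inter-rater agreement (Cohen's kappa on a proportional ~5 % subsample).

Because field datasets of this kind are typically unpublished, the
`synthetic_data` module generates datasets with planted latent structure —
`bwindi_config()` is a profile calibrated to the published structure of a
wild mountain-gorilla dataset (3220 tokens, 63 repertoire actions, 45
LCA-analyzable actions, planted morph mixtures, 97 unclear-modifier
tokens, 553 follow-hours across four social units) — so that every
downstream statistic has a known ground truth.

## Worked example

```r
library(morphrep)
res <- run_synthetic_pipeline(config = bwindi_config(), seed = 1)
res$report
```

prints (the morph stage takes a couple of minutes):

```
Gestural repertoire analysis
  tokens: 3220 total, 3203 in repertoire (63 actions)
  average contribution under uniform use: 51 tokens/action
  regular-use repertoire: 16 actions
  LCA: 3024 instances across 45 actions
  morphs: 126 units (19 unimorphic, 26 polymorphic with 89 morphs, 18 unspecified)
  shared with other species: 48/63 actions (76%)
  overall rate: 5.82 tokens/h (6 rounded)
  action asymptote: token 1530 (48% of dataset)
```

Reading: 63 gesture actions passed the ≥ 3-token threshold (3203 of 3220
tokens); under uniform use each would have contributed 51 tokens; the 16
most frequent actions jointly cover ~70 % of tokens; 45 actions had ≥ 10
clear tokens for morph detection over 3024 instances, resolving the
repertoire into 126 units; sampling reached its detection asymptote at
token 1530 (48 % of the dataset), i.e. the second half of coding added no
new gesture action.

`run_pipeline()` is the same engine for data read from CSV files
(`read_tokens()`, `read_individuals()`, `read_effort()`), and
`inst/cli/morphrep.R` wraps both as a command line:

```sh
Rscript inst/cli/morphrep.R simulate --out data/ --seed 1
Rscript inst/cli/morphrep.R run --tokens data/tokens.csv \
  --individuals data/individuals.csv --effort data/effort.csv --out report/
```

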