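# palacerel

Tools for asking whether the *reliability* of a spatial context's neural
representation predicts later memory for the items associated with that
context. The setting is a "memory palace" experiment: participants learn a
virtual environment of 23 interconnected rooms, then learn one novel object
per room, and finally verbally recall the rooms and objects during fMRI
scanning. The package implements the full analysis chain for surface-based
searchlight data — pattern reliability, cross-participant decoding, recall
reinstatement scoring, and the map-level statistics linking them — together
with a synthetic-data generator that emulates the whole study design so
every stage can be validated end to end with planted, recoverable effects.

It is aimed at cognitive-neuroimaging researchers doing multivariate
pattern analysis of episodic memory, and at anyone who wants a tested
reference implementation of these analyses.

## The core statistic

For each searchlight and participant, room templates are estimated twice
(one GLM per pre-learning room-video run), and the two template sets are
correlated room-by-room, giving a 23 × 23 similarity matrix *S* whose rows
are run-1 rooms and columns run-2 rooms. The **room reliability** of room
*r* is

    rel_r = S[r, r] − mean_{r′ ≠ r} S[r, r′]

— the *stability* of the room's pattern over time minus its average
confusability with other rooms (*distinctiveness*). Reliability is computed
from data collected **before** object learning, so it cannot contain object
information.

Downstream, a leave-one-participant-out multinomial logistic classifier —
trained on the other N−1 participants' object templates, valid because each
participant has an independent random room–object pairing — yields a
per-timepoint probability that each object's representation is active
during recall. The **reinstatement score** of an object is its mean
classifier probability over the timepoints the participant verbally
recalled it, averaged over a network of the top-50 decodable searchlights.
Per searchlight, the 23 reliabilities are correlated with the 23 paired
objects' reinstatement scores within participant; Fisher-z transformed
correlations are averaged across participants and recall task types, with
inference by within-participant object-label permutation and BH-FDR.
Participant-specific model comparison (ΔR² of own- vs other-participant
predictors) and a partial-correlation control (residualizing on
retrieval-time room reinstatement) complete the chain.

## Worked example

Simulate a small study with a planted direct reliability → reinstatement
effect, measure reliability from the synthetic BOLD data, and test the
association map:

```r
library(palacerel)

cfg <- sim_config(n_participants = 8, n_searchlights = 12, seed = 42)
ds  <- simulate_dataset(cfg, tasks = "room_video")
ds
#> <synthetic_dataset> 8 participants, 23 rooms, 12 searchlights (3 signal)

rel <- room_reliability_by_searchlight(ds)   # participant x searchlight x room
round(apply(rel, 2, mean), 3)
#>  [1] -0.017 -0.009  0.010 -0.005  0.456 -0.003  0.453 -0.008 -0.009 -0.018
#> [11]  0.453 -0.020

inputs <- truth_pair_inputs(ds)
res <- reliability_reinstatement_map(rel, inputs$scores, n_perm = 200, seed = 7)
subset(as.data.frame(res$map), sig)
#>    searchlight_id      stat           p         q  sig
#> 5               5 0.7074705 0.004975124 0.0199005 TRUE
#> 7               7 0.7451586 0.004975124 0.0199005 TRUE
#> 11             11 0.6591398 0.004975124 0.0199005 TRUE

ds$signal_searchlights
#> [1]  5  7 11
```

Mean reliability is ~0.46 in the three searchlights that carry planted room
structure and ~0 elsewhere, and the permutation-tested composite map
recovers exactly the planted searchlights (`stat` is the Fisher-z composite
correlation between room reliability and paired-object reinstatement;
`p` its two-sided permutation p; `q` the BH-FDR adjusted value).

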