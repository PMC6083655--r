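# pcmc — post-conflict / matched-control analysis of social behaviour

`pcmc` implements the PC–MC (post-conflict / matched-control) method for
studying reconciliation in group-living animals, together with everything a
complete post-conflict study needs around it: behavioural event-log and
conflict-record I/O with validation, dyadic relationship metrics, tie-corrected
nonparametric tests with exact small-sample p-values, all-subsets AICc model
selection with model averaging, and a synthetic-data generator with known
ground truth. It is aimed at behavioural ecologists analysing focal-sampling
data from species such as wolves, dogs, primates or hyenas.

## The method

After each aggressive conflict the victim is observed for a fixed window (a
10-minute *PC* observation); a *matched control* (*MC*) of the same duration is
recorded on a later day at the same time of day, in the absence of recent
aggression. For each pair, the minute of the first opponent-directed
affiliative contact in the PC is compared with the MC:

* **attracted** — opponents affiliated only in the PC, or earlier in the PC;
* **dispersed** — only in the MC, or earlier in the MC;
* **neutral** — same minute, or no contact in either.

The **corrected conciliatory tendency** of individual *i* is

```
CCT_i = (attracted_i − dispersed_i) / (attracted_i + dispersed_i + neutral_i)
```

and the group value is the unweighted mean over individuals. The **time rule**
compares the distributions of first-affiliation minutes in PC versus MC
(two-sample Kolmogorov–Smirnov, then a per-individual Wilcoxon test inside the
divergence window) to establish when affiliation functions as reconciliation.

Relationship-quality predictors are computed per dyad: the asymmetry index
`(B_a→v − B_v→a) / B_a↔v` for affiliative (AFFav) and aggressive (AGGav)
behaviours, David's scores `DS = w + w2 − l − l2` from the direction of
submissive behaviours, and the dyadic rank distance (difference in David's
scores). Variation in reconciliation (occurrence, initiator, intensity,
latency, duration) is explored with all-subsets candidate sets of mixed-effect
models ranked by `AICc = −2 logL + 2k + 2k(k+1)/(n−k−1)`, Akaike weights
`w_i ∝ exp(−Δ_i/2)`, conditional model-averaged estimates with adjusted
standard errors, and relative variable importance (RVI, the summed weight of
the models containing a term).

## Worked example

The package bundles the summary tables of a captive wolf/dog study
(`canid_study_tables()`). Reproducing the conciliatory tendencies of the ten
wolf victims:

```r
library(pcmc)
tab <- canid_study_tables()$concil_counts
tab$cct_pct <- round(100 * cct(tab$attracted, tab$dispersed, tab$neutral), 2)
g <- group_cct(tab$cct_pct / 100)
```

```
     victim attracted dispersed neutral cct_pct
1   Aragorn        12         4       8   33.33
2      Tala        13         1       5   63.16
...
10  Tatonga         0         1       3  -25.00
group CCT = 22.45% (s.e. 7.43%, n = 10)
```

Each `cct_pct` is the per-victim conciliatory tendency; the group value of
about 22% says that roughly one conflict in five is followed by affiliation
earlier than baseline. A full synthetic study runs end to end:

```r
ds  <- generate_dataset(scenario_config("wolf", n_conflicts = 175), seed = 7)
rep <- run_full_analysis(ds, observation_hours = 219)
rep
```

```
PC-MC analysis: 175 conflicts, 175 labelled pairs (dyad filter applied)
  aggression rate: 0.80 per observation hour
  group CCT: 34.31% (s.e. 8.98%, n = 11 individuals)
  attracted vs dispersed: Z adj = 2.80, p = 0.001953
time rule: KS D = 0.625, p = 4.759e-09; divergence window: minute 2
  within-window Wilcoxon: Z adj = 2.41, p = 0.01562 (n = 7)
```

Here the synthetic wolves reconcile (attracted pairs exceed dispersed ones,
`p ≈ 0.002`) and the PC first-contact distribution diverges from the MC
baseline early in the observation. `recovery_report(ds)` compares every
estimate with the generator's ground truth (attracted fraction 0.394 against a
true reconciliation probability of 0.42; latent hierarchy recovered with
Kendall tau 1.0). A thin command-line front end with `simulate`, `validate`,
`report` and `compare` subcommands ships in `inst/cli/pcmc.R`.

## Further reading

The methods vignette (`vignettes/pcmc-methods.Rmd`) documents the labelling
and CCT conventions, the tie-correction and exact-enumeration rules of the
test layer, the AICc parameter-counting calibration, what the synthetic
generator does and does not emulate, and the package's design decisions on
every point the method leaves open.
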