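# workseq

Life-course sequence analysis of work schedules, linked to later health.

## The problem

Epidemiologists studying nonstandard work (evenings, nights, irregular hours,
weekends) increasingly ask not whether someone *ever* worked such schedules,
but how their whole schedule *trajectory* over a decade of working life
relates to health measured years later. The standard design codes each
person-year in a 10-year age window (25–34, 35–44, 45–54) as one of five
schedule states — not working (`NW`), standard daytime (`ST`), evenings
(`EVE`, 3–9 pm), nights (`NGT`, 9 pm–6 am), other nonstandard (`ONS`) — plus
missingness (`MIS`) as an ordinary sixth state, clusters the resulting
sequences into a small set of trajectory types, and regresses standardized
health outcomes at the window-end age on trajectory membership. `workseq`
implements that pipeline as tested, reusable R functions, together with a
synthetic panel generator with known latent classes so the whole machinery
can be validated without restricted survey microdata.

## The method

Dissimilarity between two state sequences \(x, y\) is the optimal-matching
(OM) edit distance, computed by the Needleman–Wunsch dynamic program

    D(i,j) = min( D(i-1,j) + indel, D(i,j-1) + indel, D(i-1,j-1) + sub(x_i, y_j) )

with `indel = 1` and substitution costs from the transition-rate (TRATE)
convention `sub(a,b) = 2·indel − p(a→b) − p(b→a)`, where the `p` are pooled
empirical one-step transition rates. Sequences are clustered with Ward's
minimum-variance method under the squared-dissimilarity (`ward.D2`)
convention; the number of clusters is selected by the Calinski–Harabasz
pseudo-F with Duda–Hart (`Je(2)/Je(1)`, pseudo-T²) tie-breaking over a
configurable range (default 4–8), with an explicit override for substantive
choices. Cluster–outcome associations are estimated by OLS (continuous
outcomes standardized to mean 50, SD 10, so 1 point = 0.1 SD) and logistic
regression (binary outcomes), with the mainly-`ST` cluster as reference.

## Worked example

```r
library(workseq)

sim <- generate_panel(generator_config(n_persons = 400, seed = 1))
cfg <- pipeline_config(windows = list(c(25, 35)), seed = 1)
run <- run_pipeline(sim$panel, sim$covariates, sim$outcomes, cfg,
                    out_dir = "ws_run")
run
#> <ws_run> 1 window(s); config hash 7e77f3d0eca04a92e6b8df31e6deb959
#>   window 25-34: 400 sequences, k = 4, ref 'mainly ST'

run$windows[["25"]]$solution$diagnostics
#> # A tibble: 5 × 4
#>       k    ch dh_ratio dh_pseudo_t2
#>   <int> <dbl>    <dbl>        <dbl>
#> 1     4  310.    0.731        30.9
#> 2     5  296.    0.698        82.7
#> 3     6  266.    0.857        10.7
#> 4     7  244.    0.547       108.
#> 5     8  226.    0.772         8.55

tidy(run$windows[["25"]]$profiles)
#> # A tibble: 4 × 6
#>   cluster label      size share mean_transitions modal
#>     <int> <chr>     <int> <dbl>            <dbl> <chr>
#> 1       1 mainly ST   193 0.482             1.94 MIS-ST-ST-ST-ST-ST-ST-ST-ST-M…
#> 2       2 mainly NW    81 0.202             1.88 MIS-NW-NW-NW-NW-NW-NW-NW-NW-M…
#> 3       3 mainly ONS   40 0.1               1.55 MIS-ONS-ONS-ONS-ONS-ONS-ONS-O…
#> 4       4 volatile     86 0.215             4.5  MIS-MIS-NGT-ONS-NGT-NGT-NGT-N…
```

The Calinski–Harabasz index peaks at k = 4 and the four recovered clusters
match the generator's archetypes (adjusted Rand index 0.86 against the true
latent classes). The regression step then estimates each cluster's contrast
against the mainly-`ST` reference on the standardized physical-function
score:

```r
subset(run$windows[["25"]]$effects, outcome == "sf_physical")[, 3:6]
#>                      term   estimate std.error  p.value
#>               (Intercept) 51.08          1.48   9.6e-121
#>    cluster_labelmainly NW -4.79          1.99   0.016
#>   cluster_labelmainly ONS -2.10          1.75   0.231
#>     cluster_labelvolatile -0.81          1.30   0.534
#>   ...
```

The mainly-`NW` estimate of −4.79 points is the injected −4-point effect
(0.4 SD worse physical function than stable daytime workers) recovered
through the full pipeline; at n = 400 the other, smaller injected effects
are within one standard error of their targets but not individually
significant. `effect_size_report()` renders such tables in the
significant-cells convention (integer points for significant linear terms,
+/− for logistic terms, blank otherwise), and
`autoplot(run$windows[["25"]]$profiles)` draws the per-position state
distribution by cluster.

All artifacts (sequences, transition rates, costs, distances, dendrogram,
assignments, diagnostics, profiles, plot data, effects, manifest) are written
to `out_dir` as delimited text with a data dictionary; reruns with identical
inputs and seed are byte-identical.

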