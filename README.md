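# survmedian

Nonparametric K-sample test for the equality of **median survival times**
under right censoring, for biostatisticians and epidemiologists who need to
compare groups by their medians rather than their whole survival curves
(e.g. when curves cross).  The package also ships the Monte-Carlo machinery
that characterizes the test's size and power, delimited-text I/O for
survival tables, and a command-line interface.

## The test

With right-censored data $(Z_{ij}, \delta_{ij})$,
$Z_{ij} = \min(X_{ij}, Y_{ij})$, $\delta_{ij} = I(X_{ij} \le Y_{ij})$, let
$\hat F_i$ be group $i$'s Kaplan–Meier survival curve and $\hat\theta_0$
the Kaplan–Meier median of the pooled sample.  Each group contributes
$\eta_i = \hat F_i(\hat\theta_0)$, and the statistic is the Cochran-type
inverse-variance-weighted sum of squares

$$
C = \sum_{i=1}^K w_i\Bigl(\eta_i - \sum_{j=1}^K h_j\eta_j\Bigr)^2,
\qquad w_i = 1/\hat\sigma_i^2,\quad h_i = w_i\Big/\sum_j w_j,
$$

asymptotically $\chi^2_{K-1}$ under the null of equal medians.  The
variance $\hat\sigma_i^2$ is a *composite*: the Greenwood estimate at
$\hat\theta_0$ **plus** $\tfrac12[\hat F_i(\hat\theta_i) -
\hat F_i(\hat\theta_{i1})]^2$, where $\hat\theta_i$ is the group median
and $\hat\theta_{i1}$ the closest other uncensored time.  The Greenwood
formula alone underestimates the variance and makes the weighted statistic
anti-conservative at small sample sizes; the closed-form correction (an
order $n^{-2}$ term) restores the chi-square calibration down to 20–30
subjects per group without bootstrapping.  The Greenwood-only variant is
kept as a large-sample comparator.  See the vignette
(`vignettes/median-survival-test.Rmd`) for the full account.

## Worked example

Four groups of 20–30 subjects with ~10% censoring, drawn from a catalog
scenario in which two groups have true median 16.93 and two have 14.62:

```r
library(survmedian)
sc <- scenario_catalog(6, "exponential", 0.1, reps = 1, seed = 2026)
set.seed(2026)
d <- generate_grouped_data(sc)
surv_median_test(d)
#>   K-sample test for equality of median survival times (composite variance)
#>
#> data: 1, 2, 3, 4
#> chi-squared = 10.86, df = 3, p-value = 0.01251
#> pooled median survival time: 16.58
#>     median    eta variance weight
#> 1 20.59379 0.7000 0.011750  85.11
#> 2 13.75620 0.3958 0.011390  87.80
#> 3 13.78431 0.2800 0.008864 112.80
#> 4 18.10849 0.6032 0.009392 106.50
```

The pooled median is 16.58; the survival probabilities at that time
separate into a high pair (0.70, 0.60) and a low pair (0.40, 0.28), and the
weighted squared deviations sum to C = 10.86 on 3 degrees of freedom —
evidence (p = 0.013) that the four medians are not equal, which is correct
for this scenario.

The same analysis from a file (`time,event,group` columns; `event` is 1
for an observed event, 0 for censored):

```sh
inst/cli/survmedian test my_study.csv --variant composite
inst/cli/survmedian fixture --kind toy_uncensored --out toy.csv
```

A Monte-Carlo size check at small sample sizes and 30% censoring:

```r
run_simulation(scenario_catalog(4, "exponential", 0.3, reps = 2000, seed = 9))
#> Monte-Carlo result for scenario 'table4:exponential:p0.3'
#> replicates: 2000 (degenerate redraws: 0), alpha = 0.05
#>    variant rejection  mc_se
#>  composite    0.0570 0.0052
#>  greenwood    0.0855 0.0063
```

The composite variant holds the 5% level while the Greenwood-only variant
is visibly inflated — the motivating behaviour for the composite variance.
The same run from the shell:

```sh
inst/cli/survmedian simulate --table 4 --row exponential --rate 0.3 \
    --reps 2000 --seed 9 --out summary.csv
```

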