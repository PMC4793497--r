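Package: survmedian
Title: Nonparametric Comparison of Median Survival Times for Censored Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests the equality of median survival times across K groups of
    right-censored data using a Cochran-type chi-square statistic.  Group
    Kaplan-Meier survival probabilities evaluated at the pooled-sample median
    are combined with inverse-variance weights, where each variance is a
    composite of the Greenwood estimate and a closest-uncensored-time
    correction that keeps the type I error rate controlled at small sample
    sizes.  Includes a Monte-Carlo engine with a catalog of size and power
    scenarios over uniform, exponential and log-normal survival families with
    matched censoring distributions, delimited-text input of survival tables,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
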