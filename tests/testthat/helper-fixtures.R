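# random censored sample generators and an independent product-limit oracle

rand_sample <- function(n, cens_prob = 0.2, label = NULL) {
  x <- rexp(n, rate = 0.5)
  y <- if (cens_prob > 0) rexp(n, rate = 0.5 * cens_prob / (1 - cens_prob))
       else rep(Inf, n)
  surv_sample(pmin(x, y), as.integer(x <= y), label = label)
}

# brute-force product-limit curve: risk sets recomputed from scratch at each
# event time, survival as an explicit running product
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (j in seq_along(ut)) {
    n_j <- sum(times >= ut[j])
    d_j <- sum(times == ut[j] & events == 1)
    s <- s * (1 - d_j / n_j)
    surv[j] <- s
  }
  list(event_times = ut, surv = surv)
}

# hand-sized grouped data with known structure
toy_groups <- function() {
  grouped_surv(list(
    surv_sample(c(1, 2, 3, 4), c(1, 1, 1, 1), "A"),
    surv_sample(c(1, 2, 3, 4), c(1, 1, 1, 1), "B")))
}
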