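# shared fixtures, built in code

# a batch table with no distortion (isolates biology from batch effects)
no_batch <- function(ids = "b1") {
  data.frame(batch_id = ids, location_shift = 0, scale_factor = 1)
}

# small clean cohort spec used across module tests
quiet_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = 40, n_sites = 60, n_age_sites = 20,
                   noise_sd = 0.01, mean_depth = 50, missing_rate = 0,
                   batches = no_batch(), entropy_drift = 0, seed = 11L)
  defaults[names(args)] <- args   # replace whole elements (incl. batches)
  do.call(cohort_spec, defaults)
}

# metadata factory for hand-built matrices
make_meta <- function(ids, age_days, sex = "female", strain = "B6",
                      treatment = "none", study = "s1") {
  data.frame(sample_id = ids, age_days = age_days, sex = sex,
             strain = strain, treatment = treatment, study = study,
             stringsAsFactors = FALSE)
}

# hand-built meth_matrix from a fraction matrix (counts optional)
frac_matrix <- function(fr, chrom = "1") {
  n <- nrow(fr); p <- ncol(fr)
  if (is.null(rownames(fr))) rownames(fr) <- sprintf("s%02d", seq_len(n))
  meth_matrix(fraction = fr,
              sites = data.frame(chrom = chrom, pos = 100L * seq_len(p)),
              sample_ids = rownames(fr))
}

# closed-form per-column least-squares slope of y on x
ols_slope <- function(x, Y) {
  xc <- x - mean(x)
  as.numeric(crossprod(xc, sweep(Y, 2, colMeans(Y))) / sum(xc^2))
}

# independent drop-one F-test via explicit normal equations
brute_force_age_f <- function(y, X_full, X_red) {
  bf <- solve(crossprod(X_full), crossprod(X_full, y))
  br <- solve(crossprod(X_red), crossprod(X_red, y))
  rss_f <- sum((y - X_full %*% bf)^2)
  rss_r <- sum((y - X_red %*% br)^2)
  df2 <- length(y) - ncol(X_full)
  f <- (rss_r - rss_f) / (rss_f / df2)
  list(f = f, p = pf(f, 1, df2, lower.tail = FALSE))
}

# two-sided Fisher exact p by full enumeration over fixed margins
enumerate_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
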