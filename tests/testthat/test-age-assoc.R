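test_that("a near-deterministic age signal is detected at tiny p", {
  set.seed(2)
  n <- 20
  meta <- make_meta(sprintf("s%02d", 1:n), age_days = seq(30, 700, length.out = n),
                    sex = rep(c("male", "female"), n / 2))
  fr <- matrix(0.01 * meta$age_days / days_per_month + rnorm(n, 0, 1e-6),
               ncol = 1, dimnames = list(meta$sample_id, "1:100"))
  tab <- test_age_association(fr, meta, covariates = "sex")
  expect_lt(tab$p_value, 1e-10)
  expect_gt(tab$age_coef, 0)
})

test_that("drop-one F equals the normal-equations oracle on small instances", {
  set.seed(3)
  for (i in 1:10) {
    n <- 8
    meta <- make_meta(sprintf("s%d", 1:n), age_days = runif(n, 20, 800),
                      sex = sample(c("male", "female"), n, TRUE),
                      treatment = sample(c("none", "rapamycin"), n, TRUE))
    fr <- matrix(runif(3 * n), n, 3,
                 dimnames = list(meta$sample_id, paste0("1:", 1:3 * 10)))
    tab <- test_age_association(fr, meta, covariates = c("treatment", "sex"))
    Xr <- cbind(1, meta$treatment == "rapamycin", meta$sex == "male")
    Xf <- cbind(Xr, meta$age_days)
    for (j in 1:3) {
      orc <- brute_force_age_f(fr[, j], Xf, Xr)
      expect_equal(tab$f_stat[j], orc$f, tolerance = 1e-10)
      expect_equal(tab$p_value[j], orc$p, tolerance = 1e-10)
    }
  }
})

test_that("RSS ordering and error paths hold", {
  set.seed(4)
  n <- 12
  meta <- make_meta(sprintf("s%d", 1:n), age_days = runif(n, 20, 800),
                    sex = sample(c("male", "female"), n, TRUE))
  fr <- matrix(runif(5 * n), n, 5,
               dimnames = list(meta$sample_id, paste0("1:", 1:5)))
  tab <- test_age_association(fr, meta, covariates = "sex")
  expect_true(all(tab$rss_reduced >= tab$rss_full))
  expect_true(all(tab$f_stat >= 0))
  meta2 <- meta; meta2$dup <- meta2$age_days  # age entered twice
  expect_error(test_age_association(fr, meta2, covariates = c("sex", "dup"),
                                    age_transform = "identity"),
               "collinear")
  expect_error(test_age_association(fr[1:2, , drop = FALSE], meta[1:2, ],
                                    covariates = "sex"), "n <= p")
})

test_that("null p-values are uniform (KS) and BH controls the null", {
  set.seed(6)
  n <- 40
  meta <- make_meta(sprintf("s%02d", 1:n), age_days = runif(n, 20, 800),
                    sex = sample(c("male", "female"), n, TRUE))
  fr <- matrix(runif(n * 1000), n, 1000,
               dimnames = list(meta$sample_id, paste0("1:", 1:1000)))
  tab <- test_age_association(fr, meta, covariates = "sex")
  ks <- stats::ks.test(tab$p_value, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_lte(mean(tab$significant), 0.01)
})

test_that("BH step-up matches the hand-executed worked example", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.9), level = 0.05)
  expect_equal(r$q_value, c(0.04, 0.04, 0.04, 0.9))
  expect_equal(sum(r$rejected), 3L)
  expect_true(all(bh_fdr(rep(0, 5), 0.01)$rejected))
  expect_true(bh_fdr(0.04, 0.05)$rejected)
  expect_length(bh_fdr(numeric(), 0.05)$q_value, 0)
})

test_that("replication keeps shared signal and drops primary-only signal", {
  set.seed(8)
  n <- 60
  mk_cohort <- function(signal_sites, seed, study) {
    set.seed(seed)
    meta <- make_meta(sprintf("%s_%02d", study, 1:n),
                      age_days = runif(n, 20, 800),
                      sex = sample(c("male", "female"), n, TRUE),
                      study = study)
    fr <- matrix(runif(n * 6, 0.3, 0.5), n, 6)
    for (j in signal_sites) {
      fr[, j] <- 0.3 + 0.3 * (meta$age_days / 800) + rnorm(n, 0, 0.01)
    }
    dimnames(fr) <- list(meta$sample_id, paste0("1:", 1:6 * 10))
    list(matrix = frac_matrix(fr), meta = meta)
  }
  prim <- mk_cohort(c(1, 2), seed = 100, study = "a")   # sites 1,2 real
  repl <- mk_cohort(1, seed = 200, study = "b")          # only site 1 real
  ids <- site_ids(prim$matrix)   # planted signal at the first two sites
  tab <- test_age_association(prim$matrix, prim$meta, covariates = "sex")
  expect_true(all(ids[1:2] %in% tab$site_id[tab$significant]))
  kept <- replicate_associations(tab, list(repl), covariates = "sex")
  expect_true(ids[1] %in% kept)
  expect_false(ids[2] %in% kept)
})

test_that("entropy formula hits its closed-form anchors", {
  m5 <- matrix(0.5, 2, 7, dimnames = list(c("a", "b"), NULL))
  expect_equal(methylome_entropy(m5)$samples$entropy, c(1, 1))
  m01 <- matrix(rep(c(0, 1), 5), 2, 5, dimnames = list(c("a", "b"), NULL))
  expect_equal(methylome_entropy(m01)$samples$entropy, c(0, 0))
  # single site at MF = 0.25, evaluated directly
  want <- (0.25 * log(0.25) + 0.75 * log(0.75)) / log(0.5)
  got <- methylome_entropy(matrix(0.25, 1, 1,
                                  dimnames = list("a", NULL)))$samples$entropy
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(round(want, 4), 0.8113)
  expect_error(methylome_entropy(matrix(numeric(), 1, 0)), "at least one")
})

test_that("entropy is base-invariant and monotone toward 0.5", {
  set.seed(9)
  fr <- matrix(runif(50), 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  ent <- methylome_entropy(fr)$samples$entropy
  # same formula in base 2: the normalizer cancels the base
  base2 <- rowSums(fr * log2(fr) + (1 - fr) * log2(1 - fr)) / (10 * log2(0.5))
  expect_equal(ent, unname(base2), tolerance = 1e-12)
  expect_true(all(ent >= 0 & ent <= 1))
  # moving any single fraction strictly closer to 0.5 never decreases entropy
  for (k in 1:20) {
    i <- sample(5, 1); j <- sample(10, 1)
    fr2 <- fr
    fr2[i, j] <- fr[i, j] + 0.5 * (0.5 - fr[i, j])
    ent2 <- methylome_entropy(fr2)$samples$entropy
    expect_gte(ent2[i] + 1e-12, ent[i])
  }
})

test_that("entropy-age correlation is positive on drifting cohorts", {
  pos <- vapply(1:10, function(s) {
    co <- simulate_cohort(quiet_spec(n_samples = 50, entropy_drift = 0.08,
                                     mean_depth = 60, seed = 50 + s))
    sub <- subset_matrix(co$matrix, sites = which(co$truth$site$is_age_site))
    methylome_entropy(sub$fraction, co$meta)$pearson_r > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})
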