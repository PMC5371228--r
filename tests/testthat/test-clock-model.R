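train_cohort <- function(seed = 1, n = 80, ...) {
  simulate_cohort(quiet_spec(n_samples = n, n_sites = 120, n_age_sites = 40,
                             slope_scale = 0.04, mean_depth = 30,
                             seed = seed, ...))
}

test_that("full shrinkage collapses the clock to the mean age", {
  co <- train_cohort(seed = 21, n = 24)
  mdl <- train_clock(co$matrix, co$meta, lambda = 1e6, alphas = 0.5,
                     seed = 1)
  expect_equal(nrow(mdl$sites), 0L)
  expect_equal(mdl$intercept, mean(log2(co$meta$age_days)), tolerance = 1e-8)
  pred <- predict_age(mdl, co$matrix, co$meta)
  expect_equal(var(pred$epi_age_days), 0)
  expect_error(train_clock(co$matrix, co$meta, alphas = numeric()),
               "empty")
})

test_that("unpenalized elastic net equals ordinary least squares", {
  set.seed(22)
  n <- 30; J <- 5
  X <- matrix(rnorm(n * J), n, J,
              dimnames = list(sprintf("s%02d", 1:n), paste0("1:", 1:J * 10)))
  beta <- c(1, -0.5, 0.3, 0, 0.8)
  y_log2 <- 5 + X %*% beta + rnorm(n, 0, 0.05)
  meta <- make_meta(rownames(X), age_days = 2^y_log2)
  mdl <- train_clock(X, meta, folds = 4, alphas = 1, lambda = 0, seed = 1,
                     thresh = 1e-14)
  ols <- lm.fit(cbind(1, X), as.numeric(y_log2))$coefficients
  w <- setNames(rep(0, J), colnames(X))
  w[mdl$sites$site_id] <- mdl$sites$weight
  expect_equal(unname(w), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(mdl$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("the clock recovers held-out age on a planted cohort", {
  co <- train_cohort(seed = 23, n = 120, missing_rate = 0.02,
                     mean_depth = 20)
  filt <- filter_clock(co$matrix)
  # hold out every third sample so both splits span the age range
  te <- seq(3, 120, by = 3); tr <- setdiff(1:120, te)
  mtr <- subset_matrix(filt$matrix, samples = tr)
  mte <- subset_matrix(filt$matrix, samples = te)
  mdl <- train_clock(mtr, co$meta[tr, ], seed = 2)
  pred <- predict_age(mdl, mte, co$meta[te, ])
  expect_gt(cor(pred$epi_age_log2, log2(pred$age_days)), 0.9)
  # determinism: same inputs and seed give an identical model
  mdl2 <- train_clock(mtr, co$meta[tr, ], seed = 2)
  expect_identical(mdl$sites, mdl2$sites)
  expect_identical(mdl$intercept, mdl2$intercept)
})

test_that("prediction is invariant to site order and checks coverage", {
  co <- train_cohort(seed = 24, n = 40)
  mdl <- train_clock(co$matrix, co$meta, seed = 3)
  perm <- sample(ncol(co$matrix$fraction))
  shuffled <- subset_matrix(co$matrix, sites = perm)
  expect_equal(predict_age(mdl, shuffled)$epi_age_days,
               predict_age(mdl, co$matrix)$epi_age_days)
  few <- subset_matrix(co$matrix, sites = 1:2)
  expect_error(predict_age(mdl, few), "missing model site")

  # hand-built model: zero weights, intercept log2(100)
  flat <- structure(list(
    sites = data.frame(site_id = character(), chrom = character(),
                       pos = integer(), weight = numeric()),
    intercept = log2(100)), class = "clock_model")
  expect_equal(predict_age(flat, co$matrix)$epi_age_days, rep(100, 40))
})

test_that("treated samples read epigenetically younger", {
  younger <- vapply(1:3, function(s) {
    n <- 100
    plan <- data.frame(
      sex = rep_len(c("male", "female"), n), strain = "UM-HET3",
      treatment = c(rep("none", 80), rep("rapamycin", 20)),
      study = "b1")
    ages <- c(2 ^ seq(log2(40), log2(790), length.out = 80), rep(669, 20))
    co <- simulate_cohort(quiet_spec(n_samples = n, n_sites = 120,
                                     n_age_sites = 40, treatment_rate = 0.5,
                                     mean_depth = 30, seed = 30 + s),
                          ages = ages, metadata_plan = plan)
    old_ctrl <- which(plan$treatment == "none" & ages > 600)
    mdl <- train_clock(subset_matrix(co$matrix, samples = 1:80),
                       co$meta[1:80, ], seed = s)
    pred <- predict_age(mdl, co$matrix, co$meta)
    t.test(pred$epi_age_months[81:100],
           pred$epi_age_months[old_ctrl])$p.value < 0.05 &&
      mean(pred$epi_age_months[81:100]) < mean(pred$epi_age_months[old_ctrl])
  }, logical(1))
  expect_true(all(younger))
})

test_that("direction classification matches planted signs", {
  co <- train_cohort(seed = 26, n = 100)
  dir <- classify_direction(co$matrix, co$meta)
  truth <- co$truth$site
  age_idx <- which(truth$is_age_site)
  want <- ifelse(truth$slope[age_idx] > 0, "gain", "loss")
  expect_gte(mean(dir$direction[age_idx] == want), 0.95)
  # gain fraction over planted sites matches frac_gain within binomial error
  gain_frac <- mean(dir$direction[age_idx] == "gain")
  expect_lt(abs(gain_frac - 0.5), 3 * sqrt(0.25 / length(age_idx)))
})

test_that("clock-site enrichment honors the enhancer/promoter precedence", {
  n <- 1000
  cand <- paste0("1:", 1:n * 10)
  ann <- matrix(FALSE, n, 3,
                dimnames = list(cand, c("enhancer", "intron", "intergenic")))
  ann[1:200, "enhancer"] <- TRUE
  ann[150:600, "intron"] <- TRUE      # 150:200 overlap the enhancer set
  ann[601:1000, "intergenic"] <- TRUE
  sel <- cand[sample(1:200, 60)]       # selected only from enhancer sites
  res <- clock_site_enrichment(sel, cand, ann)
  enh <- res[res$region == "enhancer", ]
  expect_gt(enh$odds_ratio, 1)
  expect_lt(enh$p_value, 0.01)
  # sites labeled enhancer+intron count as enhancer: intron margin shrinks
  expect_equal(sum(res[res$region == "intron", c("a", "c")]), 400L)

  # uniform selection: no region should light up (most of the time)
  set.seed(27)
  ps <- replicate(20, {
    sel0 <- cand[sample(n, 60)]
    min(clock_site_enrichment(sel0, cand, ann)$p_value)
  })
  expect_gte(mean(ps > 0.01), 0.8)
})

test_that("permutation control returns one value per shuffle", {
  co <- train_cohort(seed = 28, n = 24,
                     batches = data.frame(batch_id = c("b1", "b2"),
                                          location_shift = c(0, 0.05),
                                          scale_factor = c(1, 1.2)))
  res <- permutation_control(co$matrix, co$meta, n_permutations = 1,
                             seed = 4, combat_mode = "parametric",
                             alphas = 0.5)
  expect_length(res$permuted, 1L)
  expect_true(res$rank %in% c(1L, 2L))
  expect_error(permutation_control(co$matrix, co$meta, n_permutations = 0),
               "n_permutations")
})
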