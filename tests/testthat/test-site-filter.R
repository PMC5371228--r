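# independent rule-by-rule oracle: applies a filter profile with plain loops
oracle_filter <- function(meth, unmeth, chrom, min_reads, max_site_missing,
                          sd_bounds, max_sample_missing) {
  tot <- meth + unmeth
  fr <- ifelse(tot >= min_reads, meth / tot, NA)
  keep_site <- logical(ncol(fr))
  for (j in seq_len(ncol(fr))) {
    ok <- chrom[j] %in% as.character(1:19) &&
      mean(is.na(fr[, j])) < max_site_missing
    if (ok && !is.null(sd_bounds)) {
      s <- sd(fr[, j], na.rm = TRUE)
      ok <- !is.na(s) && s > sd_bounds[1] && s <= sd_bounds[2]
    }
    keep_site[j] <- ok
  }
  keep_samp <- rowMeans(is.na(fr[, keep_site, drop = FALSE])) <=
    max_sample_missing
  list(sites = which(keep_site), samples = which(keep_samp))
}

count_matrix <- function(depth, fr_target, chrom = NULL) {
  p <- ncol(depth)
  if (is.null(chrom)) chrom <- rep("1", p)
  meth <- round(depth * fr_target)
  meth_matrix(meth = meth, unmeth = depth - meth,
              sites = data.frame(chrom = chrom, pos = 10L * seq_len(p)),
              sample_ids = sprintf("m%02d", seq_len(nrow(depth))))
}

test_that("cross-species profile matches a hand-coded oracle on a planted toy", {
  # 10 samples x 6 sites: sites 5,6 under-covered in 3/10 samples
  # (30% > 20%); sample 10 then misses 3 of the 4 surviving sites (75% >
  # 40%), while those sites stay at 10% missing (< 20%)
  depth <- matrix(10L, 10, 6)
  depth[1:3, 5] <- 3L
  depth[c(2, 4, 6), 6] <- 4L
  depth[10, 1:3] <- 2L
  fr <- matrix(0.5, 10, 6)
  m <- count_matrix(depth, fr)
  halves <- list(subset_matrix(m, samples = 1:5),
                 subset_matrix(m, samples = 6:10))
  res <- filter_cross_species(halves)
  expect_equal(dim(res$matrix), c(9L, 4L))
  orc <- oracle_filter(m$meth, m$unmeth, m$sites$chrom, 5, 0.20, NULL, 0.40)
  expect_equal(site_ids(res$matrix), site_ids(m)[orc$sites])
  expect_equal(res$matrix$sample_ids, m$sample_ids[orc$samples])
  # conservation identity on the report
  expect_equal(res$report$sites_out +
                 Reduce(`+`, res$report$sites_removed),
               res$report$sites_in)
})

test_that("fully covered data passes the cross-species profile unchanged", {
  depth <- matrix(10L, 4, 5)
  m <- count_matrix(depth, matrix(runif(20), 4, 5))
  res <- filter_cross_species(list(subset_matrix(m, samples = 1:2),
                                   subset_matrix(m, samples = 3:4)))
  expect_equal(dim(res$matrix), c(4L, 5L))
  expect_equal(res$report$n_imputed, 0L)
  expect_error(filter_cross_species(m), "list")
  expect_error(filter_cross_species(list(m)), ">= 2 studies")
})

test_that("sex chromosomes are removed regardless of coverage", {
  depth <- matrix(20L, 4, 3)
  m <- count_matrix(depth, matrix(runif(12, 0.3, 0.7), 4, 3),
                    chrom = c("1", "X", "2"))
  res <- filter_cross_species(list(subset_matrix(m, samples = 1:2),
                                   subset_matrix(m, samples = 3:4)))
  expect_false("X" %in% res$matrix$sites$chrom)
  expect_equal(res$report$sites_removed$chromosome, 1L)
})

test_that("clock profile enforces the sd window and presence rule", {
  set.seed(5)
  depth <- matrix(10L, 10, 5)
  fr <- cbind(
    rep(0.4, 10),                      # invariant: sd = 0, removed
    rep(c(0, 1), 5),                   # sd ~ 0.53 > 0.20, removed
    runif(10, 0.3, 0.5),               # kept
    runif(10, 0.4, 0.6),               # kept
    runif(10, 0.2, 0.4)                # kept but under-covered below
  )
  depth[1:2, 5] <- 1L                  # presence 80% < 97%, removed
  m <- count_matrix(depth, fr)
  # rounding depth*fr re-quantizes fractions; recompute the planted ones
  res <- filter_clock(m)
  expect_equal(site_ids(res$matrix), site_ids(m)[3:4])
  orc <- oracle_filter(m$meth, m$unmeth, m$sites$chrom, 2,
                       1 - 0.97 + 1e-12, c(0, 0.20), 0.30)
  expect_equal(site_ids(res$matrix), site_ids(m)[orc$sites])
  expect_equal(res$report$sites_removed$sd, 2L)
  expect_equal(res$report$sites_removed$coverage, 1L)
})

test_that("imputation fills all cells without moving site means", {
  co <- simulate_cohort(quiet_spec(n_samples = 30, missing_rate = 0.1,
                                   mean_depth = 15, seed = 8))
  res <- filter_cross_species(list(subset_matrix(co$matrix, samples = 1:15),
                                   subset_matrix(co$matrix, samples = 16:30)))
  fr <- res$matrix$fraction
  expect_false(anyNA(fr))
  # observed means preserved: compare against pre-imputation means
  pre <- co$matrix$fraction[match(res$matrix$sample_ids, co$matrix$sample_ids),
                            match(site_ids(res$matrix), site_ids(co$matrix))]
  tot <- co$matrix$meth + co$matrix$unmeth
  pre[tot[match(res$matrix$sample_ids, co$matrix$sample_ids),
          match(site_ids(res$matrix), site_ids(co$matrix))] < 5] <- NA
  keep <- colSums(!is.na(pre)) > 0
  expect_equal(colMeans(fr)[keep],
               colMeans(pre, na.rm = TRUE)[keep], tolerance = 1e-12)
  # re-running the profile on its own output is the identity
  n_out <- length(res$matrix$sample_ids)
  again <- filter_cross_species(
    list(subset_matrix(res$matrix, samples = seq_len(10)),
         subset_matrix(res$matrix, samples = seq(11, n_out))))
  expect_equal(again$matrix$fraction, res$matrix$fraction)
})

test_that("relaxed projection uses >= 1 read and imputes the site mean", {
  # site 1: covered everywhere at depth 1 (observed under the relaxed rule);
  # site 2: one sample uncovered, imputed with the observed mean 0.3
  meth <- matrix(c(1L, 4L, 9L,
                   0L, 0L, 9L,
                   1L, 2L, 9L), 3, 3, byrow = TRUE)
  depth <- matrix(c(1L, 10L, 10L,
                    1L, 0L, 10L,
                    1L, 10L, 10L), 3, 3, byrow = TRUE)
  m <- meth_matrix(meth = meth, unmeth = depth - meth,
                   sites = data.frame(chrom = "1", pos = c(10L, 20L, 30L)),
                   sample_ids = c("a", "b", "c"))
  proj <- project_relaxed(m, site_ids(m)[1:2])
  expect_equal(ncol(proj$fraction), 2L)
  expect_false(anyNA(proj$fraction))
  expect_equal(unname(proj$fraction[, 1]), c(1, 0, 1))  # depth-1 observed
  expect_equal(unname(proj$fraction["b", 2]), mean(c(0.4, 0.2)))
  expect_error(project_relaxed(m, "9:999"), "no overlap")
})
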