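#' Specification of a synthetic methylome cohort
#'
#' Defines the data-generating process the pipeline assumes: a set of CpG
#' sites of which `n_age_sites` drift linearly in log2(age in days) (a
#' fraction `frac_gain` gaining methylation, the rest losing), per-site
#' disorder that contracts fractions toward 0.5 with log-age
#' (`entropy_drift`), study-level batch effects applied as a location shift
#' plus a scaling of the biological noise, binomial read sampling at
#' Poisson-distributed depth, and random missingness. Treated samples age
#' along a slowed clock: their effective (epigenetic) age is
#' `treatment_rate * age_days`.
#'
#' Defaults emulate a mouse liver RRBS cohort: 100 animals spanning roughly
#' 0.2-26 months, 500 sites of which 100 carry true age drift at 0.04
#' fraction units per log2(day), mean depth 20x, three sequencing batches
#' with distinct location/scale distortions.
#'
#' @param n_samples,n_sites,n_age_sites cohort dimensions; `n_age_sites <=
#'   n_sites`.
#' @param frac_gain fraction of drifting sites that gain methylation with age.
#' @param slope_scale drift magnitude, methylation-fraction units per unit
#'   log2(age in days).
#' @param noise_sd per-observation Gaussian sd on the fraction scale.
#' @param mean_depth expected reads per cell (Poisson).
#' @param missing_rate extra fraction of cells dropped at random, in \[0, 1).
#' @param batches data.frame with columns `batch_id`, `location_shift`,
#'   `scale_factor`; samples are assigned round-robin unless a
#'   `metadata_plan` says otherwise.
#' @param treatment_rate multiplier in (0, 1\] applied to the age drift of
#'   treated samples (effective age = rate x chronological age).
#' @param entropy_drift rate at which latent fractions contract toward 0.5
#'   per unit log2(age); 0 disables the disorder trend.
#' @param seed integer seed; fixes every output bit.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 100, n_sites = 500, n_age_sites = 100,
                        frac_gain = 0.5, slope_scale = 0.04,
                        noise_sd = 0.02, mean_depth = 20,
                        missing_rate = 0.05,
                        batches = data.frame(
                          batch_id = c("rrbs_a", "rrbs_b", "wgbs"),
                          location_shift = c(0, 0.08, -0.05),
                          scale_factor = c(1, 1.6, 0.7)),
                        treatment_rate = 0.55,
                        entropy_drift = 0.05,
                        seed = 1L) {
  stopifnot(n_age_sites <= n_sites, n_sites >= 1, n_samples >= 1)
  stopifnot(frac_gain >= 0, frac_gain <= 1, mean_depth >= 1)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (treatment_rate <= 0 || treatment_rate > 1) {
    stop("treatment_rate must lie in (0, 1]")
  }
  stopifnot(all(c("batch_id", "location_shift", "scale_factor") %in%
                  names(batches)))
  structure(
    list(n_samples = n_samples, n_sites = n_sites,
         n_age_sites = n_age_sites, frac_gain = frac_gain,
         slope_scale = slope_scale, noise_sd = noise_sd,
         mean_depth = mean_depth, missing_rate = missing_rate,
         batches = batches, treatment_rate = treatment_rate,
         entropy_drift = entropy_drift, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# reference log2 age at which the planted baseline fraction is attained;
# 180 days (~6 months) centres the drift inside [0, 1]
.ref_log_age <- log2(180)

#' Simulate a methylome cohort with known ground truth
#'
#' Generates read counts per (sample, site): the latent fraction is
#' `baseline + slope * log2(effective_age_days)` contracted toward 0.5 by
#' `(effective_age / 7)^(-entropy_drift)`, then distorted per batch as
#' `mu + location_shift + scale_factor * N(0, noise_sd)`, clamped to
#' \[0, 1\], and sampled as `Binomial(depth, mu')` with
#' `depth ~ Poisson(mean_depth)`. Cells with zero depth or dropped by
#' `missing_rate` are missing.
#'
#' @param spec a [cohort_spec()].
#' @param ages positive ages in days, length `n_samples`; defaults to a
#'   log-uniform spread over 6-790 days (~0.2-26 months).
#' @param metadata_plan optional data.frame with columns `sex`, `strain`,
#'   `treatment`, `study` (one row per sample); defaults to untreated
#'   animals split across the spec's batches.
#' @param age_site_idx optional explicit indices of the drifting sites
#'   (internal hook for paired simulations).
#' @return list with elements `matrix` (a [meth_matrix()]), `meta`
#'   (sample metadata data.frame) and `truth` (per-site and per-sample
#'   ground truth, plus the latent fraction matrix).
#' @export
simulate_cohort <- function(spec, ages = NULL, metadata_plan = NULL,
                            age_site_idx = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_samples
  p <- spec$n_sites
  if (is.null(ages)) {
    ages <- 2 ^ seq(log2(6), log2(790), length.out = n)
  }
  if (length(ages) != n) stop("ages must have length n_samples")
  if (any(ages <= 0)) stop("ages must be positive")

  if (is.null(metadata_plan)) {
    # sex drawn at random (seeded) so it cannot alias the batch cycle
    metadata_plan <- data.frame(
      sex = sample(c("male", "female"), n, replace = TRUE),
      strain = rep_len(c("B6", "UM-HET3"), n),
      treatment = rep("none", n),
      study = rep_len(spec$batches$batch_id, n)
    )
  }
  stopifnot(nrow(metadata_plan) == n,
            all(c("sex", "strain", "treatment", "study") %in%
                  names(metadata_plan)))
  if (!all(metadata_plan$study %in% spec$batches$batch_id)) {
    stop("metadata_plan uses study labels absent from spec$batches")
  }

  treated <- metadata_plan$treatment != "none"
  eff_age <- ifelse(treated, spec$treatment_rate * ages, ages)

  # sites: one synthetic chromosome per ~50 sites, positions spaced 1 kb
  sites <- data.frame(
    chrom = as.character(1 + (seq_len(p) - 1) %/% 50),
    pos = 1000L * seq_len(p)
  )

  if (is.null(age_site_idx)) {
    age_site_idx <- sort(sample.int(p, spec$n_age_sites))
  } else {
    age_site_idx <- sort(as.integer(age_site_idx))
    stopifnot(length(age_site_idx) == spec$n_age_sites,
              all(age_site_idx >= 1), all(age_site_idx <= p))
  }
  is_age <- seq_len(p) %in% age_site_idx

  baseline <- runif(p, 0.05, 0.95)
  baseline[is_age] <- runif(sum(is_age), 0.25, 0.75)
  slope <- numeric(p)
  n_age <- sum(is_age)
  if (n_age > 0) {
    sgn <- ifelse(runif(n_age) < spec$frac_gain, 1, -1)
    slope[is_age] <- sgn * spec$slope_scale * runif(n_age, 0.5, 1.5)
  }
  # store the baseline on the log2(age)=0 scale so that
  # latent = baseline0 + slope * log2(effective_age)
  baseline0 <- baseline - slope * .ref_log_age

  log_eff <- log2(eff_age)
  latent <- outer(log_eff, slope) +
    matrix(baseline0, n, p, byrow = TRUE)
  latent <- pmin(pmax(latent, 0), 1)
  if (spec$entropy_drift > 0) {
    contract <- (eff_age / 7) ^ (-spec$entropy_drift)
    contract <- pmin(contract, 1)
    latent <- 0.5 + (latent - 0.5) * contract
  }

  bidx <- match(metadata_plan$study, spec$batches$batch_id)
  shift <- spec$batches$location_shift[bidx]
  scale <- spec$batches$scale_factor[bidx]
  noise <- matrix(rnorm(n * p, 0, spec$noise_sd), n, p)
  mu_obs <- latent + shift + scale * noise
  mu_obs <- pmin(pmax(mu_obs, 0), 1)

  depth <- matrix(rpois(n * p, spec$mean_depth), n, p)
  if (spec$missing_rate > 0) {
    depth[matrix(runif(n * p), n, p) < spec$missing_rate] <- 0L
  }
  meth <- matrix(rbinom(n * p, as.vector(depth), as.vector(mu_obs)), n, p)
  unmeth <- depth - meth

  ids <- sprintf("s%03d", seq_len(n))
  meta <- data.frame(
    sample_id = ids, age_days = ages,
    sex = metadata_plan$sex, strain = metadata_plan$strain,
    treatment = metadata_plan$treatment, study = metadata_plan$study,
    stringsAsFactors = FALSE
  )
  truth <- list(
    site = data.frame(site_id = site_ids(sites), is_age_site = is_age,
                      slope = slope, baseline = baseline0),
    sample = data.frame(sample_id = ids, age_days = ages,
                        batch = metadata_plan$study,
                        treatment = metadata_plan$treatment,
                        effective_age_days = eff_age),
    latent = latent
  )
  list(matrix = meth_matrix(meth = meth, unmeth = unmeth,
                            sites = sites, sample_ids = ids),
       meta = meta, truth = truth)
}

#' Simulate two cohorts over an orthologous site space
#'
#' Produces two cohorts whose sites correspond one-to-one through a shared
#' probe space, with a planted overlap between the two age-site sets:
#' `round(shared_fraction * min(n_age_a, n_age_b))` drifting sites are
#' common to both cohorts, the remainder are disjoint where space permits.
#'
#' @param spec_a,spec_b [cohort_spec()]s with equal `n_sites`.
#' @param shared_fraction fraction in \[0, 1\] of age sites planted in both.
#' @return list with cohorts `a`, `b`, an `ortholog_map` (see
#'   [build_ortholog_space()] for the shape) and `planted_overlap`.
#' @export
simulate_orthologous_pair <- function(spec_a, spec_b, shared_fraction) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            spec_a$n_sites == spec_b$n_sites)
  p <- spec_a$n_sites
  n_shared <- round(shared_fraction * min(spec_a$n_age_sites,
                                          spec_b$n_age_sites))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec_a$seed + 1000L * spec_b$seed %% 1000L)
  perm <- sample.int(p)
  idx_a <- sort(perm[seq_len(spec_a$n_age_sites)])
  shared <- sort(perm[seq_len(n_shared)])
  rest_pool <- setdiff(perm, idx_a)
  n_rest <- spec_b$n_age_sites - n_shared
  if (n_rest > length(rest_pool)) {
    # not enough disjoint sites; overflow re-uses a-sites beyond the plan
    extra <- setdiff(idx_a, shared)[seq_len(n_rest - length(rest_pool))]
    idx_b <- sort(c(shared, rest_pool, extra))
  } else {
    idx_b <- sort(c(shared, rest_pool[seq_len(n_rest)]))
  }
  a <- simulate_cohort(spec_a, age_site_idx = idx_a)
  b <- simulate_cohort(spec_b, age_site_idx = idx_b)
  map <- data.frame(
    mouse_site = site_ids(a$matrix),
    probe_id = sprintf("cg%06d", seq_len(p)),
    human_site = site_ids(b$matrix),
    stringsAsFactors = FALSE
  )
  list(a = a, b = b,
       ortholog_map = map,
       planted_overlap = length(intersect(idx_a, idx_b)))
}
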