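#' Combine matrices from several studies over the union of their sites
#'
#' Cells absent from a study's matrix are missing. Site order is (chrom,
#' pos); sample ids must be globally unique.
#'
#' @param matrices list of [meth_matrix()]s with counts.
#' @return a [meth_matrix()]
#' @export
combine_matrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  all_sites <- unique(do.call(rbind, lapply(matrices, `[[`, "sites")))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  key <- paste0(all_sites$chrom, ":", all_sites$pos)
  ids <- unlist(lapply(matrices, `[[`, "sample_ids"))
  n <- length(ids); p <- nrow(all_sites)
  meth <- matrix(0L, n, p); unmeth <- matrix(0L, n, p)
  at <- 0
  for (m in matrices) {
    j <- match(site_ids(m), key)
    rows <- at + seq_along(m$sample_ids)
    meth[rows, j] <- m$meth
    unmeth[rows, j] <- m$unmeth
    at <- at + length(m$sample_ids)
  }
  meth_matrix(meth = meth, unmeth = unmeth, sites = all_sites,
              sample_ids = ids)
}

# fraction matrix with cells below the read threshold masked out
observed_fraction <- function(m, min_reads) {
  if (is.null(m$meth)) {
    if (min_reads > 0) {
      # count-free matrices: every nonmissing fraction counts as observed
      return(m$fraction)
    }
    return(m$fraction)
  }
  tot <- m$meth + m$unmeth
  fr <- ifelse(tot >= min_reads & tot > 0, m$meth / tot, NA_real_)
  fr[is.na(m$fraction)] <- NA_real_
  dimnames(fr) <- dimnames(m$fraction)
  fr
}

impute_site_mean <- function(fr) {
  mu <- colMeans(fr, na.rm = TRUE)
  all_missing <- !is.finite(mu)
  if (any(all_missing)) {
    warning(sum(all_missing), " site(s) with no observed values imputed ",
            "with the grand mean")
    mu[all_missing] <- mean(fr, na.rm = TRUE)
  }
  idx <- which(is.na(fr), arr.ind = TRUE)
  n_imputed <- nrow(idx)
  if (n_imputed) fr[idx] <- mu[idx[, 2]]
  list(fraction = fr, n_imputed = n_imputed)
}

filter_core <- function(m, min_reads, max_site_missing, sd_bounds,
                        max_sample_missing, chrom_whitelist) {
  fr <- observed_fraction(m, min_reads)
  p <- ncol(fr)
  removed <- c(duplicate = 0L, chromosome = 0L, coverage = 0L,
               sd = 0L)
  alive <- rep(TRUE, p)

  dup <- duplicated(site_ids(m)) | duplicated(site_ids(m), fromLast = TRUE)
  removed["duplicate"] <- sum(alive & dup)
  alive <- alive & !dup

  on_chrom <- m$sites$chrom %in% chrom_whitelist
  removed["chromosome"] <- sum(alive & !on_chrom)
  alive <- alive & on_chrom

  miss_frac <- colMeans(is.na(fr))
  cov_ok <- miss_frac < max_site_missing
  removed["coverage"] <- sum(alive & !cov_ok)
  alive <- alive & cov_ok

  if (!is.null(sd_bounds)) {
    sds <- apply(fr, 2, stats::sd, na.rm = TRUE)
    sd_ok <- !is.na(sds) & sds > sd_bounds[1] & sds <= sd_bounds[2]
    removed["sd"] <- sum(alive & !sd_ok)
    alive <- alive & sd_ok
  }
  if (!any(alive)) stop("all sites removed by filtering")

  keep_sites <- which(alive)
  fr_kept <- fr[, keep_sites, drop = FALSE]
  samp_missing <- rowMeans(is.na(fr_kept))
  keep_samples <- which(samp_missing <= max_sample_missing)
  if (!length(keep_samples)) stop("all samples removed by filtering")

  imp <- impute_site_mean(fr_kept[keep_samples, , drop = FALSE])
  out <- meth_matrix(
    meth = if (is.null(m$meth)) NULL else
      m$meth[keep_samples, keep_sites, drop = FALSE],
    unmeth = if (is.null(m$unmeth)) NULL else
      m$unmeth[keep_samples, keep_sites, drop = FALSE],
    fraction = imp$fraction,
    sites = m$sites[keep_sites, , drop = FALSE],
    sample_ids = m$sample_ids[keep_samples]
  )
  report <- list(
    sites_in = p, sites_out = length(keep_sites),
    samples_in = nrow(fr), samples_out = length(keep_samples),
    sites_removed = as.list(removed),
    samples_removed = nrow(fr) - length(keep_samples),
    n_imputed = imp$n_imputed
  )
  list(matrix = out, report = report)
}

#' Cross-species filtering profile
#'
#' The reproducibility profile applied before ortholog mapping: a cell is
#' observed iff it has >= 5 reads; a site is kept iff it is missing in
#' < 20% of samples pooled across all supplied studies, maps uniquely, and
#' lies on autosomes 1-19; samples missing > 40% of the kept sites are then
#' dropped, and remaining missing cells are imputed with the site mean.
#'
#' @param matrices list of >= 2 per-study [meth_matrix()]s (with counts).
#' @param min_reads,max_site_missing,max_sample_missing profile thresholds.
#' @param chrom_whitelist chromosomes retained (default "1".."19").
#' @return list with `matrix` (filtered, imputed) and `report`.
#' @export
filter_cross_species <- function(matrices, min_reads = 5,
                                 max_site_missing = 0.20,
                                 max_sample_missing = 0.40,
                                 chrom_whitelist = as.character(1:19)) {
  if (!is.list(matrices) || inherits(matrices, "meth_matrix")) {
    stop("supply a list of per-study matrices")
  }
  if (length(matrices) < 2) stop("cross-species profile needs >= 2 studies")
  m <- combine_matrices(matrices)
  filter_core(m, min_reads, max_site_missing, sd_bounds = NULL,
              max_sample_missing, chrom_whitelist)
}

#' Clock-construction filtering profile
#'
#' A cell is observed iff it has >= 2 reads; a site is kept iff observed in
#' at least 97% of samples, lies on autosomes 1-19, and the standard
#' deviation of its observed fractions (n-1 denominator) is > 0 and
#' <= 0.20; samples missing > 30% of kept sites are dropped; remaining
#' missing cells are imputed with the site mean.
#'
#' @param m a [meth_matrix()] with counts.
#' @param min_reads,min_presence,sd_max,max_sample_missing profile
#'   thresholds; presence is inclusive (>= 0.97).
#' @param chrom_whitelist chromosomes retained.
#' @return list with `matrix` and `report`.
#' @export
filter_clock <- function(m, min_reads = 2, min_presence = 0.97,
                         sd_max = 0.20, max_sample_missing = 0.30,
                         chrom_whitelist = as.character(1:19)) {
  filter_core(m, min_reads,
              max_site_missing = 1 - min_presence + 1e-12,
              sd_bounds = c(0, sd_max),
              max_sample_missing, chrom_whitelist)
}

#' Relaxed projection onto a target site set
#'
#' Used for single-timepoint studies and treated cohorts: restrict a matrix
#' to the clock profile's site set, count any cell with >= 1 read as
#' observed, and impute remaining missing cells with the site mean computed
#' over this matrix.
#'
#' @param m a [meth_matrix()].
#' @param target_sites character vector of "chrom:pos" site ids (0-based),
#'   or a sites data.frame / [meth_matrix()].
#' @return a [meth_matrix()] over the intersected sites, fully imputed.
#' @export
project_relaxed <- function(m, target_sites) {
  if (!is.character(target_sites)) target_sites <- site_ids(target_sites)
  idx <- match(target_sites, site_ids(m))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no overlap with target sites")
  sub <- subset_matrix(m, sites = idx)
  fr <- observed_fraction(sub, min_reads = 1)
  imp <- impute_site_mean(fr)
  meth_matrix(meth = sub$meth, unmeth = sub$unmeth,
              fraction = imp$fraction, sites = sub$sites,
              sample_ids = sub$sample_ids)
}
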