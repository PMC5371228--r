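#' Methylation matrix container
#'
#' A `meth_matrix` holds per-sample, per-CpG methylation data: methylated and
#' unmethylated read counts (when available), the derived methylation
#' fraction in \[0, 1\], and the site coordinates. Samples are rows, sites are
#' columns; a cell is missing (`NA` fraction) when it has zero total reads or
#' was dropped at simulation/import time. Positions follow a 0-based
#' convention throughout the package.
#'
#' @param meth,unmeth integer matrices (samples x sites) of methylated and
#'   unmethylated read counts, or `NULL` when only fractions exist (e.g.
#'   after imputation or probe collapse).
#' @param fraction numeric matrix (samples x sites) of methylation fractions;
#'   computed from counts when `NULL`.
#' @param sites data.frame with columns `chrom` (character, no "chr" prefix)
#'   and `pos` (0-based integer position of the CpG cytosine).
#' @param sample_ids character vector of sample identifiers (row order).
#'
#' @return An object of class `meth_matrix`: a list with elements `meth`,
#'   `unmeth`, `fraction`, `sites`, `sample_ids`.
#' @export
meth_matrix <- function(meth = NULL, unmeth = NULL, fraction = NULL,
                        sites, sample_ids) {
  sites <- normalize_sites(sites)
  n_site <- nrow(sites)
  n_samp <- length(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (is.null(fraction)) {
    if (is.null(meth) || is.null(unmeth)) {
      stop("either counts (meth, unmeth) or fraction must be supplied")
    }
    tot <- meth + unmeth
    fraction <- ifelse(tot > 0, meth / tot, NA_real_)
  }
  for (m in list(fraction, meth, unmeth)) {
    if (!is.null(m) && (nrow(m) != n_samp || ncol(m) != n_site)) {
      stop("matrix dimensions do not match samples x sites (",
           n_samp, " x ", n_site, ")")
    }
  }
  if (!is.null(meth) && (any(meth < 0, na.rm = TRUE) ||
                         any(unmeth < 0, na.rm = TRUE))) {
    stop("negative read counts")
  }
  ids <- site_ids(sites)
  dimnames(fraction) <- list(sample_ids, ids)
  if (!is.null(meth)) dimnames(meth) <- list(sample_ids, ids)
  if (!is.null(unmeth)) dimnames(unmeth) <- list(sample_ids, ids)
  structure(
    list(meth = meth, unmeth = unmeth, fraction = fraction,
         sites = sites, sample_ids = sample_ids),
    class = "meth_matrix"
  )
}

normalize_sites <- function(sites) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  sites$chrom <- sub("^chr", "", as.character(sites$chrom))
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 0)) stop("negative site positions")
  if (any(!nzchar(sites$chrom))) stop("empty chromosome labels")
  rownames(sites) <- NULL
  sites[, c("chrom", "pos"), drop = FALSE]
}

#' Canonical "chrom:pos" site identifiers (0-based)
#' @param sites a sites data.frame or `meth_matrix`
#' @return character vector
#' @export
site_ids <- function(sites) {
  if (inherits(sites, "meth_matrix")) sites <- sites$sites
  paste0(sites$chrom, ":", sites$pos)
}

#' @export
print.meth_matrix <- function(x, ...) {
  n_na <- sum(is.na(x$fraction))
  cat(sprintf(
    "meth_matrix: %d samples x %d sites (%.1f%% missing cells, counts %s)\n",
    nrow(x$fraction), ncol(x$fraction),
    100 * n_na / length(x$fraction),
    if (is.null(x$meth)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$fraction)

#' Subset a methylation matrix by samples and/or sites
#'
#' @param m a `meth_matrix`
#' @param samples logical/integer/character index over samples
#' @param sites logical/integer index over site columns
#' @return a `meth_matrix`
#' @export
subset_matrix <- function(m, samples = NULL, sites = NULL) {
  stopifnot(inherits(m, "meth_matrix"))
  if (is.null(samples)) samples <- seq_along(m$sample_ids)
  if (is.character(samples)) samples <- match(samples, m$sample_ids)
  if (is.null(sites)) sites <- seq_len(nrow(m$sites))
  take <- function(x) if (is.null(x)) NULL else x[samples, sites, drop = FALSE]
  meth_matrix(
    meth = take(m$meth), unmeth = take(m$unmeth),
    fraction = take(m$fraction),
    sites = m$sites[sites, , drop = FALSE],
    sample_ids = m$sample_ids[samples]
  )
}

#' Validate a sample metadata table against a methylation matrix
#'
#' Required columns: `sample_id`, `age_days` (> 0), `sex`, `strain`,
#' `treatment`, `study`. Every matrix sample must have exactly one row.
#'
#' @param meta data.frame of sample metadata
#' @param m optional `meth_matrix` to check coverage against
#' @return `meta`, row-ordered to match `m` when given
#' @export
check_sample_meta <- function(meta, m = NULL) {
  req <- c("sample_id", "age_days", "sex", "strain", "treatment", "study")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (any(meta$age_days <= 0)) stop("non-positive age_days in metadata")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.null(m)) {
    idx <- match(m$sample_ids, meta$sample_id)
    if (anyNA(idx)) {
      stop("samples without metadata: ",
           paste(m$sample_ids[is.na(idx)], collapse = ", "))
    }
    meta <- meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

days_per_month <- 365.25 / 12
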