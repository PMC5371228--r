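#' Build a covariate + age design matrix
#'
#' Categorical covariates are one-hot encoded against a reference level
#' (first level alphabetically); age enters as a single continuous column,
#' last. Covariates that are constant across the samples are dropped with a
#' message (they carry no information and would break the fit).
#'
#' @param meta sample metadata data.frame.
#' @param covariates character vector of metadata column names.
#' @param age_transform `"identity"` (age in days as given) or `"log2"`.
#' @return list with `full` and `reduced` (no-age) design matrices and
#'   `age_col` index.
#' @keywords internal
build_design <- function(meta, covariates, age_transform = "identity") {
  n <- nrow(meta)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (!cv %in% names(meta)) stop("covariate not in metadata: ", cv)
    v <- meta[[cv]]
    if (is.numeric(v)) {
      if (stats::sd(v) == 0) { message("dropping constant covariate ", cv); next }
      X <- cbind(X, stats::setNames(data.frame(v), cv))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) { message("dropping constant covariate ", cv); next }
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      X <- cbind(X, mm)
    }
  }
  X <- as.matrix(X)
  age <- switch(age_transform,
                identity = meta$age_days,
                log2 = log2(meta$age_days),
                stop("unknown age_transform: ", age_transform))
  full <- cbind(X, age = age)
  list(full = full, reduced = X, age_col = ncol(full))
}

#' Covariate-adjusted age association with a drop-one F-test
#'
#' For every site, fits ordinary least squares of the methylation fraction
#' on covariates plus age and on the covariates alone, and tests the age
#' term with the F statistic
#' `F = ((RSS_reduced - RSS_full)/1) / (RSS_full/(n - p_full))`, with the
#' p-value from the upper tail of F(1, n - p_full). Benjamini-Hochberg q
#' values are attached and the age-associated set is `{q <= fdr_level}`.
#'
#' @param m a [meth_matrix()] with no missing fractions (filter/impute
#'   first).
#' @param meta metadata (matched to the matrix).
#' @param covariates covariate column names (e.g. `c("treatment", "sex")`).
#' @param fdr_level FDR threshold for the significant set (default 0.01).
#' @param age_transform passed to the design builder.
#' @return data.frame per site: `site_id`, `rss_full`, `rss_reduced`,
#'   `f_stat`, `p_value`, `q_value`, `age_coef`, `significant`.
#' @export
test_age_association <- function(m, meta, covariates = c("treatment", "sex"),
                                 fdr_level = 0.01,
                                 age_transform = "identity") {
  if (inherits(m, "meth_matrix")) {
    Y <- m$fraction
    ids <- site_ids(m)
  } else {
    Y <- as.matrix(m)
    ids <- colnames(Y)
  }
  if (anyNA(Y)) stop("matrix has missing cells; filter/impute first")
  meta <- check_sample_meta(meta)[match(rownames(Y), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples")

  d <- build_design(meta, covariates, age_transform)
  n <- nrow(Y); p_full <- ncol(d$full)
  if (n <= p_full) stop("not enough samples for the design (n <= p)")
  qr_full <- qr(d$full)
  if (qr_full$rank < p_full) {
    bad <- colnames(d$full)[qr_full$pivot[(qr_full$rank + 1):p_full]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  qr_red <- qr(d$reduced)

  rss_full <- colSums(qr.resid(qr_full, Y)^2)
  rss_red <- colSums(qr.resid(qr_red, Y)^2)
  df2 <- n - p_full
  f_stat <- pmax(rss_red - rss_full, 0) / (rss_full / df2)
  p <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
  coefs <- qr.coef(qr_full, Y)
  age_coef <- coefs[d$age_col, ]

  bh <- bh_fdr(p, fdr_level)
  data.frame(site_id = ids, rss_full = rss_full, rss_reduced = rss_red,
             f_stat = f_stat, p_value = p, q_value = bh$q_value,
             age_coef = age_coef, significant = bh$rejected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p vector of p-values in \[0, 1\].
#' @param level FDR level for the rejection set.
#' @return list with `q_value` and logical `rejected` (`q <= level`).
#' @export
bh_fdr <- function(p, level = 0.01) {
  if (!length(p)) return(list(q_value = numeric(), rejected = logical()))
  stopifnot(all(p >= 0 & p <= 1))
  q <- stats::p.adjust(p, method = "BH")
  list(q_value = q, rejected = q <= level)
}

#' Replicate age associations in independent cohorts
#'
#' Restricts testing to the sites found significant in a primary cohort,
#' pools the replication cohorts' samples, re-runs the drop-one F-test on
#' that restricted set, applies BH within the set, and returns the sites
#' significant in both analyses.
#'
#' @param primary an association table from [test_age_association()].
#' @param replication list of cohorts, each a list with `matrix` and `meta`.
#' @param covariates,fdr_level,age_transform as in
#'   [test_age_association()].
#' @return character vector of replicated site ids.
#' @export
replicate_associations <- function(primary, replication,
                                   covariates = c("treatment", "sex"),
                                   fdr_level = 0.01,
                                   age_transform = "identity") {
  candidates <- primary$site_id[primary$significant]
  if (!length(candidates)) return(character())
  frs <- list(); metas <- list()
  for (co in replication) {
    idx <- match(candidates, site_ids(co$matrix))
    if (all(is.na(idx))) next
    frs[[length(frs) + 1]] <-
      co$matrix$fraction[, idx, drop = FALSE]
    metas[[length(metas) + 1]] <- check_sample_meta(co$meta)
  }
  if (!length(frs)) stop("no candidate sites present in replication data")
  Y <- do.call(rbind, frs)
  colnames(Y) <- candidates
  meta <- do.call(rbind, metas)
  rownames(Y) <- meta$sample_id
  rep_tab <- test_age_association(Y, meta, covariates, fdr_level,
                                  age_transform)
  rep_tab$site_id[rep_tab$significant]
}

#' Normalized methylome entropy
#'
#' Per-sample disorder statistic over a set of (age-associated) sites:
#' `Entropy = 1/(N log(1/2)) * sum_i [MF_i log MF_i + (1-MF_i) log(1-MF_i)]`
#' with any term whose fraction is exactly 0 or 1 contributing 0. Values lie
#' in \[0, 1\]: 0 when every site is fully (un)methylated, 1 when every site
#' sits at 0.5. The normalizer cancels the logarithm base. The Pearson
#' correlation of entropy with age (untransformed, in months) is reported.
#'
#' @param m a [meth_matrix()] (or plain fraction matrix, samples x sites)
#'   already restricted to the site set of interest.
#' @param meta optional metadata; when given, per-sample ages and the
#'   entropy-age Pearson r are attached.
#' @return list with `samples` (data.frame sample_id, entropy, and ages
#'   when available), `pearson_r` (or `NA`), `n_sites`.
#' @export
methylome_entropy <- function(m, meta = NULL) {
  fr <- if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m)
  if (!ncol(fr)) stop("entropy needs at least one site")
  if (anyNA(fr)) stop("matrix has missing cells; filter/impute first")
  if (any(fr < 0 | fr > 1)) stop("fractions outside [0, 1]")
  term <- function(x) ifelse(x <= 0 | x >= 1, 0,
                             x * log(x) + (1 - x) * log(1 - x))
  ent <- rowSums(term(fr)) / (ncol(fr) * log(0.5))
  out <- data.frame(sample_id = rownames(fr), entropy = ent,
                    row.names = NULL, stringsAsFactors = FALSE)
  r <- NA_real_
  if (!is.null(meta)) {
    meta <- check_sample_meta(meta)
    age <- meta$age_days[match(out$sample_id, meta$sample_id)]
    out$age_days <- age
    out$age_months <- age / days_per_month
    if (stats::sd(out$age_months) > 0 && stats::sd(ent) > 0) {
      r <- stats::cor(ent, out$age_months)
    }
  }
  list(samples = out, pearson_r = r, n_sites = ncol(fr))
}
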