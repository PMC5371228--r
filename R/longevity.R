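#' Compare epigenetic ages between treatments and matched controls
#'
#' Each treated group is compared with the untreated samples sharing its
#' genetic background and age group: the reported reduction is
#' `mean(control epigenetic age) - mean(treated epigenetic age)` in months,
#' with a two-sided two-sample t-test (Student's equal-variance by default).
#' A one-way ANOVA of epigenetic age on treatment is run across the oldest
#' age group (the design's 22-month animals).
#'
#' @param pred a prediction table from [predict_age()] (with metadata
#'   columns attached).
#' @param meta sample metadata.
#' @param age_group optional vector of age-group labels per sample;
#'   defaults to the chronological age rounded to whole months.
#' @param var_equal use the pooled-variance t statistic (default `TRUE`;
#'   `FALSE` gives Welch).
#' @param anova_group age-group label for the ANOVA; defaults to the oldest
#'   group containing a treated sample.
#' @return list: `comparisons` (per treatment x strain x age group:
#'   n, means, `reduction_months`, `t_stat`, `p_value`) and `anova`
#'   (`f_stat`, `p_value`, `group`).
#' @export
compare_treatments <- function(pred, meta, age_group = NULL,
                               var_equal = TRUE, anova_group = NULL) {
  meta <- check_sample_meta(meta)
  idx <- match(pred$sample_id, meta$sample_id)
  strain <- meta$strain[idx]
  treatment <- meta$treatment[idx]
  age_m <- meta$age_days[idx] / days_per_month
  if (is.null(age_group)) age_group <- as.character(round(age_m))
  epi <- pred$epi_age_months

  treated_groups <- unique(data.frame(treatment, strain, age_group,
                                      stringsAsFactors = FALSE))
  treated_groups <- treated_groups[treated_groups$treatment != "none", ,
                                   drop = FALSE]
  rows <- lapply(seq_len(nrow(treated_groups)), function(i) {
    g <- treated_groups[i, ]
    tr <- which(treatment == g$treatment & strain == g$strain &
                  age_group == g$age_group)
    ct <- which(treatment == "none" & strain == g$strain &
                  age_group == g$age_group)
    if (length(ct) < 2 || length(tr) < 2) {
      stop("treated group without matched control (or n < 2): ",
           g$treatment, "/", g$strain, "/", g$age_group)
    }
    if (stats::sd(c(epi[ct], epi[tr])) == 0) {
      tt <- list(statistic = 0, p.value = 1)   # identical groups
    } else {
      tt <- stats::t.test(epi[ct], epi[tr], var.equal = var_equal)
    }
    data.frame(treatment = g$treatment, strain = g$strain,
               age_group = g$age_group, n_treated = length(tr),
               n_control = length(ct),
               mean_treated = mean(epi[tr]), mean_control = mean(epi[ct]),
               reduction_months = mean(epi[ct]) - mean(epi[tr]),
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, rows)

  anova <- NULL
  if (is.null(anova_group) && nrow(comparisons)) {
    grp_age <- suppressWarnings(as.numeric(comparisons$age_group))
    anova_group <- comparisons$age_group[which.max(grp_age)]
  }
  if (!is.null(anova_group)) {
    sel <- which(age_group == anova_group)
    if (length(unique(treatment[sel])) >= 2) {
      fit <- stats::aov(epi[sel] ~ factor(treatment[sel]))
      s <- summary(fit)[[1]]
      anova <- list(f_stat = s$`F value`[1], p_value = s$`Pr(>F)`[1],
                    group = anova_group)
    }
  }
  list(comparisons = comparisons, anova = anova)
}

#' PCA of clock sites with a PC1 ~ age + treatment regression
#'
#' Centered (not scaled) principal components of the methylation fractions
#' restricted to the clock's sites. PC1's sign is fixed so that it
#' correlates positively with age. Per genetic background, a multivariate
#' linear regression of PC1 on age and treatment (categorical) is fitted.
#'
#' @param m a [meth_matrix()] restricted to the clock sites.
#' @param meta sample metadata.
#' @return list: `scores`, `loadings`, `var_explained`, `regressions`
#'   (per strain: term, estimate, p_value).
#' @export
pca_clock_sites <- function(m, meta) {
  fr <- if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m)
  if (nrow(fr) < 3) stop("PCA needs at least 3 samples")
  meta <- check_sample_meta(meta)
  idx <- match(rownames(fr), meta$sample_id)
  age <- meta$age_days[idx]
  pc <- stats::prcomp(fr, center = TRUE, scale. = FALSE)
  flip <- stats::cor(pc$x[, 1], age)
  if (!is.na(flip) && flip < 0) {
    pc$x[, 1] <- -pc$x[, 1]
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  regs <- lapply(unique(meta$strain[idx]), function(st) {
    sel <- which(meta$strain[idx] == st)
    if (length(sel) < 4) return(NULL)
    df <- data.frame(pc1 = pc$x[sel, 1], age = age[sel],
                     treatment = factor(meta$treatment[idx][sel]))
    if (nlevels(df$treatment) < 2) {
      fit <- stats::lm(pc1 ~ age, data = df)
    } else {
      fit <- stats::lm(pc1 ~ age + treatment, data = df)
    }
    cf <- summary(fit)$coefficients
    data.frame(strain = st, term = rownames(cf), estimate = cf[, 1],
               p_value = cf[, 4], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  list(scores = pc$x, loadings = pc$rotation, var_explained = ve,
       regressions = do.call(rbind, regs))
}

#' Hierarchical clustering of samples over scaled methylation values
#'
#' Sites are rescaled per site to \[0, 1\] (subtract the minimum, divide by
#' the range; `"zscore"` available as an alternative); zero-range sites are
#' dropped with a warning. Samples are clustered on Euclidean distance with
#' average linkage. The site subset is either the top-k most variable sites
#' (variance over `variance_samples`, n-1 denominator) or an explicit set.
#'
#' @param m a [meth_matrix()].
#' @param sites `"top_variable"` or a character vector of site ids.
#' @param k number of top-variable sites (default 20).
#' @param scale `"minmax"` (default) or `"zscore"`.
#' @param variance_samples sample ids over which to rank variance
#'   (default: all).
#' @return list: `hclust` (the dendrogram), `order` (leaf order),
#'   `matrix` (scaled values, samples in leaf order), `sites_used`.
#' @export
cluster_heatmap <- function(m, sites = "top_variable", k = 20,
                            scale = c("minmax", "zscore"),
                            variance_samples = NULL) {
  scale <- match.arg(scale)
  fr <- if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m)
  if (identical(sites, "top_variable")) {
    vs <- if (is.null(variance_samples)) fr else
      fr[rownames(fr) %in% variance_samples, , drop = FALSE]
    v <- apply(vs, 2, stats::var, na.rm = TRUE)
    if (k > ncol(fr)) stop("k exceeds the site count")
    sel <- order(v, decreasing = TRUE)[seq_len(k)]
  } else {
    sel <- match(sites, colnames(fr))
    if (anyNA(sel)) stop("unknown site id(s) in `sites`")
  }
  sub <- fr[, sel, drop = FALSE]
  scaled <- apply(sub, 2, function(x) {
    if (scale == "minmax") {
      rng <- range(x)
      if (diff(rng) == 0) return(rep(NA_real_, length(x)))
      (x - rng[1]) / diff(rng)
    } else {
      if (stats::sd(x) == 0) return(rep(NA_real_, length(x)))
      (x - mean(x)) / stats::sd(x)
    }
  })
  drop_cols <- which(colSums(is.na(scaled)) > 0)
  if (length(drop_cols)) {
    warning(length(drop_cols), " zero-range site(s) dropped before clustering")
    scaled <- scaled[, -drop_cols, drop = FALSE]
  }
  hc <- stats::hclust(stats::dist(scaled, method = "euclidean"),
                      method = "average")
  list(hclust = hc, order = hc$order,
       matrix = scaled[hc$order, , drop = FALSE],
       sites_used = colnames(scaled))
}
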