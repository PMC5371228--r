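#' Train an elastic-net epigenetic clock
#'
#' Regresses log2(age in days) on methylation fractions with the elastic-net
#' penalty `lambda * [alpha ||w||_1 + (1 - alpha)/2 ||w||_2^2]` (the
#' `glmnet` objective with the residual term scaled by 1/(2n)).
#' Hyperparameters are chosen by k-fold cross-validation: samples are
#' shuffled once by `seed` and split into contiguous blocks; for every
#' (alpha, lambda) pair the mean held-out criterion across folds is
#' computed, the best pair is refit on all training data.
#'
#' @param m a [meth_matrix()] with no missing fractions (batch-adjusted).
#' @param meta sample metadata (ages in days).
#' @param folds number of CV folds (default 4).
#' @param alphas L1 mixing fractions to scan.
#' @param lambda optional explicit penalty sequence; by default glmnet's
#'   auto-scaled 50-value logarithmic path per alpha.
#' @param n_lambda path length when `lambda` is `NULL`.
#' @param criterion model-selection metric: `"mse"` (mean held-out squared
#'   error, minimized; the default) or `"pearson"` (mean held-out Pearson
#'   r, maximized). Pearson r is scale-invariant and so cannot distinguish
#'   shrinkage levels; per-fold r is always reported regardless of the
#'   selection metric.
#' @param seed integer controlling the fold shuffle.
#' @param thresh glmnet convergence threshold.
#' @return a `clock_model`: `sites` (data.frame site_id, chrom, pos,
#'   weight for nonzero weights), `intercept` (log2 days), `alpha`,
#'   `lambda`, `cv` (per alpha/lambda mean criterion and per-fold values
#'   at the chosen pair), `train_samples`.
#' @export
train_clock <- function(m, meta, folds = 4,
                        alphas = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                        lambda = NULL, n_lambda = 50,
                        criterion = c("mse", "pearson"),
                        seed = 1L, thresh = 1e-10) {
  criterion <- match.arg(criterion)
  if (!length(alphas)) stop("empty hyperparameter grid")
  X <- if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m)
  if (anyNA(X)) stop("matrix has missing cells; filter/impute first")
  meta <- check_sample_meta(meta)
  meta <- meta[match(rownames(X), meta$sample_id), ]
  y <- log2(meta$age_days)
  n <- nrow(X)
  if (n < 2 * folds) stop("need at least 2 samples per fold")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  # shuffle once, then split into contiguous blocks of comparable size
  ord <- sample.int(n)
  foldid <- integer(n)
  splits <- split(ord, cut(seq_len(n), folds, labels = FALSE))
  for (k in seq_len(folds)) foldid[splits[[k]]] <- k

  best <- list(score = if (criterion == "pearson") -Inf else Inf)
  cv_rows <- list()
  for (a in alphas) {
    lam <- lambda
    if (is.null(lam)) {
      lam <- glmnet::glmnet(X, y, alpha = a, nlambda = n_lambda,
                            thresh = thresh)$lambda
    }
    mse <- matrix(NA_real_, folds, length(lam))
    pear <- matrix(NA_real_, folds, length(lam))
    for (k in seq_len(folds)) {
      tr <- foldid != k
      if (stats::sd(y[tr]) == 0) stop("degenerate fold: constant age")
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = a,
                            lambda = lam, thresh = thresh)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      for (l in seq_len(ncol(pred))) {
        mse[k, l] <- mean((pred[, l] - y[!tr])^2)
        pear[k, l] <- if (stats::sd(pred[, l]) == 0) 0 else
          stats::cor(pred[, l], y[!tr])
      }
    }
    perf <- if (criterion == "pearson") pear else mse
    mean_perf <- colMeans(perf)
    pick <- if (criterion == "pearson") which.max(mean_perf) else
      which.min(mean_perf)
    cv_rows[[length(cv_rows) + 1]] <- data.frame(
      alpha = a, lambda = lam[pick], score = mean_perf[pick],
      fold_r = mean(pear[, pick]))
    better <- if (criterion == "pearson") mean_perf[pick] > best$score else
      mean_perf[pick] < best$score
    if (better) {
      best <- list(score = mean_perf[pick], alpha = a,
                   lambda = lam[pick], lam_seq = lam,
                   fold_scores = perf[, pick], fold_r = pear[, pick])
    }
  }

  fit <- glmnet::glmnet(X, y, alpha = best$alpha, lambda = best$lam_seq,
                        thresh = thresh)
  # best$lambda is a knot of lam_seq, so no exact refit is needed
  cf <- as.numeric(stats::coef(fit)[, which.min(abs(best$lam_seq -
                                                      best$lambda))])
  w <- cf[-1]
  nz <- which(w != 0)
  sites_df <- if (inherits(m, "meth_matrix")) m$sites else
    data.frame(chrom = NA_character_, pos = NA_integer_)[rep(1, ncol(X)), ]
  structure(
    list(
      sites = data.frame(site_id = colnames(X)[nz],
                         chrom = sites_df$chrom[nz],
                         pos = sites_df$pos[nz],
                         weight = w[nz], stringsAsFactors = FALSE),
      intercept = cf[1], alpha = best$alpha, lambda = best$lambda,
      cv = do.call(rbind, cv_rows), cv_score = best$score,
      fold_scores = best$fold_scores, fold_r = best$fold_r,
      criterion = criterion,
      train_samples = rownames(X), foldid = foldid, seed = seed),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "clock_model: %d sites, intercept %.3f log2(days); alpha=%.2f lambda=%.4g; CV %s=%.3f\n",
    nrow(x$sites), x$intercept, x$alpha, x$lambda, x$criterion, x$cv_score))
  invisible(x)
}

#' Predict epigenetic age
#'
#' `epigenetic age (days) = 2^(b + sum_j w_j x_j)`; the residual
#' (epigenetic minus chronological, in months of 30.4375 days) is attached
#' when metadata is supplied.
#'
#' @param model a `clock_model`.
#' @param m a [meth_matrix()] containing all model sites (project with
#'   [project_relaxed()] first if needed).
#' @param meta optional metadata with chronological ages.
#' @return data.frame per sample: `sample_id`, `epi_age_log2`,
#'   `epi_age_days`, `epi_age_months`, and with metadata `age_days`,
#'   `age_months`, `residual_months`.
#' @export
predict_age <- function(model, m, meta = NULL) {
  X <- if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m)
  idx <- match(model$sites$site_id, colnames(X))
  if (anyNA(idx)) {
    stop("matrix missing model site(s): ",
         paste(model$sites$site_id[is.na(idx)], collapse = ", "))
  }
  Xs <- X[, idx, drop = FALSE]
  if (anyNA(Xs)) stop("missing values at model sites; impute first")
  lg <- model$intercept + as.numeric(Xs %*% model$sites$weight)
  out <- data.frame(sample_id = rownames(X), epi_age_log2 = lg,
                    epi_age_days = 2^lg,
                    epi_age_months = 2^lg / days_per_month,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- check_sample_meta(meta)
    age <- meta$age_days[match(out$sample_id, meta$sample_id)]
    out$age_days <- age
    out$age_months <- age / days_per_month
    out$residual_months <- out$epi_age_months - out$age_months
  }
  out
}

#' Covariate-shuffle permutation control for the full pipeline
#'
#' For each permutation, the covariate rows (age, sex, treatment) are
#' shuffled within each study, batch correction is refit, the clock is
#' retrained with the same strategy, and the mean |residual| over the
#' designated wild-type samples (against their true chronological ages) is
#' recorded. A real age signal should give the unpermuted model the
#' smallest residual.
#'
#' @param m a filtered, imputed (unadjusted) [meth_matrix()].
#' @param meta sample metadata.
#' @param n_permutations number of covariate shuffles (>= 1).
#' @param seed master seed for shuffles and fold assignment.
#' @param wt_ids sample ids evaluated (default: untreated samples).
#' @param combat_mode prior mode for the batch correction.
#' @param ... further arguments to [train_clock()].
#' @return list: `real` (mean |residual| months), `permuted` (vector),
#'   `rank` (1 = real model smallest).
#' @export
permutation_control <- function(m, meta, n_permutations = 20, seed = 1L,
                                wt_ids = NULL,
                                combat_mode = "nonparametric", ...) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  meta <- check_sample_meta(meta, m)
  if (is.null(wt_ids)) wt_ids <- meta$sample_id[meta$treatment == "none"]

  run_once <- function(meta_used) {
    cb <- correct_batches(m, meta_used, mode = combat_mode)
    mdl <- train_clock(cb$matrix, meta_used, seed = seed, ...)
    pred <- predict_age(mdl, cb$matrix, meta)  # true ages for evaluation
    mean(abs(pred$residual_months[pred$sample_id %in% wt_ids]))
  }

  real <- run_once(meta)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed + 7L)
  shuffle_cols <- c("age_days", "sex", "treatment")
  permuted <- vapply(seq_len(n_permutations), function(b) {
    pm <- meta
    for (st in unique(pm$study)) {
      rows <- which(pm$study == st)
      pm[rows, shuffle_cols] <- pm[rows[sample.int(length(rows))],
                                   shuffle_cols]
    }
    run_once(pm)
  }, numeric(1))
  list(real = real, permuted = permuted,
       rank = 1L + sum(permuted < real))
}

#' Classify per-site methylation direction with age
#'
#' Sign of the Pearson correlation between a site's fraction and log2(age)
#' over the training samples; zero correlation is reported as `"flat"`.
#'
#' @param m a [meth_matrix()] (typically restricted to clock sites).
#' @param meta metadata with ages.
#' @return data.frame: `site_id`, `cor`, `direction` in
#'   {"gain", "loss", "flat"}.
#' @export
classify_direction <- function(m, meta) {
  fr <- if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m)
  meta <- check_sample_meta(meta)
  age <- log2(meta$age_days[match(rownames(fr), meta$sample_id)])
  cc <- suppressWarnings(as.numeric(stats::cor(fr, age)))
  cc[is.na(cc)] <- 0
  data.frame(site_id = colnames(fr), cor = cc,
             direction = ifelse(cc > 0, "gain",
                                ifelse(cc < 0, "loss", "flat")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Region enrichment of clock-selected sites
#'
#' Fisher 2x2 tests of (selected vs unselected candidate sites) x
#' (in-region vs not), after resolving multi-label sites to a single label
#' by precedence (enhancer, then promoter, then exon/intron/intergenic).
#'
#' @param model_sites character site ids selected by the clock.
#' @param candidate_sites character ids of all candidate sites.
#' @param annotation logical matrix from [annotate_sites()] over the
#'   candidates.
#' @param precedence label priority, highest first.
#' @return data.frame as in [region_enrichment()].
#' @export
clock_site_enrichment <- function(model_sites, candidate_sites, annotation,
                                  precedence = c("enhancer", "TSS/promoter",
                                                 "exon", "intron",
                                                 "intergenic")) {
  stopifnot(all(model_sites %in% candidate_sites),
            nrow(annotation) == length(candidate_sites))
  labs <- intersect(precedence, colnames(annotation))
  if (!length(labs)) stop("annotation lacks all requested regions")
  resolved <- rep(NA_character_, length(candidate_sites))
  for (lab in labs) {                 # highest precedence assigned first
    hit <- is.na(resolved) & annotation[, lab]
    resolved[hit] <- lab
  }
  one_hot <- vapply(labs, function(l) !is.na(resolved) & resolved == l,
                    logical(length(resolved)))
  one_hot <- matrix(one_hot, ncol = length(labs),
                    dimnames = list(candidate_sites, labs))
  region_enrichment(candidate_sites %in% model_sites, one_hot, labs)
}

#' Export a clock model as TSV (chrom, start, stop 0-based, weight;
#' intercept as a final row)
#' @param model a `clock_model`
#' @param path output path
#' @export
write_clock_model <- function(model, path) {
  df <- data.frame(chrom = model$sites$chrom, start = model$sites$pos,
                   stop = model$sites$pos + 1L,
                   weight = model$sites$weight)
  df <- rbind(df, data.frame(chrom = "intercept", start = NA, stop = NA,
                             weight = model$intercept))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
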