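## Empirical-Bayes location/scale batch adjustment.
##
## Model per site g, sample j in batch i:
##   Y_gj = alpha_g + X_j beta_g + gamma_ig + delta_ig eps_gj
## Sites are standardized with a covariate-adjusted least-squares fit and the
## pooled variance; per-batch location (gamma) and scale (delta) estimates
## are shrunk toward the across-site prior, either parametrically
## (normal / inverse-gamma, iterated to convergence) or nonparametrically
## (posterior expectation under the empirical prior over the other sites,
## computed by exact summation - no Monte Carlo). Covariate signal (age on
## the log2-day scale, sex, treatment) is restored after adjustment.

encode_covariates <- function(meta, covariates, levels = NULL) {
  n <- nrow(meta)
  X <- NULL
  lv <- list()
  for (cv in covariates) {
    if (cv == "age") {
      X <- cbind(X, age = log2(meta$age_days))
      next
    }
    if (!cv %in% names(meta)) stop("covariate not in metadata: ", cv)
    v <- meta[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, matrix(v, ncol = 1, dimnames = list(NULL, cv)))
    } else {
      lev <- if (!is.null(levels) && cv %in% names(levels)) levels[[cv]]
             else sort(unique(as.character(v)))
      if (!all(v %in% lev)) {
        stop("covariate ", cv, " has level(s) unseen at fit time: ",
             paste(setdiff(v, lev), collapse = ", "))
      }
      f <- factor(v, levels = lev)
      if (nlevels(f) >= 2) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, lev[-1])
        X <- cbind(X, mm)
      }
      lv[[cv]] <- lev
    }
  }
  list(X = X, levels = lv)
}

# parametric prior moment estimators (inverse-gamma on delta^2)
.aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
.bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

# iterate the coupled parametric posterior-mode equations for one batch
.it_sol <- function(sdat, g_hat, d_hat, g_bar, t2, a, b, conv = 1e-4) {
  n <- ncol(sdat)
  g_old <- g_hat; d_old <- d_hat
  repeat {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    ss <- rowSums((sdat - g_new)^2)
    d_new <- (0.5 * ss + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_new, delta_star = d_new)
}

# posterior expectations under the empirical prior: site g's estimates are
# the likelihood-weighted average of every other site's (gamma_hat,
# delta_hat); exact summation over sites, no randomness
.int_eprior <- function(sdat, g_hat, d_hat) {
  G <- nrow(sdat); n <- ncol(sdat)
  g_star <- numeric(G); d_star <- numeric(G)
  for (i in seq_len(G)) {
    g <- g_hat[-i]; d <- d_hat[-i]
    x <- sdat[i, ]
    sum2 <- vapply(seq_along(g),
                   function(j) sum((x - g[j])^2), numeric(1))
    log_lh <- -(n / 2) * log(2 * pi * d) - sum2 / (2 * d)
    w <- exp(log_lh - max(log_lh))
    w <- w / sum(w)
    g_star[i] <- sum(w * g)
    d_star[i] <- sum(w * d)
  }
  list(gamma_star = g_star, delta_star = d_star)
}

#' Fit an empirical-Bayes batch-adjustment model
#'
#' @param m a [meth_matrix()] with no missing fractions.
#' @param meta metadata; the `study` column defines the batch.
#' @param covariates biological covariates whose signal must be preserved;
#'   `"age"` is entered as log2(age in days).
#' @param mode `"nonparametric"` (default, empirical prior) or
#'   `"parametric"` (normal/inverse-gamma prior, iterated posterior modes).
#' @param batch_col metadata column holding the batch label.
#' @return a `batch_model`: per-site grand mean, covariate coefficients,
#'   pooled variance, and per-batch per-site `gamma_star` / `delta_star`.
#' @export
fit_batch_model <- function(m, meta, covariates = c("age", "sex", "treatment"),
                            mode = c("nonparametric", "parametric"),
                            batch_col = "study") {
  mode <- match.arg(mode)
  Y <- t(if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m))
  if (anyNA(Y)) stop("matrix has missing cells; filter/impute first")
  meta <- check_sample_meta(meta)
  meta <- meta[match(colnames(Y), meta$sample_id), ]
  batch <- factor(meta[[batch_col]])
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("singleton batch(es): ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  n <- ncol(Y); G <- nrow(Y)

  B <- stats::model.matrix(~ 0 + batch)
  colnames(B) <- levels(batch)
  enc <- encode_covariates(meta, covariates)
  design <- cbind(B, enc$X)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
    stop("covariate confounded with batch; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  B_hat <- solve(crossprod(design), t(design) %*% t(Y))  # p x G
  n_batch <- nlevels(batch)
  grand_mean <- crossprod(tab / n, B_hat[seq_len(n_batch), , drop = FALSE])
  fitted <- t(design %*% B_hat)
  var_pooled <- rowMeans((Y - fitted)^2)
  if (any(var_pooled <= 0)) stop("zero pooled variance at some site(s)")

  cov_part <- if (is.null(enc$X)) matrix(0, G, n) else
    t(enc$X %*% B_hat[-seq_len(n_batch), , drop = FALSE])
  stand_mean <- matrix(grand_mean, G, n) + cov_part
  s_data <- (Y - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, n_batch, G,
                      dimnames = list(levels(batch), rownames(Y)))
  delta_hat <- gamma_hat
  for (i in seq_len(n_batch)) {
    cols <- which(batch == levels(batch)[i])
    gamma_hat[i, ] <- rowMeans(s_data[, cols, drop = FALSE])
    # ML (1/n_i) variance: with identical batches this gives delta = 1
    # exactly, so adjustment of batch-free data is the identity
    delta_hat[i, ] <- rowMeans(
      (s_data[, cols, drop = FALSE] - gamma_hat[i, ])^2)
  }
  delta_hat[delta_hat < 1e-12] <- 1e-12

  gamma_star <- gamma_hat; delta_star <- delta_hat
  for (i in seq_len(n_batch)) {
    cols <- which(batch == levels(batch)[i])
    if (mode == "parametric") {
      sol <- .it_sol(s_data[, cols, drop = FALSE], gamma_hat[i, ],
                     delta_hat[i, ], mean(gamma_hat[i, ]),
                     stats::var(gamma_hat[i, ]),
                     .aprior(delta_hat[i, ]), .bprior(delta_hat[i, ]))
    } else {
      sol <- .int_eprior(s_data[, cols, drop = FALSE], gamma_hat[i, ],
                         delta_hat[i, ])
    }
    gamma_star[i, ] <- sol$gamma_star
    delta_star[i, ] <- sol$delta_star
  }

  structure(
    list(site_id = rownames(Y), grand_mean = as.numeric(grand_mean),
         cov_coef = B_hat[-seq_len(n_batch), , drop = FALSE],
         cov_names = colnames(enc$X), cov_levels = enc$levels,
         covariates = covariates, batch_col = batch_col,
         batches = levels(batch), var_pooled = var_pooled,
         gamma_star = gamma_star, delta_star = delta_star, mode = mode),
    class = "batch_model"
  )
}

#' Apply a fitted batch model to a matrix
#'
#' Standardizes each cell with the model's grand mean, covariate fit and
#' pooled variance, removes the batch's location/scale parameters, and
#' restores the covariate-predicted mean. Adjusted values may leave
#' \[0, 1\]; they are deliberately not clamped (a linear clock consumes them
#' raw) - clamp only in exported per-site reports.
#'
#' @param m a [meth_matrix()] over the model's sites.
#' @param model a `batch_model`.
#' @param meta metadata for the samples being adjusted.
#' @return a [meth_matrix()] with adjusted fractions (counts dropped).
#' @export
apply_batch_model <- function(m, model, meta) {
  Y <- t(if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m))
  if (!identical(rownames(Y), model$site_id)) {
    stop("sites do not match the fitted model")
  }
  meta <- check_sample_meta(meta)
  meta <- meta[match(colnames(Y), meta$sample_id), ]
  batch <- as.character(meta[[model$batch_col]])
  unseen <- setdiff(batch, model$batches)
  if (length(unseen)) {
    stop("unseen batch label(s): ", paste(unseen, collapse = ", "))
  }
  enc <- encode_covariates(meta, model$covariates, levels = model$cov_levels)
  G <- nrow(Y); n <- ncol(Y)
  cov_part <- if (is.null(enc$X)) matrix(0, G, n) else
    t(enc$X[, model$cov_names, drop = FALSE] %*% model$cov_coef)
  stand_mean <- matrix(model$grand_mean, G, n) + cov_part
  s_data <- (Y - stand_mean) / sqrt(model$var_pooled)
  bi <- match(batch, model$batches)
  adj <- (s_data - t(model$gamma_star[bi, , drop = FALSE])) /
    t(sqrt(model$delta_star[bi, , drop = FALSE]))
  out <- adj * sqrt(model$var_pooled) + stand_mean
  sites <- if (inherits(m, "meth_matrix")) m$sites else
    data.frame(chrom = "1", pos = seq_len(G))
  res <- meth_matrix(fraction = t(out), sites = sites,
                     sample_ids = colnames(Y))
  colnames(res$fraction) <- rownames(Y)
  res
}

#' Fit and apply batch correction in one step
#' @inheritParams fit_batch_model
#' @return list with `matrix` (adjusted) and `model`
#' @export
correct_batches <- function(m, meta, covariates = c("age", "sex", "treatment"),
                            mode = "nonparametric", batch_col = "study") {
  model <- fit_batch_model(m, meta, covariates, mode, batch_col)
  list(matrix = apply_batch_model(m, model, meta), model = model)
}

#' Variance of leading principal components explained by batch
#'
#' R-squared of a regression of each of the top principal-component scores
#' on the batch factor; used before vs after adjustment to verify removal
#' of technology/strain structure.
#'
#' @param m a [meth_matrix()].
#' @param meta metadata with the batch column.
#' @param n_pc number of leading components (default 2).
#' @param batch_col metadata column holding the batch label.
#' @return data.frame with `pc`, `var_explained` (of the data) and `r2`
#'   (PC ~ batch).
#' @export
batch_pc_r2 <- function(m, meta, n_pc = 2, batch_col = "study") {
  fr <- if (inherits(m, "meth_matrix")) m$fraction else as.matrix(m)
  meta <- check_sample_meta(meta)
  meta <- meta[match(rownames(fr), meta$sample_id), ]
  batch <- factor(meta[[batch_col]])
  pc <- stats::prcomp(fr, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  r2 <- vapply(seq_len(n_pc), function(k) {
    summary(stats::lm(pc$x[, k] ~ batch))$r.squared
  }, numeric(1))
  data.frame(pc = seq_len(n_pc), var_explained = ve[seq_len(n_pc)], r2 = r2)
}

#' Batch-structure diagnostic before vs after adjustment
#'
#' @param before,after [meth_matrix()]s over the same samples.
#' @param meta metadata.
#' @param n_pc,batch_col as in [batch_pc_r2()].
#' @return data.frame with `pc`, `r2_before`, `r2_after`.
#' @export
check_batch_removal <- function(before, after, meta, n_pc = 2,
                                batch_col = "study") {
  b <- batch_pc_r2(before, meta, n_pc, batch_col)
  a <- batch_pc_r2(after, meta, n_pc, batch_col)
  data.frame(pc = b$pc, r2_before = b$r2, r2_after = a$r2)
}
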