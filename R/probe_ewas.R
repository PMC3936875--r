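# Per-probe EWAS: ordinary least squares of beta on smoking status with
# slide, plate and cell-mixture surrogate covariates; two-sided t-test on
# the smoking coefficient; BH across all fitted probes.

#' Fit per-probe linear models of methylation on smoking
#'
#' For every probe with at least `min_complete` unmasked samples and
#' non-degenerate design, fits `beta ~ smoker + slide + plate + PC1..PCk`
#' by OLS and reports the smoking coefficient's t statistic and two-sided
#' p-value. Smoking is coded 1 = smoker, so the coefficient is the
#' smoker-minus-nonsmoker methylation difference. Adjusted p-values are BH
#' over all fitted probes (m = number fitted). Probes skipped (too few
#' complete cases, zero variance, rank-deficient design) are reported with
#' reasons in the `skipped` attribute.
#'
#' @param betas Cohort [beta_matrix()].
#' @param sheet Sample sheet (sample_id, smoker, slide, plate).
#' @param surrogates Optional surrogate scores from [compute_surrogates()];
#'   `NULL` fits without cell-mixture covariates.
#' @param min_complete Minimum unmasked samples per probe (default 10).
#' @param m_values Model on the logit (M-value) scale instead of the beta
#'   scale (default `FALSE`; betas clipped to \[0.001, 0.999\] before the
#'   transform).
#' @return data.frame of per-probe results sorted by input probe order:
#'   probe_id, mean_beta_smokers, mean_beta_nonsmokers, coefficient,
#'   t_statistic, raw_p, adjusted_p, n_used.
#' @export
fit_probe_models <- function(betas, sheet, surrogates = NULL,
                             min_complete = 10L, m_values = FALSE) {
  stopifnot(inherits(betas, "beta_matrix"))
  ids <- colnames(betas$values)
  idx <- match(ids, sheet$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("sample sheet missing sample(s): %s",
                 paste(ids[is.na(idx)][1:3], collapse = ", ")))
  }
  sh <- sheet[idx, , drop = FALSE]
  covars <- data.frame(smoker = sh$smoker)
  # reference level = first by lexical order; single-level factors dropped
  for (v in c("slide", "plate")) {
    lev <- sort(unique(sh[[v]]))
    if (length(lev) > 1L) covars[[v]] <- factor(sh[[v]], levels = lev)
  }
  X <- stats::model.matrix(~ ., data = covars)
  if (!is.null(surrogates)) {
    sc <- surrogates$scores
    si <- match(ids, rownames(sc))
    if (anyNA(si)) stop("surrogate scores missing cohort sample(s)")
    X <- cbind(X, sc[si, , drop = FALSE])
  }
  coef_idx <- match("smoker", colnames(X))

  Y <- betas$values
  group_smoker <- sh$smoker == 1L
  mean_s <- rowMeans(Y[, group_smoker, drop = FALSE], na.rm = TRUE)
  mean_n <- rowMeans(Y[, !group_smoker, drop = FALSE], na.rm = TRUE)
  if (m_values) {
    Yfit <- log2(pmin(pmax(Y, 0.001), 0.999) /
                 (1 - pmin(pmax(Y, 0.001), 0.999)))
  } else Yfit <- Y

  n_probes <- nrow(Y)
  out_t <- out_p <- out_b <- rep(NA_real_, n_probes)
  out_n <- integer(n_probes)
  skip_reason <- rep(NA_character_, n_probes)

  fit_one <- function(y, rows) {
    Xs <- X[rows, , drop = FALSE]
    if (stats::var(y) == 0) return("zero variance")
    qx <- qr(Xs)
    if (qx$rank < ncol(Xs)) return("rank-deficient design")
    df <- length(y) - ncol(Xs)
    if (df < 1L) return("insufficient residual df")
    b <- qr.coef(qx, y)
    res <- y - as.vector(Xs %*% b)
    s2 <- sum(res^2) / df
    if (s2 < 1e-24) return("zero variance")
    xtxi <- chol2inv(qr.R(qx))
    se <- sqrt(s2 * xtxi[coef_idx, coef_idx])
    tt <- b[coef_idx] / se
    list(b = b[coef_idx], t = tt, p = 2 * stats::pt(-abs(tt), df),
         n = length(y))
  }

  complete <- !apply(betas$mask, 1L, any)
  # batch path: one QR for all fully observed probes
  if (any(complete)) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      skip_reason[complete] <- "rank-deficient design"
    } else {
      Yc <- t(Yfit[complete, , drop = FALSE])
      B <- qr.coef(qx, Yc)
      res <- Yc - X %*% B
      df <- nrow(X) - ncol(X)
      s2 <- colSums(res^2) / df
      xtxi_ss <- chol2inv(qr.R(qx))[coef_idx, coef_idx]
      tt <- B[coef_idx, ] / sqrt(s2 * xtxi_ss)
      ci <- which(complete)
      zero <- s2 < 1e-24 |
        apply(Yfit[complete, , drop = FALSE], 1L, stats::var) == 0
      ok <- ci[!zero]
      out_b[ok] <- B[coef_idx, !zero]
      out_t[ok] <- tt[!zero]
      out_p[ok] <- 2 * stats::pt(-abs(tt[!zero]), df)
      out_n[ok] <- nrow(X)
      skip_reason[ci[zero]] <- "zero variance"
    }
  }
  for (i in which(!complete)) {
    rows <- which(!betas$mask[i, ])
    if (length(rows) < min_complete) {
      skip_reason[i] <- "too few complete cases"
      next
    }
    f <- fit_one(Yfit[i, rows], rows)
    if (is.character(f)) {
      skip_reason[i] <- f
    } else {
      out_b[i] <- f$b; out_t[i] <- f$t; out_p[i] <- f$p; out_n[i] <- f$n
    }
  }

  fitted <- which(!is.na(out_p))
  if (length(fitted) == 0L) stop("no probe could be fitted")
  adj <- rep(NA_real_, n_probes)
  adj[fitted] <- bh_adjust(out_p[fitted])
  res <- data.frame(
    probe_id = rownames(Y)[fitted],
    mean_beta_smokers = mean_s[fitted],
    mean_beta_nonsmokers = mean_n[fitted],
    coefficient = out_b[fitted],
    t_statistic = out_t[fitted],
    raw_p = out_p[fitted],
    adjusted_p = adj[fitted],
    n_used = out_n[fitted],
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  sk <- which(!is.na(skip_reason))
  attr(res, "skipped") <- data.frame(probe_id = rownames(Y)[sk],
                                     reason = skip_reason[sk],
                                     stringsAsFactors = FALSE)
  attr(res, "m_total") <- length(fitted)
  res
}

#' Count probes significant after FDR correction
#'
#' @param results Probe results from [fit_probe_models()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with `n_significant` and `threshold`.
#' @export
summarize_counts <- function(results, alpha = 0.05) {
  list(n_significant = sum(results$adjusted_p <= alpha),
       threshold = alpha)
}
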