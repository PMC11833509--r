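#' Fit per-protein linear models on log2 TMT ratios
#'
#' For each protein the model is
#' \deqn{log2TMTratio = b0 + b1 TRT + b2 SR}
#' where `TRT` and `SR` are indicator variables for the bait
#' proximity-labeling condition and the spatial reference, and the negative
#' control `NC` is the baseline.  The bait-versus-NC log2 fold change is the
#' `b1` coefficient; the bait-versus-SR fold change is the `b1 - b2`
#' contrast.  Fitting is ordinary least squares per protein; on a balanced
#' design the coefficients reduce to group-mean differences.
#'
#' Proteins with missing channels are refit on the observed channels; a
#' protein is dropped (and recorded) when a group becomes empty or the
#' residual degrees of freedom fall below 1.
#'
#' @param quant a `protein_quant` table in log2-ratio mode
#'   (see [normalize_log2_ratios()]).
#' @param design a [tmt_design()]; defaults to the design attached to `quant`.
#' @return A data.frame of class `tmt_model_fits`, one row per fitted
#'   protein: `protein_id`, `gene_symbol`, `unique_peptides`, `b0`, `b1`,
#'   `b2`, `s2`, `df`, `fc_nc` (= b1), `fc_sr` (= b1 - b2), and the
#'   unscaled contrast variances `cvar_nc`, `cvar_sr`
#'   (\eqn{c^T (X^T X)^{-1} c}).  Dropped proteins are listed in the
#'   `dropped` attribute.
#' @export
fit_protein_models <- function(quant, design = attr(quant, "design")) {
  stopifnot(inherits(design, "tmt_design"))
  vals <- quant_values(quant)
  X <- design_matrix(design)
  n <- nrow(vals)
  out <- data.frame(protein_id = quant$protein_id,
                    gene_symbol = quant$gene_symbol,
                    unique_peptides = quant$unique_peptides,
                    b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                    s2 = NA_real_, df = NA_real_,
                    fc_nc = NA_real_, fc_sr = NA_real_,
                    cvar_nc = NA_real_, cvar_sr = NA_real_,
                    stringsAsFactors = FALSE)
  c_nc <- c(0, 1, 0)
  c_sr <- c(0, 1, -1)
  keep <- rep(TRUE, n)
  drop_reason <- character(n)
  complete <- !apply(vals, 1L, anyNA)

  # fast path: complete proteins share one design matrix
  XtXi <- solve(crossprod(X))
  H <- XtXi %*% t(X)               # coefficient operator
  cv_nc <- drop(t(c_nc) %*% XtXi %*% c_nc)
  cv_sr <- drop(t(c_sr) %*% XtXi %*% c_sr)
  if (any(complete)) {
    Y <- vals[complete, , drop = FALSE]
    B <- Y %*% t(H)                 # n x 3 coefficients
    fitted <- B %*% t(X)
    rss <- rowSums((Y - fitted)^2)
    dfc <- ncol(X) * 0 + (nrow(X) - 3L)
    out$b0[complete] <- B[, 1]; out$b1[complete] <- B[, 2]
    out$b2[complete] <- B[, 3]
    out$s2[complete] <- rss / dfc
    out$df[complete] <- dfc
    out$cvar_nc[complete] <- cv_nc
    out$cvar_sr[complete] <- cv_sr
  }
  for (i in which(!complete)) {
    obs <- !is.na(vals[i, ])
    grp <- design$group[obs]
    empty <- setdiff(c("TRT", "SR", "NC"), grp)
    if (length(empty)) {
      keep[i] <- FALSE
      drop_reason[i] <- paste0("empty group: ", paste(empty, collapse = ","))
      next
    }
    dfi <- sum(obs) - 3L
    if (dfi < 1L) {
      keep[i] <- FALSE
      drop_reason[i] <- "residual df < 1"
      next
    }
    Xi <- X[obs, , drop = FALSE]
    XtXii <- solve(crossprod(Xi))
    b <- drop(XtXii %*% crossprod(Xi, vals[i, obs]))
    res <- vals[i, obs] - drop(Xi %*% b)
    out$b0[i] <- b[1]; out$b1[i] <- b[2]; out$b2[i] <- b[3]
    out$s2[i] <- sum(res^2) / dfi
    out$df[i] <- dfi
    out$cvar_nc[i] <- drop(t(c_nc) %*% XtXii %*% c_nc)
    out$cvar_sr[i] <- drop(t(c_sr) %*% XtXii %*% c_sr)
  }
  out$fc_nc <- out$b1
  out$fc_sr <- out$b1 - out$b2
  dropped <- data.frame(protein_id = out$protein_id[!keep],
                        reason = drop_reason[!keep],
                        stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tmt_model_fits", "data.frame")
  attr(out, "design") <- design
  attr(out, "dropped") <- dropped
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' toward which per-protein residual variances are shrunk, by the
#' method-of-moments on log sample variances.  Writing
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)} for protein g with
#' residual variance \eqn{s_g^2} on \eqn{d_g} df, the excess spread of the
#' \eqn{e_g} over their expected sampling variance \eqn{\psi'(d_g/2)}
#' determines `d0` through trigamma inversion
#' (\eqn{\psi'(d_0/2) = } mean of \eqn{(e_g-\bar e)^2 n/(n-1) - \psi'(d_g/2)}),
#' and \eqn{s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))}.  When the
#' excess spread is non-positive the prior is flagged infinite and the
#' prior variance is the plain mean of the sample variances (so a set of
#' identical variances returns exactly that common value).
#'
#' Only proteins with `df >= 1` and `s2 > 0` inform the prior; at least 10
#' such proteins are required.
#'
#' @param fits a `tmt_model_fits` data.frame (or any data.frame with
#'   numeric columns `s2` and `df`).
#' @return list of class `eb_prior` with elements `d0` (possibly `Inf`)
#'   and `s0_sq`.
#' @export
estimate_eb_prior <- function(fits) {
  ok <- is.finite(fits$s2) & fits$s2 > 0 & fits$df >= 1
  s2 <- fits$s2[ok]
  df <- fits$df[ok]
  n <- length(s2)
  if (n < 10L)
    stop("need at least 10 proteins with positive residual variance; got ", n)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * n / (n - 1) - trigamma(df / 2))
  if (rhs <= 0) {
    prior <- list(d0 = Inf, s0_sq = mean(s2))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    prior <- list(d0 = d0, s0_sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
  }
  class(prior) <- "eb_prior"
  prior
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on a
#' convergence-stable transform, following the standard approach for
#' empirical-Bayes prior estimation.
#'
#' @param x positive target value.
#' @return y with `trigamma(y) = x` (to near machine precision).
#' @export
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Moderated t statistics for a contrast
#'
#' Shrinks each protein's residual variance toward the prior,
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}
#' (\eqn{\tilde s^2 = s_0^2} when `d0` is infinite), and forms
#' \eqn{t = \hat c / (\tilde s \sqrt{c^T (X^T X)^{-1} c})} with
#' \eqn{c = (0,1,0)} for the NC contrast (fc_nc) and \eqn{c = (0,1,-1)}
#' for the SR contrast (fc_sr).  Two-sided p-values use a Student-t with
#' `d0 + df` degrees of freedom (normal when `d0` is infinite).
#'
#' Degenerate cases: a zero posterior variance with a nonzero estimate
#' gives `p = 0` with a warning; a zero estimate gives `t = 0`, `p = 1`.
#'
#' @param fits a `tmt_model_fits` data.frame.
#' @param prior an [estimate_eb_prior()] result (use `d0 = 0` for the
#'   unmoderated ordinary t-test).
#' @param contrast `"NC"` or `"SR"`.
#' @return data.frame with columns `t`, `p`, `df_total`.
#' @export
moderated_t <- function(fits, prior, contrast = c("NC", "SR")) {
  contrast <- match.arg(contrast)
  est <- if (contrast == "NC") fits$fc_nc else fits$fc_sr
  cvar <- if (contrast == "NC") fits$cvar_nc else fits$cvar_sr
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s2post <- rep(s0, nrow(fits))
    df_total <- rep(Inf, nrow(fits))
  } else {
    s2post <- (d0 * s0 + fits$df * fits$s2) / (d0 + fits$df)
    df_total <- d0 + fits$df
  }
  se <- sqrt(s2post * cvar)
  t <- est / se
  zero_se <- se == 0
  if (any(zero_se & est != 0))
    warning("zero posterior variance with nonzero estimate: p set to 0")
  t[zero_se & est != 0] <- sign(est[zero_se & est != 0]) * Inf
  t[est == 0] <- 0
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t)),
              2 * stats::pt(-abs(t), df_total))
  p[est == 0] <- 1
  data.frame(t = t, p = p, df_total = df_total)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment, q(i) = min over j >= i of p(j) * n / j
#' on the sorted p-values, clipped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH")
}
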