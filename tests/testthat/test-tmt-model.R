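test_that("raw-intensity normalization follows the per-protein median-ratio rule", {
  d <- design6()
  # target protein plus two constant proteins (whose ratios are all zero),
  # so the per-channel medians are zero and channel centering is a no-op
  tab <- data.frame(protein_id = c("A", "C1", "C2"),
                    gene_symbol = c("a", "c1", "c2"),
                    unique_peptides = 5L)
  vals <- rbind(c(4, 4, 1, 1, 1, 1), rep(2, 6), rep(5, 6))
  for (j in 1:6) tab[[d$channel[j]]] <- vals[, j]
  q <- protein_quant(tab, d)
  out <- normalize_log2_ratios(q, "raw_intensity")
  # hand oracle: log2(x / median(x)) with median(4,4,1,1,1,1) = 1
  expect_equal(unname(unlist(out[out$protein_id == "A", d$channel])),
               log2(c(4, 4, 1, 1, 1, 1) / 1))
  # constant-channel proteins land at ratio 0 everywhere
  expect_equal(unname(unlist(out[out$protein_id == "C1", d$channel])),
               rep(0, 6))
})

test_that("normalization rejects nonpositive intensities and passes precomputed tables through", {
  d <- design6()
  vals <- rbind(c(2, 2, 2, 2, 2, 2), c(1, 0, 3, 3, 3, 3))
  q <- quant_from_matrix(vals, ids = c("OK", "BAD"))
  out <- normalize_log2_ratios(q, "raw_intensity")
  expect_false("BAD" %in% out$protein_id)
  expect_equal(attr(out, "rejected")$protein_id, "BAD")
  set.seed(1)
  q2 <- quant_from_matrix(matrix(rnorm(60), 10))
  out2 <- normalize_log2_ratios(q2, "precomputed")
  expect_equal(quant_values(out2), quant_values(q2))
})

test_that("per-protein OLS reduces to group means on the balanced design", {
  d <- design6()
  q <- quant_from_matrix(rbind(c(2, 2, 1, 1, 0, 0), rep(3.5, 6)))
  fits <- fit_protein_models(q)
  expect_equal(fits$b0[1], 0)
  expect_equal(fits$b1[1], 2)
  expect_equal(fits$b2[1], 1)
  expect_equal(fits$s2[1], 0)
  expect_equal(fits$df[1], 3)
  expect_equal(fits$fc_nc[1], 2)
  expect_equal(fits$fc_sr[1], 1)
  # null protein: all channels equal
  expect_equal(unlist(fits[2, c("b0", "b1", "b2")], use.names = FALSE),
               c(3.5, 0, 0))
})

test_that("OLS coefficients match the normal-equations oracle on random data", {
  set.seed(11)
  d <- design6()
  X <- design_matrix(d)
  vals <- matrix(rnorm(50 * 6), 50)
  fits <- fit_protein_models(quant_from_matrix(vals))
  for (i in seq_len(50)) {
    o <- ols_oracle(vals[i, ], X)
    expect_equal(unlist(fits[i, c("b0", "b1", "b2")], use.names = FALSE), o$b,
                 tolerance = 1e-10)
    expect_equal(fits$s2[i], o$s2, tolerance = 1e-10)
    expect_equal(fits$df[i], o$df)
  }
  # group-mean closed form on the balanced design
  gm <- function(v, g) mean(v[d$group == g])
  i <- 7L
  expect_equal(fits$b0[i], gm(vals[i, ], "NC"))
  expect_equal(fits$b1[i], gm(vals[i, ], "TRT") - gm(vals[i, ], "NC"))
  expect_equal(fits$b2[i], gm(vals[i, ], "SR") - gm(vals[i, ], "NC"))
})

test_that("proteins with missing channels are refit or dropped with a reason", {
  d <- design6()
  vals <- rbind(c(2, NA, 1, 1, 0, 0),      # refit on 5 channels, df = 2
                c(NA, NA, 1, 1, 0, 0),     # TRT group empty -> dropped
                c(1, 2, 3, 4, 5, 6))
  fits <- fit_protein_models(quant_from_matrix(vals))
  expect_equal(nrow(fits), 2L)
  expect_equal(fits$df[1], 2)
  expect_equal(fits$b1[1], 2)              # remaining TRT value minus NC mean
  dropped <- attr(fits, "dropped")
  expect_equal(dropped$protein_id, "P002")
  expect_match(dropped$reason, "TRT")
})

test_that("empirical-Bayes prior recovers simulated scaled-chi-square variances", {
  set.seed(101)
  d0 <- 4; s0 <- 1; df <- 3; n <- 2000
  s2 <- s0 * d0 / rchisq(n, d0) * rchisq(n, df) / df
  prior <- estimate_eb_prior(data.frame(s2 = s2, df = df))
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.10)

  # heavier tail
  set.seed(102)
  d0 <- 1; s0 <- 0.25; n <- 5000
  s2 <- s0 * d0 / rchisq(n, d0) * rchisq(n, df) / df
  prior <- estimate_eb_prior(data.frame(s2 = s2, df = df))
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.10)
})

test_that("prior estimation agrees with the limma cross-check and handles degenerate spread", {
  skip_if_not_installed("limma")
  set.seed(103)
  s2 <- 0.5 * rchisq(200, 3) / 3 * (2 / rchisq(200, 2))
  prior <- estimate_eb_prior(data.frame(s2 = s2, df = 3))
  sq <- limma::squeezeVar(s2, df = 3)
  expect_equal(prior$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0_sq, sq$var.prior, tolerance = 1e-6)

  # all variances identical: infinite prior df, s0^2 = the common value
  prior2 <- estimate_eb_prior(data.frame(s2 = rep(0.3, 50), df = 3))
  expect_true(is.infinite(prior2$d0))
  expect_equal(prior2$s0_sq, 0.3)

  expect_error(estimate_eb_prior(data.frame(s2 = rep(1, 5), df = 3)),
               "at least 10")
})

test_that("moderated t matches the closed form, its limits, and limma", {
  d <- design6()
  # hand evaluation: s2 = 0.04, df = 3, d0 = 4, s0^2 = 0.09, fc_sr = 1,
  # balanced 2/2/2 so c' (X'X)^-1 c = 1 for both contrasts
  fits <- data.frame(fc_nc = 2, fc_sr = 1, s2 = 0.04, df = 3,
                     cvar_nc = 1, cvar_sr = 1)
  prior <- structure(list(d0 = 4, s0_sq = 0.09), class = "eb_prior")
  s2post <- (4 * 0.09 + 3 * 0.04) / (4 + 3)
  mt <- moderated_t(fits, prior, "SR")
  expect_equal(mt$t, 1 / sqrt(s2post))
  expect_equal(mt$df_total, 7)
  expect_equal(mt$p, 2 * pt(-abs(mt$t), 7))

  # d0 = 0: ordinary OLS t exactly (heteroskedastic proteins so the
  # empirical-Bayes prior further below has a finite d0)
  set.seed(21)
  sdev <- sqrt(0.5 * 2 / rchisq(20, 2))
  q <- quant_from_matrix(matrix(rnorm(120), 20) * sdev)
  f <- fit_protein_models(q)
  mt0 <- moderated_t(f, structure(list(d0 = 0, s0_sq = 1),
                                  class = "eb_prior"), "NC")
  t_ols <- f$fc_nc / sqrt(f$s2 * f$cvar_nc)
  expect_equal(mt0$t, t_ols, tolerance = 1e-12)

  # d0 -> infinity: the denominator variance converges to s0^2 (the
  # deviation is df (s2 - s0^2) / d0, so assert on variances near the prior)
  set.seed(22)
  f_lim <- data.frame(fc_nc = rnorm(20), fc_sr = 0, s2 = runif(20, 0.2, 0.3),
                      df = 3, cvar_nc = 1, cvar_sr = 1)
  mt_inf <- moderated_t(f_lim, structure(list(d0 = 1e6, s0_sq = 0.25),
                                         class = "eb_prior"), "NC")
  t_lim <- f_lim$fc_nc / sqrt(0.25)
  expect_equal(mt_inf$t, t_lim, tolerance = 1e-6)

  # zero contrast estimate: t = 0, p = 1
  fz <- data.frame(fc_nc = 0, fc_sr = 0, s2 = 0.1, df = 3,
                   cvar_nc = 1, cvar_sr = 1)
  mtz <- moderated_t(fz, prior, "NC")
  expect_equal(mtz$t, 0)
  expect_equal(mtz$p, 1)

  skip_if_not_installed("limma")
  # full-route cross-check against limma on the same matrix and contrasts
  X <- design_matrix(d)
  lf <- limma::lmFit(quant_values(q), X)
  lf <- limma::contrasts.fit(lf, cbind(nc = c(0, 1, 0), sr = c(0, 1, -1)))
  eb <- limma::eBayes(lf)
  prior_pkg <- estimate_eb_prior(f)
  expect_equal(prior_pkg$d0, eb$df.prior, tolerance = 1e-6)
  mt_nc <- moderated_t(f, prior_pkg, "NC")
  mt_sr <- moderated_t(f, prior_pkg, "SR")
  expect_equal(mt_nc$t, unname(eb$t[, "nc"]), tolerance = 1e-8)
  expect_equal(mt_sr$t, unname(eb$t[, "sr"]), tolerance = 1e-8)
  expect_equal(mt_nc$p, unname(eb$p.value[, "nc"]), tolerance = 1e-8)
})

test_that("BH adjustment equals the step-up oracle and preserves rank order", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  set.seed(31)
  for (rep_i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
    # monotone non-decreasing in sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "within")
})
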