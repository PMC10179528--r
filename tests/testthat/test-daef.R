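ref <- daef_reference_coefficients()

test_that("multilinear fit recovers exact coefficients and slope ratios", {
  for (i in seq_len(nrow(ref))) {
    d <- make_regression_dataset(ref$beta0[i], ref$beta1[i], ref$beta2[i],
                                 noise_sd = 0, n = 29, seed = 20 + i)
    f <- multilinear_fit(d$Y, d$DA, d$EF, ref$outcome[i])
    expect_equal(c(f$beta0, f$beta1, f$beta2),
                 c(ref$beta0[i], ref$beta1[i], ref$beta2[i]),
                 tolerance = 1e-10)
    expect_equal(f$r2, 1, tolerance = 1e-10)
  }
  # printed slope ratios for the stress rows
  dz <- make_regression_dataset(-1.3, -10.6, -17.3, 0, 29, seed = 1)
  expect_equal(round(with(dz, multilinear_fit(Y, DA, EF))$ratio, 2), 1.63)
  dv <- make_regression_dataset(4.3, 9.4, 14.0, 0, 29, seed = 1)
  expect_equal(round(with(dv, multilinear_fit(Y, DA, EF))$ratio, 2), 1.49)

  # constant outcome: zero slopes, undefined ratio
  n <- 10
  f0 <- multilinear_fit(rep(2, n), runif(n), runif(n, -1, 1))
  expect_equal(c(f0$beta1, f0$beta2), c(0, 0), tolerance = 1e-12)
  expect_true(is.na(f0$ratio))

  expect_error(multilinear_fit(1:8, 1:8, 2 * (1:8)), "collinear")
  expect_error(multilinear_fit(1:3, 1:3, c(1, 0, 1)), "4 samples")
})

test_that("gamma aggregation reproduces the canonical 1.69 and is order-invariant", {
  ratios <- ref$beta2 / ref$beta1
  expect_equal(round(aggregate_gamma(ratios), 2), 1.69)
  expect_equal(aggregate_gamma(ratios), aggregate_gamma(rev(ratios)))
  expect_equal(aggregate_gamma(ratios, "mean"), mean(ratios))
  expect_equal(aggregate_gamma(5), 5) # single defined ratio
  expect_equal(aggregate_gamma(rep(1.3, 4), "mean"),
               aggregate_gamma(rep(1.3, 4), "median"))
  expect_error(aggregate_gamma(NA_real_), "no defined")
})

test_that("daef_index follows its closed form and bounds", {
  expect_equal(daef_index(0.5, 0, 7), 0.5)
  expect_equal(daef_index(0.5, 0.06), 0.6014)
  expect_equal(daef_index(0, -1), -1.69)
  expect_error(daef_index(1.5, 0), "DA")
  expect_error(daef_index(0.5, 2), "EF")
})

test_that("scale equivariance: scaling Y scales betas, not ratio or R^2", {
  d <- make_regression_dataset(1, 2, 3, noise_sd = 0.5, n = 29, seed = 31)
  f1 <- multilinear_fit(d$Y, d$DA, d$EF)
  f2 <- multilinear_fit(100 * d$Y, d$DA, d$EF)
  expect_equal(c(f2$beta0, f2$beta1, f2$beta2),
               100 * c(f1$beta0, f1$beta1, f1$beta2), tolerance = 1e-12)
  expect_equal(f2$ratio, f1$ratio, tolerance = 1e-12)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
})

test_that("correlation screen reports exact and null relationships", {
  x <- seq(0.1, 3, length.out = 29)
  scr <- correlation_matrix(data.frame(x = x, y = 2 * x))
  expect_equal(scr$r2["x", "y"], 1, tolerance = 1e-12)

  # null distribution of r^2 between independent normals: E[r^2] = 1/(n-1)
  set.seed(40)
  r2s <- replicate(300, {
    d <- data.frame(a = rnorm(29), b = rnorm(29))
    suppressWarnings(correlation_matrix(d))$r2["a", "b"]
  })
  expect_lt(abs(mean(r2s) - 1 / 28), 0.01)

  expect_warning(correlation_matrix(data.frame(a = rnorm(10), b = rep(1, 10))),
                 "constant")
  expect_error(correlation_matrix(data.frame(a = 1:2, b = 2:3)), "3 samples")
})

test_that("correlation structure of a reference-shaped cohort is recovered", {
  # build a population with the published microarchitecture R^2 magnitudes
  # (signs chosen by domain direction) and check the strongest partner of
  # trabecular thickness is the surface-to-volume ratio
  nm <- c("BV_TV", "BS_BV", "Tb_Th", "Tb_N", "Tb_Sp", "SMI", "DA", "EF")
  r2 <- diag(8)
  dimnames(r2) <- list(nm, nm)
  fill <- function(a, b, v) r2[a, b] <<- r2[b, a] <<- v
  fill("BV_TV", "BS_BV", 0.26); fill("BV_TV", "Tb_Th", 0.08)
  fill("BV_TV", "Tb_N", 0.76); fill("BV_TV", "Tb_Sp", 0.76)
  fill("BV_TV", "SMI", 0.83); fill("BV_TV", "DA", 0.005); fill("BV_TV", "EF", 0.45)
  fill("BS_BV", "Tb_Th", 0.81); fill("BS_BV", "Tb_N", 0.005)
  fill("BS_BV", "Tb_Sp", 0.01); fill("BS_BV", "SMI", 0.32)
  fill("BS_BV", "DA", 0.01); fill("BS_BV", "EF", 0.14)
  fill("Tb_Th", "Tb_N", 0.05); fill("Tb_Th", "Tb_Sp", 0.005)
  fill("Tb_Th", "SMI", 0.06); fill("Tb_Th", "DA", 0.03); fill("Tb_Th", "EF", 0.11)
  fill("Tb_N", "Tb_Sp", 0.88); fill("Tb_N", "SMI", 0.63)
  fill("Tb_N", "DA", 0.01); fill("Tb_N", "EF", 0.26)
  fill("Tb_Sp", "SMI", 0.47); fill("Tb_Sp", "DA", 0.005); fill("Tb_Sp", "EF", 0.37)
  fill("SMI", "DA", 0.01); fill("SMI", "EF", 0.33)
  fill("DA", "EF", 0.04)
  sign <- matrix(1, 8, 8, dimnames = list(nm, nm))
  neg <- rbind(c("BV_TV", "Tb_Sp"), c("BV_TV", "SMI"), c("BV_TV", "BS_BV"),
               c("Tb_N", "Tb_Sp"), c("Tb_N", "SMI"), c("Tb_Th", "BS_BV"))
  for (i in seq_len(nrow(neg))) {
    sign[neg[i, 1], neg[i, 2]] <- -1
    sign[neg[i, 2], neg[i, 1]] <- -1
  }
  R <- sqrt(r2) * sign
  diag(R) <- 1
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  L <- ev$vectors %*% diag(pmax(ev$values, 0.05)) %*% t(ev$vectors)
  D <- diag(1 / sqrt(diag(L)))
  R <- D %*% L %*% D # nearest-ish valid correlation matrix
  set.seed(50)
  X <- MASS::mvrnorm(400, mu = rep(0, 8), Sigma = R)
  colnames(X) <- nm
  scr <- suppressWarnings(correlation_matrix(as.data.frame(X)))
  row <- scr$r2["Tb_Th", setdiff(nm, "Tb_Th")]
  expect_equal(names(which.max(row)), "BS_BV")
})

test_that("daef_fit: exact data gives R^2 = 1 per own ratio, high with pooled gamma", {
  set.seed(60)
  DA <- runif(29)
  EF <- runif(29, -1, 1)
  tab <- data.frame(DA = DA, EF = EF)
  for (i in seq_len(nrow(ref)))
    tab[[ref$outcome[i]]] <- ref$beta0[i] + ref$beta1[i] * DA + ref$beta2[i] * EF
  m <- daef_fit(tab)
  expect_s3_class(m, "daef")
  # per-fit gamma: the 1D index spans the same direction as (DA, EF) slope
  for (i in seq_len(nrow(ref))) {
    own <- daef_index(DA, EF, m$ratios[ref$outcome[i]])
    expect_equal(cor(own, tab[[ref$outcome[i]]])^2, 1, tolerance = 1e-10)
  }
  expect_true(all(m$r2_table[, "DAEF"] > 0.9))
  # nesting: the own-ratio DAEF R^2 is never below DA-alone or EF-alone R^2
  for (i in seq_len(nrow(ref))) {
    own_r2 <- cor(daef_index(DA, EF, m$ratios[ref$outcome[i]]),
                  tab[[ref$outcome[i]]])^2
    expect_gte(own_r2 + 1e-12, m$r2_table[ref$outcome[i], "DA"])
    expect_gte(own_r2 + 1e-12, m$r2_table[ref$outcome[i], "EF"])
  }
  expect_equal(round(m$gamma, 2), 1.69)

  # shuffled outcomes: R^2 collapses
  set.seed(61)
  tabs <- tab
  for (o in ref$outcome) tabs[[o]] <- sample(tabs[[o]])
  ms <- daef_fit(tabs)
  expect_true(all(ms$r2_table[, "DAEF"] < 0.3))
})

test_that("daef model methods behave like a classed fit object", {
  d <- make_regression_dataset(-1.3, -10.6, -17.3, noise_sd = 0.1, n = 29,
                               seed = 70)
  names(d)[3] <- "sigma_z"
  m <- daef_fit(d, outcomes = "sigma_z")
  expect_output(print(m), "gamma")
  expect_output(print(summary(m)), "beta0")
  cf <- coef(m)
  expect_equal(rownames(cf), "sigma_z")
  expect_equal(unname(cf[1, "beta1"]), -10.6, tolerance = 0.2)
  expect_equal(predict(m, data.frame(DA = 0.5, EF = 0), type = "index"),
               0.5)
  pred <- predict(m, type = "outcome", outcome = "sigma_z")
  expect_equal(length(pred), 29)
  expect_equal(length(residuals(m)), 29)
  f <- file.path(tempdir(), "daef_plot.pdf")
  grDevices::pdf(f)
  plot(m)
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("coefficient recovery stays inside OLS confidence intervals", {
  set.seed(80)
  hits <- replicate(100, {
    s <- sample.int(1e6, 1)
    d <- make_regression_dataset(-1.3, -10.6, -17.3, noise_sd = 0.5, n = 29,
                                 seed = s)
    ci <- stats::confint(multilinear_fit(d$Y, d$DA, d$EF)$lm)
    c(ci[1, 1] <= -1.3 & -1.3 <= ci[1, 2],
      ci[2, 1] <= -10.6 & -10.6 <= ci[2, 2],
      ci[3, 1] <= -17.3 & -17.3 <= ci[3, 2])
  })
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
  expect_gte(mean(hits[3, ]), 0.9)
})
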