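test_that("genotype similarity sums phi over the gene-set product", {
  g <- c("g1", "g2", "h1")
  phi <- diag(1, 3); dimnames(phi) <- list(g, g)
  phi["g1", "h1"] <- phi["h1", "g1"] <- 0.2
  phi["g2", "h1"] <- phi["h1", "g2"] <- 0.3
  expect_equal(genotype_similarity(c("g1", "g2"), "h1", phi), 0.5)
  expect_equal(genotype_similarity(character(0), "h1", phi), 0)
  expect_equal(genotype_similarity("h1", c("g1", "g2"), phi), 0.5)  # symmetry
  expect_equal(genotype_similarity("absent", "h1", phi), 0)         # missing -> 0
})

test_that("regression rows exclude the query and geneless diseases", {
  space <- tiny_space()
  phi <- tiny_phi()
  # d4 has no genes; query d1 excluded -> only d2, d3 remain -> n = 2 < 3
  expect_error(build_regression_inputs("gQ", "d1", space, phi),
               "insufficient data")
  inp <- build_regression_inputs("gQ", "d1", space, phi, min_n = 2L)
  expect_setequal(inp$row_ids, c("d2", "d3"))
  expect_false("d1" %in% inp$row_ids)
  expect_equal(inp$x, c(0.4, 0.2))   # gQ vs {gB,gC}, gQ vs {gD}
  expect_error(build_regression_inputs("gQ", "nope", space, phi), "not in")
})

test_that("leave-out removes the candidate and the query's known genes", {
  space <- tiny_space()
  space$disease_genes$d2 <- c("gB", "gC", "gQ", "gA")  # shares gQ and d1's gA
  phi <- tiny_phi()
  with_lo <- build_regression_inputs("gQ", "d1", space, phi,
                                     leave_out = TRUE, min_n = 2L)
  without <- build_regression_inputs("gQ", "d1", space, phi,
                                     leave_out = FALSE, min_n = 2L)
  expect_equal(with_lo$x[with_lo$row_ids == "d2"], 0.4)   # gB, gC only
  expect_equal(without$x[without$row_ids == "d2"], 0.2 + 0.2 + 1 + 0.2)
})

test_that("MLE reproduces exact linear data and column symmetry", {
  fit <- fit_mle(list(Y = matrix(c(1, 3, 5), 3), x = c(0, 1, 2)))
  expect_equal(unname(fit$beta_hat), 2)
  expect_equal(unname(fit$alpha_hat), 1)
  expect_equal(unname(fit$sigma_eps_hat[1, 1]), 0)
  set.seed(10)
  y <- stats::rnorm(8)
  fit3 <- fit_mle(list(Y = cbind(y, y, y), x = stats::rnorm(8)))
  expect_equal(fit3$beta_hat[1], fit3$beta_hat[2])
  expect_equal(fit3$beta_hat[2], fit3$beta_hat[3])
  expect_error(fit_mle(list(Y = matrix(1:3, 3), x = rep(1, 3))), "degenerate")
})

test_that("MLE matches the per-column least-squares oracle", {
  set.seed(21)
  for (rep in 1:20) {
    inp <- random_regression_inputs(n = 20, p = 3)
    fit <- fit_mle(inp)
    for (j in 1:3) {
      ols <- stats::lm(inp$Y[, j] ~ inp$x)
      expect_equal(unname(fit$beta_hat[j]), unname(stats::coef(ols)[2]),
                   tolerance = 1e-10)
      expect_equal(unname(fit$alpha_hat[j]), unname(stats::coef(ols)[1]),
                   tolerance = 1e-10)
      # residual covariance diagonal = OLS sigma^2 (both use n - 2)
      expect_equal(unname(fit$sigma_eps_hat[j, j]),
                   summary(ols)$sigma^2, tolerance = 1e-10)
    }
    expect_true(isSymmetric(fit$sigma_eps_hat))
    expect_true(all(eigen(fit$sigma_eps_hat, only.values = TRUE)$values > -1e-12))
  }
})

test_that("basis-vector contrasts reproduce the classical regression t-test", {
  set.seed(22)
  for (rep in 1:20) {
    inp <- random_regression_inputs(n = 15, p = 3)
    fit <- fit_mle(inp)
    for (j in 1:3) {
      lam <- as.numeric(seq_len(3) == j)
      at <- association_test(fit, lam)
      tt <- summary(stats::lm(inp$Y[, j] ~ inp$x))$coefficients[2, "t value"]
      expect_equal(at$T, unname(tt), tolerance = 1e-10)
      expect_equal(at$p_analytical,
                   stats::pt(tt, df = 13, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("one-sided direction and degenerate fits behave as specified", {
  set.seed(23)
  x <- stats::rnorm(10)
  y <- -2 * x + stats::rnorm(10, sd = 0.1)
  at <- association_test(fit_mle(list(Y = matrix(y), x = x)))
  expect_lt(at$T, 0)
  expect_gt(at$p_analytical, 0.5)
  expect_error(
    association_test(fit_mle(list(Y = matrix(c(-1, 0, 1)), x = c(-1, 0, 1)))),
    "degenerate fit")
})

test_that("sampling distributions match the model by simulation", {
  set.seed(24)
  n <- 10; sigma <- 1.5
  x <- stats::rnorm(n)
  sxx <- sum((x - mean(x))^2)
  B <- 3000
  betas <- numeric(B); s2 <- numeric(B)
  for (b in seq_len(B)) {
    fit <- fit_mle(list(Y = matrix(1 + 2 * x + stats::rnorm(n, sd = sigma)),
                        x = x))
    betas[b] <- fit$beta_hat
    s2[b] <- fit$sigma_eps_hat[1, 1]
  }
  expect_equal(stats::var(betas), sigma^2 / sxx, tolerance = 0.1)
  expect_equal(mean(betas), 2, tolerance = 3 * sigma / sqrt(sxx * B) * 5)
  ks <- stats::ks.test((n - 2) * s2 / sigma^2, "pchisq", df = n - 2)
  expect_gt(ks$p.value, 0.001)
})

test_that("missing measures propagate as NA in the association vector", {
  set.seed(25)
  ds <- simulate_disease_space(n_diseases = 12, seed = 99)
  measures <- ds$measures
  # drop the candidate gene from one measure's matrix
  cut <- measures[[2]][rownames(measures[[2]]) != "G05",
                       colnames(measures[[2]]) != "G05"]
  measures[[2]] <- cut
  p <- gene_association_pvalues("G05", ds$truth$query_disease, ds$space,
                                measures)
  expect_length(p, 3L)
  # gene absent everywhere in measure 2 -> x all zero -> degenerate -> NA
  expect_true(is.na(p[[2]]))
  expect_true(all(is.finite(p[c(1, 3)])))
})
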