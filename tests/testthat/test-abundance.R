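test_that("spearman_rho is monotone-invariant and handles ties like midrank Pearson", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  # tied data: Pearson on midranks
  xt <- c(1, 2, 2, 3, 4, 4, 5, 6)
  yt <- c(2, 1, 3, 3, 5, 4, 4, 6)
  expect_equal(
    spearman_rho(xt, yt)$rho,
    cor(rank(xt), rank(yt)),
    tolerance = 1e-12
  )
  expect_error(spearman_rho(x, rep(1, 8)), class = "defensome_argument_error")
  expect_error(spearman_rho(1:2, 1:2), class = "defensome_argument_error")
})

test_that("size regression and residual domain test behave under planted truth", {
  set.seed(21)
  # exact linear law -> r2 = 1, residuals ~ 0
  size <- runif(100, 1, 5)
  dom <- rep(c("Archaea", "Bacteria"), 50)
  # noise-free law triggers lm's perfect-fit warning; the values are the point
  exact <- suppressWarnings(size_regression_residual_test(2 * size, size, dom))
  expect_equal(exact$r2, 1, tolerance = 1e-10)
  # equal law in both domains -> residual test null on average
  p_null <- purrr::map_dbl(1:20, function(i) {
    set.seed(i)
    size <- runif(200, 1, 5)
    counts <- round(3 * size + rnorm(200, sd = 2))
    size_regression_residual_test(counts, size, rep(c("A", "B"), 100))$residual_test_p
  })
  expect_gt(mean(p_null < 0.05), -1e-9) # sanity
  expect_lte(mean(p_null < 0.05), 0.25)
  # +5 offset in one domain at equal sizes -> flagged
  size <- runif(300, 1, 5)
  dom <- rep(c("A", "B"), 150)
  counts <- round(3 * size + 5 * (dom == "B") + rnorm(300))
  shifted <- size_regression_residual_test(counts, size, dom)
  expect_lt(shifted$residual_test_p, 1e-6)
  expect_error(
    size_regression_residual_test(counts, size, rep("A", 300)),
    class = "defensome_argument_error"
  )
})

test_that("varpart_two components sum to one and isolate unique signal", {
  set.seed(8)
  n <- 2000
  a <- rnorm(n)
  b <- 0.6 * a + rnorm(n, sd = 0.8)
  y <- 2 * a + 1 * b + rnorm(n)
  vp <- varpart_two(y, a, b)
  expect_equal(vp$unique_a + vp$unique_b + vp$shared + vp$unexplained, 1,
    tolerance = 1e-9
  )
  # identical predictors: unique parts vanish
  vp_same <- varpart_two(y, a, a + 0)
  expect_equal(vp_same$unique_a, 0, tolerance = 1e-9)
  expect_equal(vp_same$unique_b, 0, tolerance = 1e-9)
  # pure-noise block contributes nothing
  vp_noise <- varpart_two(y, cbind(a, b), rnorm(n))
  expect_lt(abs(vp_noise$unique_b), 0.01)
  # factor blocks work
  f <- sample(c("p1", "p2", "p3"), n, replace = TRUE)
  vp_f <- varpart_two(y, a, data.frame(phylum = f))
  expect_equal(
    vp_f$unique_a + vp_f$unique_b + vp_f$shared + vp_f$unexplained, 1,
    tolerance = 1e-9
  )
  expect_error(varpart_two(y, cbind(a, a), b), class = "defensome_argument_error")
})

test_that("varpart_two agrees with vegan's varpart on a numeric example", {
  skip_if_not_installed("vegan")
  set.seed(4)
  n <- 500
  a <- rnorm(n)
  b <- rnorm(n)
  y <- a + 0.5 * b + rnorm(n)
  vp <- varpart_two(y, a, b)
  vv <- vegan::varpart(y, data.frame(a = a), data.frame(b = b))
  ind <- vv$part$indfract$Adj.R.square
  expect_equal(vp$unique_a, ind[1], tolerance = 1e-8)
  expect_equal(vp$unique_b, ind[2], tolerance = 1e-8)
  expect_equal(vp$shared, ind[3], tolerance = 1e-8)
  expect_equal(vp$unexplained, ind[4], tolerance = 1e-8)
})

test_that("OGT binning follows the half-open convention", {
  expect_equal(
    as.character(bin_ogt(c(20, 49.9, 50, 79.9, 80, 85))),
    c(
      "mesophilic", "mesophilic", "thermophilic", "thermophilic",
      "hyperthermophilic", "hyperthermophilic"
    )
  )
  expect_error(bin_ogt(c(50, NA)), class = "defensome_argument_error")
})

test_that("kruskal_dunn flags a shifted group and applies Bonferroni", {
  set.seed(14)
  g <- rep(c("meso", "thermo", "hyper"), each = 40)
  v <- c(rnorm(40), rnorm(40), rnorm(40, mean = 3))
  kd <- kruskal_dunn(v, g)
  expect_lt(kd$omnibus_p, 1e-6)
  hyper_rows <- kd$pairwise$group1 == "hyper" | kd$pairwise$group2 == "hyper"
  expect_true(all(kd$pairwise$p_adjusted[hyper_rows] < 0.01))
  expect_gt(kd$pairwise$p_adjusted[!hyper_rows], 0.05)
  # Bonferroni is min(1, p * k)
  expect_equal(
    kd$pairwise$p_adjusted,
    pmin(1, kd$pairwise$p_raw * nrow(kd$pairwise))
  )
  # omnibus p roughly uniform under the null
  p_null <- purrr::map_dbl(1:30, function(i) {
    set.seed(100 + i)
    kruskal_dunn(rnorm(60), rep(c("a", "b", "c"), 20))$omnibus_p
  })
  expect_gt(mean(p_null), 0.25)
  expect_lt(mean(p_null), 0.75)
  expect_error(kruskal_dunn(1:5, c("a", "a", "a", "a", "b")),
    class = "defensome_argument_error"
  )
})

test_that("nb_glm recovers planted coefficients and the Poisson limit", {
  set.seed(33)
  n <- 4000
  x <- runif(n, 0, 100)
  beta0 <- 0.5
  beta1 <- log(1.357) / 10
  mu <- exp(beta0 + beta1 * x)
  y <- rnbinom(n, size = 2, mu = mu)
  fit <- nb_glm(y, data.frame(x = x))
  expect_equal(unname(fit$coefficients["x"]), beta1, tolerance = 0.15)
  expect_equal(fit$theta, 2, tolerance = 0.2)
  expect_equal(percent_change(fit, "x", delta = 10), 35.7, tolerance = 0.1)
  # Poisson-generated data -> mean structure matches a Poisson GLM
  yp <- rpois(n, mu)
  fit_nb <- nb_glm(yp, data.frame(x = x))
  fit_pois <- glm(yp ~ x, family = poisson())
  expect_equal(unname(fit_nb$coefficients), unname(coef(fit_pois)), tolerance = 1e-3)
  # covariate rescaling: slope scales inversely, fit invariant
  fit_scaled <- nb_glm(y, data.frame(x = x / 10))
  expect_equal(unname(fit_scaled$coefficients["x"]),
    10 * unname(fit$coefficients["x"]),
    tolerance = 1e-6
  )
  expect_equal(fit_scaled$loglik, fit$loglik, tolerance = 1e-6)
  expect_error(nb_glm(rep(0, 50), data.frame(x = rnorm(50))),
    class = "defensome_degenerate_error"
  )
  expect_error(nb_glm(c(-1, 2, 3), data.frame(x = 1:3)),
    class = "defensome_argument_error"
  )
})

test_that("hurdle_nb matches an independent truncated-NB MLE and beats plain NB", {
  set.seed(55)
  n <- 1500
  x <- rnorm(n)
  p_pos <- plogis(0.3 + 0.8 * x)
  mu <- exp(1.0 + 0.4 * x)
  theta <- 1.5
  y <- integer(n)
  pos <- rbinom(n, 1, p_pos) == 1
  # zero-truncated NB draws by rejection
  for (i in which(pos)) {
    repeat {
      d <- rnbinom(1, size = theta, mu = mu[i])
      if (d > 0) {
        y[i] <- d
        break
      }
    }
  }
  fit <- hurdle_nb(y, data.frame(x = x))
  expect_equal(unname(fit$zero_part$coefficients), c(0.3, 0.8), tolerance = 0.25)
  expect_equal(unname(fit$count_part$coefficients), c(1.0, 0.4), tolerance = 0.15)
  expect_equal(fit$count_part$theta, theta, tolerance = 0.35)

  # independent direct maximization (Nelder-Mead from a different start)
  Xc <- cbind(1, x[y > 0])
  oracle <- optim(
    c(0, 0, 0),
    function(par) -defensome:::truncated_nb_loglik(par, y[y > 0], Xc),
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-12)
  )
  expect_equal(fit$count_part$loglik, -oracle$value, tolerance = 1e-4)

  # hurdle total loglik >= plain NB loglik on data with zeros
  nb <- nb_glm(y, data.frame(x = x))
  expect_gte(fit$loglik, nb$loglik - 1e-6)

  expect_error(hurdle_nb(y[y > 0], data.frame(x = x[y > 0])),
    class = "defensome_degenerate_error"
  )
})

test_that("nagelkerke_r2 follows the closed form and stays in [0, 1]", {
  expect_equal(nagelkerke_r2(-10, -10, 100), 0)
  # hand evaluation on a worked case
  l1 <- -40
  l0 <- -55
  n <- 60
  cs <- 1 - exp(2 * (l0 - l1) / n)
  expect_equal(nagelkerke_r2(l1, l0, n), cs / (1 - exp(2 * l0 / n)))
  set.seed(2)
  for (i in 1:10) {
    l0 <- -runif(1, 10, 200)
    l1 <- l0 + runif(1, 0, 50)
    r2 <- nagelkerke_r2(l1, l0, 100)
    expect_gte(r2, 0)
    expect_lte(r2, 1)
  }
  expect_error(nagelkerke_r2(-60, -55, 100), class = "defensome_argument_error")
})

test_that("tidy and glance methods expose count-model summaries", {
  set.seed(1)
  x <- runif(800, 0, 60)
  y <- rnbinom(800, size = 2, mu = exp(0.5 + 0.02 * x))
  fit <- nb_glm(y, data.frame(x = x))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(fit)
  expect_true(gl$pseudo_r2 >= 0 && gl$pseudo_r2 <= 1)
  y0 <- ifelse(rbinom(800, 1, 0.7) == 1, pmax(y, 1), 0L)
  h <- hurdle_nb(y0, data.frame(x = x))
  expect_setequal(unique(tidy(h)$component), c("zero", "count"))
  expect_equal(glance(h)$logLik, h$loglik)
})
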