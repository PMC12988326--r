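#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties and a large-sample p-value.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A tibble: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.",
      class = "defensome_argument_error"
    )
  }
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("correlation undefined for a constant vector.",
      class = "defensome_argument_error"
    )
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Genome-size regression with between-domain residual test
#'
#' Ordinary least squares of defense counts on genome size, then a Wilcoxon
#' rank-sum test comparing the residuals between domains: a significant
#' result means domain carries count signal beyond what genome size
#' explains.
#'
#' @param counts Numeric defense counts per genome.
#' @param size_mb Genome sizes in Mb.
#' @param domain Two-level factor or character vector.
#' @param min_n Minimum genomes per domain (default 10).
#' @return A tibble: `r2`, `slope`, `residual_test_p`, plus the `lm` fit as
#'   attribute `"fit"`.
#' @export
size_regression_residual_test <- function(counts, size_mb, domain, min_n = 10L) {
  domain <- factor(domain)
  if (nlevels(domain) != 2L) {
    abort("`domain` must have exactly two levels.",
      class = "defensome_argument_error"
    )
  }
  if (any(table(domain) < min_n)) {
    abort(sprintf("each domain needs >= %d genomes.", min_n),
      class = "defensome_argument_error"
    )
  }
  fit <- lm(counts ~ size_mb)
  res <- residuals(fit)
  # large-sample (normal-approximation) rank-sum test; cohort-scale data
  wt <- wilcox.test(res ~ domain, exact = FALSE)
  out <- tibble::tibble(
    r2 = summary(fit)$r.squared,
    slope = unname(coef(fit)[2]),
    residual_test_p = wt$p.value
  )
  attr(out, "fit") <- fit
  out
}

# Adjusted R^2 of an OLS fit of y on a predictor block (vector, matrix or
# data frame). Rank deficiency within a single block is an error; for the
# combined fit, cross-block collinearity is tolerated (aliased columns are
# dropped, as in the reference partitioning tool).
adj_r2 <- function(y, block, check_rank = TRUE) {
  df <- as.data.frame(block)
  names(df) <- make.names(names(df), unique = TRUE)
  if (check_rank) {
    mm <- model.matrix(~., data = df)
    if (qr(mm)$rank < ncol(mm)) {
      abort("collinear predictors within a block.",
        class = "defensome_argument_error"
      )
    }
  }
  fit <- lm(y ~ ., data = df)
  summary(fit)$adj.r.squared
}

#' Two-block variance partitioning by adjusted R-squared differences
#'
#' Partitions the variance of `y` explained by two predictor blocks into
#' unique and shared fractions using adjusted R^2 of the three OLS fits
#' (a alone, b alone, a + b):
#' `unique_a = R2_ab - R2_b`, `unique_b = R2_ab - R2_a`,
#' `shared = R2_a + R2_b - R2_ab`, `unexplained = 1 - R2_ab`. Components
#' sum to 1 by construction; adjusted R^2 can make individual components
#' slightly negative, and such values are reported as-is.
#'
#' @param y Numeric response.
#' @param predictor_a,predictor_b Predictor blocks (vector, matrix or data
#'   frame with the same number of rows as `y`).
#' @return A one-row tibble of class `varpart_two`: `unique_a`, `unique_b`,
#'   `shared`, `unexplained`.
#' @export
varpart_two <- function(y, predictor_a, predictor_b) {
  na <- NROW(predictor_a)
  nb <- NROW(predictor_b)
  if (length(y) != na || length(y) != nb) {
    abort("`y` and both predictor blocks must have the same number of rows.",
      class = "defensome_argument_error"
    )
  }
  ab <- cbind(as.data.frame(predictor_a), as.data.frame(predictor_b))
  names(ab) <- make.names(names(ab), unique = TRUE)
  r2_a <- adj_r2(y, predictor_a)
  r2_b <- adj_r2(y, predictor_b)
  r2_ab <- adj_r2(y, ab, check_rank = FALSE)
  out <- tibble::tibble(
    unique_a = r2_ab - r2_b,
    unique_b = r2_ab - r2_a,
    shared = r2_a + r2_b - r2_ab,
    unexplained = 1 - r2_ab
  )
  class(out) <- c("varpart_two", class(out))
  out
}

#' Bin optimal growth temperature into thermal categories
#'
#' Half-open convention: below 50 degC mesophilic, \[50, 80) thermophilic,
#' 80 degC and above hyperthermophilic.
#'
#' @param ogt_c Numeric OGT values in degC (finite).
#' @return Factor with levels mesophilic, thermophilic, hyperthermophilic.
#' @export
#' @examples
#' bin_ogt(c(20, 50, 85))
bin_ogt <- function(ogt_c) {
  if (!is.numeric(ogt_c) || any(!is.finite(ogt_c))) {
    abort("`ogt_c` must be finite numeric.", class = "defensome_argument_error")
  }
  cut(ogt_c,
    breaks = c(-Inf, 50, 80, Inf), right = FALSE,
    labels = c("mesophilic", "thermophilic", "hyperthermophilic")
  )
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis test followed by Dunn's z test for every
#' group pair, with Bonferroni (default) or any `p.adjust` correction.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels.
#' @param correction Multiple-testing correction for the pairwise p-values
#'   (default `"bonferroni"`).
#' @return A list with `omnibus_p`, `statistic`, `df`, and `pairwise`
#'   (tibble: group1, group2, z, p_raw, p_adjusted).
#' @export
kruskal_dunn <- function(values, groups, correction = "bonferroni") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    abort("need >= 2 groups with >= 2 observations each.",
      class = "defensome_argument_error"
    )
  }
  kw <- kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ns <- table(groups)
  # tie correction term: sum over tie groups of (t^3 - t)
  tie_tab <- table(values)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  var_base <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pw <- purrr::map(pairs, function(pr) {
    se <- sqrt(var_base * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    z <- (mean_ranks[pr[1]] - mean_ranks[pr[2]]) / se
    tibble::tibble(
      group1 = pr[1], group2 = pr[2], z = unname(z),
      p_raw = unname(2 * pnorm(-abs(z)))
    )
  })
  pw <- purrr::list_rbind(pw) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_raw, method = correction))
  list(
    omnibus_p = kw$p.value, statistic = unname(kw$statistic),
    df = unname(kw$parameter), pairwise = pw
  )
}

#' Negative-binomial GLM with a log link
#'
#' Wraps an alternating IRLS / theta maximum-likelihood fit of an NB
#' regression (as provided by `MASS::glm.nb`) behind a tidy surface; used
#' for defense counts, which are overdispersed relative to Poisson.
#'
#' @param counts Nonnegative integer response.
#' @param design Data frame (or matrix) of predictors.
#' @return Object of class `nb_fit`: `coefficients`, `theta`, `loglik`,
#'   `null_loglik`, `converged`, `n`, and the underlying `fit`.
#' @export
nb_glm <- function(counts, design) {
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be nonnegative integers.",
      class = "defensome_argument_error"
    )
  }
  if (all(counts == 0)) {
    abort("all counts are zero; NB fit is degenerate.",
      class = "defensome_degenerate_error"
    )
  }
  df <- as.data.frame(design)
  mm <- model.matrix(~., data = df)
  if (qr(mm)$rank < ncol(mm)) {
    abort("`design` must have full column rank.",
      class = "defensome_argument_error"
    )
  }
  df$.counts <- counts
  fit <- suppressWarnings(MASS::glm.nb(.counts ~ ., data = df))
  null_fit <- suppressWarnings(MASS::glm.nb(.counts ~ 1, data = df[".counts"]))
  structure(
    list(
      coefficients = coef(fit),
      theta = fit$theta,
      loglik = as.numeric(logLik(fit)),
      null_loglik = as.numeric(logLik(null_fit)),
      converged = fit$converged,
      n = length(counts),
      fit = fit
    ),
    class = "nb_fit"
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "<nb_fit> theta %.3f, loglik %.2f, n %d\n", x$theta, x$loglik, x$n
  ))
  print(x$coefficients)
  invisible(x)
}

#' Percent change in expected count per unit increase of a covariate
#'
#' For a log-link count model, a coefficient `beta` means a
#' `100 * (exp(delta * beta) - 1)` percent change in the expected count per
#' `delta`-unit covariate increase (e.g. `delta = 10` for per-10-degC
#' effects).
#'
#' @param fit An `nb_fit` (or any object with named `coefficients`).
#' @param term Coefficient name.
#' @param delta Covariate increment (default 10).
#' @return Percent change (scalar).
#' @export
percent_change <- function(fit, term, delta = 10) {
  beta <- fit$coefficients[[term]]
  100 * (exp(delta * beta) - 1)
}

# Log-likelihood of a zero-truncated NB sample: y > 0, log link mu = exp(X b).
truncated_nb_loglik <- function(par, y, X) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1])
  mu <- exp(drop(X %*% beta))
  p0 <- (theta / (theta + mu))^theta
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE) - log1p(-p0))
}

#' Hurdle negative-binomial model
#'
#' Two-part count model: a logistic regression for the zero hurdle
#' (any system present vs none) and a zero-truncated negative-binomial
#' regression, fitted by direct likelihood maximization on the positive
#' counts only (each NB term divided by `1 - P(0; mu, theta)`). Total
#' log-likelihood is the sum of the two parts.
#'
#' @param counts Nonnegative integer response containing both zeros and
#'   positives.
#' @param design_zero Predictors for the hurdle (zero) part.
#' @param design_count Predictors for the truncated count part (defaults to
#'   `design_zero`).
#' @return Object of class `hurdle_fit`: `zero_part` (glm coefficients and
#'   loglik), `count_part` (coefficients, theta, loglik, converged),
#'   `loglik`, `n`.
#' @export
hurdle_nb <- function(counts, design_zero, design_count = design_zero) {
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be nonnegative integers.",
      class = "defensome_argument_error"
    )
  }
  if (!any(counts == 0)) {
    abort("no zero counts: the hurdle part is degenerate; fit nb_glm() instead.",
      class = "defensome_degenerate_error"
    )
  }
  if (!any(counts > 0)) {
    abort("no positive counts: the truncated part is degenerate.",
      class = "defensome_degenerate_error"
    )
  }
  dfz <- as.data.frame(design_zero)
  dfc <- as.data.frame(design_count)
  dfz$.pos <- as.numeric(counts > 0)
  zero_fit <- glm(.pos ~ ., family = binomial(), data = dfz)

  pos <- counts > 0
  y <- counts[pos]
  Xc <- model.matrix(~., data = dfc[pos, , drop = FALSE])
  # start from an untruncated NB fit on the positives
  start_fit <- suppressWarnings(MASS::glm.nb(y ~ Xc - 1))
  start <- c(coef(start_fit), log(start_fit$theta))
  negll <- function(par) -truncated_nb_loglik(par, y, Xc)
  opt <- optim(start, negll,
    method = "BFGS", control = list(maxit = 500, reltol = 1e-12)
  )
  # Nelder-Mead polish from the BFGS solution; keep the better optimum
  polish <- optim(opt$par, negll,
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14)
  )
  if (polish$value < opt$value) opt <- polish
  p <- ncol(Xc)
  structure(
    list(
      zero_part = list(
        coefficients = coef(zero_fit),
        loglik = as.numeric(logLik(zero_fit))
      ),
      count_part = list(
        coefficients = setNames(unname(opt$par[seq_len(p)]), colnames(Xc)),
        theta = unname(exp(opt$par[p + 1])),
        loglik = -opt$value,
        converged = opt$convergence == 0
      ),
      loglik = as.numeric(logLik(zero_fit)) - opt$value,
      n = length(counts)
    ),
    class = "hurdle_fit"
  )
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf(
    "<hurdle_fit> total loglik %.2f (zero %.2f + truncated NB %.2f), theta %.3f\n",
    x$loglik, x$zero_part$loglik, x$count_part$loglik, x$count_part$theta
  ))
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell `1 - exp(2 * (l0 - l1) / n)` rescaled by its maximum
#' `1 - exp(2 * l0 / n)`, giving a 0--1 measure of explained variation for
#' likelihood-based models.
#'
#' @param fit_loglik Log-likelihood of the fitted model.
#' @param null_loglik Log-likelihood of the intercept-only model
#'   (`fit_loglik >= null_loglik`).
#' @param n Number of observations.
#' @return Pseudo R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit_loglik, null_loglik, n) {
  assert_scalar_number(n, "n", min = 1)
  if (!is.finite(fit_loglik) || !is.finite(null_loglik) ||
    fit_loglik < null_loglik - 1e-8) {
    abort("`fit_loglik` must be >= `null_loglik` and finite.",
      class = "defensome_argument_error"
    )
  }
  cox_snell <- 1 - exp(2 * (null_loglik - fit_loglik) / n)
  max_cs <- 1 - exp(2 * null_loglik / n)
  if (max_cs <= 0) {
    return(0)
  }
  min(1, max(0, cox_snell / max_cs))
}

#' @rdname nagelkerke_r2
#' @param fit An `nb_fit`.
#' @export
nagelkerke_r2_nb <- function(fit) {
  stopifnot(inherits(fit, "nb_fit"))
  nagelkerke_r2(fit$loglik, fit$null_loglik, fit$n)
}
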