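#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return A named numeric vector `c(low, high)`, both within \[0, 1\].
#' @export
#' @examples
#' wilson_ci(5, 10)
wilson_ci <- function(successes, n, conf = 0.95) {
  assert_scalar_number(n, "n", min = 1)
  assert_scalar_number(successes, "successes", min = 0, max = n)
  assert_scalar_number(conf, "conf", min = 0, max = 1, allow_min = FALSE, allow_max = FALSE)
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-prior-penalized binomial log-likelihood
#' `l(beta) + 0.5 * log det I(beta)` by Newton iteration on the modified
#' score, with step-halving when a step decreases the penalized likelihood.
#' Unlike the ordinary MLE, the penalized estimate is finite under complete
#' or quasi-complete separation, which is why rare systems in small phyla
#' are modelled this way.
#'
#' @param design Numeric design matrix (full column rank; include your own
#'   intercept column if wanted).
#' @param response Binary 0/1 vector, one per design row.
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol Convergence tolerance on the modified score max-norm
#'   (default 1e-8).
#' @return An object of class `firth_fit`: `coefficients`,
#'   `standard_errors`, `vcov`, `loglik`, `penalized_loglik`, `converged`,
#'   `iterations`, `fitted`.
#' @export
firth_logistic <- function(design, response, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  if (length(y) != nrow(X)) {
    abort("`response` length must match `design` rows.",
      class = "defensome_argument_error"
    )
  }
  if (!all(y %in% c(0, 1))) {
    abort("`response` must be binary 0/1.", class = "defensome_argument_error")
  }
  if (qr(X)$rank < ncol(X)) {
    abort("`design` must have full column rank.",
      class = "defensome_argument_error"
    )
  }
  p <- ncol(X)
  beta <- rep(0, p)

  penalized <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    # numerically safe log(1 + exp(eta))
    log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    ll <- sum(y * eta - log1pe)
    list(
      ll = ll, pll = ll + 0.5 * determinant(info, logarithm = TRUE)$modulus,
      mu = mu, w = w, info = info
    )
  }

  st <- penalized(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    inv_info <- solve(st$info)
    # hat diagonal of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
    h <- rowSums((X %*% inv_info) * X) * st$w
    score <- drop(crossprod(X, y - st$mu + h * (0.5 - st$mu)))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    step <- drop(inv_info %*% score)
    # step-halving on penalized log-likelihood decrease
    for (half in 0:20) {
      cand <- beta + step / 2^half
      st_cand <- penalized(cand)
      if (st_cand$pll >= st$pll - 1e-12) break
    }
    beta <- cand
    st <- st_cand
  }
  inv_info <- solve(st$info)
  structure(
    list(
      coefficients = setNames(beta, colnames(X)),
      standard_errors = setNames(sqrt(diag(inv_info)), colnames(X)),
      vcov = inv_info,
      loglik = st$ll,
      penalized_loglik = as.numeric(st$pll),
      converged = converged,
      iterations = iter,
      fitted = st$mu
    ),
    class = "firth_fit"
  )
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf(
    "<firth_fit> %d coefficients, penalized loglik %.4f, %s in %d iterations\n",
    length(x$coefficients), x$penalized_loglik,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  print(cbind(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in rank.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be p-values in [0, 1].", class = "defensome_argument_error")
  }
  p.adjust(p, method = "BH")
}

#' Phylum-versus-overall-mean prevalence contrasts
#'
#' Fits a Firth bias-reduced logistic model of presence on phylum (cell
#' means coding, so each coefficient is a phylum's prevalence on the logit
#' scale — its estimated marginal mean), then contrasts each phylum against
#' the unweighted average of the phylum means on the link scale with a Wald
#' z test. P-values are Benjamini-Hochberg adjusted across phyla; phyla
#' with fewer than `min_n` genomes are excluded before fitting.
#'
#' @param presence Binary 0/1 vector.
#' @param phylum Factor or character vector of phylum labels.
#' @param min_n Minimum genomes per phylum (default 10).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param conf Confidence level for per-phylum prevalence intervals.
#' @return A tibble of class `prevalence_contrasts`: `phylum`, `n`,
#'   `estimate` (prevalence), `ci_low`, `ci_high`, `logit_diff` (phylum
#'   minus overall mean on the link scale), `p_raw`, `p_adjusted`,
#'   `direction` (`over`, `under`, `ns`).
#' @export
phylum_contrasts <- function(presence, phylum, min_n = 10L, alpha = 0.05,
                             conf = 0.95) {
  phylum <- as.character(phylum)
  stopifnot(length(presence) == length(phylum))
  tab <- table(phylum)
  keep_levels <- names(tab)[tab >= min_n]
  if (length(keep_levels) < 2L) {
    abort(sprintf(
      "need at least 2 phyla with >= %d genomes; %d found.",
      min_n, length(keep_levels)
    ), class = "defensome_argument_error")
  }
  keep <- phylum %in% keep_levels
  y <- as.numeric(presence[keep])
  ph <- factor(phylum[keep], levels = sort(keep_levels))
  X <- model.matrix(~ 0 + ph)
  colnames(X) <- levels(ph)
  fit <- firth_logistic(X, y)

  k <- length(levels(ph))
  beta <- fit$coefficients
  V <- fit$vcov
  z_conf <- qnorm(1 - (1 - conf) / 2)
  res <- purrr::map(seq_len(k), function(j) {
    cvec <- rep(-1 / k, k)
    cvec[j] <- cvec[j] + 1
    diff <- sum(cvec * beta)
    se_diff <- sqrt(drop(t(cvec) %*% V %*% cvec))
    z <- diff / se_diff
    tibble::tibble(
      phylum = levels(ph)[j],
      n = as.integer(sum(ph == levels(ph)[j])),
      estimate = plogis(beta[j]),
      ci_low = plogis(beta[j] - z_conf * fit$standard_errors[j]),
      ci_high = plogis(beta[j] + z_conf * fit$standard_errors[j]),
      logit_diff = diff,
      p_raw = 2 * pnorm(-abs(z))
    )
  })
  out <- purrr::list_rbind(res) |>
    dplyr::mutate(
      p_adjusted = bh_fdr(.data$p_raw),
      direction = dplyr::case_when(
        .data$p_adjusted < alpha & .data$logit_diff > 0 ~ "over",
        .data$p_adjusted < alpha & .data$logit_diff < 0 ~ "under",
        TRUE ~ "ns"
      )
    )
  class(out) <- c("prevalence_contrasts", class(out))
  out
}

#' Completeness-adjusted prevalence extrapolation
#'
#' Fits an ordinary logistic regression `presence ~ completeness + domain`
#' and predicts prevalence at completeness 1 for each domain, with Wald
#' confidence intervals built on the logit scale and back-transformed by
#' the inverse logit. Incomplete assemblies depress observed prevalence;
#' this extrapolates to what fully complete genomes would show.
#'
#' @param presence Binary 0/1 vector.
#' @param completeness Completeness fractions in (0, 1].
#' @param domain Factor or character vector (both domains must be present).
#' @param conf Confidence level (default 0.95).
#' @return A tibble: `domain`, `prevalence_at_1`, `ci_low`, `ci_high`, plus
#'   the fitted `glm` as attribute `"fit"`.
#' @export
completeness_adjusted_prevalence <- function(presence, completeness, domain,
                                             conf = 0.95) {
  if (any(completeness <= 0 | completeness > 1)) {
    abort("`completeness` must be in (0, 1].", class = "defensome_argument_error")
  }
  domain <- factor(domain)
  if (nlevels(domain) < 2L) {
    abort("both domains must be present.", class = "defensome_argument_error")
  }
  dat <- data.frame(
    presence = as.numeric(presence),
    completeness = completeness, domain = domain
  )
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(presence ~ completeness + domain, family = binomial(), data = dat),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
        grepl("algorithm did not converge", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # NA coefficients are aliased terms (e.g. constant completeness), not
  # separation; predict() drops them and the extrapolation degenerates to the
  # observed prevalence, which is the right answer there.
  cf <- coef(fit)
  if (separated || any(abs(cf) > 15, na.rm = TRUE)) {
    abort(paste(
      "the logistic fit shows signs of data separation;",
      "use firth_logistic() on the same design instead."
    ), class = "defensome_separation_error")
  }
  newdat <- data.frame(completeness = 1, domain = levels(domain))
  pred <- predict(fit, newdata = newdat, type = "link", se.fit = TRUE)
  z <- qnorm(1 - (1 - conf) / 2)
  out <- tibble::tibble(
    domain = levels(domain),
    prevalence_at_1 = unname(plogis(pred$fit)),
    ci_low = unname(plogis(pred$fit - z * pred$se.fit)),
    ci_high = unname(plogis(pred$fit + z * pred$se.fit))
  )
  attr(out, "fit") <- fit
  out
}
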