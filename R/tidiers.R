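#' Tidy a Firth logistic fit
#'
#' @param x A `firth_fit`.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy firth_fit
#' @export
tidy.firth_fit <- function(x, conf_level = 0.95, ...) {
  z <- x$coefficients / x$standard_errors
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$coefficients) %||% paste0("b", seq_along(x$coefficients)),
    estimate = unname(x$coefficients),
    std.error = unname(x$standard_errors),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    conf.low = unname(x$coefficients - q * x$standard_errors),
    conf.high = unname(x$coefficients + q * x$standard_errors)
  )
}

#' @rdname tidy.firth_fit
#' @method glance firth_fit
#' @export
glance.firth_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    penalized_logLik = x$penalized_loglik,
    converged = x$converged,
    iterations = x$iterations,
    nobs = length(x$fitted)
  )
}

#' Tidy a negative-binomial fit
#'
#' @param x An `nb_fit`.
#' @param ... Unused.
#' @return Coefficient-level tibble (`tidy`) or one-row model summary
#'   (`glance`, including `theta` and Nagelkerke pseudo R-squared).
#' @method tidy nb_fit
#' @export
tidy.nb_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' @rdname tidy.nb_fit
#' @method glance nb_fit
#' @export
glance.nb_fit <- function(x, ...) {
  tibble::tibble(
    theta = x$theta,
    logLik = x$loglik,
    null_logLik = x$null_loglik,
    pseudo_r2 = nagelkerke_r2_nb(x),
    converged = x$converged,
    nobs = x$n
  )
}

#' Tidy a hurdle negative-binomial fit
#'
#' @param x A `hurdle_fit`.
#' @param ... Unused.
#' @return `tidy`: coefficient tibble with a `component` column (`zero` /
#'   `count`); `glance`: one-row summary with part and total log-likelihoods.
#' @method tidy hurdle_fit
#' @export
tidy.hurdle_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      component = "zero",
      term = names(x$zero_part$coefficients),
      estimate = unname(x$zero_part$coefficients)
    ),
    tibble::tibble(
      component = "count",
      term = names(x$count_part$coefficients),
      estimate = unname(x$count_part$coefficients)
    )
  )
}

#' @rdname tidy.hurdle_fit
#' @method glance hurdle_fit
#' @export
glance.hurdle_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    zero_logLik = x$zero_part$loglik,
    count_logLik = x$count_part$loglik,
    theta = x$count_part$theta,
    converged = x$count_part$converged,
    nobs = x$n
  )
}
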