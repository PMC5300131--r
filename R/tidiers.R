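#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns the estimated terms of a
#' power-law fit as a tibble, `glance()` a one-row model summary.
#'
#' @param x An `lvr_powerlaw`, `lvr_powerfit`, or `lvr_study` object.
#' @param ... Unused.
#' @return A tibble.
#' @name lvrnet-tidiers
NULL

#' @rdname lvrnet-tidiers
#' @export
tidy.lvr_powerlaw <- function(x, ...) {
  tibble(term = c("log10_intercept", "alpha"),
         estimate = c(x$intercept, x$alpha))
}

#' @rdname lvrnet-tidiers
#' @export
glance.lvr_powerlaw <- function(x, ...) {
  tibble(alpha = x$alpha, r.squared = x$r2, rmse = x$rmse,
         n_tail_bins = x$n_tail_bins)
}

#' @rdname lvrnet-tidiers
#' @export
tidy.lvr_powerfit <- function(x, ...) {
  tibble(term = c("log_intercept", "exponent"),
         estimate = c(x$intercept, x$exponent))
}

#' @rdname lvrnet-tidiers
#' @export
glance.lvr_powerfit <- function(x, ...) {
  tibble(exponent = x$exponent, r.squared = x$r2, n = x$n)
}

#' @rdname lvrnet-tidiers
#' @export
tidy.lvr_study <- function(x, ...) x$outcomes

#' @rdname lvrnet-tidiers
#' @export
glance.lvr_study <- function(x, ...) {
  cvf <- tryCatch(study_cvforce_fit(x), error = function(e) NULL)
  tibble(n_networks = x$config$n_networks,
         n_responders = sum(x$networks$responder == "responder", na.rm = TRUE),
         n_failures = nrow(x$failures),
         cvforce_exponent = if (is.null(cvf)) NA_real_ else cvf$exponent,
         cvforce_r2 = if (is.null(cvf)) NA_real_ else cvf$r2)
}
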