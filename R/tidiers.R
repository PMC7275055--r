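#' Tidy a Gaussian-mixture FRET fit
#'
#' @param x A `fret_mixture`.
#' @param ... Unused.
#' @return One row per component: `component`, `mean`, `sd`, `weight`.
#' @method tidy fret_mixture
#' @export
tidy.fret_mixture <- function(x, ...) {
  tibble(component = seq_len(x$k), mean = x$means, sd = x$sds,
         weight = x$weights)
}

#' @rdname tidy.fret_mixture
#' @return `glance()` returns a one-row model summary.
#' @method glance fret_mixture
#' @export
glance.fret_mixture <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, bic = unname(x$bic[paste0("k", x$k)]),
         converged = x$converged, n = x$n)
}

#' Tidy a dwell-time exponential fit
#'
#' @param x A `dwell_fit`.
#' @param ... Unused.
#' @return One row per exponential component: `term`, `rate` (per s),
#'   `std.error`, `amplitude`.
#' @method tidy dwell_fit
#' @export
tidy.dwell_fit <- function(x, ...) {
  tibble(term = paste0("k", seq_along(x$rates)), rate = x$rates,
         std.error = x$rate_se, amplitude = x$amplitudes)
}

#' @rdname tidy.dwell_fit
#' @method glance dwell_fit
#' @export
glance.dwell_fit <- function(x, ...) {
  tibble(model = x$model, aic = unname(x$aic[x$model]),
         mle_rate = x$mle_rate, n = x$n)
}
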