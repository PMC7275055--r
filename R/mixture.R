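#' Gaussian-mixture decomposition of a FRET population
#'
#' Fits one-dimensional Gaussian mixtures to per-molecule FRET samples by
#' expectation-maximisation, for each candidate number of components, and
#' selects the model by BIC (unless `k` is a single fixed value). This is
#' the multi-Gaussian fit used to decompose an smFRET population into its
#' low / intermediate / high conformational states.
#'
#' EM details: components are initialised at evenly spaced sample
#' quantiles; additional restarts jitter those initial means; component
#' standard deviations are floored at `sd_floor` to keep the likelihood
#' bounded; convergence is declared when the log-likelihood improves by
#' less than `tol`. The fit is deterministic for a given `seed` (the
#' caller's RNG state is left untouched).
#'
#' @param samples Tibble from [fret_samples()] (column `E_mean`) or a
#'   numeric vector. At least 20 samples are required.
#' @param k Candidate component counts (default `1:3`).
#' @param n_restarts EM restarts per candidate `k`.
#' @param sd_floor Lower bound on component standard deviations.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Seed for the restart jitter.
#' @return An object of class `fret_mixture`: component `means`, `sds`,
#'   `weights` (sorted by ascending mean, weights summing to 1),
#'   `k`, `loglik`, `bic` (named vector over all candidates), `converged`,
#'   `responsibilities`, `n`, and the samples used.
#' @seealso [population_fractions()], [assign_states()],
#'   [fit_states_histogram()] for the histogram-space variant.
#' @examples
#' x <- c(rnorm(300, 0.36, 0.03), rnorm(300, 0.71, 0.03))
#' fit <- fit_fret_states(x, k = 1:3)
#' fit$k
#' tidy(fit)
#' @export
fit_fret_states <- function(samples, k = 1:3, n_restarts = 20,
                            sd_floor = 0.01, tol = 1e-6, max_iter = 500,
                            seed = 1L) {
  x <- if (is.data.frame(samples)) samples$E_mean else as.numeric(samples)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) abort("at least 20 samples are required for mixture fitting")

  fits <- lapply(k, function(kk) {
    em_best_of_restarts(x, kk, n_restarts, sd_floor, tol, max_iter, seed)
  })
  bic <- vapply(fits, function(f) -2 * f$loglik + (3 * f$k - 1) * log(n), 0)
  names(bic) <- paste0("k", k)
  best <- fits[[which.min(bic)]]

  ord <- order(best$means)
  out <- list(
    k = best$k,
    means = best$means[ord],
    sds = best$sds[ord],
    weights = best$weights[ord] / sum(best$weights),
    loglik = best$loglik,
    bic = bic,
    converged = best$converged,
    responsibilities = best$resp[, ord, drop = FALSE],
    n = n,
    samples = x
  )
  class(out) <- "fret_mixture"
  out
}

em_best_of_restarts <- function(x, k, n_restarts, sd_floor, tol, max_iter, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  q <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  spread <- max(sd(x) / k, sd_floor)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu0 <- if (r == 1) q else q + rnorm(k, 0, spread)
    fit <- em_gaussian_1d(x, mu0, rep(spread, k), rep(1 / k, k),
                          sd_floor, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (k == 1) break   # single-component fit is deterministic
  }
  best
}

em_gaussian_1d <- function(x, mu, sigma, w, sd_floor, tol, max_iter) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  converged <- FALSE
  resp <- matrix(1 / k, n, k)
  for (iter in seq_len(max_iter)) {
    # E step
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    resp <- dens / tot
    ll <- sum(log(tot))
    # M step
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * outer(x, mu, "-")^2) / nk)
    sigma <- pmax(sigma, sd_floor)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(k = k, means = mu, sds = sigma, weights = w, loglik = ll,
       converged = converged, resp = resp)
}

#' @export
print.fret_mixture <- function(x, ...) {
  cat("<fret_mixture> k =", x$k, "components over", x$n, "samples\n")
  print(tidy(x))
  cat("BIC:", paste(names(x$bic), round(x$bic, 1), collapse = "  "), "\n")
  invisible(x)
}

#' Histogram-space Gaussian fit of a FRET population
#'
#' Least-squares fit of a sum of `k` Gaussians directly to an
#' area-normalised histogram — the way published population fits are drawn
#' on top of histograms. Provided as a cross-check for the sample-space EM
#' of [fit_fret_states()]; the two agree on well-sampled data.
#'
#' @param histogram A [fret_histogram()].
#' @param k Number of components (fixed; no model selection here).
#' @param sd_floor Lower bound on component standard deviations.
#' @return A `fret_mixture`-like object (class `fret_mixture`) with
#'   `loglik`/`bic`/`responsibilities` set to `NA`.
#' @export
fit_states_histogram <- function(histogram, k = 3, sd_floor = 0.01) {
  stopifnot(inherits(histogram, "fret_histogram"))
  y <- histogram$density
  bl <- histogram$bin_left
  br <- histogram$bin_right
  bw <- br - bl
  q <- quantile(attr(histogram, "samples"), probs = (seq_len(k) - 0.5) / k,
                names = FALSE)
  s0 <- max(sd(attr(histogram, "samples")) / k, sd_floor)
  par0 <- c(q, rep(log(s0), k), rep(0, k))   # means, log-sds, weight logits
  obj <- function(p) {
    mu <- p[seq_len(k)]
    sig <- pmax(exp(p[k + seq_len(k)]), sd_floor)
    w <- exp(p[2 * k + seq_len(k)])
    w <- w / sum(w)
    # model density = component mass integrated over each bin / bin width,
    # exact even when a component is narrower than a bin
    pred <- rowSums(vapply(seq_len(k), function(j) {
      w[j] * (stats::pnorm(br, mu[j], sig[j]) -
                stats::pnorm(bl, mu[j], sig[j])) / bw
    }, numeric(length(y))))
    sum((pred - y)^2)
  }
  opt <- optim(par0, obj, method = "BFGS", control = list(maxit = 2000))
  mu <- opt$par[seq_len(k)]
  sig <- pmax(exp(opt$par[k + seq_len(k)]), sd_floor)
  w <- exp(opt$par[2 * k + seq_len(k)])
  w <- w / sum(w)
  ord <- order(mu)
  out <- list(k = k, means = mu[ord], sds = sig[ord], weights = w[ord],
              loglik = NA_real_, bic = NA_real_, converged = opt$convergence == 0,
              responsibilities = NULL, n = attr(histogram, "n_molecules"),
              samples = attr(histogram, "samples"))
  class(out) <- "fret_mixture"
  out
}

#' Fractional occupancy of labelled FRET states
#'
#' Maps fitted mixture components to named conformational states and
#' reports their weights as fractions. When the fit has exactly as many
#' components as labels, the mapping is by ascending mean (low <
#' intermediate < high); with fewer components each is assigned to the
#' label whose reference mean is nearest, and absent states are reported
#' as 0 rather than forced into the fit.
#'
#' @param fit A [fit_fret_states()] result.
#' @param state_labels Labels in ascending-FRET order.
#' @param reference_means Canonical apparent-FRET means used to place
#'   components when fewer components than labels were fitted.
#' @return Tibble with `state`, `mean`, `sd`, `fraction`, `percent`
#'   (absent states have `NA` mean/sd and zero fraction).
#' @examples
#' x <- c(rnorm(200, 0.36, 0.03), rnorm(400, 0.71, 0.03))
#' population_fractions(fit_fret_states(x, k = 2))
#' @export
population_fractions <- function(fit,
                                 state_labels = c("low", "intermediate", "high"),
                                 reference_means = c(0.36, 0.57, 0.71)) {
  stopifnot(inherits(fit, "fret_mixture"))
  n_lab <- length(state_labels)
  assign_to <- if (fit$k == n_lab) {
    seq_len(n_lab)
  } else {
    vapply(fit$means, function(m) which.min(abs(m - reference_means)), 0L)
  }
  frac <- numeric(n_lab)
  mu <- rep(NA_real_, n_lab)
  sdv <- rep(NA_real_, n_lab)
  for (j in seq_len(fit$k)) {
    lab <- assign_to[j]
    frac[lab] <- frac[lab] + fit$weights[j]
    mu[lab] <- if (is.na(mu[lab])) fit$means[j] else mu[lab]
    sdv[lab] <- if (is.na(sdv[lab])) fit$sds[j] else sdv[lab]
  }
  tibble(state = factor(state_labels, levels = state_labels),
         mean = mu, sd = sdv, fraction = frac, percent = 100 * frac)
}

#' Per-frame conformational state assignment with hysteresis
#'
#' Assigns each valid frame of each trajectory to a fitted mixture
#' component. The trajectory is first smoothed with a running median
#' (width `smooth_frames`); a label change is proposed when the smoothed
#' efficiency crosses the midpoint between the current and the proposed
#' component means, pushed `hysteresis` of the half-gap further into the
#' new state's territory; and the change is accepted only if it persists
#' for at least `min_dwell` frames. The hysteresis margin plus the
#' minimum-dwell rule suppress noise-driven flicker while leaving genuine
#' long-lived transitions detectable within a frame or two.
#'
#' @param fret Tibble from [compute_fret()] (optionally already masked
#'   with [mask_after_events()]).
#' @param fit A [fit_fret_states()] result (>= 1 component).
#' @param smooth_frames Running-median width (odd; 1 disables smoothing).
#' @param min_dwell Minimum frames a new label must persist.
#' @param hysteresis Fraction of the half-gap between adjacent means added
#'   to the crossing threshold.
#' @return The input tibble with an integer `state` column (index into
#'   `fit$means`, NA on invalid frames) added.
#' @export
assign_states <- function(fret, fit, smooth_frames = 5, min_dwell = 3,
                          hysteresis = 0.25) {
  stopifnot(inherits(fit, "fret_mixture"))
  if (fit$k < 1) abort("fit must have at least one component")
  fret <- arrange(fret, .data$molecule_id, .data$frame)
  state <- rep(NA_integer_, nrow(fret))
  for (rows in split(seq_len(nrow(fret)), fret$molecule_id)) {
    ok <- fret$valid[rows] & is.finite(fret$E_fret[rows])
    if (!any(ok)) next
    e <- fret$E_fret[rows][ok]
    state[rows[ok]] <- assign_states_vector(e, fit$means, smooth_frames,
                                            min_dwell, hysteresis)
  }
  mutate(fret, state = state)
}

assign_states_vector <- function(e, means, smooth_frames, min_dwell, hysteresis) {
  n <- length(e)
  k <- length(means)
  sm <- if (smooth_frames > 1 && n >= smooth_frames) {
    stats::runmed(e, k = smooth_frames %/% 2 * 2 + 1, endrule = "median")
  } else e
  if (k == 1) return(rep(1L, n))
  nearest <- vapply(sm, function(v) which.min(abs(v - means)), 0L)
  lab <- integer(n)
  # initial label from the median of the first few smoothed frames, so a
  # single noisy opening frame cannot seed a spurious transition
  cur <- which.min(abs(median(sm[seq_len(min(5, n))]) - means))
  lab[1] <- cur
  i <- 2
  while (i <= n) {
    prop <- nearest[i]
    if (prop != cur) {
      # threshold between current and proposed means, with hysteresis
      mid <- (means[cur] + means[prop]) / 2
      h <- hysteresis * abs(means[prop] - means[cur]) / 2
      thr <- mid + sign(means[prop] - means[cur]) * h
      run_end <- min(n, i + min_dwell - 1)
      run <- sm[i:run_end]
      crossed <- if (means[prop] > means[cur]) all(run > thr) else all(run < thr)
      persists <- all(nearest[i:run_end] == prop)
      if (length(run) >= min_dwell && crossed && persists) cur <- prop
    }
    lab[i] <- cur
    i <- i + 1
  }
  lab
}
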