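#' Fit a DIPSHIFT dephasing curve for the molecular order parameter
#'
#' Least-squares comparison of an observed dephasing curve against curves
#' simulated with the same powder-average engine, over the order parameter
#' S in \[0, 1\]. The coupling evolving during t1 is `kappa * S * d_rigid`,
#' so the fitted S is directly the ratio D_exp / D_rigid. The objective
#' \deqn{RSS(S) = \sum_{t_1} [I_{obs}(t_1) - A\, I_{sim}(t_1; \kappa S D_{rigid})]^2}
#' is minimized by a coarse global scan (default step 0.01 in S) followed by
#' local refinement with [stats::optimize()]; the global scan guards against
#' the local minima produced by oscillatory curves at large d_eff/nu_r.
#'
#' The multiplicative amplitude A absorbs residual normalization error of the
#' integrated intensities. By default it is fitted but confined to
#' \[0.9, 1.1\] so that it cannot trade against S; `amplitude = "fixed"`
#' forces a pure shape fit with A = 1.
#'
#' @param curve a `dephasing_curve` with at least 5 points including t1 = 0
#' @param pair a [spin_pair()] providing the rigid-limit coupling
#' @param scale a [decoupling_scale()] providing kappa
#' @param powder powder scheme used for the simulated curves (ignored when
#'   `sim` is given)
#' @param sim optional precomputed [dipshift_simulator()] sharing the curve's
#'   t1 grid; pass one when fitting many curves to amortize the powder setup
#' @param amplitude "fit" (default, A in \[0.9, 1.1\]) or "fixed" (A = 1)
#' @param scan_step grid step of the global S scan
#' @param uncertainty method forwarded to [estimate_uncertainty()], or "none"
#' @return object of class `fit_result`: `S_fit`, `d_eff_fit` (Hz), `sigma_S`,
#'   `amplitude`, `rss`, `n_points`, `converged`, `uncertainty_method`, plus
#'   the provenance fields `kappa` and `d_rigid`
#' @export
fit_dephasing <- function(curve, pair = spin_pair(), scale = decoupling_scale(),
                          powder = powder_scheme(), sim = NULL,
                          amplitude = c("fit", "fixed"), scan_step = 0.01,
                          uncertainty = c("jackknife", "curvature",
                                          "montecarlo", "none")) {
  amplitude <- match.arg(amplitude)
  uncertainty <- match.arg(uncertainty)
  stopifnot(inherits(curve, "dephasing_curve"))
  n <- length(curve$t1)
  n_par <- if (amplitude == "fit") 2L else 1L
  if (n < max(5L, n_par + 1L)) {
    stop("curve must have at least 5 points (and more than the number of ",
         "free parameters)", call. = FALSE)
  }
  if (curve$t1[1] != 0) stop("curve must include t1 = 0", call. = FALSE)
  if (is.null(sim)) {
    mas <- mas_condition(curve$nu_r, t1_grid = curve$t1)
    sim <- dipshift_simulator(mas, powder)
  }
  iobs <- curve$intensity / curve$intensity[1]
  d_unit <- scale$kappa * pair$d_rigid  # coupling at S = 1

  eng <- .fit_engine(iobs, seq_len(n), sim, d_unit, amplitude, scan_step)
  if (eng$S >= 1 - 1e-3) {
    warning("best fit at the S = 1 boundary: rigid-limit convention suspect",
            call. = FALSE)
  }
  fit <- structure(
    list(S_fit = eng$S, d_eff_fit = d_unit * eng$S, sigma_S = 0,
         amplitude = eng$A, rss = eng$rss, n_points = n, converged = TRUE,
         uncertainty_method = "none", kappa = scale$kappa,
         d_rigid = pair$d_rigid, scan_step = scan_step,
         amplitude_mode = amplitude),
    class = "fit_result"
  )
  if (uncertainty != "none") {
    fit <- estimate_uncertainty(curve, fit, method = uncertainty, sim = sim)
  }
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> S = %.3f +/- %.3f (%s), d_eff = %.5g Hz, rss = %.3g\n",
              x$S_fit, x$sigma_S, x$uncertainty_method, x$d_eff_fit, x$rss))
  invisible(x)
}

# Core 1-D minimization over S for a (possibly subsetted) curve.
# iobs: normalized intensities; idx: columns of the t1 grid in use.
.fit_engine <- function(iobs, idx, sim, d_unit, amplitude, scan_step,
                        refine_tol = 1e-6) {
  L <- .scan_library(sim, d_unit, scan_step)  # n_S x n_t1 simulated curves
  Ls <- L$curves[, idx, drop = FALSE]
  y <- iobs[idx]
  if (amplitude == "fit") {
    A <- as.vector(Ls %*% y) / rowSums(Ls^2)
    A <- pmin(pmax(A, 0.9), 1.1)
  } else {
    A <- rep(1, nrow(Ls))
  }
  rss_scan <- rowSums((matrix(y, nrow(Ls), length(y), byrow = TRUE) - A * Ls)^2)
  i0 <- which.min(rss_scan)
  obj <- function(S) {
    isim <- sim(d_unit * S)[idx]
    a <- if (amplitude == "fit") {
      min(max(sum(isim * y) / sum(isim^2), 0.9), 1.1)
    } else 1
    list(rss = sum((y - a * isim)^2), A = a)
  }
  lo <- max(0, L$S[i0] - scan_step)
  hi <- min(1, L$S[i0] + scan_step)
  opt <- stats::optimize(function(S) obj(S)$rss, c(lo, hi), tol = refine_tol)
  cand <- if (opt$objective <= rss_scan[i0]) opt$minimum else L$S[i0]
  at <- obj(cand)
  list(S = cand, A = at$A, rss = at$rss)
}

# Cache the coarse-scan curve library on the simulator closure so repeated
# fits (jackknife, Monte-Carlo, sweeps) pay for it once.
.scan_library <- function(sim, d_unit, scan_step) {
  cache <- attr(sim, "cache")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())  # no persistence
  key <- sprintf("%.12g_%g", d_unit, scan_step)
  hit <- if (exists(key, envir = cache, inherits = FALSE)) {
    get(key, envir = cache, inherits = FALSE)
  } else NULL
  if (is.null(hit)) {
    S <- seq(0, 1, by = scan_step)
    curves <- t(vapply(S, function(s) sim(d_unit * s),
                       numeric(length(attr(sim, "mas")$t1_grid))))
    hit <- list(S = S, curves = curves)
    assign(key, hit, envir = cache)
  }
  hit
}

#' Uncertainty of a fitted order parameter
#'
#' Attaches a non-negative `sigma_S` to a converged fit. The reporting unit of
#' the experimental error is not fixed by the acquisition alone, so the method
#' is always recorded next to the value:
#' \describe{
#'   \item{jackknife}{leave-one-out over t1 points (default; needs >= 6
#'     points): refit with each point deleted and apply the jackknife
#'     variance formula.}
#'   \item{montecarlo}{refit `n_rep` replicates of the best-fit curve
#'     perturbed with Gaussian noise of sd `noise_sd` (taken from the curve's
#'     own `noise_sd` when present); `sigma_S` is the sd of the refits.}
#'   \item{curvature}{local quadratic expansion of the objective at the
#'     minimum, scaled by the residual variance.}
#' }
#'
#' @param curve the fitted `dephasing_curve`
#' @param fit a `fit_result` from [fit_dephasing()]
#' @param method one of "jackknife", "montecarlo", "curvature"
#' @param sim optional precomputed simulator on the curve's t1 grid
#' @param powder powder scheme when `sim` is not given
#' @param n_rep Monte-Carlo replicates
#' @param noise_sd Monte-Carlo noise sd (defaults to the curve's `noise_sd`)
#' @param seed optional seed for the Monte-Carlo draw
#' @return the `fit_result` with `sigma_S` and `uncertainty_method` set
#' @export
estimate_uncertainty <- function(curve, fit,
                                 method = c("jackknife", "montecarlo",
                                            "curvature"),
                                 sim = NULL, powder = powder_scheme(),
                                 n_rep = 100, noise_sd = NULL, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "dephasing_curve"), inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  n <- length(curve$t1)
  if (is.null(sim)) {
    sim <- dipshift_simulator(mas_condition(curve$nu_r, t1_grid = curve$t1),
                              powder)
  }
  iobs <- curve$intensity / curve$intensity[1]
  d_unit <- fit$kappa * fit$d_rigid
  amplitude <- fit$amplitude_mode
  scan_step <- fit$scan_step

  sigma <- switch(method,
    jackknife = {
      if (n < 6) stop("jackknife needs at least 6 points", call. = FALSE)
      s_i <- vapply(seq_len(n), function(i) {
        .fit_engine(iobs, setdiff(seq_len(n), i), sim, d_unit, amplitude,
                    scan_step, refine_tol = 1e-5)$S
      }, numeric(1))
      sqrt((n - 1) / n * sum((s_i - mean(s_i))^2))
    },
    montecarlo = {
      sd0 <- if (!is.null(noise_sd)) noise_sd else curve$noise_sd
      if (is.null(sd0)) stop("montecarlo needs 'noise_sd'", call. = FALSE)
      if (!is.null(seed)) set.seed(seed)
      base <- fit$amplitude * sim(d_unit * fit$S_fit)
      s_r <- vapply(seq_len(n_rep), function(r) {
        y <- base + stats::rnorm(n, sd = sd0)
        .fit_engine(y / y[1], seq_len(n), sim, d_unit, amplitude, scan_step,
                    refine_tol = 1e-5)$S
      }, numeric(1))
      stats::sd(s_r)
    },
    curvature = {
      h <- max(scan_step / 2, 1e-3)
      s0 <- min(max(fit$S_fit, h), 1 - h)
      rss_at <- function(S) {
        isim <- sim(d_unit * S)
        a <- if (amplitude == "fit") {
          min(max(sum(isim * iobs) / sum(isim^2), 0.9), 1.1)
        } else 1
        sum((iobs - a * isim)^2)
      }
      d2 <- (rss_at(s0 + h) - 2 * rss_at(s0) + rss_at(s0 - h)) / h^2
      n_par <- if (amplitude == "fit") 2L else 1L
      if (d2 <= 0 || n <= n_par) 0 else
        sqrt(2 * fit$rss / (n - n_par) / d2)
    })
  fit$sigma_S <- max(sigma, 0)
  fit$uncertainty_method <- method
  fit
}

#' Tabulate order-parameter fits across conditions
#'
#' One row per label and excitation condition, with S +/- sigma_S, ordered by
#' label and then by condition (CP contact times ascending, direct excitation
#' last) — the layout of the order-parameter bar charts this analysis
#' produces.
#'
#' @param results list of `fit_result` objects
#' @param labels optional character vector overriding per-result labels
#' @param conditions optional list of per-result conditions, each a list with
#'   `excitation` ("cp"/"direct") and `contact_time` (s); defaults taken from
#'   `attr(result, "condition")` or blank
#' @return data.frame with columns label, excitation, contact_time_us, S_fit,
#'   sigma_S, uncertainty_method, d_eff_fit_hz, rss, n_points
#' @export
fit_report <- function(results, labels = NULL, conditions = NULL) {
  if (length(results) == 0) stop("'results' must be non-empty", call. = FALSE)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    cond <- if (!is.null(conditions)) conditions[[i]] else
      attr(r, "condition", exact = TRUE)
    if (is.null(cond)) cond <- list(excitation = NA_character_, contact_time = NA_real_)
    data.frame(
      label = if (!is.null(labels)) labels[[i]] else
        if (!is.null(attr(r, "label"))) attr(r, "label") else "",
      excitation = cond$excitation,
      contact_time_us = if (is.null(cond$contact_time) ||
                            identical(cond$excitation, "direct")) NA_real_ else
        cond$contact_time * 1e6,
      S_fit = r$S_fit, sigma_S = r$sigma_S,
      uncertainty_method = r$uncertainty_method,
      d_eff_fit_hz = r$d_eff_fit, rss = r$rss, n_points = r$n_points,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  # direct excitation sorts after any CP contact time
  key <- ifelse(is.na(out$contact_time_us) & out$excitation %in% "direct",
                Inf, out$contact_time_us)
  out[order(out$label, key, na.last = TRUE), , drop = FALSE]
}
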