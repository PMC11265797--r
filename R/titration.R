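#' Per-residue protonation traces across pH replicas
#'
#' @param residue residue label
#' @param pH_values distinct pH of each replica window
#' @param traces list of binary vectors (1 = protonated), one per pH
#' @param frame_period_ns time between frames, ns
#' @export
protonation_series <- function(residue, pH_values, traces, frame_period_ns = 0.01) {
  pH_values <- as.numeric(pH_values)
  stopifnot(length(traces) == length(pH_values), frame_period_ns > 0)
  if (anyDuplicated(pH_values)) stop("protonation_series: duplicate pH values")
  traces <- lapply(traces, function(tr) {
    tr <- as.integer(tr)
    if (length(tr) == 0L) stop("protonation_series: empty trace")
    if (!all(tr %in% c(0L, 1L))) stop("protonation_series: traces must be binary")
    tr
  })
  structure(list(residue = residue, pH = pH_values, traces = traces,
                 frame_period_ns = frame_period_ns),
            class = "protonation_series")
}

#' @export
print.protonation_series <- function(x, ...) {
  cat("<protonation_series> residue ", x$residue, ", ", length(x$pH),
      " pH windows (", min(x$pH), "..", max(x$pH), "), ",
      length(x$traces[[1]]), " frames x ", x$frame_period_ns, " ns\n", sep = "")
  invisible(x)
}

#' Deprotonated fraction per pH window
#'
#' @param series a [protonation_series()]
#' @param frames optional integer frame range c(first, last); default all
#' @return data.frame with columns pH and fraction (deprotonated, in [0, 1])
#' @export
deprotonated_fractions <- function(series, frames = NULL) {
  stopifnot(inherits(series, "protonation_series"))
  fr <- vapply(series$traces, function(tr) {
    idx <- if (is.null(frames)) seq_along(tr) else {
      if (frames[1] > frames[2] || frames[1] < 1 || frames[2] > length(tr))
        stop("deprotonated_fractions: empty or out-of-range frame window")
      frames[1]:frames[2]
    }
    mean(1 - tr[idx])
  }, 0)
  data.frame(pH = series$pH, fraction = fr)
}

#' Fit a titration curve to per-pH deprotonated fractions
#'
#' Least-squares fit of the Henderson-Hasselbalch / Hill model
#' f_deprot(pH) = 1 / (1 + 10^(n (pKa - pH))). The Hill coefficient n is
#' fixed at 1 (single-site residue) unless `fit_hill = TRUE`. The pKa is
#' constrained to [min(pH) - 2, max(pH) + 2].
#'
#' @param fractions data.frame with columns `pH` and `fraction`
#' @param fit_hill also fit the Hill coefficient
#' @param source bookkeeping tag ("full" or "chunk")
#' @return a `pka_estimate`: list with `pKa`, `hill`, `residual` (RMS of fit
#'   residuals), `source`
#' @export
fit_titration <- function(fractions, fit_hill = FALSE, source = "full") {
  stopifnot(is.data.frame(fractions), all(c("pH", "fraction") %in% names(fractions)))
  ph <- fractions$pH; f <- fractions$fraction
  if (length(ph) < 2L) stop("fit_titration: need at least 2 pH points")
  if (any(f < 0 | f > 1)) stop("fit_titration: fractions must lie in [0, 1]")
  if (all(f <= 0) || all(f >= 1))
    stop("fit_titration: unidentifiable (all fractions 0 or all 1)")
  lo <- min(ph) - 2; hi <- max(ph) + 2
  model <- function(p, n) 1 / (1 + 10^(n * (p[1] - ph)))
  start_pka <- ph[which.min(abs(f - 0.5))]
  if (fit_hill) {
    obj <- function(p) sum((model(p, p[2]) - f)^2)
    fit <- stats::optim(c(start_pka, 1), obj, method = "L-BFGS-B",
                        lower = c(lo, 0.1), upper = c(hi, 5),
                        control = list(factr = 10))
    pka <- fit$par[1]; hill <- fit$par[2]
  } else {
    obj <- function(p) sum((model(p, 1) - f)^2)
    fit <- stats::optim(start_pka, obj, method = "L-BFGS-B",
                        lower = lo, upper = hi, control = list(factr = 10))
    pka <- fit$par[1]; hill <- 1
  }
  structure(list(pKa = pka, hill = hill,
                 residual = sqrt(fit$value / length(ph)), source = source),
            class = "pka_estimate")
}

#' @export
print.pka_estimate <- function(x, ...) {
  cat("<pka_estimate> pKa = ", format(x$pKa, digits = 4),
      " (hill ", format(x$hill, digits = 3), ", rms resid ",
      format(x$residual, digits = 3), ", ", x$source, ")\n", sep = "")
  invisible(x)
}

#' Chunked pKa estimates and their histogram
#'
#' Splits the traces into consecutive non-overlapping chunks of `chunk_ns`
#' and fits a titration curve per chunk, emulating the per-chunk pKa
#' analysis used to assess constant-pH convergence. Chunks that are
#' unidentifiable (all-protonated or all-deprotonated at every pH) are
#' skipped and counted.
#'
#' @param series a [protonation_series()]
#' @param chunk_ns chunk length, ns
#' @param fit_hill passed to [fit_titration()]
#' @return list with `estimates` (vector of chunk pKa values), `fits`
#'   (list of `pka_estimate`s), `n_skipped`, `histogram` (from [hist()],
#'   not plotted) and `bimodality` (see [bimodality_flag()])
#' @export
chunked_pka <- function(series, chunk_ns, fit_hill = FALSE) {
  stopifnot(inherits(series, "protonation_series"), chunk_ns > 0)
  frames_per_chunk <- floor(chunk_ns / series$frame_period_ns)
  n <- length(series$traces[[1]])
  if (frames_per_chunk > n)
    stop("chunked_pka: chunk (", chunk_ns, " ns) longer than trace (",
         n * series$frame_period_ns, " ns)")
  if (frames_per_chunk < 1L) stop("chunked_pka: chunk shorter than one frame")
  n_chunks <- n %/% frames_per_chunk
  fits <- list(); skipped <- 0L
  for (k in seq_len(n_chunks)) {
    rng <- c((k - 1L) * frames_per_chunk + 1L, k * frames_per_chunk)
    fr <- deprotonated_fractions(series, rng)
    fit <- tryCatch(fit_titration(fr, fit_hill = fit_hill, source = "chunk"),
                    error = function(e) NULL)
    if (is.null(fit)) skipped <- skipped + 1L else fits[[length(fits) + 1L]] <- fit
  }
  est <- vapply(fits, `[[`, 0, "pKa")
  est <- est[is.finite(est)]
  h <- if (length(est)) graphics::hist(est, plot = FALSE) else NULL
  list(estimates = est, fits = fits, n_skipped = skipped,
       histogram = h, bimodality = bimodality_flag(est))
}

#' Crude bimodality flag for a sample of estimates
#'
#' Splits the sample with 2-means and computes an Ashman-style separation
#' D = |m1 - m2| / sqrt((s1^2 + s2^2) / 2); D > 4 with both clusters
#' populated flags the distribution as bimodal (a 2-means split of a
#' unimodal Gaussian already yields D of about 2.7, so the threshold sits
#' well above that). A lightweight screen, not a formal test.
#'
#' @param x numeric sample
#' @return list with `bimodal` (logical), `separation` (D) and cluster means
#' @export
bimodality_flag <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 4L)
    return(list(bimodal = FALSE, separation = NA_real_, means = NA_real_))
  km <- stats::kmeans(x, centers = 2, nstart = 5)
  m <- as.numeric(km$centers)
  s <- vapply(1:2, function(k) stats::sd(x[km$cluster == k]), 0)
  s[is.na(s)] <- 0
  pooled <- sqrt((s[1]^2 + s[2]^2) / 2)
  D <- if (pooled > 0) abs(diff(m)) / pooled else Inf
  frac <- min(table(km$cluster)) / length(x)
  list(bimodal = D > 4 && frac >= 0.15, separation = D, means = sort(m))
}

#' Replicate mean and standard deviation of pKa estimates
#'
#' @param estimates numeric vector of per-replicate pKa values, or a list of
#'   `pka_estimate`s
#' @return list with `mean`, `sd` (sample SD, n-1 denominator; NA when fewer
#'   than 2 replicates) and `n`
#' @export
replicate_stats <- function(estimates) {
  if (is.list(estimates) && all(vapply(estimates, inherits, NA, "pka_estimate")))
    estimates <- vapply(estimates, `[[`, 0, "pKa")
  estimates <- as.numeric(estimates)
  list(mean = mean(estimates),
       sd = if (length(estimates) >= 2L) stats::sd(estimates) else NA_real_,
       n = length(estimates))
}

#' Convert a pKa shift to a protonation free-energy change
#'
#' ddG_protonation = -RT ln(10) * delta_pKa: a positive pKa shift makes
#' protonation more favourable by RT ln 10 per log unit (1.4186 kcal/mol at
#' 310 K).
#'
#' @param delta_pka pKa shift (log units)
#' @param temperature temperature, K
#' @return free-energy change, kcal/mol
#' @export
pka_shift_to_ddg <- function(delta_pka, temperature = DEFAULT_TEMPERATURE) {
  -rt_ln10(temperature) * delta_pka
}
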