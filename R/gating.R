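# G1/0 gating: a two-component Gaussian mixture is fitted to the single-cell
# distribution of total nuclear Hoechst intensity (a proxy for DNA content);
# cells within +/-2 SD of the lower-mean ("first") peak are kept, then
# restricted further by +/-2 MAD windows on nuclear size and Hoechst texture.

#' Fit a two-component Gaussian mixture to total Hoechst intensity
#'
#' Maximum-likelihood fit by expectation-maximisation.  Components are
#' initialised at the 25th and 75th percentiles with equal weights and a
#' common SD, and reported sorted by mean (component 1 = lower mean = 2N
#' peak).  A vanishing component SD is floored at `1e-6 * sd(x)` and flagged.
#' The fit is deterministic: the initialisation is quantile-based, so the
#' same data always give the same parameters regardless of input order.
#'
#' @param totals Numeric vector of total Hoechst intensities (>= 50 positive
#'   finite values).
#' @param seed Integer seed (kept for interface stability; the default EM is
#'   deterministic).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   falls below `tol` or after `max_iter` iterations.
#' @return An object of class `hoechst_mixture`: list with `weight`, `mean`,
#'   `sd` (length-2, sorted by mean), `loglik` (trace across iterations),
#'   `n`, `sd_floored`, `converged`.
#' @examples
#' x <- c(rnorm(700, 100, 5), rnorm(300, 200, 5))
#' fit <- fit_hoechst_mixture(x)
#' tidy(fit)
#' @export
fit_hoechst_mixture <- function(totals, seed = 1L, max_iter = 500L,
                                tol = 1e-8) {
  x <- as.numeric(totals)
  if (length(x) < 50L || any(!is.finite(x)) || any(x <= 0)) {
    abort("need at least 50 positive finite Hoechst totals",
          class = "platetalk_insufficient_data")
  }
  n <- length(x)
  qs <- quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- qs
  sigma <- rep(max(sd(x) / 2, 1e-12), 2)
  w <- c(0.5, 0.5)
  sd_floor <- 1e-6 * sd(x)
  floored <- FALSE
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    loglik <- c(loglik, sum(log(tot)))
    r <- d1 / tot
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / n
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sigma <- sqrt(c(sum(r * (x - mu[1])^2) / n1,
                    sum((1 - r) * (x - mu[2])^2) / n2))
    if (any(sigma < sd_floor)) {
      sigma <- pmax(sigma, sd_floor)
      floored <- TRUE
    }
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol * abs(loglik[it - 1])) break
  }
  ord <- order(mu)
  w <- w[ord]; mu <- mu[ord]; sigma <- sigma[ord]
  # Degenerate (unimodal) contract: when the fitted components are not
  # separated (Ashman D < 3, i.e. the mixture does not describe two distinct
  # DNA-content modes), EM has merely split a single mode in two, and a
  # "first peak +/- 2 SD" window around either half would clip the bulk of
  # the population.  Report two identical components at the sample moments
  # instead, so the G1 window covers the single mode.
  ashman_d <- abs(diff(mu)) / sqrt(mean(sigma^2))
  # model selection: does a single Gaussian describe the data at least as
  # well (BIC)?  Guards against a component latching onto a tail artefact.
  ll1 <- sum(dnorm(x, mean(x), max(population_sd(x), sd_floor), log = TRUE))
  ll2 <- sum(log(pmax(w[1] * dnorm(x, mu[1], sigma[1]) +
                        w[2] * dnorm(x, mu[2], sigma[2]),
                      .Machine$double.xmin)))
  bic_single <- -2 * ll1 + 2 * log(n)
  bic_mixture <- -2 * ll2 + 5 * log(n)
  # DNA replication doubles content: genuine 2N/4N modes sit near a 2x mean
  # ratio.  Components closer than 1.5x are a split of a single mode, not
  # two DNA-content classes.
  mean_ratio <- mu[2] / mu[1]
  collapsed <- (is.finite(ashman_d) && ashman_d < 3) ||
    bic_single <= bic_mixture || mean_ratio < 1.5
  if (collapsed) {
    mu <- rep(mean(x), 2)
    sigma <- rep(max(population_sd(x), sd_floor), 2)
    w <- c(0.5, 0.5)
  }
  structure(
    list(weight = w, mean = mu, sd = sigma,
         loglik = loglik, n = n, sd_floored = floored,
         collapsed = collapsed,
         converged = length(loglik) < max_iter),
    class = "hoechst_mixture"
  )
}

#' @export
print.hoechst_mixture <- function(x, ...) {
  cat("<hoechst_mixture> n =", x$n, "\n")
  for (k in 1:2) {
    cat(sprintf("  component %d: weight %.3f, mean %.4g, sd %.4g\n",
                k, x$weight[k], x$mean[k], x$sd[k]))
  }
  cat(sprintf("  log-likelihood %.4f after %d iteration(s)%s\n",
              utils::tail(x$loglik, 1), length(x$loglik),
              if (x$sd_floored) " [sd floored]" else ""))
  invisible(x)
}

#' @rdname fit_hoechst_mixture
#' @param x A `hoechst_mixture`.
#' @param ... Unused.
#' @export
tidy.hoechst_mixture <- function(x, ...) {
  tibble(component = 1:2, weight = x$weight, mean = x$mean, sd = x$sd)
}

#' @rdname fit_hoechst_mixture
#' @export
glance.hoechst_mixture <- function(x, ...) {
  tibble(n = x$n, loglik = utils::tail(x$loglik, 1),
         iterations = length(x$loglik), converged = x$converged,
         sd_floored = x$sd_floored, collapsed = x$collapsed)
}

#' Gate records to the G1/0 (first) Hoechst peak
#'
#' Keeps the records whose total Hoechst intensity lies within the closed
#' interval `[mean1 - 2 sd1, mean1 + 2 sd1]` around the lower-mean mixture
#' component.
#'
#' @param records Nucleus tibble (from [extract_features()]) with a
#'   `total_<hoechst_channel>` column.
#' @param fit A [fit_hoechst_mixture()] result.
#' @param hoechst_channel DNA channel label.
#' @return A list: `records` (retained rows), `window` (length-2 numeric).
#' @export
gate_g1 <- function(records, fit, hoechst_channel = "hoechst") {
  totals <- records[[paste0("total_", hoechst_channel)]]
  window <- c(fit$mean[1] - 2 * fit$sd[1], fit$mean[1] + 2 * fit$sd[1])
  keep <- totals >= window[1] & totals <= window[2]
  list(records = records[keep, ], window = window)
}

#' MAD quality windows on nuclear size and Hoechst texture
#'
#' Keeps records within the closed `median +/- 2 MAD` window for *both*
#' nuclear area and Hoechst intensity CV, with the unscaled MAD
#' `median(|x - median(x)|)` (no 1.4826 consistency factor).  Windows are
#' computed on the supplied (post-G1) population.  A zero MAD collapses the
#' window to the median: only records equal to the median survive, with a
#' warning.
#'
#' @param records Post-G1 nucleus tibble (>= 10 rows).
#' @param hoechst_channel DNA channel label (for the `cv_` column).
#' @param n_mad Half-width of the window in MAD units.
#' @return A list: `records` (retained), `area_window`, `cv_window`.
#' @export
mad_filter <- function(records, hoechst_channel = "hoechst", n_mad = 2) {
  if (nrow(records) < 10L) {
    abort("need at least 10 records to set MAD windows",
          class = "platetalk_insufficient_data")
  }
  windows <- lapply(list(area = records$area,
                         cv = records[[paste0("cv_", hoechst_channel)]]),
                    function(x) {
                      m <- median(x); d <- mad_raw(x)
                      if (d == 0) warn("zero MAD: window collapses to the median")
                      c(m - n_mad * d, m + n_mad * d)
                    })
  cv <- records[[paste0("cv_", hoechst_channel)]]
  keep <- records$area >= windows$area[1] & records$area <= windows$area[2] &
    !is.na(cv) & cv >= windows$cv[1] & cv <= windows$cv[2]
  list(records = records[keep, ],
       area_window = windows$area, cv_window = windows$cv)
}

#' Gate a whole plate
#'
#' Fits the Hoechst mixture and applies the G1/0 gate per well (staining
#' intensity is a per-well property; set `per_well = FALSE` to pool), then
#' applies the MAD quality windows computed on the plate-pooled post-G1
#' population: nuclear size and texture are morphological properties shared
#' across wells, and pooling keeps the window estimates stable.
#'
#' @param records Plate nucleus tibble from [quantify_plate()].
#' @param hoechst_channel DNA channel label.
#' @param per_well Fit the mixture per well (default) or once for the pooled
#'   plate.
#' @param qc_per_well Compute the MAD windows per well instead of per plate.
#' @param seed Seed forwarded to [fit_hoechst_mixture()].
#' @return A list with `records` (gated cells, `gate` column set to
#'   `"g1_qc"`) and `report`: one row per well with mixture parameters, gate
#'   windows and counts `n_input >= n_after_hoechst >= n_after_qc`.
#' @export
gate_cells <- function(records, hoechst_channel = "hoechst",
                       per_well = TRUE, qc_per_well = FALSE, seed = 1L) {
  groups <- if (per_well) split(records, records$well_id) else list(plate = records)
  fits <- if (per_well) NULL else
    fit_hoechst_mixture(records[[paste0("total_", hoechst_channel)]], seed)
  g1_out <- imap(groups, function(rec, key) {
    fit <- fits %||% fit_hoechst_mixture(
      rec[[paste0("total_", hoechst_channel)]], seed)
    g1 <- gate_g1(rec, fit, hoechst_channel)
    list(records = g1$records, fit = fit, window = g1$window,
         n_input = nrow(rec))
  })
  pooled_g1 <- bind_rows(map(g1_out, "records"))
  plate_qc <- if (qc_per_well) NULL else mad_filter(pooled_g1, hoechst_channel)
  out <- imap(g1_out, function(g1, key) {
    qc <- if (qc_per_well) mad_filter(g1$records, hoechst_channel) else plate_qc
    keep <- if (qc_per_well) qc$records else
      qc$records[qc$records$well_id %in% unique(g1$records$well_id), ]
    fit <- g1$fit
    report <- tibble(
      well_id = if (per_well) key else NA_character_,
      weight1 = fit$weight[1], mean1 = fit$mean[1], sd1 = fit$sd[1],
      weight2 = fit$weight[2], mean2 = fit$mean[2], sd2 = fit$sd[2],
      hoechst_lo = g1$window[1], hoechst_hi = g1$window[2],
      area_lo = qc$area_window[1], area_hi = qc$area_window[2],
      cv_lo = qc$cv_window[1], cv_hi = qc$cv_window[2],
      n_input = g1$n_input, n_after_hoechst = nrow(g1$records),
      n_after_qc = nrow(keep)
    )
    list(records = keep, report = report)
  })
  gated <- bind_rows(map(out, "records"))
  if (nrow(gated)) gated$gate <- "g1_qc"
  list(records = gated, report = bind_rows(map(out, "report")))
}
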