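# Population-level response statistics: per-replicate well medians of total
# nuclear TF intensity, control/canonical anchored normalization, min-max
# curve scaling, and Welch t-test crosstalk calls.

#' Median total nuclear intensity of one well
#'
#' @param records Gated nucleus tibble for a single well.
#' @param channel Readout channel label.
#' @return Median of per-cell total intensity; `NA` with a warning when the
#'   well has no gated cells (callers exclude such wells from replicates).
#' @export
summarize_well <- function(records, channel) {
  totals <- records[[paste0("total_", channel)]]
  if (is.null(totals)) {
    abort(sprintf("no 'total_%s' column in the records", channel),
          class = "platetalk_config_error")
  }
  if (!length(totals)) {
    warn("well has zero gated cells; median reported as NA")
    return(NA_real_)
  }
  median(totals)
}

#' Replicate-level well medians for every condition
#'
#' Joins gated cells to the plate layout and computes, for each
#' (condition, replicate, channel), the median total nuclear intensity over
#' that replicate's cells.  Wells with zero gated cells are dropped with a
#' warning.
#'
#' @param gated Gated nucleus tibble (from [gate_cells()]`$records`).
#' @param layout The [plate_layout()].
#' @param channels Readout channels; defaults to all non-Hoechst channels.
#' @return Tibble `condition`, `channel`, `replicate`, `well_median`.
#' @export
summarize_conditions <- function(gated, layout, channels = NULL) {
  channels <- channels %||% tf_channels(layout)
  wells <- layout$wells[layout$wells$role %in% c("sample", "control"),
                        c("well_id", "condition", "replicate")]
  joined <- left_join(gated, wells, by = "well_id")
  grps <- distinct(joined[, c("condition", "replicate")])
  out <- pmap(tidyr::expand_grid(grps, channel = channels),
              function(condition, replicate, channel) {
                rec <- joined[joined$condition == condition &
                                joined$replicate == replicate, ]
                tibble(condition = condition, channel = channel,
                       replicate = replicate,
                       well_median = summarize_well(rec, channel))
              })
  out <- bind_rows(out)
  out[!is.na(out$well_median), ] |>
    arrange(.data$channel, .data$condition, .data$replicate)
}

#' Anchor-normalise condition responses
#'
#' Rescales every replicate median so that, per channel, the across-replicate
#' mean of the control condition is exactly 0 and the mean of the canonical
#' ligand condition is exactly 1:
#' `y = (x - mean_control) / (mean_canonical - mean_control)`.
#' SDs scale by the same factor, so the normalised values are invariant to
#' any global affine transform `a * x + b` (a > 0) of the raw intensities.
#'
#' @param medians Replicate-median tibble from [summarize_conditions()].
#' @param control,canonical Condition labels of the anchors.  `canonical` may
#'   be a named character vector (channel to canonical condition) when
#'   different channels report different pathways.
#' @return The input with a `norm_median` column appended.
#' @export
normalize_conditions <- function(medians, control = "control",
                                 canonical = NULL) {
  if (is.null(canonical)) {
    abort("a canonical condition must be named", class = "platetalk_config_error")
  }
  split(medians, medians$channel) |>
    map(function(df) {
      ch <- df$channel[1]
      canon <- if (!is.null(names(canonical))) canonical[[ch]] else canonical
      m_ctrl <- mean(df$well_median[df$condition == control])
      m_can <- mean(df$well_median[df$condition == canon])
      if (!is.finite(m_ctrl) || !is.finite(m_can)) {
        abort(sprintf("channel '%s': control ('%s') or canonical ('%s') condition missing",
                      ch, control, canon),
              class = "platetalk_incomplete_design")
      }
      if (m_can == m_ctrl) {
        abort(sprintf("channel '%s': conditions '%s' and '%s' have equal means; scale is degenerate",
                      ch, control, canon),
              class = "platetalk_degenerate_scale")
      }
      mutate(df, norm_median = (.data$well_median - m_ctrl) / (m_can - m_ctrl))
    }) |>
    bind_rows()
}

#' Summarise normalised responses per condition
#'
#' @param normalized Output of [normalize_conditions()].
#' @return Tibble `condition`, `channel`, `n`, `mean_raw`, `sd_raw`,
#'   `norm_mean`, `norm_sd` (SD defined for n >= 2).
#' @export
condition_response <- function(normalized) {
  normalized |>
    group_by(.data$condition, .data$channel) |>
    summarise(n = dplyr::n(),
              mean_raw = mean(.data$well_median),
              sd_raw = if (dplyr::n() >= 2) sd(.data$well_median) else NA_real_,
              norm_mean = mean(.data$norm_median),
              norm_sd = if (dplyr::n() >= 2) sd(.data$norm_median) else NA_real_,
              .groups = "drop")
}

#' Min-max scale a response curve
#'
#' Rescales an ordered time-course or dose-response curve to span `[0, 1]`:
#' `(x - min) / (max - min)`.  Monotone curves stay monotone and the
#' operation is idempotent.
#'
#' @param curve Numeric vector (>= 2 points, not all equal).
#' @return The scaled curve.
#' @export
scale_minmax <- function(curve) {
  if (length(curve) < 2L) {
    abort("a curve needs at least two points", class = "platetalk_degenerate_scale")
  }
  rng <- range(curve)
  if (diff(rng) == 0) {
    abort("flat curve: min equals max, scale is degenerate",
          class = "platetalk_degenerate_scale")
  }
  (curve - rng[1]) / diff(rng)
}

#' Welch two-sample comparison of replicate medians
#'
#' Two-sided unequal-variance (Welch) t-test.  Degenerate inputs are handled
#' explicitly: two zero-variance groups give p = 1 when equal and p = 0
#' (with a warning) when different.
#'
#' @param a,b Numeric vectors of replicate medians (>= 2 each).
#' @return Tibble `estimate` (mean(a) - mean(b)), `t`, `df`, `p_value`.
#' @export
compare_conditions <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least two replicate values",
          class = "platetalk_insufficient_data")
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(estimate = 0, t = 0, df = NA_real_, p_value = 1))
    }
    warn("both groups have zero variance but differ; p reported as 0")
    return(tibble(estimate = mean(a) - mean(b),
                  t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                  p_value = 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Build the crosstalk call table
#'
#' For each readout channel, compares (by Welch t-test on replicate medians):
#' the canonical ligand against control (`canonical`, the anchor effect);
#' every other single ligand against control (`cross-activation`); every
#' combination condition against the canonical ligand alone
#' (`cross-modulation`); and every combination against control
#' (`combination-vs-control`, reported alongside since either contrast may be
#' of interest).  Combination conditions are labelled `"A+B"`.  No
#' multiplicity correction is applied by default (per-comparison alpha);
#' Holm correction is available via `adjust`.
#'
#' @param medians Replicate-median tibble from [summarize_conditions()].
#' @param design Tibble `channel`, `canonical` naming each readout's
#'   canonical ligand condition.
#' @param control Control condition label.
#' @param alpha Significance level per comparison.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method applied
#'   per channel.
#' @return Tibble of crosstalk calls: `channel`, `type`, `condition`,
#'   `reference`, `norm_effect` (difference of normalised means), `t`, `df`,
#'   `p_value`, `significant`.
#' @export
build_crosstalk_matrix <- function(medians, design, control = "control",
                                   alpha = 0.05, adjust = "none") {
  design <- as_tibble(design)
  stopifnot(all(c("channel", "canonical") %in% names(design)))
  canon_map <- setNames(design$canonical, design$channel)
  normalized <- normalize_conditions(medians, control, canon_map)
  calls <- map(seq_len(nrow(design)), function(i) {
    ch <- design$channel[i]; canon <- design$canonical[i]
    df <- normalized[normalized$channel == ch, ]
    conds <- unique(df$condition)
    needed <- c(control, canon)
    if (!all(needed %in% conds)) {
      abort(paste0("channel '", ch, "' is missing condition(s): ",
                   paste(setdiff(needed, conds), collapse = ", ")),
            class = "platetalk_incomplete_design")
    }
    singles <- setdiff(conds[!grepl("\\+", conds)], c(control, canon))
    combos <- conds[grepl("\\+", conds)]
    grab <- function(cond) df$norm_median[df$condition == cond]
    one <- function(cond, ref, type) {
      cmp <- compare_conditions(grab(cond), grab(ref))
      tibble(channel = ch, type = type, condition = cond, reference = ref,
             norm_effect = cmp$estimate, t = cmp$t, df = cmp$df,
             p_value = cmp$p_value)
    }
    bind_rows(
      one(canon, control, "canonical"),
      bind_rows(map(singles, one, ref = control, type = "cross-activation")),
      bind_rows(map(combos, one, ref = canon, type = "cross-modulation")),
      bind_rows(map(combos, one, ref = control, type = "combination-vs-control"))
    )
  }) |> bind_rows()
  calls |>
    group_by(.data$channel) |>
    mutate(p_value = stats::p.adjust(.data$p_value, method = adjust)) |>
    ungroup() |>
    mutate(significant = .data$p_value < alpha)
}

#' Format a plain-text crosstalk report
#'
#' @param calls Output of [build_crosstalk_matrix()].
#' @param alpha Significance level quoted in the header.
#' @return A character vector of report lines (invisibly written to `path`
#'   when given).
#' @param path Optional file to write the report to.
#' @export
format_crosstalk_report <- function(calls, alpha = 0.05, path = NULL) {
  lines <- c(
    sprintf("Crosstalk calls (two-sided Welch t-test, alpha = %.3g, '*' = significant)", alpha),
    "")
  for (ch in unique(calls$channel)) {
    lines <- c(lines, paste0("readout: ", ch))
    sub <- calls[calls$channel == ch, ]
    lines <- c(lines, sprintf(
      "  %-24s %-22s vs %-12s effect %+.3f  p %.4g %s",
      sub$type, sub$condition, sub$reference, sub$norm_effect,
      sub$p_value, ifelse(sub$significant, "*", "")))
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
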