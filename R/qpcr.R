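# qPCR arm: technical-replicate collapsing, reference-gene normalisation of
# threshold cycles (delta-Ct), relative expression by delta-delta-Ct with
# amplification efficiency fixed at 2 (100%), and Welch tests on the Ct
# (log) scale.

#' Collapse technical qPCR replicates
#'
#' Arithmetic mean of the technical-replicate Ct values on the cycle scale.
#' One missing value of three is tolerated (with a warning); fewer than two
#' finite values is an error.
#'
#' @param ct_values Numeric vector of technical-replicate Ct values (cycles);
#'   `NA` marks a failed well.
#' @return The mean Ct.
#' @export
collapse_technical <- function(ct_values) {
  finite <- ct_values[is.finite(ct_values)]
  if (!length(finite)) {
    abort("all technical replicates are missing",
          class = "platetalk_missing_measurement")
  }
  if (length(finite) < 2L) {
    abort("fewer than two finite technical replicates",
          class = "platetalk_missing_measurement")
  }
  if (length(finite) < length(ct_values)) {
    warn(sprintf("%d of %d technical replicates missing; mean taken over the rest",
                 length(ct_values) - length(finite), length(ct_values)))
  }
  mean(finite)
}

#' Relative expression by delta-delta-Ct
#'
#' With amplification efficiency fixed at 2 per cycle, the expression of a
#' sample relative to the control mean is
#' `2^-(dCt_sample - dCt_control_mean)`, where `dCt = Ct_target -
#' Ct_reference` is the reference-gene-normalised threshold cycle.
#'
#' @param dct_sample Sample delta-Ct (cycles).
#' @param dct_control_mean Mean control delta-Ct (cycles).
#' @return Fold change (dimensionless, > 0).
#' @export
relative_expression <- function(dct_sample, dct_control_mean) {
  stopifnot(is.finite(dct_sample), is.finite(dct_control_mean))
  2^-(dct_sample - dct_control_mean)
}

#' Test differential expression on the delta-Ct scale
#'
#' Two-sided Welch t-test of per-replicate delta-Ct values between a
#' condition and the control.  Testing on the Ct (log-expression) scale keeps
#' the Gaussian assumption defensible; fold changes are for display.
#'
#' @param dct_condition,dct_control Per-experimental-replicate delta-Ct
#'   values (>= 2 each).
#' @return Tibble `estimate` (delta-delta-Ct, condition minus control), `t`,
#'   `df`, `p_value`.
#' @export
test_expression <- function(dct_condition, dct_control) {
  compare_conditions(dct_condition, dct_control)
}

#' Analyse a qPCR threshold-cycle table
#'
#' Full qPCR arm: collapse technical replicates per (condition, replicate,
#' gene); form `dCt = Ct_target - Ct_reference` per sample; compute fold
#' change vs the control-mean dCt; and Welch-test each condition against
#' control on the dCt scale.
#'
#' @param ct_table Data frame with columns `condition`, `replicate`, `gene`,
#'   `technical_rep`, `ct`.
#' @param target_gene,reference_gene Gene labels; the reference is typically
#'   an abundant housekeeping transcript such as 18S rRNA.
#' @param control Control condition label.
#' @param alpha Significance level.
#' @return A list: `samples` (per condition x replicate: collapsed Cts, dCt,
#'   fold) and `tests` (per condition: mean fold, delta-delta-Ct, t, p,
#'   verdict).
#' @export
analyze_qpcr <- function(ct_table, target_gene, reference_gene = "18S",
                         control = "control", alpha = 0.05) {
  ct <- as_tibble(ct_table)
  needed <- c("condition", "replicate", "gene", "technical_rep", "ct")
  if (!all(needed %in% names(ct))) {
    abort(paste0("qPCR table needs columns: ", paste(needed, collapse = ", ")),
          class = "platetalk_config_error")
  }
  collapsed <- ct |>
    filter(.data$gene %in% c(target_gene, reference_gene)) |>
    group_by(.data$condition, .data$replicate, .data$gene) |>
    summarise(ct = collapse_technical(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  if (!all(c(target_gene, reference_gene) %in% names(collapsed))) {
    abort("target or reference gene absent from the table",
          class = "platetalk_missing_measurement")
  }
  samples <- collapsed |>
    mutate(dct = .data[[target_gene]] - .data[[reference_gene]])
  dct_ctrl <- samples$dct[samples$condition == control]
  if (length(dct_ctrl) < 2L) {
    abort("need at least two control replicates",
          class = "platetalk_insufficient_data")
  }
  samples <- samples |>
    mutate(fold = 2^-(.data$dct - mean(dct_ctrl)))
  tests <- samples |>
    filter(.data$condition != control) |>
    group_by(.data$condition) |>
    summarise(n = dplyr::n(),
              mean_fold = 2^-(mean(.data$dct) - mean(dct_ctrl)),
              ddct = mean(.data$dct) - mean(dct_ctrl),
              .groups = "drop")
  stats <- map(tests$condition, function(cond) {
    test_expression(samples$dct[samples$condition == cond], dct_ctrl)
  }) |> bind_rows()
  tests <- bind_cols(tests, stats[, c("t", "df", "p_value")]) |>
    mutate(significant = .data$p_value < alpha)
  list(samples = samples, tests = tests)
}

#' Simulate a qPCR threshold-cycle table
#'
#' Draws triplicate technical replicates around per-sample true Ct values for
#' a target and a reference gene.  The target's true Ct shifts by
#' `-log2(fold)` relative to control; a per-sample amplification offset,
#' shared by both genes, is added and should be removed by reference-gene
#' normalisation.
#'
#' @param fold_table Named numeric vector: condition to true fold change
#'   (control is implied at fold 1 and added automatically).
#' @param n_replicates Experimental replicates per condition.
#' @param ct_target,ct_reference Baseline true Cts (cycles).
#' @param sigma_dct Between-replicate SD of delta-Ct (cycles).
#' @param sigma_tech Within-triplicate technical SD (cycles).
#' @param sigma_sample SD of the shared per-sample amplification offset.
#' @param seed Integer seed.
#' @return A tibble in the [analyze_qpcr()] input schema with genes
#'   `"target"` and `"18S"`.
#' @export
simulate_ct_table <- function(fold_table, n_replicates = 3L,
                              ct_target = 24, ct_reference = 10,
                              sigma_dct = 0.2, sigma_tech = 0.1,
                              sigma_sample = 0.5, seed = 1L) {
  conds <- union("control", names(fold_table))
  folds <- setNames(rep(1, length(conds)), conds)
  folds[names(fold_table)] <- fold_table
  with_seed(seed, {
    rows <- tidyr::expand_grid(condition = conds,
                               replicate = seq_len(n_replicates))
    rows$offset <- rnorm(nrow(rows), 0, sigma_sample)
    rows$dct_noise <- rnorm(nrow(rows), 0, sigma_dct)
    out <- pmap(rows, function(condition, replicate, offset, dct_noise) {
      true_target <- ct_target - log2(folds[[condition]]) + offset + dct_noise
      true_ref <- ct_reference + offset
      bind_rows(
        tibble(condition = condition, replicate = replicate, gene = "target",
               technical_rep = 1:3,
               ct = rnorm(3, true_target, sigma_tech)),
        tibble(condition = condition, replicate = replicate, gene = "18S",
               technical_rep = 1:3,
               ct = rnorm(3, true_ref, sigma_tech))
      )
    })
    bind_rows(out)
  })
}
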