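#' Total brood size per animal
#'
#' Sums the three daily progeny counts per animal and drops censored animals
#' (those that crawled off the plate) from the analysis set.
#'
#' @param records Data frame `strain, animal, day1, day2, day3, censored`
#'   (as from [gen_brood()] or a CSV in the same layout).
#' @param drop_censored Exclude censored animals, default `TRUE`.
#' @return The uncensored records with a `total` column appended.
#' @export
total_brood <- function(records, drop_censored = TRUE) {
  need <- c("strain", "animal", "day1", "day2", "day3")
  stopifnot(all(need %in% names(records)))
  if (drop_censored && "censored" %in% names(records)) {
    records <- records[!records$censored, , drop = FALSE]
  }
  records$total <- records$day1 + records$day2 + records$day3
  records
}

#' Pairwise brood-size tests against a control strain
#'
#' Two-sample t test of each strain's total brood against the control, with
#' Bonferroni correction over the strains tested, ordered by increasing raw
#' p-value; a strain is significant when its corrected p is at most
#' `alpha`.
#'
#' @param records Data frame accepted by [total_brood()], or one already
#'   carrying a `total` column.
#' @param control Name of the control strain in `records`.
#' @param alpha Significance level on the corrected p, default 0.05.
#' @param var_equal Use the equal-variance (Student) t test (default); set
#'   `FALSE` for Welch.
#' @param n_comparisons Bonferroni multiplier; defaults to the number of
#'   strains tested.
#' @return Data frame `strain, n, mean_total, t, p, p_bonferroni,
#'   significant`, ordered by increasing `p`. Strains with fewer than two
#'   uncensored animals are skipped with a warning.
#' @export
brood_test <- function(records, control, alpha = 0.05, var_equal = TRUE,
                       n_comparisons = NULL) {
  if (!"total" %in% names(records)) records <- total_brood(records)
  stopifnot(control %in% records$strain)
  ctrl <- records$total[records$strain == control]
  if (length(ctrl) < 2) stop("control strain has fewer than 2 animals")
  strains <- setdiff(unique(records$strain), control)
  rows <- list()
  for (s in strains) {
    x <- records$total[records$strain == s]
    if (length(x) < 2) {
      warning("strain ", s, " has fewer than 2 uncensored animals; skipped")
      next
    }
    tt <- stats::t.test(x, ctrl, var.equal = var_equal)
    rows[[s]] <- data.frame(
      strain = s, n = length(x), mean_total = mean(x),
      t = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no strain with enough animals to test")
  out <- do.call(rbind, rows)
  k <- if (is.null(n_comparisons)) nrow(out) else n_comparisons
  out$p_bonferroni <- pmin(1, out$p * k)
  out$significant <- out$p_bonferroni <= alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-strain brood effect ratio relative to control
#'
#' Mean brood-size ratio of each strain to the control mean, with the 95%
#' confidence interval of the mean ratio over animals (t distribution).
#' Ratios below 1 indicate a brood reduction.
#'
#' @inheritParams brood_test
#' @param conf_level Confidence level, default 0.95.
#' @return Data frame `strain, effect, ci_low, ci_high, n` (one row per
#'   non-control strain).
#' @export
brood_effect_summary <- function(records, control, conf_level = 0.95) {
  if (!"total" %in% names(records)) records <- total_brood(records)
  ctrl_mean <- mean(records$total[records$strain == control])
  strains <- setdiff(unique(records$strain), control)
  rows <- lapply(strains, function(s) {
    ratios <- records$total[records$strain == s] / ctrl_mean
    ci <- if (length(ratios) >= 2 && stats::sd(ratios) > 0) {
      stats::t.test(ratios, conf.level = conf_level)$conf.int
    } else if (length(ratios) >= 2) {
      rep(mean(ratios), 2) # zero spread: degenerate interval
    } else {
      c(NA_real_, NA_real_)
    }
    data.frame(
      strain = s, effect = mean(ratios), ci_low = ci[1], ci_high = ci[2],
      n = length(ratios), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Compare knockout and knock-down effect summaries
#'
#' Pairs per-locus effect ratios from the mutant (genomic deletion) arm and
#' the RNAi (transcript knock-down) arm -- brood reduction or length ratio,
#' both relative to their own controls -- and classifies each locus by
#' whether each arm's 95% CI excludes the no-effect reference 1 and whether
#' the two arms' CIs overlap:
#' `no-effect` (neither excludes 1), `concordant` (overlapping CIs, at least
#' one arm with an effect), `mutant-stronger` / `rnai-stronger` (the named
#' arm's ratio is lower, i.e. farther below 1, with non-overlapping CIs, or
#' it alone shows an effect). Swapping the two arms reflects the
#' classification.
#'
#' @param mutant,rnai Data frames `strain, effect, ci_low, ci_high` from
#'   [brood_effect_summary()] or [length_ratio_at()] (the `ratio` column is
#'   accepted as `effect`); each locus must appear in both.
#' @return Data frame `strain, mutant_effect, rnai_effect, class`.
#' @export
effect_comparison <- function(mutant, rnai) {
  norm <- function(df) {
    if (!"effect" %in% names(df) && "ratio" %in% names(df)) {
      df$effect <- df$ratio
    }
    stopifnot(all(c("strain", "effect", "ci_low", "ci_high") %in% names(df)))
    df
  }
  mutant <- norm(mutant); rnai <- norm(rnai)
  common <- intersect(mutant$strain, rnai$strain)
  if (length(common) == 0) stop("no locus present in both arms")
  mi <- match(common, mutant$strain)
  ri <- match(common, rnai$strain)
  excl1 <- function(df, i) df$ci_high[i] < 1 | df$ci_low[i] > 1
  m_eff <- excl1(mutant, mi)
  r_eff <- excl1(rnai, ri)
  overlap <- mutant$ci_low[mi] <= rnai$ci_high[ri] &
    rnai$ci_low[ri] <= mutant$ci_high[mi]
  cls <- character(length(common))
  for (k in seq_along(common)) {
    cls[k] <- if (!m_eff[k] && !r_eff[k]) {
      "no-effect"
    } else if (overlap[k]) {
      "concordant"
    } else if (m_eff[k] && !r_eff[k]) {
      "mutant-stronger"
    } else if (r_eff[k] && !m_eff[k]) {
      "rnai-stronger"
    } else if (mutant$effect[mi[k]] < rnai$effect[ri[k]]) {
      "mutant-stronger"
    } else {
      "rnai-stronger"
    }
  }
  data.frame(
    strain = common,
    mutant_effect = mutant$effect[mi],
    rnai_effect = rnai$effect[ri],
    class = cls,
    stringsAsFactors = FALSE
  )
}

#' Delta-Ct relative expression
#'
#' Relative qRT-PCR quantification against a reference gene: per-replicate
#' `dCt = Ct_target - Ct_reference` (replicates paired by index), the
#' condition-vs-control `ddCt`, and the fold change `2^-ddCt`, with t-based
#' confidence intervals on the replicate dCt values and a two-sample t test
#' of condition against control dCt.
#'
#' @param ct_target,ct_reference Ct replicates of the target and reference
#'   gene in the condition of interest (>= 2 replicates).
#' @param ct_target_control,ct_reference_control The same in the control
#'   condition; omit both for a plain dCt summary (fold is then `2^-dCt`).
#' @param conf_level Confidence level, default 0.95.
#' @param paired Pair replicates by index (default); otherwise means are
#'   taken first and the CI uses the pooled replicate spread.
#' @return A list with `delta_ct`, `delta_ct_ci`, `delta_delta_ct`, `fold`,
#'   `fold_ci`, and (when a control is given) `p` from the t test.
#' @export
delta_ct <- function(ct_target, ct_reference,
                     ct_target_control = NULL, ct_reference_control = NULL,
                     conf_level = 0.95, paired = TRUE) {
  stopifnot(length(ct_target) >= 2, length(ct_reference) >= 2)
  dct_reps <- if (paired && length(ct_target) == length(ct_reference)) {
    ct_target - ct_reference
  } else {
    ct_target - mean(ct_reference)
  }
  dct <- mean(dct_reps)
  ci <- if (stats::sd(dct_reps) > 0) {
    stats::t.test(dct_reps, conf.level = conf_level)$conf.int
  } else {
    rep(dct, 2) # zero spread: degenerate interval
  }

  if (is.null(ct_target_control)) {
    return(list(
      delta_ct = dct, delta_ct_ci = as.numeric(ci),
      delta_delta_ct = NA_real_,
      fold = 2^-dct, fold_ci = 2^-rev(as.numeric(ci))
    ))
  }
  stopifnot(!is.null(ct_reference_control))
  dct_ctrl_reps <- if (paired &&
    length(ct_target_control) == length(ct_reference_control)) {
    ct_target_control - ct_reference_control
  } else {
    ct_target_control - mean(ct_reference_control)
  }
  ddct <- dct - mean(dct_ctrl_reps)
  tt <- stats::t.test(dct_reps, dct_ctrl_reps, conf.level = conf_level)
  ci_dd <- as.numeric(tt$conf.int)
  list(
    delta_ct = dct, delta_ct_ci = as.numeric(ci),
    delta_delta_ct = ddct,
    fold = 2^-ddct, fold_ci = 2^-rev(ci_dd),
    p = tt$p.value
  )
}
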