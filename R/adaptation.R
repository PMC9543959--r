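#' Correlation between perturbation and per-module predicted performance
#'
#' Pearson correlation, per task-relevant module, between the applied
#' feedback perturbation and the module's predicted-performance fragment
#' over the selected trials. A negative correlation indicates that the
#' module's recruitment compensates for the perturbation, the signature of
#' motor adaptation.
#'
#' @param fragments A `module_fragments` object or a K x R matrix.
#' @param perturbation Per-trial perturbation series, length K.
#' @param trial_subset Indices of the trials entering the correlation
#'   (default: all).
#' @return A tibble with columns `module` and `rho`.
#' @export
perturbation_correlation <- function(fragments, perturbation,
                                     trial_subset = NULL) {
  yhat <- if (inherits(fragments, "module_fragments")) fragments$yhat else as.matrix(fragments)
  if (length(perturbation) != nrow(yhat)) {
    abort("`perturbation` must have one value per trial")
  }
  idx <- trial_subset %||% seq_len(nrow(yhat))
  if (length(idx) < 3) abort("need at least 3 trials for a correlation")
  p <- perturbation[idx]
  if (sd(p) == 0) abort("perturbation is constant on the selected trials; correlation undefined")
  rho <- apply(yhat[idx, , drop = FALSE], 2, function(y) {
    if (sd(y) == 0) abort("a fragment series is constant; correlation undefined")
    cor(y, p)
  })
  tibble::tibble(module = seq_len(ncol(yhat)), rho = as.numeric(rho))
}

#' Group-level test of perturbation-fragment correlations
#'
#' Two-sided one-sample t-test, per module, of the across-subject
#' correlation values against zero, with a multiplicity correction across
#' the modules tested (Bonferroni by default).
#'
#' @param rho Tibble with columns `subject`, `module`, `rho` (one row per
#'   subject per module), or a subjects x modules matrix.
#' @param correction `"bonferroni"` (default), `"holm"`, or `"none"`.
#' @return A tibble with columns `module`, `n_subjects`, `mean_rho`,
#'   `t`, `df`, `p_raw`, `p_corrected`, `correction`.
#' @export
group_correlation_test <- function(rho, correction = c("bonferroni", "holm", "none")) {
  correction <- match.arg(correction)
  if (is.matrix(rho)) {
    rho <- tibble::tibble(
      subject = rep(seq_len(nrow(rho)), times = ncol(rho)),
      module = rep(seq_len(ncol(rho)), each = nrow(rho)),
      rho = as.numeric(rho)
    )
  }
  res <- rho |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_rho = mean(.data$rho),
      t = {
        if (dplyr::n() < 2) abort("need at least 2 subjects")
        if (sd(.data$rho) == 0) {
          abort("all subjects have identical correlation; t-test undefined")
        }
        unname(t.test(.data$rho)$statistic)
      },
      df = dplyr::n() - 1L,
      p_raw = t.test(.data$rho)$p.value,
      .groups = "drop"
    )
  res$p_corrected <- p.adjust(res$p_raw, method = correction)
  res$correction <- correction
  res
}

#' Average a temporal module within contiguous phases
#'
#' Splits the J frames into `n_phases` contiguous blocks (earlier blocks
#' one frame larger when J is not divisible) and averages the module value
#' within each block, the feature used for across-experiment comparisons
#' of temporal modules.
#'
#' @param t_module Length-J numeric temporal module.
#' @param n_phases Number of phases (default 3).
#' @return A tibble with columns `phase`, `n_frames`, `mean`.
#' @export
phase_average <- function(t_module, n_phases = 3) {
  J <- length(t_module)
  if (n_phases > J) abort("`n_phases` exceeds the number of frames")
  base <- J %/% n_phases
  extra <- J %% n_phases
  sizes <- rep(base, n_phases) + c(rep(1L, extra), rep(0L, n_phases - extra))
  assignment <- rep(seq_len(n_phases), times = sizes)
  means <- as.numeric(tapply(t_module, assignment, mean))
  tibble::tibble(phase = seq_len(n_phases), n_frames = sizes, mean = means)
}

#' Compare module features across experiments
#'
#' For each module feature (a spatial-module joint weight or a
#' phase-averaged temporal value), runs a one-way ANOVA of the per-subject
#' values across experiments followed by Tukey's HSD on all experiment
#' pairs.
#'
#' @param features Tibble with columns `subject`, `experiment`, `feature`,
#'   `value`: one row per subject per experiment per feature.
#' @return An object of class `module_comparison`: list with `anova` (a
#'   tibble of `feature`, `F`, `p`) and `tukey` (a tibble of `feature`,
#'   `contrast`, `diff`, `p_adj`).
#' @export
compare_across_experiments <- function(features) {
  need <- c("subject", "experiment", "feature", "value")
  if (!all(need %in% names(features))) {
    abort(paste("`features` needs columns:", paste(need, collapse = ", ")))
  }
  if (length(unique(features$experiment)) < 2) {
    abort("need at least 2 experiments")
  }
  counts <- features |>
    dplyr::count(.data$feature, .data$experiment)
  if (any(counts$n < 2)) abort("need at least 2 subjects per experiment")
  per_feature <- features |>
    dplyr::group_split(.data$feature)
  anova_rows <- list()
  tukey_rows <- list()
  for (df in per_feature) {
    df$experiment <- factor(df$experiment)
    fit <- aov(value ~ experiment, data = df)
    an <- summary(fit)[[1L]]
    anova_rows[[length(anova_rows) + 1L]] <- tibble::tibble(
      feature = df$feature[1L],
      F = an[["F value"]][1L],
      p = an[["Pr(>F)"]][1L]
    )
    tk <- TukeyHSD(fit)$experiment
    tukey_rows[[length(tukey_rows) + 1L]] <- tibble::tibble(
      feature = df$feature[1L],
      contrast = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"]
    )
  }
  structure(
    list(anova = dplyr::bind_rows(anova_rows),
         tukey = dplyr::bind_rows(tukey_rows)),
    class = "module_comparison"
  )
}

#' @export
print.module_comparison <- function(x, ...) {
  cat("<module_comparison>\n")
  print(x$anova)
  invisible(x)
}

#' @export
tidy.module_comparison <- function(x, ...) x$tukey

#' @export
glance.module_comparison <- function(x, ...) x$anova
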