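# End-to-end analysis of a cohort: exclusion -> response labelling ->
# accuracy -> mixture fits -> bias curves -> trade-off correlations ->
# classical + Bayes-factor inference, bundled into tidy tables.

cell_split <- function(errs) {
  split(errs, list(errs$subject_id, errs$role, errs$response_index),
        drop = TRUE, sep = "|")
}

#' Per-cell recall accuracy table
#'
#' Recall accuracy (inverse circular SD of the signed errors) for every
#' subject x cue-role x response-index cell of a long error table from
#' [response_errors()].
#'
#' @param errs Output of [response_errors()].
#' @return Data frame: `subject_id`, `role`, `response_index`, `n`,
#'   `accuracy` (1/radian).
#' @export
accuracy_table <- function(errs) {
  out <- do.call(rbind, lapply(cell_split(errs), function(d)
    data.frame(subject_id = d$subject_id[1], role = d$role[1],
               response_index = d$response_index[1],
               n = nrow(d), accuracy = recall_accuracy(d$error))))
  rownames(out) <- NULL
  out[order(out$subject_id, out$role, out$response_index), ]
}

#' Per-cell mixture-model fits
#'
#' Fits the von Mises + uniform mixture to every subject x role x response
#' cell.
#'
#' @param errs Output of [response_errors()].
#' @param min_n Minimum errors per cell (default 20).
#' @return Data frame with `p_mem`, `kappa`, `loglik`, `converged` per cell.
#' @export
mixture_table <- function(errs, min_n = 20) {
  out <- do.call(rbind, lapply(cell_split(errs), function(d) {
    fit <- fit_mixture(d$error, min_n = min_n)
    data.frame(subject_id = d$subject_id[1], role = d$role[1],
               response_index = d$response_index[1], n = fit$n,
               p_mem = fit$p_mem, kappa = fit$kappa, loglik = fit$loglik,
               converged = fit$converged)
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$role, out$response_index), ]
}

#' Per-cell bias curves and area-difference statistics
#'
#' Sliding-bin bias curves and their area differences for every subject x
#' role x response cell.
#'
#' @param errs Output of [response_errors()].
#' @param n_bins,frac Binning parameters (see [sliding_bin_bias()]).
#' @return List with `stats` (one row per cell: `area_diff`, `direction`)
#'   and `curves` (one row per cell x bin, degrees).
#' @export
bias_tables <- function(errs, n_bins = 64, frac = 1/4) {
  cells <- cell_split(errs)
  curves <- lapply(cells, function(d)
    sliding_bin_bias(d$delta, d$error, n_bins = n_bins, frac = frac))
  stats_tab <- do.call(rbind, Map(function(d, cv) {
    ad <- area_difference(cv)
    data.frame(subject_id = d$subject_id[1], role = d$role[1],
               response_index = d$response_index[1],
               n = cv$n_trials, occupancy = cv$occupancy,
               area_diff = ad$area_diff, direction = ad$direction)
  }, cells, curves))
  curves_tab <- do.call(rbind, Map(function(d, cv)
    data.frame(subject_id = d$subject_id[1], role = d$role[1],
               response_index = d$response_index[1],
               center_deg = rad2deg(cv$centers),
               mean_bias_deg = rad2deg(cv$mean_bias),
               occupancy = cv$occupancy),
    cells, curves))
  rownames(stats_tab) <- rownames(curves_tab) <- NULL
  list(stats = stats_tab[order(stats_tab$subject_id, stats_tab$role,
                               stats_tab$response_index), ],
       curves = curves_tab)
}

#' Per-subject trade-off correlations by condition
#'
#' Pearson correlation between the absolute errors of the two responses,
#' per subject and condition, with Fisher z.
#'
#' @param trials A `trial_cohort`.
#' @return Data frame: `subject_id`, `condition`, `n_trials`, `r`, `z`.
#' @export
tradeoff_table <- function(trials) {
  trials <- as.data.frame(trials)
  cells <- split(trials, list(trials$subject_id, trials$condition),
                 drop = TRUE, sep = "|")
  out <- do.call(rbind, lapply(cells, function(d) {
    items <- as.matrix(d[c("item1_deg", "item2_deg", "item3_deg",
                           "item4_deg")])
    i <- seq_len(nrow(d))
    e1 <- signed_error(deg2rad(d$response1_deg),
                       deg2rad(items[cbind(i, d$probe1_item)]))
    e2 <- signed_error(deg2rad(d$response2_deg),
                       deg2rad(items[cbind(i, d$probe2_item)]))
    tr <- trialwise_error_correlation(e1, e2, condition = d$condition[1])
    data.frame(subject_id = d$subject_id[1], condition = tr$condition,
               n_trials = tr$n_trials, r = tr$r, z = tr$z)
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$condition), ]
}

accuracy_inference <- function(acc) {
  res <- list()
  res$omnibus <- rm_anova(acc, dv = "accuracy", subject = "subject_id",
                          factors = c("role", "response_index"))
  res$omnibus$effect <- paste0("omnibus_cue_x_response: ",
                               res$omnibus$effect)
  for (pairing in list(c("cued", "neutral"), c("uncued", "neutral"))) {
    sub <- acc[acc$role %in% pairing, ]
    av <- rm_anova(sub, dv = "accuracy", subject = "subject_id",
                   factors = c("role", "response_index"))
    av$effect <- paste0(pairing[1], "_vs_neutral_2x2: ", av$effect)
    res[[paste0(pairing[1], "_vs_neutral")]] <- av
  }
  wide <- function(role, idx)
    acc$accuracy[acc$role == role & acc$response_index == idx][
      order(acc$subject_id[acc$role == role & acc$response_index == idx])]
  tt <- NULL
  for (idx in 1:2) {
    tt <- rbind(tt,
      paired_t(wide("cued", idx), wide("neutral", idx),
               effect = sprintf("benefit_cued_vs_neutral_resp%d", idx)),
      paired_t(wide("uncued", idx), wide("neutral", idx),
               effect = sprintf("cost_uncued_vs_neutral_resp%d", idx)))
  }
  res$paired <- tt
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("inference_result", "data.frame")
  out
}

analyze_core <- function(trials, mixture_min_n = 20, n_bins = 64,
                         frac = 1/4) {
  errs <- response_errors(trials)
  acc <- accuracy_table(errs)
  mix <- mixture_table(errs, min_n = mixture_min_n)
  bias <- bias_tables(errs, n_bins = n_bins, frac = frac)
  tro <- tradeoff_table(trials)

  inf <- list(accuracy = accuracy_inference(acc))

  # bias: one-sample t per (role, response) cell + cue-effect ANOVA per
  # response index
  bias_inf <- NULL
  for (idx in 1:2) {
    b <- bias$stats[bias$stats$response_index == idx, ]
    for (role in unique(b$role)) {
      row <- bias_group_test(b$area_diff[b$role == role])
      row$effect <- sprintf("bias_%s_resp%d", role, idx)
      bias_inf <- rbind(bias_inf, row)
    }
    av <- rm_anova(b, dv = "area_diff", subject = "subject_id",
                   factors = "role")
    av$effect <- sprintf("bias_cue_effect_resp%d", idx)
    bias_inf <- rbind(bias_inf, av)
  }
  class(bias_inf) <- c("inference_result", "data.frame")
  inf$bias <- bias_inf

  tg <- tradeoff_group_test(tro)
  tro_inf <- rbind(tg$per_condition,
                   within(tg$anova,
                          effect <- paste0("tradeoff_cue_effect: ", effect)))
  class(tro_inf) <- c("inference_result", "data.frame")
  inf$tradeoff <- tro_inf

  list(accuracy = acc, mixture = mix, bias_stats = bias$stats,
       bias_curves = bias$curves, tradeoff = tro, inference = inf)
}

#' Analyse a full experiment
#'
#' Runs the complete pipeline on a cohort of trial data: participant
#' exclusion (Rayleigh criterion), response labelling by cue role, recall
#' accuracy (inverse circular SD) per subject x role x response, mixture
#' fits per cell, sliding-bin bias curves and area-difference statistics,
#' trial-wise trade-off correlations, and the inference families: the
#' omnibus cue x response ANOVA, cued-vs-neutral and uncued-vs-neutral 2x2
#' ANOVAs, per-response paired t tests with JZS Bayes factors, one-sample
#' bias tests, and the trade-off correlation tests. No multiplicity
#' correction is applied. Deterministic given the input data.
#'
#' When the cohort mixes order-cued and order-uncued sessions (the E3
#' design) the pipeline is run once per session type and a combined
#' order-cue x response x cue-role ANOVA on accuracy is added.
#'
#' @param trials A `trial_cohort`.
#' @param exclusion_alpha Rayleigh-test level for exclusion (default 0.01).
#' @param mixture_min_n Minimum errors per cell for a mixture fit.
#' @param n_bins,frac Bias-curve binning parameters.
#' @return Object of class `retro_results`: list with `exclusion`, and
#'   either the core tables (`accuracy`, `mixture`, `bias_stats`,
#'   `bias_curves`, `tradeoff`, `inference`) or, for mixed-order cohorts,
#'   `sessions` (one core bundle per session type) plus `order_anova`.
#' @export
analyze_experiment <- function(trials, exclusion_alpha = 0.01,
                               mixture_min_n = 20, n_bins = 64, frac = 1/4) {
  excl <- exclude_participants(trials, alpha = exclusion_alpha)
  kept <- excl$retained
  if (nrow(kept) == 0) stop("analyze_experiment: no subjects retained")
  d <- as.data.frame(kept)
  out <- list(exclusion = excl$report)
  if (length(unique(d$order_cued)) > 1) {
    labels <- c(`FALSE` = "order_uncued", `TRUE` = "order_cued")
    out$sessions <- lapply(split(d, labels[as.character(d$order_cued)]),
      function(sub) {
        class(sub) <- c("trial_cohort", "data.frame")
        analyze_core(sub, mixture_min_n, n_bins, frac)
      })
    errs <- response_errors(kept)
    errs$order_cue <- ifelse(errs$order_cued, "cued", "uncued")
    acc3 <- do.call(rbind, lapply(
      split(errs, errs$order_cue), function(e) {
        a <- accuracy_table(e)
        a$order_cue <- e$order_cue[1]
        a
      }))
    out$order_anova <- rm_anova(acc3, dv = "accuracy",
                                subject = "subject_id",
                                factors = c("order_cue", "response_index",
                                            "role"))
  } else {
    out <- c(out, analyze_core(kept, mixture_min_n, n_bins, frac))
  }
  class(out) <- "retro_results"
  out
}

#' @export
print.retro_results <- function(x, ...) {
  cat("Retrocue analysis results\n")
  cat(sprintf("  subjects retained: %d of %d\n",
              sum(!x$exclusion$excluded), nrow(x$exclusion)))
  fams <- if (!is.null(x$sessions)) {
    cat(sprintf("  session types: %s (+ combined order-cue ANOVA)\n",
                paste(names(x$sessions), collapse = ", ")))
    x$sessions[[1]]$inference
  } else x$inference
  cat(sprintf("  inference families: %s\n",
              paste(names(fams), collapse = ", ")))
  invisible(x)
}

write_core <- function(core, dir, prefix = "") {
  w <- function(d, name)
    utils::write.csv(d, file.path(dir, paste0(prefix, name, ".csv")),
                     row.names = FALSE, quote = FALSE)
  w(core$accuracy, "accuracy")
  w(core$mixture, "mixture")
  w(core$bias_stats, "bias_stats")
  w(core$bias_curves, "bias_curves")
  w(core$tradeoff, "tradeoff")
  inf <- do.call(rbind, Map(function(d, fam) {
    d$family <- fam
    d
  }, core$inference, names(core$inference)))
  w(inf[c("family", setdiff(names(inf), "family"))], "inference")
}

#' Write a results bundle to a directory of tidy CSVs
#'
#' @param results A `retro_results` bundle.
#' @param dir Output directory (created if absent).
#' @param manifest Optional named list (seed, config path, ...) recorded in
#'   `run_manifest.txt` alongside the package version.
#' @return Invisibly, `dir`.
#' @export
write_results <- function(results, dir, manifest = list()) {
  stopifnot(inherits(results, "retro_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$exclusion, file.path(dir, "exclusion.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(results$sessions)) {
    for (nm in names(results$sessions))
      write_core(results$sessions[[nm]], dir, prefix = paste0(nm, "_"))
    utils::write.csv(results$order_anova,
                     file.path(dir, "order_cue_anova.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    write_core(results, dir)
  }
  manifest <- c(list(package = "retrocue",
                     version = as.character(
                       utils::packageVersion("retrocue"))),
                manifest)
  writeLines(paste(names(manifest), vapply(manifest, format, ""),
                   sep = ": "),
             file.path(dir, "run_manifest.txt"))
  invisible(dir)
}
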