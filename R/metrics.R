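#' Genetic gain between consecutive cycles
#'
#' Gain in genetic standard-deviation units:
#' (mean_j - mean_i) / sigma_cycle1, where sigma_cycle1 is the GEBV standard
#' deviation among the initial crossing parents, held fixed across cycles so
#' gains are comparable across cycles and traits.
#'
#' @param mean_i,mean_j mean parental GEBVs at cycles i and j = i + 1.
#' @param sigma_cycle1 GEBV SD among the initial crossing parents (> 0).
#' @return scalar gain.
#' @export
genetic_gain <- function(mean_i, mean_j, sigma_cycle1) {
  if (any(sigma_cycle1 <= 0)) stop("sigma_cycle1 must be positive")
  (mean_j - mean_i) / sigma_cycle1
}

#' Per-replicate genetic gains for each cycle transition
#'
#' Expands a simulation result into one row per (replicate, trait,
#' transition), with the gain computed by [genetic_gain()] against that
#' replicate's initial-parent GEBV standard deviation.
#'
#' @param result a `sim_result`.
#' @return data.frame with columns `replicate`, `trait`, `transition`,
#'   `gain`.
#' @export
cycle_gains <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  rec <- result$records
  out <- list()
  for (r in unique(rec$replicate)) {
    rr <- rec[rec$replicate == r, ]
    rr <- rr[order(rr$cycle), ]
    for (trait in c("GY", "OL")) {
      mu <- rr[[paste0("mean_gebv_", trait)]]
      sigma1 <- rr[[paste0("sd_gebv_", trait)]][rr$cycle == 0]
      k <- seq_len(nrow(rr) - 1)
      out[[length(out) + 1]] <- data.frame(
        replicate = r, trait = trait, transition = paste0("c", k),
        gain = genetic_gain(mu[k], mu[k + 1], sigma1))
    }
  }
  do.call(rbind, out)
}

#' Gain table in the strategy-comparison layout
#'
#' Rows indexed by (trait, transition c1..cK) plus a `Sum` row per trait;
#' one column per strategy. The transition labeled `ck` is the gain from the
#' parents of cycle k-1 (cycle 0 = initial random parents) to the parents
#' of cycle k. Given simulation results, per-replicate gains are averaged
#' over replicates (averaging happens on gains, so the per-replicate
#' sigma-normalization is preserved). Given a data.frame of per-cycle gain
#' values (columns `trait`, `transition`, one per strategy), the Sum rows
#' are appended as-is.
#'
#' @param results named list of `sim_result` objects (one per strategy), or
#'   a per-cycle gain data.frame as described above.
#' @return data.frame with columns `trait`, `transition` and one column per
#'   strategy; `Sum` rows hold the column sums of the per-cycle rows.
#' @export
gain_table <- function(results) {
  if (is.data.frame(results)) {
    per_cycle <- results
  } else {
    stopifnot(is.list(results), length(results) >= 1)
    cols <- lapply(names(results), function(s) {
      g <- cycle_gains(results[[s]])
      ag <- stats::aggregate(gain ~ trait + transition, g, mean)
      names(ag)[3] <- s
      ag
    })
    per_cycle <- Reduce(function(a, b) merge(a, b, by = c("trait", "transition")),
                        cols)
    ord <- order(per_cycle$trait,
                 as.integer(sub("^c", "", per_cycle$transition)))
    per_cycle <- per_cycle[ord, ]
  }
  strat_cols <- setdiff(names(per_cycle), c("trait", "transition"))
  sums <- do.call(rbind, lapply(unique(per_cycle$trait), function(tr) {
    block <- per_cycle[per_cycle$trait == tr, strat_cols, drop = FALSE]
    cbind(data.frame(trait = tr, transition = "Sum"),
          as.data.frame(as.list(colSums(block))))
  }))
  names(sums) <- names(per_cycle)
  out <- do.call(rbind, lapply(unique(per_cycle$trait), function(tr) {
    rbind(per_cycle[per_cycle$trait == tr, ],
          sums[sums$trait == tr, ])
  }))
  rownames(out) <- NULL
  out
}

#' Expected gain under reciprocal recurrent selection
#'
#' The expected per-trait gain when the progenies of two independently
#' improved single-trait streams are intercrossed: the arithmetic mean of
#' the two streams' cumulative gains for that trait.
#'
#' @param sum_trait_under_A cumulative gain for the trait in stream A.
#' @param sum_trait_under_B cumulative gain for the trait in stream B.
#' @return `(sum_trait_under_A + sum_trait_under_B) / 2`.
#' @export
reciprocal_recurrent_expectation <- function(sum_trait_under_A,
                                             sum_trait_under_B) {
  (sum_trait_under_A + sum_trait_under_B) / 2
}

#' Inbreeding trajectory per strategy
#'
#' Replicate-averaged inbreeding coefficient per cycle, with the rate of
#' inbreeding between consecutive cycles.
#'
#' @param results named list of `sim_result` objects, or a single one.
#' @return data.frame with columns `strategy`, `cycle`, `F_mean`,
#'   `delta_F` (NA at cycle 0).
#' @export
inbreeding_trajectory <- function(results) {
  if (inherits(results, "sim_result")) results <- list(results)
  if (is.null(names(results)))
    names(results) <- vapply(results, `[[`, "", "strategy")
  out <- do.call(rbind, lapply(names(results), function(s) {
    rec <- results[[s]]$records
    ag <- stats::aggregate(F ~ cycle, rec, mean)
    ag <- ag[order(ag$cycle), ]
    data.frame(strategy = s, cycle = ag$cycle, F_mean = ag$F,
               delta_F = c(NA, delta_F(ag$F[-nrow(ag)], ag$F[-1])))
  }))
  rownames(out) <- NULL
  out
}

#' Reference per-cycle gains for the full-scale safflower program
#'
#' Per-cycle genetic gains (genetic-SD units) reported for the full-scale
#' study conditions - the 349-accession safflower panel with 6911 SNPs, 50
#' replicates - for the four strategies. Used to validate the gain-table
#' aggregation and the reciprocal-recurrent comparison arithmetic against
#' the published full-scale values.
#'
#' @return data.frame with columns `trait`, `transition`, `GS_GY`, `GS_OL`,
#'   `GS_GY_OL`, `GS_GY_OL_Rel`.
#' @export
reference_gains <- function() {
  data.frame(
    trait = rep(c("GY", "OL"), each = 4),
    transition = rep(paste0("c", 1:4), 2),
    GS_GY = c(1.609, 0.454, 0.308, 0.238, 0.204, -0.125, -0.029, -0.025),
    GS_OL = c(0.499, 0.013, 0.010, -0.003, 1.939, 0.365, 0.254, 0.219),
    GS_GY_OL = c(1.175, 0.256, 0.206, 0.145, 1.632, 0.305, 0.166, 0.140),
    GS_GY_OL_Rel = c(0.995, 0.373, 0.233, 0.188, 1.112, 0.618, 0.279, 0.163))
}

#' Write strategy-comparison figures and their underlying tables
#'
#' Writes a mean +/- SD GEBV-by-cycle figure per trait and an F-by-cycle
#' figure, plus CSV files of the plotted values (so figure data round-trip
#' losslessly).
#'
#' @param results named list of `sim_result` objects.
#' @param out_dir output directory (created if missing).
#' @param format image format, `"png"` or `"svg"`.
#' @return invisible character vector of the files written.
#' @export
plot_results <- function(results, out_dir, format = c("png", "svg")) {
  format <- match.arg(format)
  if (!length(results)) {
    warning("no strategies to plot; nothing written")
    return(invisible(character(0)))
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory")
  }
  if (is.null(names(results)))
    names(results) <- vapply(results, `[[`, "", "strategy")
  traj <- do.call(rbind, lapply(names(results), function(s) {
    rec <- results[[s]]$records
    do.call(rbind, lapply(c("GY", "OL"), function(tr) {
      ag <- stats::aggregate(rec[[paste0("mean_gebv_", tr)]],
                             list(cycle = rec$cycle), mean)
      sdv <- stats::aggregate(rec[[paste0("sd_gebv_", tr)]],
                              list(cycle = rec$cycle), mean)
      data.frame(strategy = s, trait = tr, cycle = ag$cycle,
                 mean_gebv = ag$x, sd_gebv = sdv$x)
    }))
  }))
  inb <- inbreeding_trajectory(results)
  files <- character(0)
  gebv_csv <- file.path(out_dir, "gebv_trajectories.csv")
  write.csv(traj, gebv_csv, row.names = FALSE)
  inb_csv <- file.path(out_dir, "inbreeding.csv")
  write.csv(inb, inb_csv, row.names = FALSE)
  p1 <- ggplot2::ggplot(traj, ggplot2::aes(.data$cycle, .data$mean_gebv,
                                           colour = .data$strategy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_gebv - .data$sd_gebv,
                                      ymax = .data$mean_gebv + .data$sd_gebv,
                                      fill = .data$strategy),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "Cycle", y = "Mean parental GEBV (+/- SD)") +
    ggplot2::theme_minimal()
  f1 <- file.path(out_dir, paste0("gebv_trajectories.", format))
  ggplot2::ggsave(f1, p1, width = 8, height = 4, dpi = 150)
  p2 <- ggplot2::ggplot(inb, ggplot2::aes(.data$cycle, .data$F_mean,
                                          colour = .data$strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Cycle", y = "Inbreeding coefficient F") +
    ggplot2::theme_minimal()
  f2 <- file.path(out_dir, paste0("inbreeding.", format))
  ggplot2::ggsave(f2, p2, width = 6, height = 4, dpi = 150)
  files <- c(gebv_csv, inb_csv, f1, f2)
  invisible(files)
}
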