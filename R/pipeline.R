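# End-to-end composition: phantom cell -> T2 map + thickness map -> per-VOI
# measures -> long cohort table ready for the statistical ladder.

# default anatomical frame of the phantom world (+x medial, +y anterior,
# +z proximal, notch plane x = 0)
phantom_frame <- function() anatomical_frame()

#' Analyze one knee-timepoint cell of a simulated cohort
#'
#' Runs the full measurement chain on a [simulate_knee_timepoint()] cell:
#' VOI partition of the bone mesh, per-voxel T2 fitting over the cartilage
#' mask, voxel-to-VOI/layer assignment, robust median T2 per (sub-)VOI and
#' layer, thickness map and per-VOI means, and the medial-lateral ratios.
#'
#' @param cell a [simulate_knee_timepoint()] result (rendered).
#' @param exclude_first,quantile_type fit/aggregation options (see
#'   [fit_voxel_t2()], [median_t2()]).
#' @param ap_fractions,ml_fractions VOI boundaries (see [partition_vois()]).
#' @param layers also compute superficial/deep layer medians (default
#'   `TRUE`).
#' @return data.frame with columns `family`, `measure`, `layer`, `value`.
#' @export
analyze_knee_timepoint <- function(cell, exclude_first = TRUE,
                                   quantile_type = 7,
                                   ap_fractions = c(1, 2) / 3,
                                   ml_fractions = c(1, 2) / 3,
                                   layers = TRUE) {
  .assert(!is.null(cell$render), "cell was generated without rendering")
  mod <- cell$models
  part <- partition_vois(mod$bone, phantom_frame(),
                         ap_fractions = ap_fractions,
                         ml_fractions = ml_fractions)
  vol <- cell$render$volume
  mask <- cell$render$truth$mask
  fit <- fit_t2_map(vol, mask = mask, exclude_first = exclude_first)
  asg <- assign_voxels(mask, vol$geometry, mod$bone, mod$cartilage, part)
  t2v <- fit$t2[asg$voxel]
  ok <- fit$valid[asg$voxel]

  rows <- list()
  add <- function(family, measure, layer, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, measure = measure, layer = layer, value = value,
      stringsAsFactors = FALSE)
  }
  sel_label <- function(lab) {
    if (lab %in% .SUBVOI_LEVELS) !is.na(asg$subvoi) & asg$subvoi == lab & ok
    else asg$voi == lab & ok
  }
  t2_full <- setNames(rep(NA_real_, 12), c(.VOI_LEVELS, .SUBVOI_LEVELS))
  for (lab in c(.VOI_LEVELS, .SUBVOI_LEVELS)) {
    sel <- sel_label(lab)
    if (any(sel)) {
      t2_full[lab] <- median_t2(t2v[sel], quantile_type = quantile_type)$median
    }
    add("t2", lab, "full", t2_full[[lab]])
    if (layers) {
      for (ly in c("deep", "superficial")) {
        s2 <- sel & asg$layer == ly
        add("t2", lab, ly,
            if (any(s2)) median_t2(t2v[s2], quantile_type = quantile_type)$median
            else NA_real_)
      }
    }
  }
  tm <- compute_thickness(mod$bone, mod$cartilage)
  thk <- mean_thickness_per_voi(tm, part)
  th_full <- setNames(thk$mean_mm, thk$voi)
  for (lab in names(th_full)) add("thickness", lab, "full", th_full[[lab]])
  r_t2 <- ml_ratio(t2_full)
  r_th <- ml_ratio(th_full)
  for (rn in names(r_t2)) add("t2_ratio", rn, "full", r_t2[[rn]])
  for (rn in names(r_th)) add("thickness_ratio", rn, "full", r_th[[rn]])
  do.call(rbind, rows)
}

#' Measure a whole simulated cohort into a long cohort table
#'
#' Applies [analyze_knee_timepoint()] to every cell of a rendered
#' [simulate_cohort()] result (or generates cells on the fly when the
#' cohort was built with `keep_cells = FALSE`).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param ... options passed to [analyze_knee_timepoint()].
#' @return long-format data.frame: `knee`, `timepoint`, `months`, `family`,
#'   `measure`, `layer`, `value`.
#' @export
cohort_table <- function(cohort, ...) {
  .assert(inherits(cohort, "phantom_cohort"), "cohort must be a phantom_cohort")
  out <- list()
  for (k in seq_len(cohort$n_knees)) {
    for (tp in 1:3) {
      cell <- if (!is.null(cohort$cells)) cohort$cells[[k]][[tp]]
              else simulate_knee_timepoint(cohort$spec, cohort$model, k, tp,
                                           cohort$seed, render = TRUE)
      meas <- analyze_knee_timepoint(cell, ...)
      meas$knee <- k
      meas$timepoint <- cell$timepoint
      meas$months <- cohort$model$months[tp]
      out[[length(out) + 1L]] <- meas
    }
  }
  df <- do.call(rbind, out)
  df[, c("knee", "timepoint", "months", "family", "measure", "layer", "value")]
}

#' Fast statistics-level cohort simulation (no image rendering)
#'
#' Builds an observed cohort table directly from the phantom ground truth:
#' each knee's baseline per-(sub-)VOI values are perturbed by the
#' progression multipliers and by per-(knee, timepoint, VOI) lognormal
#' scan noise; ratio measures are derived from the observed VOI values.
#' This is the cohort generator used for large statistical simulations
#' (e.g. type-I error studies) where rendering every volume is unnecessary.
#'
#' @param n_knees number of knees.
#' @param spec a [phantom_spec()].
#' @param model a [progression_model()].
#' @param seed cohort seed.
#' @return long-format observed cohort table (same shape as
#'   [cohort_table()], layer = "full").
#' @export
simulate_cohort_table <- function(n_knees, spec, model, seed = spec$seed) {
  .assert(n_knees >= 2, "n_knees must be >= 2")
  labs <- c(.VOI_LEVELS, .SUBVOI_LEVELS)
  out <- list()
  for (k in seq_len(n_knees)) {
    sp <- .perturb_spec(spec, model, seed, k)
    base <- .knee_baseline_truth(sp)
    for (tp in 1:3) {
      kl <- c("KL1", "KL2", "KL3")[tp]
      scan <- .scan_factors(model, seed, k, tp)
      t2m <- .mult_lookup(base$voi, base$subvoi, model$t2_mult[[kl]])
      thm <- .mult_lookup(base$voi, base$subvoi, model$th_mult[[kl]])
      t2_obs <- setNames(base$t2 * t2m * scan$t2[labs], labs)
      th_obs <- setNames(base$thickness * thm * scan$th[labs], labs)
      df <- rbind(
        data.frame(family = "t2", measure = labs, value = unname(t2_obs),
                   stringsAsFactors = FALSE),
        data.frame(family = "thickness", measure = labs,
                   value = unname(th_obs), stringsAsFactors = FALSE),
        data.frame(family = "t2_ratio", measure = names(.RATIO_PAIRS),
                   value = unname(ml_ratio(t2_obs)), stringsAsFactors = FALSE),
        data.frame(family = "thickness_ratio", measure = names(.RATIO_PAIRS),
                   value = unname(ml_ratio(th_obs)), stringsAsFactors = FALSE)
      )
      df$knee <- k; df$timepoint <- kl; df$months <- model$months[tp]
      df$layer <- "full"
      out[[length(out) + 1L]] <- df
    }
  }
  df <- do.call(rbind, out)
  df[, c("knee", "timepoint", "months", "family", "measure", "layer", "value")]
}

#' Annualized percent-per-year change per measure from a cohort table
#'
#' Computes, per knee and measure, the annualized change between two
#' severity timepoints, then summarizes across knees.
#'
#' @param table long cohort table (see [cohort_table()]).
#' @param from,to timepoint labels (default KL1 to KL3).
#' @return data.frame with `family`, `measure`, `layer`, `mean_pct_year`,
#'   `median_pct_year`, `n`.
#' @export
annualized_change_table <- function(table, from = "KL1", to = "KL3") {
  a <- table[table$timepoint == from, ]
  b <- table[table$timepoint == to, ]
  key <- c("knee", "family", "measure", "layer")
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  months <- m$months_b - m$months_a
  .assert(all(months > 0), "timepoints are not ordered in time")
  m$pct_year <- annualized_change(m$value_a, m$value_b, months)
  agg <- stats::aggregate(pct_year ~ family + measure + layer, data = m,
                          FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                              median = median(x, na.rm = TRUE),
                                              n = sum(!is.na(x))))
  data.frame(family = agg$family, measure = agg$measure, layer = agg$layer,
             mean_pct_year = agg$pct_year[, "mean"],
             median_pct_year = agg$pct_year[, "median"],
             n = agg$pct_year[, "n"], stringsAsFactors = FALSE)
}
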