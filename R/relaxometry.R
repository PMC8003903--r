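#' Multi-echo magnitude MR volume
#'
#' Container for a multi-slice multi-echo (MSME) acquisition: one magnitude
#' volume per echo time with shared geometry.
#'
#' @param echo_times numeric vector of echo times (ms), strictly ascending,
#'   length >= 3.
#' @param data 4D numeric array `dims x n_echoes` of magnitudes (>= 0).
#' @param geometry an [image_geometry()] describing origin, spacing and
#'   direction cosines.
#' @return An object of class `multi_echo_volume`.
#' @export
multi_echo_volume <- function(echo_times, data, geometry) {
  echo_times <- as.numeric(echo_times)
  .assert(length(echo_times) >= 3, "at least 3 echoes are required")
  .assert(all(diff(echo_times) > 0), "echo times must be strictly ascending")
  .assert(is.array(data) && length(dim(data)) == 4,
          "data must be a 4D array (x, y, z, echo)")
  .assert(dim(data)[4] == length(echo_times),
          "4th array dimension must match the number of echoes")
  .assert(inherits(geometry, "image_geometry"), "geometry must be an image_geometry")
  .assert(all(dim(data)[1:3] == geometry$dims),
          "geometry dims do not match the data array")
  .assert(all(data >= 0), "magnitude signals must be >= 0")
  structure(list(echo_times = echo_times, data = data, geometry = geometry),
            class = "multi_echo_volume")
}

#' @export
print.multi_echo_volume <- function(x, ...) {
  cat(sprintf("<multi_echo_volume> %s voxels, %d echoes (TE %s ms)\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              length(x$echo_times),
              paste(x$echo_times, collapse = ", ")))
  invisible(x)
}

#' Monoexponential T2 fit for a single voxel
#'
#' Least-squares fit of `ln(signal)` against echo time; `T2 = -1/slope`,
#' `S0 = exp(intercept)`. By default the first echo is excluded to limit
#' stimulated-echo contamination of multi-echo trains.
#'
#' A non-positive slope yields a negative or infinite T2 which is returned
#' as-is; the per-VOI aggregation ([median_t2()]) excludes such values.
#' Voxels with non-positive signal at any used echo, or with fewer than two
#' usable echoes, are invalid.
#'
#' @param signal numeric vector of per-echo magnitudes.
#' @param echo_times numeric vector of echo times (ms), ascending.
#' @param exclude_first drop the first echo before fitting (default `TRUE`).
#' @return list with `t2` (ms), `s0`, `r2` (of the log-linear fit), `valid`,
#'   `reason` (`NA` when valid).
#' @export
#' @examples
#' te <- seq(10, 70, 10)
#' fit_voxel_t2(1000 * exp(-te / 40), te)$t2
fit_voxel_t2 <- function(signal, echo_times, exclude_first = TRUE) {
  .assert(length(signal) == length(echo_times),
          "signal and echo_times lengths differ")
  .assert(all(diff(echo_times) > 0), "echo times must be strictly ascending")
  use <- if (exclude_first) -1L else seq_along(echo_times)
  s <- signal[use]
  te <- echo_times[use]
  if (any(!is.finite(s)) || any(s <= 0)) {
    return(list(t2 = NA_real_, s0 = NA_real_, r2 = NA_real_, valid = FALSE,
                reason = "nonpositive_signal"))
  }
  if (length(s) < 2) {
    return(list(t2 = NA_real_, s0 = NA_real_, r2 = NA_real_, valid = FALSE,
                reason = "too_few_echoes"))
  }
  y <- log(s)
  mx <- mean(te); my <- mean(y)
  sxx <- sum((te - mx)^2)
  sxy <- sum((te - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
  t2 <- if (slope == 0) Inf else -1 / slope
  list(t2 = t2, s0 = exp(intercept), r2 = r2, valid = TRUE, reason = NA_character_)
}

#' Per-voxel T2 map over a masked volume
#'
#' Vectorized application of [fit_voxel_t2()] to every voxel inside `mask`;
#' values are identical to the voxel-wise function.
#'
#' @param volume a [multi_echo_volume()].
#' @param mask logical array matching the volume dims; `NULL` fits all
#'   voxels.
#' @param exclude_first see [fit_voxel_t2()].
#' @return An object of class `t2_map`: arrays `t2`, `s0`, `r2`, logical
#'   `valid`, character `reason`, plus the `mask` and `geometry`.
#' @export
fit_t2_map <- function(volume, mask = NULL, exclude_first = TRUE) {
  .assert(inherits(volume, "multi_echo_volume"),
          "volume must be a multi_echo_volume")
  dims <- dim(volume$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  .assert(all(dim(mask) == dims), "mask dims do not match the volume")
  if (!any(mask)) warning("empty mask: no voxels fitted")

  nvox <- prod(dims)
  sig <- matrix(volume$data, nrow = nvox)  # voxels x echoes
  te <- volume$echo_times
  use <- if (exclude_first) -1L else seq_along(te)
  s <- sig[, use, drop = FALSE]
  teu <- te[use]

  idx <- which(as.vector(mask))
  t2 <- array(NA_real_, dims); s0 <- array(NA_real_, dims)
  r2 <- array(NA_real_, dims); valid <- array(FALSE, dims)
  reason <- array(NA_character_, dims)
  reason[!mask] <- "outside_mask"
  if (length(idx)) {
    su <- s[idx, , drop = FALSE]
    bad <- rowSums(!is.finite(su) | su <= 0) > 0
    reason[idx[bad]] <- "nonpositive_signal"
    ok <- idx[!bad]
    if (length(ok)) {
      y <- log(s[ok, , drop = FALSE])
      mx <- mean(teu)
      cx <- teu - mx
      sxx <- sum(cx^2)
      my <- rowMeans(y)
      yc <- y - my
      sxy <- as.vector(yc %*% cx)
      slope <- sxy / sxx
      syy <- rowSums(yc^2)
      t2v <- ifelse(slope == 0, Inf, -1 / slope)
      t2[ok] <- t2v
      s0[ok] <- exp(my - slope * mx)
      r2[ok] <- ifelse(syy > 0, sxy^2 / (sxx * syy), 1)
      valid[ok] <- TRUE
    }
  }
  structure(list(t2 = t2, s0 = s0, r2 = r2, valid = valid, reason = reason,
                 mask = mask, geometry = volume$geometry),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  v <- x$t2[x$valid & is.finite(x$t2) & x$t2 > 0]
  cat(sprintf("<t2_map> %s voxels, %d valid; median T2 %.2f ms\n",
              paste(dim(x$t2), collapse = "x"), sum(x$valid),
              if (length(v)) median(v) else NA_real_))
  invisible(x)
}

#' Robust median T2 with the negative / IQR-outlier exclusion rule
#'
#' Aggregates per-voxel T2 values in a (sub-)VOI: values strictly less than
#' 0 ms are removed first; a single outlier pass then removes values greater
#' than the median plus three times the interquartile range of the
#' remainder; the median of the survivors is returned. Infinite fitted T2
#' (zero decay slope) always counts as an outlier.
#'
#' @param values numeric vector of T2 values (ms); `NA`s are dropped with a
#'   count.
#' @param quantile_type quantile convention for the IQR (default 7, linear
#'   interpolation of order statistics; see [stats::quantile()]).
#' @param iqr_on `"after_negative_removal"` (default) computes the
#'   median/IQR threshold on the negatives-removed sample; `"all_values"`
#'   computes it on the full input.
#' @return list with `median` (ms, `NA` when nothing survives), `n_used`,
#'   `n_excluded_negative`, `n_excluded_outlier`, `reason`.
#' @export
#' @examples
#' median_t2(c(-5, 30, 40, 50))$median  # 40
#' median_t2(c(30, 35, 40, 45, 200))$median  # 37.5
median_t2 <- function(values, quantile_type = 7,
                      iqr_on = c("after_negative_removal", "all_values")) {
  iqr_on <- match.arg(iqr_on)
  .assert(length(values) > 0, "empty T2 collection")
  x <- values[!is.na(values)]
  if (!length(x)) {
    return(list(median = NA_real_, n_used = 0L, n_excluded_negative = 0L,
                n_excluded_outlier = 0L, reason = "all_missing"))
  }
  neg <- x < 0  # strict: 0 ms itself is kept
  x1 <- x[!neg]
  if (!length(x1)) {
    return(list(median = NA_real_, n_used = 0L, n_excluded_negative = sum(neg),
                n_excluded_outlier = 0L, reason = "all_negative"))
  }
  ref <- if (iqr_on == "after_negative_removal") x1 else x
  fin <- ref[is.finite(ref)]
  if (length(fin)) {
    qs <- quantile(fin, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
    cutoff <- qs[2] + 3 * (qs[3] - qs[1])
  } else {
    cutoff <- -Inf  # only infinite values: all excluded as outliers
  }
  out <- x1 > cutoff  # Inf values are always > any finite cutoff
  keep <- x1[!out]
  if (!length(keep)) {
    return(list(median = NA_real_, n_used = 0L, n_excluded_negative = sum(neg),
                n_excluded_outlier = sum(out), reason = "all_excluded"))
  }
  list(median = median(keep), n_used = length(keep),
       n_excluded_negative = sum(neg), n_excluded_outlier = sum(out),
       reason = NA_character_)
}

#' Medial-lateral ratios of per-VOI summaries
#'
#' Computes the homologous medial/lateral ratios Ra = Ma/La, Rc = Mc/Lc,
#' Rp = Mp/Lp and the anterior sub-VOI ratios Rae, Rac, Rai. A missing or
#' zero lateral value yields `NA`.
#'
#' @param summaries named numeric vector of per-VOI values (names from
#'   [voi_labels()]).
#' @return named numeric vector of ratios.
#' @export
#' @examples
#' ml_ratio(c(Ma = 1.8, La = 2.0))[["Ra"]]  # 0.9
ml_ratio <- function(summaries) {
  .assert(!is.null(names(summaries)), "summaries must be named by VOI")
  out <- rep(NA_real_, length(.RATIO_PAIRS))
  names(out) <- names(.RATIO_PAIRS)
  for (rn in names(.RATIO_PAIRS)) {
    pair <- .RATIO_PAIRS[[rn]]
    m <- summaries[pair[1]]; l <- summaries[pair[2]]
    if (!is.na(m) && !is.na(l) && length(m) && length(l) && l != 0) {
      out[rn] <- as.numeric(m) / as.numeric(l)
    }
  }
  out
}

#' Annualized percent change
#'
#' `100 * ((v_end - v_start) / v_start) / (months / 12)`, the percent-per-year
#' change rate used to compare longitudinal cartilage studies.
#'
#' @param v_start,v_end values at the two timepoints (same units).
#' @param months_between elapsed time in months (> 0).
#' @return percent per year (vectorized); `NA` where `v_start == 0`.
#' @export
#' @examples
#' annualized_change(2.0, 1.7, 24)  # -7.5 %/year
annualized_change <- function(v_start, v_end, months_between) {
  .assert(all(months_between > 0), "months_between must be positive")
  out <- 100 * ((v_end - v_start) / v_start) / (months_between / 12)
  out[v_start == 0] <- NA_real_
  out
}
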