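#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the reference implementation in [stats::shapiro.test()]
#' with an explicit degenerate-input flag.
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @return list with `W`, `p`, `n`, `degenerate`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  .assert(length(values) >= 3 && length(values) <= 5000,
          "Shapiro-Wilk requires 3 <= n <= 5000")
  if (var(values) == 0) {
    return(list(W = NA_real_, p = NA_real_, n = length(values),
                degenerate = TRUE))
  }
  ht <- shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value, n = length(values),
       degenerate = FALSE)
}

#' Friedman repeated-measures test
#'
#' Nonparametric omnibus test for a timepoint effect: values are ranked
#' within each subject's row (mid-ranks for ties) and the rank-sum
#' chi-squared statistic, with the standard tie correction, is referred to a
#' chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param matrix numeric n x k matrix, subjects in rows, timepoints in
#'   columns; complete rows required.
#' @param method `"chisq"` (default): asymptotic chi-squared p;
#'   `"simulate"`: Monte-Carlo permutation p over random within-row
#'   reorderings of the observed values (useful at small n, where the
#'   asymptotic p deviates from the exact permutation distribution).
#' @param n_perm number of Monte-Carlo permutations for
#'   `method = "simulate"`.
#' @param seed RNG seed for the Monte-Carlo p.
#' @return list with `chisq`, `df`, `p`, `n`, `k`.
#' @export
#' @examples
#' friedman(rbind(c(1, 2, 3), c(2, 4, 6), c(1, 5, 9)))$chisq  # 6
friedman <- function(matrix, method = c("chisq", "simulate"),
                     n_perm = 20000, seed = 1L) {
  method <- match.arg(method)
  m <- as.matrix(matrix)
  .assert(is.numeric(m), "matrix must be numeric")
  .assert(!anyNA(m), "missing cells: Friedman requires complete rows")
  n <- nrow(m); k <- ncol(m)
  .assert(n >= 2 && k >= 3, "Friedman requires n >= 2 subjects and k >= 3 timepoints")
  stat <- function(mm) {
    r <- t(apply(mm, 1, rank))  # mid-ranks within each row
    rj <- colSums(r)
    # Conover tie-corrected form; reduces to 12/(nk(k+1)) sum Rj^2 - 3n(k+1)
    # when no ties are present
    a1 <- sum(r^2)
    c1 <- n * k * (k + 1)^2 / 4
    den <- a1 - c1
    if (den <= 0) return(c(0, 0))
    c((k - 1) * sum((rj - n * (k + 1) / 2)^2) / den, den)
  }
  s0 <- stat(m)
  chisq <- s0[1]
  if (s0[2] <= 0) {
    p <- 1
  } else if (method == "chisq") {
    p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  } else {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      mp <- t(apply(m, 1, sample))
      if (stat(mp)[1] >= chisq - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(chisq = chisq, df = k - 1, p = p, n = n, k = k)
}

# exact null distribution of W+ for ranks 1..n (no ties): subset-sum counts
.signed_rank_counts <- function(n) {
  counts <- c(1, rep(0, n * (n + 1) / 2))
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts  # counts[w + 1] = number of sign patterns with W+ == w
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's convention; `zero_method =
#' "pratt"` keeps them in the ranking). With no ties among the absolute
#' differences and n at most `exact_cutoff`, the two-sided p-value is exact
#' (from the full sign-assignment distribution computed by convolution);
#' otherwise the normal approximation with mid-ranks, tie correction, and
#' continuity correction is used. The normal-approximation `z` is always
#' reported for effect-size use.
#'
#' @param x,y paired numeric samples.
#' @param exact_cutoff maximum n for the exact distribution (default 25).
#' @param zero_method `"wilcoxon"` (drop zero differences, default) or
#'   `"pratt"` (rank them, then drop their contribution).
#' @return list with `w_plus`, `w_minus`, `statistic` (min of the two), `n`
#'   (pairs used), `p`, `z`, `exact`, `degenerate`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, -2, 3, 4, 5), rep(0, 5))$p  # 0.1875
wilcoxon_signed_rank <- function(x, y, exact_cutoff = 25,
                                 zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  .assert(length(x) == length(y), "x and y must be paired (equal length)")
  d <- x - y
  d <- d[!is.na(d)]
  if (all(d == 0)) {
    return(list(w_plus = NA_real_, w_minus = NA_real_, statistic = NA_real_,
                n = 0L, p = NA_real_, z = NA_real_, exact = FALSE,
                degenerate = TRUE))
  }
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    n <- length(d)
    rr <- rank(abs(d))           # mid-ranks of the non-zero differences
    w_plus <- sum(rr[d > 0])
  } else {
    rall <- rank(abs(d))         # zeros participate in the ranking (Pratt) ...
    rr <- rall[d != 0]           # ... but contribute to neither sign's sum
    n <- sum(d != 0)
    w_plus <- sum(rall[d > 0])
  }
  .assert(n >= 2, "fewer than 2 non-zero differences")
  w_minus <- sum(rr) - w_plus
  ties <- any(duplicated(rr))
  # normal approximation (always computed; supplies z for effect sizes);
  # var(W+) = sum(r_i^2)/4 is the tie-corrected variance, equal to
  # n(n+1)(2n+1)/24 when ranks are 1..n
  mu <- sum(rr) / 2
  sig2 <- sum(rr^2) / 4
  z_num <- w_plus - mu
  cc <- sign(z_num) * min(0.5, abs(z_num))  # continuity correction
  z <- if (sig2 > 0) (z_num - cc) / sqrt(sig2) else 0
  if (!ties && zero_method == "wilcoxon" && n <= exact_cutoff) {
    counts <- .signed_rank_counts(n)
    tot <- 2^n
    t_obs <- min(w_plus, w_minus)
    p <- min(1, 2 * sum(counts[seq_len(t_obs + 1)]) / tot)
    exact <- TRUE
  } else {
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  list(w_plus = w_plus, w_minus = w_minus,
       statistic = min(w_plus, w_minus), n = n, p = p, z = z,
       exact = exact, degenerate = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition of an n x k complete matrix into subject,
#' time and error sums of squares; `F = MS_time / MS_error` on
#' (k - 1, (n - 1)(k - 1)) degrees of freedom. Sphericity is assumed by
#' default; `gg = TRUE` applies the Greenhouse-Geisser correction.
#'
#' @param matrix numeric n x k matrix, subjects in rows.
#' @param gg apply the Greenhouse-Geisser epsilon correction.
#' @return list with `F`, `df1`, `df2`, `p`, `ss` (named sums of squares),
#'   and `epsilon` when `gg`.
#' @export
rm_anova <- function(matrix, gg = FALSE) {
  m <- as.matrix(matrix)
  .assert(is.numeric(m), "matrix must be numeric")
  .assert(!anyNA(m), "missing cells: repeated-measures ANOVA requires complete rows")
  n <- nrow(m); k <- ncol(m)
  .assert(n >= 2 && k >= 2, "need n >= 2 subjects and k >= 2 timepoints")
  gm <- mean(m)
  ss_total <- sum((m - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_time <- n * sum((colMeans(m) - gm)^2)
  ss_err <- ss_total - ss_subj - ss_time
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_time <- ss_time / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_time / ms_err else ifelse(ms_time > 0, Inf, 0)
  eps <- 1
  if (gg) {
    # Greenhouse-Geisser epsilon from the double-centered covariance matrix
    s <- stats::cov(m)
    dc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) +
      mean(s)
    eps <- sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
    eps <- min(1, max(1 / (k - 1), eps))
  }
  p <- pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  out <- list(F = f, df1 = df1, df2 = df2, p = p,
              ss = c(time = ss_time, subject = ss_subj, error = ss_err))
  if (gg) out$epsilon <- eps
  out
}

#' Paired t-test
#'
#' @param x,y paired numeric samples.
#' @return list with `t`, `df`, `p`, `n`, `mean_diff`, `degenerate` (zero
#'   variance of the differences).
#' @export
paired_t <- function(x, y) {
  .assert(length(x) == length(y), "x and y must be paired (equal length)")
  d <- (x - y)
  d <- d[!is.na(d)]
  n <- length(d)
  .assert(n >= 2, "paired t requires n >= 2")
  s <- sd(d)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1, p = NA_real_, n = n,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1), n = n,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Effect size for a pairwise comparison
#'
#' Parametric family: Cohen's d_z = mean(d) / sd(d) of the paired
#' differences. Nonparametric family: r = |Z| / sqrt(n) from the Wilcoxon
#' signed-rank normal approximation.
#'
#' @param x,y paired numeric samples.
#' @param family `"parametric"` or `"nonparametric"`.
#' @return effect size (absolute value for the nonparametric family; signed
#'   d_z for the parametric family), `NA` when degenerate.
#' @export
effect_size <- function(x, y, family = c("parametric", "nonparametric")) {
  family <- match.arg(family)
  d <- x - y
  d <- d[!is.na(d)]
  if (family == "parametric") {
    s <- sd(d)
    if (s == 0) return(if (all(d == 0)) 0 else NA_real_)
    return(mean(d) / s)
  }
  if (all(d == 0)) return(0)
  w <- wilcoxon_signed_rank(x, y)
  if (w$degenerate) return(0)
  abs(w$z) / sqrt(w$n)
}

# reshape a long cohort table into a complete n x 3 matrix for one measure;
# knees without all three timepoints are dropped (count reported)
.measure_matrix <- function(table, measure_id, timepoints = c("KL1", "KL2", "KL3")) {
  sub <- table[table$measure_id == measure_id, c("knee", "timepoint", "value")]
  wide <- lapply(timepoints, function(tp) {
    v <- sub$value[sub$timepoint == tp]
    names(v) <- sub$knee[sub$timepoint == tp]
    v
  })
  knees <- Reduce(intersect, lapply(wide, names))
  keep <- knees[!sapply(knees, function(k) any(sapply(wide, function(w) is.na(w[k]))))]
  m <- sapply(wide, function(w) w[keep])
  if (length(keep) == 1L) m <- matrix(m, nrow = 1)
  dimnames(m) <- list(keep, timepoints)
  attr(m, "n_dropped") <- length(unique(sub$knee)) - length(keep)
  m
}

#' Severity-timepoint statistical analysis of a cohort table
#'
#' Implements the full statistical ladder per measure: a Shapiro-Wilk
#' normality gate (applied per measure family by default) routes each
#' measure either to Friedman + Wilcoxon signed-rank (non-normal) or to
#' repeated-measures ANOVA + paired t (normal). The omnibus test is judged
#' at `alpha` (default 0.05); the three pairwise comparisons (KL1-KL2,
#' KL1-KL3, KL2-KL3) run only when the omnibus is significant and are
#' judged strictly at the Bonferroni-corrected `bonferroni_alpha` (default
#' the conventional printed value 0.017). An effect size accompanies every
#' pairwise result (Cohen's d_z parametric, r = |Z|/sqrt(n) nonparametric).
#'
#' @param table long-format cohort data.frame with columns `knee`,
#'   `timepoint` (KL1/KL2/KL3), `family`, `measure`, `value` and optionally
#'   `layer` (defaults to "full").
#' @param alpha omnibus significance level.
#' @param bonferroni_alpha pairwise significance level (strict `<`).
#' @param gate `"auto"` (Shapiro-Wilk per family), `"nonparametric"`,
#'   `"parametric"`, or a named character vector mapping family ->
#'   route for explicit overrides.
#' @param gate_reject_frac in auto mode, a family routes nonparametric when
#'   more than this fraction of its per-measure, per-timepoint Shapiro-Wilk
#'   tests reject at 0.05 (default 0.2, well above the nominal 5% false
#'   positive rate).
#' @param exact_cutoff passed to [wilcoxon_signed_rank()].
#' @return data.frame of test results: one omnibus row per measure plus
#'   pairwise rows when run; columns `measure`, `family`, `layer`, `route`,
#'   `test`, `comparison`, `statistic`, `p`, `effect_size`, `direction`
#'   (sign of the mean paired change, later minus earlier timepoint; the
#'   nonparametric effect size r is unsigned, so direction carries the
#'   sign), `n`, `significant`.
#' @export
run_severity_analysis <- function(table, alpha = 0.05,
                                  bonferroni_alpha = 0.017,
                                  gate = "auto", gate_reject_frac = 0.2,
                                  exact_cutoff = 25) {
  need <- c("knee", "timepoint", "family", "measure", "value")
  .assert(all(need %in% names(table)),
          paste("cohort table must have columns:", paste(need, collapse = ", ")))
  if (is.null(table$layer)) table$layer <- "full"
  table$measure_id <- paste(table$family, table$measure, table$layer, sep = "|")
  ids <- unique(table$measure_id)
  info <- unique(table[, c("measure_id", "family", "measure", "layer")])

  # normality gate per family
  fams <- unique(info$family)
  route_for <- setNames(character(length(fams)), fams)
  for (f in fams) {
    if (identical(gate, "nonparametric") || identical(gate, "parametric")) {
      route_for[f] <- gate
    } else if (!is.null(names(gate)) && f %in% names(gate)) {
      route_for[f] <- gate[[f]]
    } else {
      ps <- c()
      for (id in info$measure_id[info$family == f]) {
        m <- .measure_matrix(table, id)
        if (nrow(m) >= 3) {
          for (j in seq_len(ncol(m))) {
            sw <- shapiro_wilk(m[, j])
            if (!sw$degenerate) ps <- c(ps, sw$p)
          }
        }
      }
      frac <- if (length(ps)) mean(ps < 0.05) else 0
      route_for[f] <- if (frac > gate_reject_frac) "nonparametric" else "parametric"
    }
  }

  pairs <- list(c("KL1", "KL2"), c("KL1", "KL3"), c("KL2", "KL3"))
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...,
                                                                stringsAsFactors = FALSE)
  for (id in ids) {
    meta <- info[info$measure_id == id, ][1, ]
    route <- route_for[[meta$family]]
    m <- .measure_matrix(table, id)
    if (nrow(m) < 2) next
    if (route == "nonparametric") {
      om <- friedman(m)
      om_stat <- om$chisq; om_p <- om$p; om_test <- "friedman"
    } else {
      om <- rm_anova(m)
      om_stat <- om$F; om_p <- om$p; om_test <- "rm_anova"
    }
    om_sig <- !is.na(om_p) && om_p < alpha
    add(measure = meta$measure, family = meta$family, layer = meta$layer,
        route = route, test = om_test, comparison = "omnibus",
        statistic = om_stat, p = om_p, effect_size = NA_real_,
        direction = NA_real_, n = nrow(m), significant = om_sig)
    if (!om_sig) next  # gatekeeping: no post-hoc without a significant omnibus
    for (pr in pairs) {
      a <- m[, pr[1]]; b <- m[, pr[2]]
      if (route == "nonparametric") {
        ht <- wilcoxon_signed_rank(b, a, exact_cutoff = exact_cutoff)
        stat <- ht$statistic; p <- ht$p
        es <- if (ht$degenerate) 0 else abs(ht$z) / sqrt(ht$n)
        test <- "wilcoxon"
      } else {
        ht <- paired_t(b, a)
        stat <- ht$t; p <- ht$p
        es <- effect_size(b, a, "parametric")
        test <- "paired_t"
      }
      add(measure = meta$measure, family = meta$family, layer = meta$layer,
          route = route, test = test,
          comparison = paste(pr, collapse = "-"),
          statistic = stat, p = p, effect_size = es,
          direction = sign(mean(b - a)), n = length(a),
          significant = !is.na(p) && p < bonferroni_alpha)
    }
  }
  do.call(rbind, rows)
}
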