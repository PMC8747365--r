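#' Align two R-R series into paired heart-rate measurements
#'
#' Matches intervals from two instruments by interval mid-time (monotone
#' nearest-neighbor matching within a tolerance) and converts matched
#' intervals to instantaneous heart rate (60000 / interval ms = bpm).
#' Unmatched intervals on either side are counted, not silently dropped.
#'
#' @param a,b \code{rr_series} from the two instruments.
#' @param tolerance maximum mid-time difference for a match, in ms
#'   (default 250).
#' @return object of class \code{paired_measurements}: \code{a}, \code{b}
#'   (bpm, equal length), \code{n_unmatched_a}, \code{n_unmatched_b},
#'   \code{alignment_rule}.
#' @export
align_rr <- function(a, b, tolerance = 250) {
  stopifnot(inherits(a, "rr_series"), inherits(b, "rr_series"))
  tol_s <- tolerance / 1000
  ia <- 1L; ib <- 1L
  ma <- integer(0); mb <- integer(0)
  na <- length(a$t_mid); nb <- length(b$t_mid)
  while (ia <= na && ib <= nb) {
    dt <- a$t_mid[ia] - b$t_mid[ib]
    if (abs(dt) <= tol_s) {
      # prefer the closer of b[ib], b[ib+1] for a[ia]
      if (ib < nb && abs(a$t_mid[ia] - b$t_mid[ib + 1L]) < abs(dt)) {
        ib <- ib + 1L
        next
      }
      ma <- c(ma, ia); mb <- c(mb, ib)
      ia <- ia + 1L; ib <- ib + 1L
    } else if (dt > 0) ib <- ib + 1L else ia <- ia + 1L
  }
  if (length(ma) == 0L)
    stop(sprintf("no interval pairs matched within %g ms; check alignment or tolerance",
                 tolerance))
  structure(list(a = 60000 / a$intervals[ma], b = 60000 / b$intervals[mb],
                 n_unmatched_a = na - length(ma),
                 n_unmatched_b = nb - length(mb),
                 alignment_rule = sprintf("nearest mid-time within %g ms", tolerance)),
            class = "paired_measurements")
}

#' Construct paired measurements directly
#'
#' @param a,b equal-length numeric series, time-aligned.
#' @param alignment_rule free-text description of how pairs were matched.
#' @return a \code{paired_measurements} object.
#' @export
paired_measurements <- function(a, b, alignment_rule = "pre-aligned") {
  stopifnot(length(a) == length(b), length(a) >= 2L,
            !anyNA(a), !anyNA(b))
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 n_unmatched_a = 0L, n_unmatched_b = 0L,
                 alignment_rule = alignment_rule),
            class = "paired_measurements")
}

#' Bland-Altman agreement analysis
#'
#' Differences are defined as (a - b), conventionally (this work -
#' reference). Bias is the mean difference, sd_diff the sample standard
#' deviation (n-1) of the differences, and the 95\% limits of agreement
#' are bias +/- 1.96 sd_diff.
#'
#' @param pairs a \code{paired_measurements} with >= 2 pairs.
#' @return object of class \code{agreement_report}: \code{bias},
#'   \code{sd_diff}, \code{loa_low}, \code{loa_high}, \code{n}, plus
#'   \code{mean_ab} and \code{diff_ab} per pair (for plotting).
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  d <- pairs$a - pairs$b
  if (length(d) < 2L) stop("at least 2 pairs are required")
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d),
                 mean_ab = (pairs$a + pairs$b) / 2, diff_ab = d),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> bias %.3f +/- %.3f (sd), LoA [%.3f, %.3f], n=%d\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  if (!is.null(x$wilcoxon_p))
    cat(sprintf("  Wilcoxon signed-rank: V = %g, p = %.4g\n",
                x$wilcoxon_stat, x$wilcoxon_p))
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, ...) {
  plot(x$mean_ab, x$diff_ab, xlab = "mean of pair", ylab = "difference (a - b)",
       main = "Bland-Altman", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2), col = c("red", "blue", "red"))
  invisible(x)
}

# exact null distribution of the signed-rank statistic for given |d| ranks
# (midranks allowed). Returns list(support, prob) over W+ = sum of positive
# ranks; computed by the generating-function recursion equivalent to
# enumerating all 2^n sign assignments.
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))  # doubled ranks are integers
  S <- sum(r2)
  dd <- numeric(S + 1L)
  dd[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dd[seq_len(S + 1L - r)])
    dd <- (dd + shifted) / 2
  }
  list(support = (0:S) / 2, prob = dd)
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Zero differences are dropped and ties in |difference| receive midranks
#' (standard Wilcoxon conventions). The null distribution is computed
#' exactly (full enumeration over sign assignments, evaluated by a
#' generating-function recursion) for n below \code{exact_limit}; beyond
#' that a normal approximation with continuity correction and tie
#' correction is used. The p-value is two-sided.
#'
#' @param pairs a \code{paired_measurements}, or a numeric vector of
#'   differences (then \code{b} must be missing), or two numeric vectors.
#' @param b optional second series when \code{pairs} is the first.
#' @param exact_limit maximum n for the exact null (default 24).
#' @return list with \code{statistic} (V = sum of positive ranks),
#'   \code{p_value}, \code{n} (non-zero differences), \code{method}.
#' @export
wilcoxon_signed_rank <- function(pairs, b = NULL, exact_limit = 24L) {
  d <- if (inherits(pairs, "paired_measurements")) pairs$a - pairs$b
       else if (!is.null(b)) as.numeric(pairs) - as.numeric(b)
       else as.numeric(pairs)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1.0, n = 0L,
                method = "all differences zero"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    null <- signed_rank_null(r)
    p_le <- sum(null$prob[null$support <= V + 1e-9])
    p_ge <- sum(null$prob[null$support >= V - 1e-9])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = V, p_value = p, n = n, method = method)
}

#' Full agreement report: Bland-Altman plus Wilcoxon signed-rank
#'
#' @param pairs a \code{paired_measurements}.
#' @param exact_limit passed to \code{\link{wilcoxon_signed_rank}}.
#' @return an \code{agreement_report} with \code{wilcoxon_stat} and
#'   \code{wilcoxon_p} fields added.
#' @export
agreement_report <- function(pairs, exact_limit = 24L) {
  rep <- bland_altman(pairs)
  w <- wilcoxon_signed_rank(pairs, exact_limit = exact_limit)
  rep$wilcoxon_stat <- w$statistic
  rep$wilcoxon_p <- w$p_value
  rep
}
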