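#' Wilcoxon signed-rank test for paired samples
#'
#' Classic Wilcoxon treatment: zero differences are discarded, absolute
#' differences receive mid-ranks under ties, and `W` is the sum of ranks of
#' the positive differences.  In `exact` mode the two-sided p-value is
#' computed from the full null distribution of `W` (every sign assignment
#' equally likely), obtained by convolution over the (doubled, hence
#' integer) mid-ranks, so it remains exact under ties.  In `normal_approx`
#' mode a normal approximation with tie-corrected variance and continuity
#' correction is used.  `auto` chooses exact when the effective sample size
#' is at most 25 and there are no tied absolute differences, matching
#' common statistical-package behaviour.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return An object of class `wilcoxon_result`: list with `statistic` (W),
#'   `p_value`, `n`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 1L) stop("need at least one pair")
  d <- as.numeric(a) - as.numeric(b)
  if (any(!is.finite(d))) stop("non-finite differences")
  nz <- d[d != 0]
  n_eff <- length(nz)
  if (n_eff == 0L)
    stop("all paired differences are zero: signed-rank test undefined")
  rk <- rank(abs(nz))
  W <- sum(rk[nz > 0])
  ties <- anyDuplicated(abs(nz)) > 0L

  if (mode == "auto")
    mode <- if (n_eff <= 25 && !ties) "exact" else "normal_approx"

  if (mode == "exact") {
    p <- exact_signed_rank_p(rk, W)
  } else {
    mu <- n_eff * (n_eff + 1) / 4
    tab <- table(rk)
    sigma2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
      sum(tab^3 - tab) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(statistic = W, p_value = p, n = length(a),
                 n_effective = n_eff, method = mode),
            class = "wilcoxon_result")
}

# Exact two-sided p for W = sum of signed mid-ranks of positives.
# Mid-ranks are multiples of 1/2; doubling gives integers, so the null
# distribution of 2W is a 0/1 convolution over the doubled ranks.
exact_signed_rank_p <- function(rk, W) {
  r2 <- as.integer(round(2 * rk))
  total <- sum(r2)
  cnt <- numeric(total + 1)  # counts over 2W = 0..total
  cnt[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), cnt[seq_len(total + 1 - r)])
    cnt <- cnt + shifted
  }
  nconf <- sum(cnt)
  w2 <- round(2 * W)
  p_le <- sum(cnt[seq_len(w2 + 1)]) / nconf
  p_ge <- sum(cnt[(w2 + 1):(total + 1)]) / nconf
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, p = %.5g (%s, n_eff = %d of %d)\n",
              x$statistic, x$p_value, x$method, x$n_effective, x$n))
  invisible(x)
}

#' Cohort summary of per-subject segment motions
#'
#' Aggregates tidy per-subject motion records into a Table-1-style summary:
#' mean and sample standard deviation (n - 1 denominator) of each measure
#' per condition, meniscus and segment.
#'
#' @param records Data.frame with columns `subject, condition, meniscus,
#'   segment, avg_mm, ml_mm, ap_mm` (one row per subject x condition x
#'   meniscus x segment), e.g. from [run_subject()] or
#'   [simulate_cohort()] ground truth.
#' @return A data.frame of class `cohort_summary` with columns `condition,
#'   meniscus, segment, measure, mean, sd, n`.
#' @export
summarize_cohort <- function(records) {
  records <- as.data.frame(records)
  need <- c("subject", "condition", "meniscus", "segment",
            "avg_mm", "ml_mm", "ap_mm")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (length(unique(records$subject)) < 2L)
    stop("need at least 2 subjects to summarise a cohort")
  long <- do.call(rbind, lapply(c(avg = "avg_mm", ml = "ml_mm", ap = "ap_mm"),
    function(col) {
      data.frame(condition = records$condition, meniscus = records$meniscus,
                 segment = records$segment,
                 measure = sub("_mm$", "", col), value = records[[col]])
    }))
  agg <- stats::aggregate(value ~ condition + meniscus + segment + measure,
                          data = long,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(agg[, c("condition", "meniscus", "segment", "measure")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]))
  out <- out[order(out$condition, out$meniscus,
                   match(out$segment, c("AH", "IH", "PH", "whole")),
                   match(out$measure, c("avg", "ml", "ap"))), ]
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Paired Wilcoxon comparisons across conditions and menisci
#'
#' Builds the full comparison grid used for reporting: internal vs external
#' rotation within each meniscus, and MM vs LM within each condition, for
#' every segment (AH, IH, PH, whole) and measure (avg, ml, ap).  Pairing is
#' by subject; no multiplicity adjustment is applied (the analysis is
#' exploratory).
#'
#' @param records Tidy records as for [summarize_cohort()], containing both
#'   conditions for every subject.
#' @param conditions Length-2 character vector naming the two conditions.
#' @param mode Passed to [wilcoxon_signed_rank()].
#' @return A data.frame of class `cohort_tests` with one row per
#'   comparison: `comparison, meniscus, condition, segment, measure, W,
#'   p_value, n_effective, method`.
#' @export
compare_conditions <- function(records, conditions = c("internal", "external"),
                               mode = "auto") {
  records <- as.data.frame(records)
  subs <- sort(unique(records$subject))
  if (length(subs) < 2L) stop("need at least 2 subjects for paired testing")
  segs <- intersect(c("AH", "IH", "PH", "whole"), unique(records$segment))
  measures <- c(avg = "avg_mm", ml = "ml_mm", ap = "ap_mm")

  pick <- function(cond, men, seg, col) {
    sel <- records$condition == cond & records$meniscus == men &
      records$segment == seg
    sub <- records[sel, ]
    m <- match(subs, sub$subject)
    if (anyNA(m))
      stop("missing pair for subjects: ",
           paste(subs[is.na(m)], collapse = ", "),
           " (", cond, "/", men, "/", seg, ")")
    sub[[col]][m]
  }

  rows <- list()
  run_test <- function(label, men, cond, a, b) {
    force(a); force(b)  # pairing errors must escape the tryCatch below
    res <- tryCatch(wilcoxon_signed_rank(a, b, mode = mode),
                    error = function(e) NULL)
    data.frame(comparison = label, meniscus = men, condition = cond,
               W = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               n_effective = if (is.null(res)) 0L else res$n_effective,
               method = if (is.null(res)) "undefined" else res$method)
  }
  for (seg in segs) for (meas in names(measures)) {
    col <- measures[[meas]]
    for (men in c("MM", "LM")) {
      rw <- run_test(paste0(men, ": ", conditions[1], " vs ", conditions[2]),
                     men, "both",
                     pick(conditions[1], men, seg, col),
                     pick(conditions[2], men, seg, col))
      rows[[length(rows) + 1]] <- cbind(rw, segment = seg, measure = meas)
    }
    for (cond in conditions) {
      rw <- run_test(paste0("MM vs LM: ", cond), "both", cond,
                     pick(cond, "MM", seg, col),
                     pick(cond, "LM", seg, col))
      rows[[length(rows) + 1]] <- cbind(rw, segment = seg, measure = meas)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("comparison", "meniscus", "condition", "segment", "measure",
                 "W", "p_value", "n_effective", "method")]
  rownames(out) <- NULL
  class(out) <- c("cohort_tests", class(out))
  out
}
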