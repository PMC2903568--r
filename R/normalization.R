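#' Estimate the power-transformation exponent from quantile symmetry
#'
#' The exponent \eqn{\lambda} is chosen so that the transformed score
#' distribution is symmetric around its median in the quantile sense:
#' \deqn{(T_{1-q}^\lambda + T_q^\lambda)/2 = M^\lambda,}
#' where \eqn{M} is the sample median and \eqn{T_q, T_{1-q}} the lower and
#' upper q-th quantiles. The equation is solved numerically for
#' \eqn{\lambda \in [0.01, 5]}; with a grid of q levels (the default,
#' 0.05 to 0.45 in steps of 0.05) the estimate is the median of the per-q
#' solutions. Degenerate inputs (zero or non-positive median, coincident
#' quantiles) or a bracket without a sign change fall back to
#' \eqn{\lambda = 1} with a warning.
#'
#' @param scores Numeric vector of non-negative scores.
#' @param q Quantile level(s) in (0, 0.5).
#' @param interval Search bracket for the exponent.
#' @return The estimated exponent (a single number).
#' @export
estimate_lambda <- function(scores, q = seq(0.05, 0.45, by = 0.05),
                            interval = c(0.01, 5)) {
  stopifnot(all(q > 0 & q < 0.5))
  M <- stats::median(scores)
  if (!is.finite(M) || M <= 0) {
    warning("non-positive median; falling back to lambda = 1")
    return(1)
  }
  sols <- numeric(0)
  for (qq in q) {
    Tq <- unname(stats::quantile(scores, qq))
    T1q <- unname(stats::quantile(scores, 1 - qq))
    if (T1q == Tq) next # flat tails carry no asymmetry information
    f <- function(l) (T1q^l + Tq^l) / 2 - M^l
    flo <- f(interval[1L]); fhi <- f(interval[2L])
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) next
    sols <- c(sols, stats::uniroot(f, interval, tol = 1e-9)$root)
  }
  if (length(sols) == 0L) {
    warning("no quantile-symmetry root in the bracket; falling back to lambda = 1")
    return(1)
  }
  stats::median(sols)
}

#' Power transformation of a score
#'
#' `score^lambda`; strictly increasing in the score for `lambda > 0`, so
#' ranks within a length combination are preserved.
#'
#' @param score Numeric vector of non-negative scores.
#' @param lambda Positive exponent.
#' @return Transformed scores.
#' @export
power_transform <- function(score, lambda) {
  stopifnot(lambda > 0, all(score >= 0))
  score^lambda
}

#' Kolmogorov-Smirnov normality check
#'
#' Tests whether a sample is consistent with a normal distribution whose
#' mean and SD are estimated from the same sample. Because estimating the
#' parameters makes the plain KS test anti-conservative, the default applies
#' the Lilliefors correction ([nortest::lillie.test()]); `lilliefors =
#' FALSE` runs the naive one-sample KS test against
#' `N(mean(scores), sd(scores))` instead.
#'
#' @param scores Numeric sample (at least 20 values recommended).
#' @param alpha Significance level for the pass flag, default 0.1.
#' @param lilliefors Apply the Lilliefors correction (default `TRUE`).
#' @return List with `p` and `pass` (`pass` iff `p >= alpha`).
#' @export
ks_normality <- function(scores, alpha = 0.1, lilliefors = TRUE) {
  if (length(scores) < 4L) stop("need at least 4 observations")
  if (length(scores) < 20L) {
    warning("fewer than 20 observations; the normality check is weak")
  }
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) return(list(p = 0, pass = FALSE))
  p <- if (lilliefors) {
    suppressWarnings(nortest::lillie.test(scores)$p.value)
  } else {
    suppressWarnings(
      stats::ks.test(scores, "pnorm", mean(scores), s)$p.value
    )
  }
  list(p = p, pass = p >= alpha)
}

#' Fit the normalization lookup table from null samples
#'
#' For every length-combination cell of the null: estimate the power
#' exponent by quantile symmetry, transform the cell's scores, and record
#' the raw median (`m_ss`), the transformed median and SD (`m_tss`,
#' `std_tss`), and the KS normality result of the transformed sample.
#' Zero-inflated cells (non-positive raw median) and constant cells are
#' flagged `degenerate` and kept with `lambda = 1`, so normalization can
#' still center and scale them. `lambda` may also be forced to a fixed
#' exponent, or to `"log"` for the logarithmic comparator transform (cells
#' with non-positive scores are then flagged degenerate and left
#' untransformable).
#'
#' @param null A [build_null()] result.
#' @param measure One measure name present in `null`.
#' @param q Quantile grid passed to [estimate_lambda()].
#' @param alpha KS significance level, default 0.1.
#' @param lilliefors Use the Lilliefors-corrected KS test (default `TRUE`).
#' @param lambda `"estimate"` (default), a fixed positive/negative number,
#'   or `"log"`.
#' @return Object of class `null_table`: a data.frame with one row per cell
#'   (`L1`, `L2`, `lambda`, `m_ss`, `m_tss`, `std_tss`, `ks_p`, `ks_pass`,
#'   `degenerate`) with attributes `measure`, `alpha` and `pass_fraction`
#'   (share of non-degenerate cells whose transformed scores pass the KS
#'   check).
#' @export
fit_null_table <- function(null, measure, q = seq(0.05, 0.45, by = 0.05),
                           alpha = 0.1, lilliefors = TRUE,
                           lambda = "estimate") {
  stopifnot(measure %in% null$measures)
  rows <- lapply(null$cells, function(cell) {
    s <- cell$scores[, measure]
    m_ss <- stats::median(s)
    degenerate <- FALSE
    lam <- NA_real_
    if (identical(lambda, "log")) {
      if (any(s <= 0)) {
        return(data.frame(L1 = cell$L1, L2 = cell$L2, lambda = NA_real_,
                          m_ss = m_ss, m_tss = NA_real_, std_tss = NA_real_,
                          ks_p = NA_real_, ks_pass = NA, degenerate = TRUE))
      }
      t <- log(s)
    } else {
      if (m_ss <= 0 || length(unique(s)) == 1L) {
        degenerate <- TRUE
        lam <- 1
      } else if (identical(lambda, "estimate")) {
        lam <- suppressWarnings(estimate_lambda(s, q = q))
      } else {
        lam <- lambda
        if (lam < 0 && any(s <= 0)) {
          return(data.frame(L1 = cell$L1, L2 = cell$L2, lambda = lam,
                            m_ss = m_ss, m_tss = NA_real_, std_tss = NA_real_,
                            ks_p = NA_real_, ks_pass = NA, degenerate = TRUE))
        }
      }
      t <- s^lam
    }
    m_tss <- stats::median(t)
    std_tss <- stats::sd(t)
    if (!is.finite(std_tss) || std_tss == 0) {
      degenerate <- TRUE
      ks <- list(p = NA_real_, pass = NA)
    } else {
      ks <- ks_normality(t, alpha = alpha, lilliefors = lilliefors)
    }
    data.frame(L1 = cell$L1, L2 = cell$L2,
               lambda = if (identical(lambda, "log")) NA_real_ else lam,
               m_ss = m_ss, m_tss = m_tss, std_tss = std_tss,
               ks_p = ks$p, ks_pass = ks$pass, degenerate = degenerate)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  usable <- !tab$degenerate
  pass_fraction <- if (any(usable)) mean(tab$ks_pass[usable]) else NA_real_
  structure(tab, measure = measure, alpha = alpha,
            transform = if (identical(lambda, "log")) "log" else "power",
            pass_fraction = pass_fraction,
            class = c("null_table", "data.frame"))
}

#' @export
print.null_table <- function(x, ...) {
  cat(sprintf("null_table for %s: %d cells, KS pass fraction %.3f\n",
              attr(x, "measure"), nrow(x), attr(x, "pass_fraction")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Normality pass fractions for the power transform and simple comparators
#'
#' Refits the null table under the estimated-exponent power transform, the
#' identity, the fixed exponents 1/3, 1/2, 2 and -1, and the log transform,
#' and reports the fraction of cells whose transformed null scores pass the
#' KS normality check — the summary used to judge whether a measure is
#' normalizable at all. Transforms undefined on a cell (log or inverse with
#' non-positive scores) skip that cell.
#'
#' @param null A [build_null()] result.
#' @param measure One measure name.
#' @param ... Passed to [fit_null_table()] (e.g. `alpha`, `lilliefors`).
#' @return data.frame with columns `transform` and `pass_fraction`.
#' @export
transform_comparison <- function(null, measure, ...) {
  specs <- list(power_estimated = "estimate", identity = 1,
                cube_root = 1 / 3, square_root = 1 / 2, square = 2,
                inverse = -1, log = "log")
  do.call(rbind, lapply(names(specs), function(nm) {
    tab <- suppressWarnings(
      fit_null_table(null, measure, lambda = specs[[nm]], ...)
    )
    data.frame(transform = nm,
               pass_fraction = attr(tab, "pass_fraction"),
               row.names = NULL)
  }))
}

#' Normalize raw similarity scores against the null table
#'
#' The normalized similarity score (NSS) of a raw score with length
#' combination `(L1, L2)` is
#' \deqn{NSS = (raw^{\hat\lambda} - M_{TSS}) / STD_{TSS},}
#' the z-score of the power-transformed raw score within its cell's
#' transformed null distribution. The NSS is length-comparable: a value of
#' 0 means "no more similar than random term groups of the same annotation
#' lengths". Length combinations outside the modeled grid are clamped to
#' the nearest modeled cell with a warning.
#'
#' @param raw Numeric vector of raw scores.
#' @param L1,L2 Annotation lengths (vectors recycled against `raw`).
#' @param table A [fit_null_table()] result (power transform).
#' @return Numeric vector of normalized scores.
#' @export
normalize_score <- function(raw, L1, L2, table) {
  stopifnot(inherits(table, "null_table"))
  if (identical(attr(table, "transform"), "log")) {
    stop("normalize_score requires a power-transform null table")
  }
  nn <- max(length(raw), length(L1), length(L2))
  raw <- rep_len(raw, nn); L1 <- rep_len(as.integer(L1), nn)
  L2 <- rep_len(as.integer(L2), nn)
  lo <- pmin(L1, L2); hi <- pmax(L1, L2)
  key <- paste0(lo, ",", hi)
  tabkey <- paste0(table$L1, ",", table$L2)
  row <- match(key, tabkey)
  if (anyNA(row)) {
    # clamp unmodeled combinations to the nearest modeled cell
    miss <- which(is.na(row))
    for (i in miss) {
      dist <- abs(table$L1 - lo[i]) + abs(table$L2 - hi[i])
      row[i] <- which.min(dist) # ties: first (smallest) cell
    }
    warning(length(miss), " score(s) with unmodeled length combination(s) ",
            "clamped to the nearest null cell")
  }
  bad <- !is.finite(table$std_tss[row]) | table$std_tss[row] <= 0
  if (any(bad)) stop("degenerate null cell(s) with zero spread; cannot normalize")
  (raw^table$lambda[row] - table$m_tss[row]) / table$std_tss[row]
}

#' Bias audit of normalized scores
#'
#' The counterpart of [bias_report()] after normalization: every equal-size
#' null cell's scores are normalized through the fitted table and the
#' Spearman correlation of the per-size median NSS against size is
#' reported. Applied to held-out null samples, a correlation near zero
#' demonstrates that the length dependence has been removed.
#'
#' @param null A [build_null()] result (typically held-out samples drawn
#'   with a different seed than the table's training samples).
#' @param table A [fit_null_table()] result.
#' @return A `bias_report` (one row; the table's measure).
#' @export
normalized_bias_report <- function(null, table) {
  measure <- attr(table, "measure")
  equal <- Filter(function(cell) cell$L1 == cell$L2, null$cells)
  if (length(equal) < 3L) stop("need equal-size cells for at least 3 sizes")
  sizes <- vapply(equal, `[[`, 0L, "L1")
  med <- vapply(equal, function(cell) {
    stats::median(normalize_score(cell$scores[, measure], cell$L1, cell$L2,
                                  table))
  }, 0)
  sds <- vapply(equal, function(cell) {
    stats::sd(normalize_score(cell$scores[, measure], cell$L1, cell$L2, table))
  }, 0)
  st <- spearman_trend(sizes, med)
  prof <- data.frame(measure = measure, size = sizes, median = med, sd = sds,
                     row.names = NULL)
  structure(data.frame(measure = measure, spearman_r = st$r, p_value = st$p,
                       row.names = NULL),
            profiles = prof, class = c("bias_report", "data.frame"))
}
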