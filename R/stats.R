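# Per-frequency group-comparison battery: central tendency, variability,
# effect sizes, and Benjamini-Hochberg control across frequencies.

#' Coefficient of variation
#' @param x numeric vector
#' @return sd(x) / mean(x)
#' @export
cv <- function(x) stats::sd(x) / mean(x)

#' Log variance ratio between two groups
#' @param a,b numeric vectors
#' @return `ln(var(a) / var(b))` (antisymmetric under group swap)
#' @export
lnvr <- function(a, b) log(stats::var(a) / stats::var(b))

#' Cohen's d with pooled standard deviation
#' @param a,b numeric vectors
#' @return standardized mean difference (antisymmetric under group swap)
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Benjamini-Hochberg adjustment with rejection set
#'
#' Step-up adjusted q-values and the rejection set at level `alpha`.
#'
#' @param pvals p-values in [0, 1]
#' @param alpha FDR level (default 0.05)
#' @return list: `q` (adjusted values), `reject` (logical)
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) return(list(q = numeric(0), reject = logical(0)))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Unpaired per-frequency comparison battery
#'
#' At each frequency: two-sided Mann-Whitney U test on central tendency,
#' Fligner-Killeen test on spread, per-group coefficient of variation,
#' log variance ratio, Cohen's d (pooled SD), and BH adjustment across
#' frequencies (separately for the central and variability families).
#'
#' @param a,b animal x frequency matrices (independent groups); columns are
#'   a common frequency grid
#' @param alpha BH level (default 0.05)
#' @return data.frame of class `comparison_report`: `freq`, `p_central`,
#'   `q_central`, `p_var`, `q_var`, `cv_a`, `cv_b`, `lnvr`, `cohen_d`
#' @export
compare_unpaired <- function(a, b, alpha = 0.05) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b))
  if (nrow(a) < 2 || nrow(b) < 2) {
    warning("group size < 2: tests skipped")
    return(data.frame(freq = col_freqs(a), p_central = NA, q_central = NA,
                      p_var = NA, q_var = NA, cv_a = NA, cv_b = NA,
                      lnvr = NA, cohen_d = NA))
  }
  nfreq <- ncol(a)
  p_c <- p_v <- cva <- cvb <- lv <- d <- numeric(nfreq)
  for (i in seq_len(nfreq)) {
    x <- a[, i]; y <- b[, i]
    p_c[i] <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    p_v[i] <- stats::fligner.test(list(x, y))$p.value
    cva[i] <- cv(x); cvb[i] <- cv(y)
    lv[i] <- lnvr(x, y); d[i] <- cohens_d(x, y)
  }
  out <- data.frame(freq = col_freqs(a), p_central = p_c,
                    q_central = bh_adjust(p_c, alpha)$q,
                    p_var = p_v, q_var = bh_adjust(p_v, alpha)$q,
                    cv_a = cva, cv_b = cvb, lnvr = lv, cohen_d = d)
  class(out) <- c("comparison_report", class(out))
  attr(out, "kind") <- "unpaired"
  out
}

#' Paired per-frequency comparison battery
#'
#' At each frequency: paired t test on central tendency, and a permutation
#' test on the log variance difference `T = ln var(a) - ln var(b)` where the
#' null is built by independently swapping each animal's condition pair (all
#' `2^n` assignments when n <= 12, otherwise `n_perm` seeded draws with
#' add-one smoothing); two-sided p is the proportion of `|T_perm| >= |T_obs|`.
#' CV, lnVR, Cohen's d and BH adjustment as in [compare_unpaired()].
#'
#' @param a,b animal x frequency matrices with identical animal order
#'   (rownames are checked when present)
#' @param alpha BH level
#' @param n_perm sampled permutations when exhaustive enumeration is too
#'   large (default 10000)
#' @param seed RNG seed for sampled permutations
#' @return data.frame of class `comparison_report`
#' @export
compare_paired <- function(a, b, alpha = 0.05, n_perm = 10000, seed = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(dim(a) == dim(b))
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("paired comparison requires identical animal order in both groups")
  }
  n <- nrow(a)
  if (n < 2) {
    warning("group size < 2: tests skipped")
    return(data.frame(freq = col_freqs(a), p_central = NA, q_central = NA,
                      p_var = NA, q_var = NA, cv_a = NA, cv_b = NA,
                      lnvr = NA, cohen_d = NA))
  }
  nfreq <- ncol(a)
  p_c <- p_v <- cva <- cvb <- lv <- d <- numeric(nfreq)
  swaps <- if (n <= 12) {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  } else NULL
  for (i in seq_len(nfreq)) {
    x <- a[, i]; y <- b[, i]
    p_c[i] <- if (stats::sd(x - y) == 0) 1 else stats::t.test(x, y,
                                                              paired = TRUE)$p.value
    p_v[i] <- perm_logvar_p(x, y, swaps, n_perm, seed + i)
    cva[i] <- cv(x); cvb[i] <- cv(y)
    lv[i] <- lnvr(x, y); d[i] <- cohens_d(x, y)
  }
  out <- data.frame(freq = col_freqs(a), p_central = p_c,
                    q_central = bh_adjust(p_c, alpha)$q,
                    p_var = p_v, q_var = bh_adjust(p_v, alpha)$q,
                    cv_a = cva, cv_b = cvb, lnvr = lv, cohen_d = d)
  class(out) <- c("comparison_report", class(out))
  attr(out, "kind") <- "paired"
  out
}

# Two-sided permutation p for T = ln var(x) - ln var(y) under per-animal
# condition swaps. `swaps` is the exhaustive assignment matrix or NULL.
perm_logvar_p <- function(x, y, swaps = NULL, n_perm = 10000, seed = 1) {
  n <- length(x)
  t_obs <- log(stats::var(x)) - log(stats::var(y))
  if (!is.finite(t_obs)) return(NA_real_)
  t_stats <- function(S) {                     # S: n x P swap indicator
    A <- x * (1 - S) + y * S
    B <- y * (1 - S) + x * S
    va <- (colSums(A^2) - colSums(A)^2 / n) / (n - 1)
    vb <- (colSums(B^2) - colSums(B)^2 / n) / (n - 1)
    log(va) - log(vb)
  }
  if (!is.null(swaps)) {
    tp <- t_stats(t(swaps) * 1)
    mean(abs(tp) >= abs(t_obs) - 1e-12)
  } else {
    tp <- with_seed(seed,
                    t_stats(matrix(stats::runif(n * n_perm) < 0.5, n) * 1))
    (1 + sum(abs(tp) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  }
}

#' Shapiro-Wilk normality report
#'
#' Reports W and p per frequency. The report is informational: the battery's
#' stated tests are run regardless of the outcome.
#'
#' @param values numeric vector (one frequency) or matrix (animal x frequency)
#' @return data.frame (`freq`, `W`, `p`, `skipped`)
#' @export
shapiro_gate <- function(values) {
  values <- as.matrix(values)
  out <- lapply(seq_len(ncol(values)), function(i) {
    x <- values[, i]
    if (length(x) < 3 || stats::sd(x) == 0) {
      return(data.frame(freq = i, W = NA_real_, p = NA_real_, skipped = TRUE))
    }
    s <- stats::shapiro.test(x)
    data.frame(freq = i, W = unname(s$statistic), p = s$p.value,
               skipped = FALSE)
  })
  out <- do.call(rbind, out)
  out$freq <- col_freqs(values)
  out
}

col_freqs <- function(m) {
  cn <- colnames(m)
  if (is.null(cn)) seq_len(ncol(m)) else suppressWarnings({
    v <- as.numeric(cn)
    if (anyNA(v)) seq_len(ncol(m)) else v
  })
}
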