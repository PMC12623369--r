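# Graph metrics on PLV matrices and mixed-model analysis of eigenvector
# centrality against sleep duration.

CANONICAL_BANDS <- data.frame(
  band = c("delta", "theta", "alpha", "beta", "gamma"),
  lo = c(0.5, 4, 8, 12, 30),
  hi = c(4, 8, 12, 30, 100)
)

#' Eigenvector centrality of a connectivity matrix
#'
#' Leading eigenvector of the symmetric non-negative PLV matrix (diagonal
#' zeroed), computed by power iteration to `tol`; entries are non-negative
#' and the vector has unit L2 norm. A disconnected matrix is handled
#' per connected component (each component's subvector unit-normalized) with
#' a warning.
#'
#' @param mat symmetric non-negative matrix (channel x channel)
#' @param tol convergence tolerance (default 1e-10)
#' @param max_iter iteration cap
#' @return named numeric vector of centralities
#' @export
evc <- function(mat, tol = 1e-10, max_iter = 10000) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-8) stop("matrix must be symmetric")
  if (min(mat) < 0) stop("matrix must be non-negative")
  diag(mat) <- 0
  n <- nrow(mat)
  comp <- connected_components(mat > 0)
  if (length(unique(comp)) > 1) {
    warning("disconnected matrix: eigenvector centrality per component")
  }
  out <- numeric(n)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1) { out[idx] <- 1; next }
    out[idx] <- power_iteration(mat[idx, idx, drop = FALSE], tol, max_iter)
  }
  names(out) <- rownames(mat)
  out
}

power_iteration <- function(M, tol, max_iter) {
  n <- nrow(M)
  # positive diagonal shift: keeps eigenvectors, makes the leading
  # eigenvalue strictly dominant (bipartite graphs otherwise oscillate)
  shift <- max(rowSums(abs(M)))
  if (shift == 0) return(rep(1 / sqrt(n), n))
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.vector(M %*% v) + shift * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(v)
    w <- w / nw
    if (sqrt(sum((w - v)^2)) < tol) { v <- w; break }
    v <- w
  }
  if (sum(v) < 0) v <- -v
  abs(v) / sqrt(sum(v^2))
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Band-averaged PLV matrices
#'
#' Averages the frequency-resolved PLV matrices over the bank frequencies
#' whose centers fall inside each canonical band (delta 0.5-4, theta 4-8,
#' alpha 8-12, beta 12-30, gamma 30-100 Hz; lower edge inclusive).
#'
#' @param plvres a `plv_result` from [plv_pipeline()]
#' @param bands data.frame (`band`, `lo`, `hi`); defaults to the canonical set
#' @return named list of channel x channel matrices
#' @export
band_average_plv <- function(plvres, bands = CANONICAL_BANDS) {
  out <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- plvres$freqs >= bands$lo[i] & plvres$freqs < bands$hi[i]
    if (!any(sel)) return(NULL)
    apply(plvres$matrices[, , sel, drop = FALSE], c(1, 2), mean)
  })
  names(out) <- bands$band
  out[!vapply(out, is.null, logical(1))]
}

#' Per-channel centrality table for one session
#'
#' Computes eigenvector centrality of the band-averaged PLV matrix
#' restricted to each region, and attaches the session's normalized SWS
#' duration. Rows are (animal, condition, region, band, channel).
#'
#' @param plvres a `plv_result`
#' @param hyp the session `hypnogram`
#' @param animal animal identifier
#' @param condition condition label (e.g. `"NOLESION"`, `"D7"`, `"D14"`)
#' @param bands band definition (default canonical)
#' @return data.frame with columns `animal`, `condition`, `region`, `band`,
#'   `channel`, `evc`, `sqrt_evc`, `norm_sws_duration`
#' @export
centrality_table <- function(plvres, hyp, animal, condition,
                             bands = CANONICAL_BANDS) {
  dur <- sws_duration(hyp)$normalized
  bm <- band_average_plv(plvres, bands)
  rows <- list()
  for (b in names(bm)) {
    for (r in unique(plvres$region_of)) {
      sel <- names(plvres$region_of)[plvres$region_of == r]
      if (length(sel) < 2) next
      v <- evc(bm[[b]][sel, sel, drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        animal = animal, condition = condition, region = r, band = b,
        channel = sel, evc = unname(v), sqrt_evc = sqrt(unname(v)),
        norm_sws_duration = dur)
    }
  }
  do.call(rbind, rows)
}

#' Mixed-model slopes of centrality against sleep duration
#'
#' Per (region, band), fits `sqrt_evc ~ norm_sws_duration * condition` with a
#' random intercept per animal (random slopes are unidentifiable with a
#' handful of animals) and extracts the per-condition slope of centrality on
#' normalized SWS duration via `emmeans::emtrends`, plus pairwise slope
#' contrasts between conditions. With a single condition the interaction is
#' dropped. A singular or failing mixed fit falls back to ordinary least
#' squares with a message. Slope p-values are Benjamini-Hochberg adjusted
#' across bands and conditions within each region.
#'
#' @param tab a centrality table ([centrality_table()] rows, possibly many
#'   sessions bound together)
#' @param alpha BH level used for the rejection flag (default 0.05)
#' @return list: `slopes` data.frame (`region`, `band`, `condition`,
#'   `slope`, `se`, `df`, `t`, `p`, `p_adj`), `contrasts` data.frame
#' @export
fit_sleep_centrality <- function(tab, alpha = 0.05) {
  stopifnot(all(c("animal", "condition", "region", "band", "sqrt_evc",
                  "norm_sws_duration") %in% names(tab)))
  tab$animal <- factor(tab$animal)
  tab$condition <- factor(tab$condition)
  if (nlevels(tab$animal) < 2) stop("need at least 2 animals")
  slopes <- list(); contrasts <- list()
  for (r in unique(tab$region)) {
    for (b in unique(tab$band)) {
      d <- tab[tab$region == r & tab$band == b, , drop = FALSE]
      if (nrow(d) < 4 || length(unique(d$norm_sws_duration)) < 2) next
      multi <- nlevels(droplevels(d$condition)) > 1
      d$condition <- droplevels(d$condition)
      form <- if (multi) {
        sqrt_evc ~ norm_sws_duration * condition + (1 | animal)
      } else {
        sqrt_evc ~ norm_sws_duration + (1 | animal)
      }
      fit <- tryCatch({
        m <- lmerTest::lmer(form, data = d,
                            control = lme4::lmerControl(
                              check.conv.singular = "ignore"))
        m
      }, error = function(e) NULL)
      if (is.null(fit)) {
        message("mixed fit failed for ", r, "/", b,
                ": falling back to ordinary least squares")
        fit <- stats::lm(if (multi) {
          sqrt_evc ~ norm_sws_duration * condition
        } else sqrt_evc ~ norm_sws_duration, data = d)
      }
      tr <- emmeans::emtrends(fit, if (multi) ~condition else ~1,
                              var = "norm_sws_duration")
      ts <- as.data.frame(summary(tr, infer = c(FALSE, TRUE)))
      est_col <- grep("trend", names(ts), value = TRUE)[1]
      slopes[[length(slopes) + 1]] <- data.frame(
        region = r, band = b,
        condition = if (multi) as.character(ts$condition) else
          as.character(unique(d$condition)),
        slope = ts[[est_col]], se = ts$SE, df = ts$df,
        t = ts$t.ratio, p = ts$p.value)
      if (multi) {
        pc <- as.data.frame(summary(graphics::pairs(tr)))
        contrasts[[length(contrasts) + 1]] <- data.frame(
          region = r, band = b, contrast = as.character(pc$contrast),
          estimate = pc$estimate, se = pc$SE, df = pc$df,
          t = pc$t.ratio, p = pc$p.value)
      }
    }
  }
  slopes <- do.call(rbind, slopes)
  if (!is.null(slopes)) {
    slopes$p_adj <- NA_real_
    for (r in unique(slopes$region)) {
      sel <- slopes$region == r
      slopes$p_adj[sel] <- stats::p.adjust(slopes$p[sel], method = "BH")
    }
    slopes$significant <- slopes$p_adj <= alpha
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else NULL
  list(slopes = slopes, contrasts = contrasts)
}
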