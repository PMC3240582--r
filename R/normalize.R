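#' Depth normalization to 10 million tags
#'
#' Multiplies every bin by `1e7 / tag_total` so tracks from libraries of
#' different depths are comparable. Idempotent: a track already normalized
#' is returned unchanged.
#'
#' @param track A `bin_track`.
#' @return The normalized `bin_track` (flagged `depth_normalized`).
#' @export
depth_normalize <- function(track) {
  stopifnot(inherits(track, "bin_track"))
  if (isTRUE(track$depth_normalized)) return(track)
  if (is.na(track$tag_total) || track$tag_total <= 0) {
    abort("tag_total must be positive for depth normalization")
  }
  f <- 1e7 / track$tag_total
  track$scores <- lapply(track$scores, function(s) s * f)
  track$depth_normalized <- TRUE
  track
}

# Shared histogram of two score vectors on common cells. Cells are labelled
# by their midpoint; `binwidth` defaults to Freedman-Diaconis on the control.
score_histograms <- function(exp_s, ctrl_s, binwidth = NULL) {
  if (is.null(binwidth)) {
    iqr <- stats::IQR(ctrl_s)
    binwidth <- 2 * iqr / length(ctrl_s)^(1 / 3)
    if (!is.finite(binwidth) || binwidth <= 0) {
      rng <- diff(range(c(exp_s, ctrl_s)))
      binwidth <- if (rng > 0) rng / 100 else 1
    }
  }
  lo <- min(exp_s, ctrl_s)
  cell <- function(s) floor((s - lo) / binwidth + 0.5)
  k_max <- max(cell(exp_s), cell(ctrl_s))
  ce <- tabulate(cell(exp_s) + 1L, nbins = k_max + 1L)
  cc <- tabulate(cell(ctrl_s) + 1L, nbins = k_max + 1L)
  tibble(score = lo + (0:k_max) * binwidth, exp = ce, ctrl = cc,
         occupied = ce + cc > 0)
}

#' Critical value separating shared noise from enrichment
#'
#' The right-most histogram crossing of the experimental and control
#' score-frequency curves: the largest score cell v with control count >=
#' experimental count such that every occupied cell above v has
#' experimental count > control count. Scores at or below v are treated as
#' shared noise when fitting the noise normalizer.
#'
#' @param exp,ctrl Depth-normalized `bin_track`s (or bare score vectors).
#' @param binwidth Histogram cell width in score units (default:
#'   Freedman-Diaconis on the control scores).
#' @return The critical score value (cell midpoint).
#' @export
critical_value <- function(exp, ctrl, binwidth = NULL) {
  exp_s <- if (inherits(exp, "bin_track")) all_scores(exp) else exp
  ctrl_s <- if (inherits(ctrl, "bin_track")) all_scores(ctrl) else ctrl
  if (length(exp_s) == 0 || length(ctrl_s) == 0) abort("empty score vectors")
  h <- score_histograms(exp_s, ctrl_s, binwidth)
  h <- h[h$occupied, , drop = FALSE]
  if (nrow(h) == 0 || all(h$exp == h$ctrl)) {
    abort("score histograms are identical: datasets are incomparable (no crossing)",
          class = "chipscore_no_crossing")
  }
  exp_dom_above <- rev(cumprod(rev(h$exp > h$ctrl)))  # 1 if all cells above+at are exp-dominant
  ok <- h$ctrl >= h$exp &
    c(exp_dom_above[-1], 1) == 1
  if (!any(ok)) {
    abort("experimental and control score curves never cross",
          class = "chipscore_no_crossing")
  }
  h$score[max(which(ok))]
}

#' Noise normalizer for background subtraction
#'
#' Finds the factor c by which experimental scores are multiplied so that
#' the sub-critical (noise) parts of the experimental and control score
#' histograms agree: a grid search maximizing the Pearson correlation of
#' the two histograms, centered on the ratio X/Y of the control and
#' experimental modal histogram scores. Both estimates are reported; if the
#' sub-critical histograms are degenerate the X/Y ratio (or 1) is used with
#' a warning.
#'
#' @inheritParams critical_value
#' @param critical Critical value from [critical_value()].
#' @param grid_span,grid_n Multiplicative grid around X/Y: `grid_n` points
#'   spanning `[ratio/grid_span, ratio*grid_span]`.
#' @return A `noise_normalization` list: `c`, `method` ("correlation-max"
#'   or "ratio"), `ratio`, `X`, `Y`, `critical`.
#' @export
noise_normalizer <- function(exp, ctrl, critical, binwidth = NULL,
                             grid_span = 5, grid_n = 201) {
  exp_s <- if (inherits(exp, "bin_track")) all_scores(exp) else exp
  ctrl_s <- if (inherits(ctrl, "bin_track")) all_scores(ctrl) else ctrl

  modal_score <- function(s) {
    if (length(s) == 0) return(NA_real_)
    h <- score_histograms(s, s, binwidth)
    h$score[which.max(h$exp)]
  }
  # X, Y: the score locations of the two histogram peaks
  X <- modal_score(ctrl_s)
  Y <- modal_score(exp_s)
  ratio <- if (is.finite(X) && is.finite(Y) && Y > 0) X / Y else NA_real_

  sub_c <- ctrl_s[ctrl_s <= critical]
  degenerate <- length(unique(round(exp_s[exp_s <= critical], 10))) < 3 ||
    length(unique(round(sub_c, 10))) < 3
  if (degenerate) {
    c_hat <- if (is.finite(ratio) && ratio > 0) ratio else 1
    warn("sub-critical score histograms are degenerate; falling back to the X/Y ratio estimate")
    return(structure(list(c = c_hat, method = "ratio", ratio = ratio,
                          X = X, Y = Y, critical = critical),
                     class = "noise_normalization"))
  }

  center <- if (is.finite(ratio) && ratio > 0) ratio else 1
  grid <- center * exp(seq(log(1 / grid_span), log(grid_span),
                           length.out = grid_n))
  # compare histogram cells below the critical value: the scaled
  # experimental histogram (of all scores) against the control histogram
  iqr <- stats::IQR(sub_c)
  bw <- binwidth %||% max(2 * iqr / length(sub_c)^(1 / 3), 1e-9)
  n_keep <- max(3L, as.integer(ceiling(critical / bw)))
  hc <- tabulate(pmin(floor(ctrl_s / bw) + 1L, n_keep + 1L),
                 nbins = n_keep + 1L)[seq_len(n_keep)]
  score_cor <- vapply(grid, function(cc) {
    he <- tabulate(pmin(floor(cc * exp_s / bw) + 1L, n_keep + 1L),
                   nbins = n_keep + 1L)[seq_len(n_keep)]
    if (sd(he) == 0 || sd(hc) == 0) return(-Inf)
    cor(he, hc)
  }, numeric(1))
  if (all(!is.finite(score_cor))) {
    c_hat <- if (is.finite(ratio) && ratio > 0) ratio else 1
    warn("noise histogram correlation undefined on the grid; using the X/Y ratio estimate")
    return(structure(list(c = c_hat, method = "ratio", ratio = ratio,
                          X = X, Y = Y, critical = critical),
                     class = "noise_normalization"))
  }
  structure(list(c = grid[which.max(score_cor)], method = "correlation-max",
                 ratio = ratio, X = X, Y = Y, critical = critical),
            class = "noise_normalization")
}

#' @export
print.noise_normalization <- function(x, ...) {
  cat("<noise_normalization> c =", signif(x$c, 4), "(", x$method, ")",
      " X/Y ratio =", signif(x$ratio, 4),
      " critical =", signif(x$critical, 4), "\n")
  invisible(x)
}

#' Background subtraction
#'
#' Adjusted score per bin: `max(0, c * exp - ctrl)` with c the noise
#' normalizer. Both tracks must be depth-normalized and share the bin
#' layout.
#'
#' @inheritParams critical_value
#' @param norm A [noise_normalizer()] result, or a bare numeric c.
#' @return A `bin_track` of adjusted scores (mark/mode inherited from
#'   `exp`), carrying the normalization as attribute `norm`.
#' @export
subtract_background <- function(exp, ctrl, norm) {
  stopifnot(inherits(exp, "bin_track"), inherits(ctrl, "bin_track"))
  if (!identical(lapply(exp$scores, length), lapply(ctrl$scores, length))) {
    abort("experimental and control tracks have mismatched bin layouts")
  }
  cc <- if (inherits(norm, "noise_normalization")) norm$c else as.numeric(norm)
  out <- exp
  out$scores <- purrr::map2(exp$scores, ctrl$scores,
                            function(e, c0) pmax(0, cc * e - c0))
  attr(out, "norm") <- norm
  out
}

#' Empirical FDR thresholding of adjusted scores
#'
#' For a candidate adjusted score s the false discovery rate is estimated
#' as the number of null bins at or above s (bins the control indicates
#' should occur by chance) over the number of experimental bins at or above
#' s. The curve is monotonized so it is non-increasing in s (each score is
#' assigned the worst raw ratio at or beyond it), and the reporting
#' threshold is the smallest s with FDR below `alpha` — the smallest score
#' beyond which the estimated FDR always stays below the level. Bins below
#' the threshold are zeroed in the reported track.
#'
#' The null adjusted scores are produced by the role-swapped subtraction
#' `max(0, ctrl - c * exp)` (see [null_adjusted()]), an empirical exchange
#' null.
#'
#' @param exp_adj Adjusted experimental `bin_track` (from
#'   [subtract_background()]) or numeric scores.
#' @param null_adj Null adjusted `bin_track` or numeric scores.
#' @param alpha FDR control level (default 0.001).
#' @return An `fdr_track`: list with `track` (reported bin_track, sub-
#'   threshold bins zeroed), `adjusted` (unthresholded scores), `curve`
#'   (tibble: score, fdr_raw, fdr), `threshold` (Inf, flagged, when no
#'   score reaches the level), `alpha`.
#' @export
fdr_threshold <- function(exp_adj, null_adj, alpha = 0.001) {
  e <- if (inherits(exp_adj, "bin_track")) all_scores(exp_adj) else exp_adj
  nl <- if (inherits(null_adj, "bin_track")) all_scores(null_adj) else null_adj
  s_grid <- sort(unique(e[e > 0]))
  if (length(s_grid) == 0) {
    warn("no positive adjusted scores: nothing to report")
    return(structure(list(track = zero_track(exp_adj), adjusted = exp_adj,
                          curve = tibble(score = numeric(),
                                         fdr_raw = numeric(), fdr = numeric()),
                          threshold = Inf, alpha = alpha),
                     class = "fdr_track"))
  }
  se <- sort(e); sn <- sort(nl)
  # exact count of values >= s: left-open intervals put ties below the cut
  n_ge <- function(sorted, s) {
    length(sorted) - findInterval(s, sorted, left.open = TRUE)
  }
  ne <- n_ge(se, s_grid)
  nn <- n_ge(sn, s_grid)
  fdr_raw <- nn / ne
  fdr <- rev(cummax(rev(fdr_raw)))
  curve <- tibble(score = s_grid, fdr_raw = fdr_raw, fdr = fdr)
  idx <- which(fdr < alpha)
  threshold <- if (length(idx) > 0) s_grid[min(idx)] else Inf
  if (!is.finite(threshold)) {
    warn("no adjusted score reaches the requested FDR level; threshold undefined")
  }
  reported <- exp_adj
  if (inherits(exp_adj, "bin_track")) {
    reported$scores <- lapply(exp_adj$scores,
                              function(s) ifelse(s >= threshold, s, 0))
  }
  structure(list(track = reported, adjusted = exp_adj, curve = curve,
                 threshold = threshold, alpha = alpha),
            class = "fdr_track")
}

zero_track <- function(tr) {
  if (!inherits(tr, "bin_track")) return(tr)
  tr$scores <- lapply(tr$scores, function(s) s * 0)
  tr
}

#' @export
print.fdr_track <- function(x, ...) {
  n_called <- if (inherits(x$track, "bin_track")) {
    sum(all_scores(x$track) > 0)
  } else NA_integer_
  cat("<fdr_track> alpha =", x$alpha, " threshold =",
      signif(x$threshold, 4), " bins reported:", n_called, "\n")
  invisible(x)
}

#' Null adjusted scores by role-swapped subtraction
#'
#' @inheritParams subtract_background
#' @return A `bin_track` of `max(0, ctrl - c * exp)`.
#' @export
null_adjusted <- function(exp, ctrl, norm) {
  cc <- if (inherits(norm, "noise_normalization")) norm$c else as.numeric(norm)
  out <- ctrl
  out$scores <- purrr::map2(exp$scores, ctrl$scores,
                            function(e, c0) pmax(0, c0 - cc * e))
  out
}

#' Full normalization pipeline for one experimental/control pair
#'
#' Depth normalization, critical value, noise normalizer, background
#' subtraction, exchange-null construction, and FDR thresholding.
#'
#' @inheritParams critical_value
#' @inheritParams fdr_threshold
#' @param c_override Optional fixed noise normalizer (skips critical-value
#'   and histogram fitting; appropriate when the experimental library has
#'   no genuine shared noise floor with the control).
#' @return An `fdr_track` (see [fdr_threshold()]), with the
#'   `noise_normalization` attached as `$norm`.
#' @export
normalize_pair <- function(exp, ctrl, alpha = 0.001, binwidth = NULL,
                           c_override = NULL) {
  exp <- depth_normalize(exp)
  ctrl <- depth_normalize(ctrl)
  norm <- if (!is.null(c_override)) {
    structure(list(c = c_override, method = "fixed", ratio = NA_real_,
                   X = NA_real_, Y = NA_real_, critical = NA_real_),
              class = "noise_normalization")
  } else {
    crit <- critical_value(exp, ctrl, binwidth)
    noise_normalizer(exp, ctrl, crit, binwidth)
  }
  adj <- subtract_background(exp, ctrl, norm)
  nul <- null_adjusted(exp, ctrl, norm)
  out <- fdr_threshold(adj, nul, alpha)
  out$norm <- norm
  out
}

#' Merged regions of reported (above-threshold) bins
#'
#' @param x An `fdr_track`.
#' @return Tibble of 0-based half-open regions (`chrom`, `start`, `end`)
#'   covering maximal runs of reported bins.
#' @export
call_regions <- function(x) {
  stopifnot(inherits(x, "fdr_track"), inherits(x$track, "bin_track"))
  bin <- x$track$bin
  purrr::imap(x$track$scores, function(s, chrom) {
    r <- rle(s > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    tibble(chrom = chrom, start = starts[keep] * bin,
           end = pmin(ends[keep] * bin, length(s) * bin))
  }) %>% bind_rows()
}
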