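feature_levels <- c("transposon", "cds", "utr5", "utr3", "intron",
                    "intergenic")

#' Bin-level genomic feature map
#'
#' Labels every 50-bp bin with one of transposon/repeat, CDS, 5' UTR,
#' 3' UTR, intron, intergenic. Labels are exclusive under the precedence
#' transposon > CDS > 5'UTR > 3'UTR > intron > intergenic: a bin takes the
#' highest-precedence category it overlaps at all (precedence beats
#' majority), so per-percentile compositions sum to 100%.
#'
#' @param genes Gene tibble (as in a `synthetic_world`), or a world.
#' @param transposons Transposon-copy tibble (ignored when a world is given).
#' @param layout Named chromosome lengths (ignored when a world is given).
#' @param bin Bin width (default 50).
#' @return A `feature_map`: list with `bins` (per-chromosome factor-coded
#'   integer vectors), `levels`, `fractions` (genome-wide bin fractions).
#' @export
feature_map <- function(genes, transposons = NULL, layout = NULL, bin = 50L) {
  if (inherits(genes, "synthetic_world")) {
    world <- genes
    genes <- world$genes; transposons <- world$transposons
    layout <- world$layout
  }
  nb <- ceiling(layout / bin)
  bins <- lapply(nb, function(n) rep(6L, n))  # intergenic

  paint <- function(bins, df, code) {
    if (is.null(df) || nrow(df) == 0) return(bins)
    for (chrom in unique(df$chrom)) {
      d <- df[df$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        b0 <- d$start[i] %/% bin
        b1 <- (d$end[i] - 1L) %/% bin
        rng <- (b0:b1) + 1L
        rng <- rng[rng >= 1 & rng <= length(bins[[chrom]])]
        bins[[chrom]][rng] <- pmin(bins[[chrom]][rng], code)
      }
    }
    bins
  }

  if (!is.null(genes) && nrow(genes) > 0) {
    sub <- gene_subfeatures(genes)
    code <- c(cds = 2L, utr5 = 3L, utr3 = 4L, intron = 5L)
    # paint low precedence first so pmin keeps the strongest label
    for (ty in c("intron", "utr3", "utr5", "cds")) {
      bins <- paint(bins, sub[sub$type == ty, , drop = FALSE], code[[ty]])
    }
  }
  bins <- paint(bins, transposons, 1L)

  tab <- tabulate(unlist(bins), nbins = 6L)
  structure(list(bins = bins, levels = feature_levels,
                 fractions = setNames(tab / sum(tab), feature_levels),
                 bin = as.integer(bin)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat("<feature_map>", sum(lengths(x$bins)), "bins;",
      paste(x$levels, round(100 * x$fractions, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

check_same_layout <- function(track, fmap) {
  if (!identical(lapply(track$scores, length), lapply(fmap$bins, length))) {
    abort("track and feature map have mismatched bin layouts")
  }
}

# stable ascending order of bins by score, ties by genomic position
ordered_bins <- function(track, fmap) {
  s <- all_scores(track)
  lab <- unlist(fmap$bins, use.names = FALSE)
  tibble(score = s, feature = feature_levels[lab])[order(s), , drop = FALSE]
}

#' Feature composition of score percentiles
#'
#' Bins are ranked ascending by score, split into `n` equal-count groups
#' (ties broken by genomic order), and each group's percentage of bins per
#' feature label is reported against the genome-wide baseline.
#'
#' @param track A `bin_track`.
#' @param fmap A [feature_map()] on the same layout.
#' @param n Number of percentiles (default 100).
#' @return Tibble (`percentile`, `feature`, `percentage`) with the
#'   genome-wide percentages as attribute `baseline`; class
#'   `percentile_composition`.
#' @export
percentile_composition <- function(track, fmap, n = 100L) {
  check_same_layout(track, fmap)
  df <- ordered_bins(track, fmap)
  if (n > nrow(df)) abort("more percentiles than bins")
  df$percentile <- ceiling(seq_len(nrow(df)) * n / nrow(df))
  out <- df %>%
    count(.data$percentile, .data$feature) %>%
    group_by(.data$percentile) %>%
    mutate(percentage = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select("percentile", "feature", "percentage") %>%
    tidyr::complete(percentile = seq_len(n), feature = feature_levels,
                    fill = list(percentage = 0))
  attr(out, "baseline") <- 100 * fmap$fractions
  class(out) <- c("percentile_composition", class(out))
  out
}

#' Fraction of total track score per feature label
#'
#' @inheritParams percentile_composition
#' @return Named numeric vector of score fractions (summing to 1).
#' @export
score_fraction_by_feature <- function(track, fmap) {
  check_same_layout(track, fmap)
  s <- all_scores(track)
  tot <- sum(s)
  if (tot <= 0) abort("track has zero total score; fractions undefined")
  lab <- unlist(fmap$bins, use.names = FALSE)
  acc <- vapply(1:6, function(code) sum(s[lab == code]), numeric(1))
  setNames(acc / tot, feature_levels)
}

#' Transposon-class score totals and densities
#'
#' Per family: total track score over bins overlapping member copies,
#' total copy length, and density (score per bp).
#'
#' @param track A `bin_track`.
#' @param transposons Transposon-copy tibble (`family`, `chrom`, `start`,
#'   `end`), or a `synthetic_world`.
#' @return Tibble (`family`, `total_score`, `total_length`, `density`).
#' @export
transposon_class_density <- function(track, transposons) {
  if (inherits(transposons, "synthetic_world")) {
    transposons <- transposons$transposons
  }
  if (is.null(transposons) || nrow(transposons) == 0) {
    abort("transposon annotation is empty")
  }
  bin <- track$bin
  rows <- transposons %>%
    group_by(.data$family) %>%
    summarise(total_length = sum(.data$end - .data$start), .groups = "drop")
  if (any(rows$total_length <= 0)) abort("zero-length transposon class")
  score_of <- purrr::pmap_dbl(
    transposons[c("chrom", "start", "end")],
    function(chrom, start, end) {
      s <- track$scores[[chrom]]
      b0 <- start %/% bin; b1 <- (end - 1L) %/% bin
      sum(s[(b0:b1) + 1L], na.rm = TRUE)
    })
  tot <- tibble(family = transposons$family, score = score_of) %>%
    group_by(.data$family) %>%
    summarise(total_score = sum(.data$score), .groups = "drop")
  left_join(rows, tot, by = "family") %>%
    mutate(density = .data$total_score / .data$total_length) %>%
    select("family", "total_score", "total_length", "density")
}

#' Pairwise mark correlations over transposon-class densities
#'
#' Pearson r and p (t-transform, n - 2 df) between per-class densities of
#' each pair of marks.
#'
#' @param tables Named list of [transposon_class_density()] tibbles.
#' @return List with matrices `r` and `p` and a long tibble `pairs`.
#' @export
mark_correlation_matrix <- function(tables) {
  marks <- names(tables)
  stopifnot(length(marks) >= 2)
  classes <- sort(unique(unlist(lapply(tables, function(t) t$family))))
  if (length(classes) < 3) abort("need at least 3 transposon classes")
  m <- vapply(tables, function(t) {
    t$density[match(classes, t$family)]
  }, numeric(length(classes)))
  r <- diag(1, length(marks)); dimnames(r) <- list(marks, marks)
  p <- r * 0 + NA; diag(p) <- 0
  for (i in seq_along(marks)) for (j in seq_along(marks)) {
    if (i < j) {
      if (sd(m[, i]) == 0 || sd(m[, j]) == 0) {
        r[i, j] <- r[j, i] <- NA
      } else {
        ct <- cor.test(m[, i], m[, j])
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  pairs <- tidyr::expand_grid(mark1 = marks, mark2 = marks) %>%
    filter(.data$mark1 < .data$mark2) %>%
    mutate(r = purrr::map2_dbl(.data$mark1, .data$mark2, ~ r[.x, .y]),
           p = purrr::map2_dbl(.data$mark1, .data$mark2, ~ p[.x, .y]))
  list(r = r, p = p, pairs = pairs)
}

#' Percentile correlation with an external windowed track
#'
#' External 1-kb windows are ranked by their own score into `n` equal-count
#' percentiles; the Pearson correlation between per-percentile mean
#' external score and per-percentile mean track score is returned. Windows
#' intersecting multiple bins take the mean bin score.
#'
#' @param track A `bin_track`.
#' @param external Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and `score`.
#' @param n Number of percentiles (default 100).
#' @return List with `r`, `percentiles` tibble.
#' @export
windowed_percentile_correlation <- function(track, external, n = 100L) {
  if (nrow(external) < n) abort("fewer windows than percentiles")
  bin <- track$bin
  track_mean <- purrr::pmap_dbl(
    external[c("chrom", "start", "end")],
    function(chrom, start, end) {
      s <- track$scores[[chrom]]
      b0 <- start %/% bin; b1 <- (end - 1L) %/% bin
      idx <- (b0:b1) + 1L
      idx <- idx[idx >= 1 & idx <= length(s)]
      if (length(idx) == 0) NA_real_ else mean(s[idx])
    })
  df <- external %>%
    mutate(track_score = track_mean) %>%
    filter(!is.na(.data$track_score)) %>%
    arrange(.data$score) %>%
    mutate(percentile = ceiling(row_number() * n / n()))
  per <- df %>%
    group_by(.data$percentile) %>%
    summarise(external = mean(.data$score),
              track = mean(.data$track_score), .groups = "drop")
  list(r = cor(per$external, per$track), percentiles = per)
}
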