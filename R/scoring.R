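#' Fragment-extension score matrix
#'
#' The bin-resolution survival function of the fragment-length
#' distribution: `w[i] = Pr(L > i * bin)` for `i = 0..n_bins-1`. A sequenced
#' 5' tag deposits `w[0]` in the bin containing its 5' base and
#' `w[1]..w[n_bins-1]` in the following bins along the read strand,
#' reflecting the probability that the precipitated fragment reached that
#' far. Mass beyond the last bin is truncated into it (the survival value
#' there counts all longer fragments).
#'
#' @param frag A [frag_dist()].
#' @param bin Bin width in bp (default 50).
#' @param n_bins Number of bins covered by one tag (default 10: the 5' bin
#'   plus the downstream 9).
#' @return A `score_matrix`: list with `w`, `bin`, `n_bins`.
#' @export
score_matrix <- function(frag, bin = 50L, n_bins = 10L) {
  stopifnot(inherits(frag, "frag_dist"), bin >= 1, n_bins >= 1)
  w <- frag_survival(frag, (seq_len(n_bins) - 1) * bin)
  stopifnot(all(diff(w) <= 1e-12), w[1] > 0)
  structure(list(w = w, bin = as.integer(bin), n_bins = as.integer(n_bins)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> bin", x$bin, "bp, w =",
      paste(round(x$w, 3), collapse = " "), "\n")
  invisible(x)
}

new_bin_track <- function(scores, bin, tag_total, mode, mark,
                          depth_normalized = FALSE, tags_used = NA_integer_) {
  structure(list(scores = scores, bin = as.integer(bin),
                 tag_total = tag_total, tags_used = tags_used,
                 mode = mode, mark = mark,
                 depth_normalized = depth_normalized),
            class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  cat("<bin_track>", x$mark, " mode:", x$mode, " bin:", x$bin, "bp, ",
      sum(lengths(x$scores)), "bins over", length(x$scores),
      "chromosome(s)\n")
  cat("  tag_total:", x$tag_total,
      if (isTRUE(x$depth_normalized)) " (depth-normalized to 1e7 tags)" else "",
      "\n")
  invisible(x)
}

#' @method tidy bin_track
#' @export
tidy.bin_track <- function(x, ...) {
  purrr::imap(x$scores, function(s, chrom) {
    tibble(chrom = chrom,
           start = (seq_along(s) - 1L) * x$bin,
           score = as.numeric(s))
  }) %>% bind_rows()
}

track_layout <- function(track) {
  vapply(track$scores, length, integer(1)) * track$bin
}

all_scores <- function(track) unlist(track$scores, use.names = FALSE)

#' Score mapped tags into fixed-width genome bins
#'
#' Allocates each tag site's extension weights into 50-bp bins: a
#' plus-strand site with 5' position p deposits `w[0..n_bins-1]` into the
#' bin containing p and the following bins toward increasing coordinates; a
#' minus-strand site extends toward decreasing coordinates. In `U` mode only
#' unique tags (k = 1) contribute, with weight 1; in `U+M` mode every site
#' of a multi-mapping tag contributes with weight 1/k, so each tag
#' distributes exactly one tag-equivalent across its sites. Bins off the
#' chromosome end are truncated.
#'
#' @param tags Tag tibble (`read_id`, `chrom`, `pos` 0-based 5' position,
#'   `strand`, `k`), as produced by [map_tags()] or the simulators.
#' @param matrix A [score_matrix()].
#' @param mode "U+M" (default) or "U".
#' @param layout Named vector of chromosome lengths (bp), or a
#'   `synthetic_world`.
#' @param mark Mark label stored on the track.
#' @return A `bin_track` whose `tag_total` is the number of distinct mapped
#'   tags in the input (the library depth used by [depth_normalize()]), and
#'   `tags_used` the number contributing in the chosen mode.
#' @export
score_tags <- function(tags, matrix, mode = c("U+M", "U"), layout,
                       mark = "mark") {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "score_matrix"))
  if (inherits(layout, "synthetic_world")) layout <- layout$layout
  bin <- matrix$bin
  nb <- ceiling(layout / bin)
  scores <- lapply(nb, numeric)
  tag_total <- length(unique(tags$read_id))

  if (nrow(tags) > 0) {
    if (!all(tags$chrom %in% names(layout))) {
      abort("tags reference chromosomes absent from layout")
    }
    if (any(tags$pos < 0 | tags$pos >= layout[tags$chrom])) {
      abort("tag site beyond chromosome end")
    }
  }
  use <- if (mode == "U") tags[tags$k == 1, , drop = FALSE] else tags
  tags_used <- length(unique(use$read_id))
  if (nrow(use) > 0) {
    w <- matrix$w
    wt <- if (mode == "U") rep(1, nrow(use)) else 1 / use$k
    bin0 <- use$pos %/% bin
    dir <- ifelse(use$strand == "+", 1L, -1L)
    for (chrom in unique(use$chrom)) {
      ci <- use$chrom == chrom
      nbin <- nb[[chrom]]
      b0 <- bin0[ci]; d <- dir[ci]; w0 <- wt[ci]
      idx_all <- integer(0); val_all <- numeric(0)
      for (i in seq_len(matrix$n_bins)) {
        b <- b0 + d * (i - 1L)
        ok <- b >= 0L & b < nbin
        if (any(ok)) {
          idx_all <- c(idx_all, b[ok] + 1L)
          val_all <- c(val_all, w0[ok] * w[i])
        }
      }
      acc <- rowsum(val_all, idx_all)
      scores[[chrom]][as.integer(rownames(acc))] <-
        scores[[chrom]][as.integer(rownames(acc))] + acc[, 1]
    }
  }
  new_bin_track(scores, bin, tag_total, mode, mark, FALSE, tags_used)
}
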