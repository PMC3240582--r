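#' Rank-based expression grouping
#'
#' Sorts genes by expression and splits them into `n` equal-count groups
#' (group 1 = lowest). Ties are broken by stable gene-id order, so an
#' all-equal expression table yields a deterministic grouping.
#'
#' @param expr Tibble with `gene_id` and `expression`.
#' @param n Number of groups (10 for expression groups, 100 for
#'   percentiles).
#' @return The input with an added integer `group` column.
#' @export
expression_groups <- function(expr, n = 10L) {
  stopifnot(all(c("gene_id", "expression") %in% names(expr)))
  if (n > nrow(expr)) abort("more groups than genes")
  if (any(!is.finite(expr$expression))) abort("expression values must be finite")
  ord <- order(expr$expression)  # stable: ties keep input (gene-id) order
  out <- expr[ord, , drop = FALSE]
  out$group <- as.integer(ceiling(seq_len(nrow(out)) * n / nrow(out)))
  out[order(ord), , drop = FALSE]
}

trimmed_mean <- function(x, trim) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (trim <= 0) return(mean(x))
  k <- floor(n * trim)
  if (k < 1) abort("group too small for the requested trimming")
  x <- sort(x)[(k + 1):(n - k)]
  mean(x)
}

#' Expression-stratified metagene profile
#'
#' Average mark profile over genes aligned at a common anchor (TSS, gene
#' midpoint, or TxEnd), oriented so positive offsets are downstream on the
#' gene strand, stratified by expression group. Per offset step the mean is
#' trimmed (`trim` fraction of genes removed at each end). Genes with
#' multiple annotated anchors contribute the average over their anchors
#' once; windows truncated by a chromosome end contribute the positions
#' they cover. Unique-mode (U) scores are the intended input, keeping
#' transposon-derived multi-mapping signal out of gene-centric averages.
#'
#' @param track A `bin_track` (U mode recommended).
#' @param world A `synthetic_world` (or list with `genes` and
#'   `transcripts`).
#' @param groups Tibble from [expression_groups()] (`gene_id`, `group`);
#'   a single group covering all genes if omitted.
#' @param anchor "tss", "midpoint" or "txend".
#' @param flank Half-window in bp (default 2000).
#' @param step Offset resolution in bp (default 10).
#' @param trim Trimming fraction per side for the per-offset mean
#'   (default 0.05, i.e. 10% of genes in total).
#' @return A `meta_profile` tibble: `anchor`, `group`, `offset`, `mean`,
#'   `n_genes`.
#' @export
metagene <- function(track, world, groups = NULL,
                     anchor = c("tss", "midpoint", "txend"),
                     flank = 2000L, step = 10L, trim = 0.05) {
  anchor <- match.arg(anchor)
  anchors <- anchor_positions(world, anchor)
  genes <- world$genes
  if (is.null(groups)) {
    groups <- tibble(gene_id = genes$gene_id, group = 1L)
  }
  offsets <- seq(-flank, flank, by = step)
  bin <- track$bin
  layout <- track_layout(track)

  per_gene <- anchors %>%
    inner_join(groups %>% select("gene_id", "group"), by = "gene_id") %>%
    inner_join(genes %>% select("gene_id"), by = "gene_id")

  # score at each (anchor, offset): matrix anchors x offsets
  mat <- matrix(NA_real_, nrow(per_gene), length(offsets))
  dir <- ifelse(per_gene$strand == "+", 1L, -1L)
  for (j in seq_along(offsets)) {
    gpos <- per_gene$pos + dir * offsets[j]
    ok <- gpos >= 0 & gpos < layout[per_gene$chrom]
    idx <- which(ok)
    if (length(idx) > 0) {
      b <- gpos[idx] %/% bin + 1L
      mat[idx, j] <- vapply(seq_along(idx), function(r) {
        track$scores[[per_gene$chrom[idx[r]]]][b[r]]
      }, numeric(1))
    }
  }
  # average multi-anchor genes into one row per gene
  gene_key <- paste(per_gene$gene_id)
  agg <- rowsum(mat, gene_key, na.rm = TRUE)
  cnt <- rowsum((!is.na(mat)) * 1, gene_key)
  gmat <- agg / pmax(cnt, 1)
  gmat[cnt == 0] <- NA
  gid <- rownames(agg)
  ggrp <- groups$group[match(gid, groups$gene_id)]

  out <- purrr::map(sort(unique(ggrp)), function(g) {
    rows <- which(ggrp == g)
    tibble(anchor = anchor, group = g, offset = offsets,
           mean = vapply(seq_along(offsets), function(j) {
             trimmed_mean(gmat[rows, j], trim)
           }, numeric(1)),
           n_genes = length(rows))
  }) %>% bind_rows()
  class(out) <- c("meta_profile", class(out))
  out
}

#' Named TSS-window specification
#'
#' The ten promoter-chromatin summary windows used for signature building:
#' per mark, mean score over a fixed strand-oriented window around the TSS.
#'
#' @return Tibble with `feature`, `mark`, `from`, `to` (bp relative to
#'   TSS, gene-strand oriented, half-open `[from, to)`).
#' @export
tss_window_spec <- function() {
  tibble::tribble(
    ~feature,      ~mark,      ~from, ~to,
    "H3K4me3_U",   "H3K4me3",  -500,    0,
    "H3K4me3_D",   "H3K4me3",     0,  500,
    "H3K9me3_T",   "H3K9me3",  -100,  400,
    "H3K9me3_U",   "H3K9me3",  -750, -250,
    "H3K9ac_U",    "H3K9ac",   -500,    0,
    "H3K9ac_D",    "H3K9ac",      0,  500,
    "H3K27me3",    "H3K27me3", -250,  250,
    "HP1a",        "HP1a",     -100,  400,
    "polII_T",     "polII",    -100,  100,
    "polII_D",     "polII",     100,  400
  )
}

#' Per-gene mean scores over named TSS windows
#'
#' For each gene and window, the mean bin score over the strand-oriented
#' window. Windows running off a chromosome end are truncated (flagged via
#' the `truncated` attribute).
#'
#' @param tracks Named list of `bin_track`s, keyed by mark.
#' @param world A `synthetic_world`.
#' @param spec Window specification ([tss_window_spec()] by default); must
#'   reference marks present in `tracks`.
#' @return Wide tibble: `gene_id` plus one column per window feature.
#' @export
tss_window_means <- function(tracks, world, spec = tss_window_spec()) {
  genes <- world$genes
  if (any(spec$to <= spec$from)) abort("zero- or negative-width window")
  missing <- setdiff(unique(spec$mark), names(tracks))
  if (length(missing) > 0) {
    abort(paste("no track supplied for mark(s):",
                paste(missing, collapse = ", ")))
  }
  n_trunc <- 0L
  cols <- purrr::pmap(spec, function(feature, mark, from, to) {
    tr <- tracks[[mark]]
    bin <- tr$bin
    layout <- track_layout(tr)
    vals <- vapply(seq_len(nrow(genes)), function(i) {
      dir <- if (genes$strand[i] == "+") 1L else -1L
      a <- genes$tss[i] + dir * from
      b <- genes$tss[i] + dir * (to - 1L)
      lo <- min(a, b); hi <- max(a, b)
      L <- layout[[genes$chrom[i]]]
      if (lo < 0 || hi >= L) n_trunc <<- n_trunc + 1L
      lo <- max(lo, 0); hi <- min(hi, L - 1L)
      if (hi < lo) return(NA_real_)
      idx <- (lo %/% bin):(hi %/% bin) + 1L
      mean(tr$scores[[genes$chrom[i]]][idx])
    }, numeric(1))
    setNames(list(vals), feature)
  })
  out <- tibble(gene_id = genes$gene_id) %>%
    bind_cols(as_tibble(purrr::flatten(cols)))
  attr(out, "truncated") <- n_trunc
  out
}

#' Fold-of-change percentiles between two expression conditions
#'
#' Genes are ranked by the ratio of their expression in the perturbed
#' (e.g. knockdown) condition versus the reference and split into `n`
#' equal-count percentiles (percentile 1 = most repressed). Genes with a
#' zero reference value are excluded with a message.
#'
#' @param expr Tibble with `gene_id`, `wt`, `kd` (positive expression
#'   values).
#' @param n Number of percentiles (default 100).
#' @return Tibble `gene_id`, `wt`, `kd`, `ratio`, `percentile`.
#' @export
fold_change_percentiles <- function(expr, n = 100L) {
  stopifnot(all(c("gene_id", "wt", "kd") %in% names(expr)))
  drop <- expr$wt == 0
  if (any(drop)) {
    inform(sprintf("%d gene(s) with zero reference expression excluded",
                   sum(drop)))
    expr <- expr[!drop, , drop = FALSE]
  }
  if (n > nrow(expr)) abort("more percentiles than usable genes")
  expr$ratio <- expr$kd / expr$wt
  ord <- order(expr$ratio)
  out <- expr[ord, , drop = FALSE]
  out$percentile <- as.integer(ceiling(seq_len(nrow(out)) * n / nrow(out)))
  out[order(ord), , drop = FALSE]
}

#' Structural and contextual per-gene features
#'
#' The per-gene feature panel used alongside fold-of-change percentiles:
#' expression level, gene length, distance to centromere, exon count and
#' density, counts of embedded genes on the sense and antisense strand,
#' local gene density, and transposon/repeat density upstream of, within,
#' and downstream of the gene body.
#'
#' @param world A `synthetic_world`.
#' @param centromeres Optional named vector of per-chromosome centromere
#'   positions (bp); the distance feature is omitted when absent.
#' @param flank Flank width (bp) for the up/downstream transposon
#'   densities (default 2000).
#' @param density_window Window (bp) for local gene density (default 1e5).
#' @return Tibble with one row per gene.
#' @export
gene_features <- function(world, centromeres = NULL, flank = 2000L,
                          density_window = 1e5) {
  g <- world$genes
  tx <- world$transposons
  expr <- world$expression

  tx_bp_in <- function(chrom, lo, hi) {
    if (nrow(tx) == 0 || hi <= lo) return(0)
    d <- tx[tx$chrom == chrom, , drop = FALSE]
    if (nrow(d) == 0) return(0)
    sum(pmax(0, pmin(d$end, hi) - pmax(d$start, lo)))
  }

  len <- g$end - g$start
  mid <- (g$start + g$end) / 2
  out <- tibble(
    gene_id = g$gene_id,
    expression = expr$expression[match(g$gene_id, expr$gene_id)],
    length = len,
    n_exons = g$n_exons,
    exon_density = g$n_exons / (len / 1000),
    n_variants = g$n_variants
  )
  out$embedded_sense <- vapply(seq_len(nrow(g)), function(i) {
    sum(g$chrom == g$chrom[i] & g$start >= g$start[i] & g$end <= g$end[i] &
          g$strand == g$strand[i]) - 1L
  }, integer(1))
  out$embedded_antisense <- vapply(seq_len(nrow(g)), function(i) {
    sum(g$chrom == g$chrom[i] & g$start >= g$start[i] & g$end <= g$end[i] &
          g$strand != g$strand[i])
  }, integer(1))
  out$local_gene_density <- vapply(seq_len(nrow(g)), function(i) {
    lo <- mid[i] - density_window / 2; hi <- mid[i] + density_window / 2
    sum(g$chrom == g$chrom[i] & (g$start + g$end) / 2 >= lo &
          (g$start + g$end) / 2 < hi) / (density_window / 1e5)
  }, numeric(1))
  out$tx_density_upstream <- vapply(seq_len(nrow(g)), function(i) {
    if (g$strand[i] == "+") {
      tx_bp_in(g$chrom[i], g$start[i] - flank, g$start[i]) / flank
    } else tx_bp_in(g$chrom[i], g$end[i], g$end[i] + flank) / flank
  }, numeric(1))
  out$tx_density_body <- vapply(seq_len(nrow(g)), function(i) {
    tx_bp_in(g$chrom[i], g$start[i], g$end[i]) / len[i]
  }, numeric(1))
  out$tx_density_downstream <- vapply(seq_len(nrow(g)), function(i) {
    if (g$strand[i] == "+") {
      tx_bp_in(g$chrom[i], g$end[i], g$end[i] + flank) / flank
    } else tx_bp_in(g$chrom[i], g$start[i] - flank, g$start[i]) / flank
  }, numeric(1))
  if (!is.null(centromeres)) {
    out$dist_centromere <- unname(abs(mid - centromeres[g$chrom]))
  } else {
    inform("centromere coordinates not supplied; distance feature omitted")
  }
  out
}
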