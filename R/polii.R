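#' Internal splice-junction sites of annotated genes
#'
#' Donor (exon to intron) and acceptor (intron to exon) junctions, oriented
#' by transcription direction. The anchor position of a junction is the
#' first base after the boundary in transcription direction, so negative
#' offsets at a donor are exonic and negative offsets at an acceptor are
#' intronic. Junctions within `min_tss_dist` of the gene's TSS are excluded
#' to keep the TSS footprint out of junction profiles.
#'
#' @param genes Gene tibble (as in a `synthetic_world`).
#' @param min_tss_dist Minimum distance (bp) from the TSS (default 500).
#' @return Tibble `gene_id`, `chrom`, `strand`, `type`
#'   ("donor"/"acceptor"), `pos` (0-based).
#' @export
junction_sites <- function(genes, min_tss_dist = 500L) {
  rows <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$strand, genes$tss,
         genes$exon_starts, genes$exon_ends),
    function(gid, chrom, strand, tss, es, ee) {
      n <- length(es)
      if (n < 2) return(NULL)
      if (strand == "+") {
        don <- ee[-n]; acc <- es[-1]
      } else {
        don <- es[-1] - 1L; acc <- ee[-n] - 1L
      }
      out <- tibble(gene_id = gid, chrom = chrom, strand = strand,
                    type = rep(c("donor", "acceptor"), c(length(don),
                                                         length(acc))),
                    pos = c(don, acc))
      out[abs(out$pos - tss) >= min_tss_dist, , drop = FALSE]
    })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), type = character(), pos = integer()))
  }
  out
}

#' Promoter and gene-body polII scores with overlap masking
#'
#' Per gene: mean adjusted polII score over the TSS-surrounding promoter
#' window (-500 to +500 bp) and over the gene-body window (+750 to
#' +2500 bp downstream of the TSS), both strand-oriented. Bins falling in
#' the promoter-or-body window of more than one gene are excluded from
#' every window they touch. The stalling index SI is the promoter score
#' over the body score (+Inf when the body score is zero but the promoter
#' is not).
#'
#' @param track Adjusted `bin_track` (U mode recommended).
#' @param world A `synthetic_world`, or a gene tibble.
#' @param promoter_window,body_window Oriented half-open windows in bp
#'   relative to TSS.
#' @return Tibble `gene_id`, `promoter_score`, `body_score`, `si`,
#'   `incomplete` (TRUE when a window had no usable bins).
#' @export
promoter_body_scores <- function(track, world,
                                 promoter_window = c(-500L, 500L),
                                 body_window = c(750L, 2500L)) {
  genes <- if (inherits(world, "synthetic_world")) world$genes else world
  bin <- track$bin
  layout <- track_layout(track)

  window_bins <- function(i, win) {
    dir <- if (genes$strand[i] == "+") 1L else -1L
    a <- genes$tss[i] + dir * win[1]
    b <- genes$tss[i] + dir * (win[2] - 1L)
    lo <- max(min(a, b), 0L)
    hi <- min(max(a, b), layout[[genes$chrom[i]]] - 1L)
    if (hi < lo) return(integer(0))
    (lo %/% bin):(hi %/% bin) + 1L
  }

  n_g <- nrow(genes)
  prom <- lapply(seq_len(n_g), window_bins, win = promoter_window)
  body <- lapply(seq_len(n_g), window_bins, win = body_window)

  # bins claimed by >1 gene (within its promoter-or-body windows) are masked
  claims <- tibble(
    gene = rep(seq_len(n_g), lengths(prom) + lengths(body)),
    chrom = rep(genes$chrom, lengths(prom) + lengths(body)),
    bin_i = unlist(purrr::map2(prom, body, c))
  ) %>% distinct()
  dup <- claims %>%
    count(.data$chrom, .data$bin_i) %>%
    filter(.data$n > 1)
  masked <- paste(dup$chrom, dup$bin_i)

  mean_win <- function(i, bins_i) {
    keep <- bins_i[!(paste(genes$chrom[i], bins_i) %in% masked)]
    if (length(keep) == 0) return(NA_real_)
    mean(track$scores[[genes$chrom[i]]][keep])
  }
  ps <- vapply(seq_len(n_g), function(i) mean_win(i, prom[[i]]), numeric(1))
  bs <- vapply(seq_len(n_g), function(i) mean_win(i, body[[i]]), numeric(1))
  si <- ifelse(bs > 0, ps / bs, ifelse(ps > 0, Inf, 0))
  tibble(gene_id = genes$gene_id, promoter_score = ps, body_score = bs,
         si = si, incomplete = is.na(ps) | is.na(bs))
}

#' Classify promoter-proximal polII state
#'
#' Elongating: promoter score >= `thr_promoter` and SI < `thr_elong`.
#' Stalled: promoter score >= `thr_promoter` and SI > `thr_stall`.
#' No polII: promoter and body scores both < `thr_none`. Everything else
#' is unclassified. A gene with promoter signal but zero body score has
#' SI = +Inf and is stalled.
#'
#' @param records Tibble from [promoter_body_scores()].
#' @param thr_promoter,thr_elong,thr_stall,thr_none Thresholds (defaults
#'   5, 3, 10, 1).
#' @return The input with an added `class` column.
#' @export
classify_polii <- function(records, thr_promoter = 5, thr_elong = 3,
                           thr_stall = 10, thr_none = 1) {
  records %>%
    mutate(class = case_when(
      .data$incomplete ~ "unclassified",
      .data$promoter_score >= thr_promoter & .data$si < thr_elong ~ "elongating",
      .data$promoter_score >= thr_promoter & .data$si > thr_stall ~ "stalled",
      .data$promoter_score < thr_none & .data$body_score < thr_none ~ "none",
      TRUE ~ "unclassified"
    ))
}

# Offsets of tag 5' (or 3') ends relative to anchors, oriented by anchor
# strand, with the tag's orientation (sense/antisense) relative to the
# anchor. One row per (tag, anchor-within-flank) pair.
relative_tag_offsets <- function(tags, anchors, flank, end = c("5", "3"),
                                 read_len = 35L) {
  end <- match.arg(end)
  pos <- tags$pos
  if (end == "3") {
    pos <- pos + ifelse(tags$strand == "+", read_len - 1L,
                        -(read_len - 1L))
  }
  rows <- vector("list", 0)
  for (chrom in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == chrom, , drop = FALSE]
    ti <- which(tags$chrom == chrom)
    if (length(ti) == 0 || nrow(a) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[ti] + 1L, width = 1L),
      IRanges::IRanges(start = a$pos - flank + 1L, width = 2L * flank + 1L))
    if (length(ov) == 0) next
    qi <- ti[S4Vectors::queryHits(ov)]
    ai <- S4Vectors::subjectHits(ov)
    dir <- ifelse(a$strand[ai] == "+", 1L, -1L)
    rows[[length(rows) + 1]] <- tibble(
      rel = (pos[qi] - a$pos[ai]) * dir,
      orientation = ifelse(tags$strand[qi] == a$strand[ai],
                           "sense", "antisense"),
      anchor = ai, gene_id = if ("gene_id" %in% names(a))
        a$gene_id[ai] else NA_character_)
  }
  if (length(rows) == 0) {
    return(tibble(rel = integer(), orientation = character(),
                  anchor = integer(), gene_id = character()))
  }
  bind_rows(rows)
}

bin_label <- function(rel, bin) (floor(rel / bin) + 1L) * bin

#' Strand-resolved positioning histogram around anchors
#'
#' Counts tag 5' positions in `bin`-bp windows around anchor points,
#' separated by tag orientation relative to the anchor strand, scales each
#' library to 10 million tags, and reports the ChIP minus mock difference
#' (positive = enrichment, negative = depletion). Windows are labelled by
#' their right edge: offset +35 covers +30..+34.
#'
#' @param chip_tags,mock_tags Tag tibbles (read-level; one row per site).
#' @param anchors Tibble with `chrom`, `pos`, `strand` (e.g. TSSs from
#'   [anchor_positions()]).
#' @param flank Half-window (default 1000 bp).
#' @param bin Window width (default 5 bp).
#' @param chip_total,mock_total Library depths (default: distinct reads in
#'   each table).
#' @return A `position_histogram` tibble: `orientation`, `offset`, `chip`,
#'   `mock`, `value`.
#' @export
position_histogram <- function(chip_tags, mock_tags, anchors,
                               flank = 1000L, bin = 5L,
                               chip_total = NULL, mock_total = NULL) {
  if (nrow(mock_tags) == 0) abort("empty mock library: cannot normalize")
  chip_total <- chip_total %||% length(unique(chip_tags$read_id))
  mock_total <- mock_total %||% length(unique(mock_tags$read_id))
  offsets <- seq(-flank + bin, flank, by = bin)
  count_side <- function(tags) {
    r <- relative_tag_offsets(tags, anchors, flank)
    r$offset <- bin_label(r$rel, bin)
    r %>%
      count(.data$orientation, .data$offset) %>%
      tidyr::complete(orientation = c("sense", "antisense"),
                      offset = offsets, fill = list(n = 0L)) %>%
      filter(.data$offset %in% offsets)
  }
  chip <- count_side(chip_tags) %>% rename(chip = "n")
  mock <- count_side(mock_tags) %>% rename(mock = "n")
  out <- left_join(chip, mock, by = c("orientation", "offset")) %>%
    mutate(chip = .data$chip * 1e7 / chip_total,
           mock = .data$mock * 1e7 / mock_total,
           value = .data$chip - .data$mock)
  class(out) <- c("position_histogram", class(out))
  out
}

#' Modal offset of a positioning histogram
#'
#' The label of the maximal `bin`-bp window within a search range. Ties are
#' broken toward the anchor (smaller absolute offset); an exact-distance
#' tie takes the smaller (upstream) offset.
#'
#' @param hist A [position_histogram()] (or any tibble with `offset`,
#'   `value`, `orientation`).
#' @param window Length-2 numeric search range for the offset label.
#' @param orientation Which strand side to search (default "sense").
#' @return The modal offset label (bp), or NA with a warning if the window
#'   holds no signal.
#' @export
mode_offset <- function(hist, window = c(0, 200), orientation = "sense") {
  d <- hist %>%
    filter(.data$orientation == !!orientation,
           .data$offset >= window[1], .data$offset <= window[2])
  if (nrow(d) == 0 || all(d$value == 0)) {
    warn("no signal in the search window; modal offset undefined")
    return(NA_real_)
  }
  best <- d$value == max(d$value)
  cand <- d$offset[best]
  cand[order(abs(cand), cand)][1]
}

#' Kolmogorov-Smirnov comparison of positional samples
#'
#' Two-sample KS test on (e.g.) read 5' or 3' end offsets of two tag
#' populations.
#'
#' @param ends_a,ends_b Numeric samples of positions.
#' @return List with `D`, `p`.
#' @export
ks_compare <- function(ends_a, ends_b) {
  stopifnot(length(ends_a) > 0, length(ends_b) > 0)
  if (length(ends_a) < 5 || length(ends_b) < 5) {
    warn("sample size < 5: asymptotic KS p-value unreliable")
  }
  kt <- suppressWarnings(ks.test(ends_a, ends_b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' PolII occupancy profiles at splice junctions
#'
#' [position_histogram()] anchored at donor (exon-intron) and acceptor
#' (intron-exon) junctions, oriented in transcription direction.
#'
#' @inheritParams position_histogram
#' @param junctions Tibble from [junction_sites()].
#' @param flank Half-window (default 300 bp).
#' @return A `junction_profile` tibble: `type`, `orientation`, `offset`,
#'   `chip`, `mock`, `value`.
#' @export
junction_profiles <- function(chip_tags, mock_tags, junctions,
                              flank = 300L, bin = 5L,
                              chip_total = NULL, mock_total = NULL) {
  if (nrow(junctions) == 0) abort("no junctions supplied")
  chip_total <- chip_total %||% length(unique(chip_tags$read_id))
  mock_total <- mock_total %||% length(unique(mock_tags$read_id))
  out <- purrr::map(c("donor", "acceptor"), function(ty) {
    j <- junctions[junctions$type == ty, , drop = FALSE]
    if (nrow(j) == 0) return(NULL)
    position_histogram(chip_tags, mock_tags, j, flank = flank, bin = bin,
                       chip_total = chip_total, mock_total = mock_total) %>%
      mutate(type = ty, .before = 1)
  }) %>% bind_rows()
  class(out) <- c("junction_profile", class(out))
  out
}

#' Detect genes with polII slowing at exon ends
#'
#' A gene is flagged when its ChIP-over-mock occupancy ratio in the
#' exon-side window (default -120 to -60 bp) of its donor junctions is at
#' least `tau` times the same ratio over its gene body. Both ratios use
#' depth-scaled per-bp read rates, so the criterion is scale-free; the
#' mock-subtracted body level cannot anchor a ratio (it is near zero for a
#' uniformly transcribed body), hence the ratio form of the detector.
#' Genes with fewer than 2 exons, or without mock coverage in the window
#' or body, are not flagged.
#'
#' @inheritParams position_histogram
#' @param world A `synthetic_world`.
#' @param window Exon-side window of donor-junction offsets (bp).
#' @param tau Enrichment ratio threshold (default 2).
#' @param min_tss_dist Junction TSS-exclusion distance (default 500).
#' @return Tibble `gene_id`, `window_enrichment`, `body_enrichment`,
#'   `slowing`.
#' @export
detect_slowing_genes <- function(chip_tags, mock_tags, world,
                                 window = c(-120, -60), tau = 2,
                                 bin = 5L, min_tss_dist = 500L) {
  genes <- world$genes
  genes2 <- genes[genes$n_exons >= 2, , drop = FALSE]
  if (nrow(genes2) == 0) {
    return(tibble(gene_id = character(), window_enrichment = numeric(),
                  body_enrichment = numeric(), slowing = logical()))
  }
  sc <- 1e7 / length(unique(chip_tags$read_id))
  sm <- 1e7 / length(unique(mock_tags$read_id))
  jx <- junction_sites(genes2, min_tss_dist = min_tss_dist)
  jx <- jx[jx$type == "donor", , drop = FALSE]

  win_stat <- function(tags) {
    r <- relative_tag_offsets(tags, jx, flank = 300L)
    r$offset <- bin_label(r$rel, bin)
    r %>%
      filter(.data$offset >= window[1], .data$offset <= window[2]) %>%
      count(.data$gene_id)
  }
  wc <- win_stat(chip_tags) %>% rename(chip = "n")
  wm <- win_stat(mock_tags) %>% rename(mock = "n")

  body_counts <- vapply(seq_len(nrow(genes2)), function(i) {
    lo <- genes2$start[i]; hi <- genes2$end[i]
    c(sum(chip_tags$chrom == genes2$chrom[i] & chip_tags$pos >= lo &
            chip_tags$pos < hi),
      sum(mock_tags$chrom == genes2$chrom[i] & mock_tags$pos >= lo &
            mock_tags$pos < hi))
  }, numeric(2))

  out <- tibble(gene_id = genes2$gene_id,
                body_chip = body_counts[1, ], body_mock = body_counts[2, ]) %>%
    left_join(wc, by = "gene_id") %>%
    left_join(wm, by = "gene_id") %>%
    mutate(chip = dplyr::coalesce(.data$chip, 0L),
           mock = dplyr::coalesce(.data$mock, 0L),
           window_enrichment = ifelse(.data$mock > 0,
                                      (sc * .data$chip) / (sm * .data$mock),
                                      NA_real_),
           body_enrichment = ifelse(.data$body_mock > 0,
                                    (sc * .data$body_chip) /
                                      (sm * .data$body_mock), NA_real_),
           slowing = !is.na(.data$window_enrichment) &
             !is.na(.data$body_enrichment) & .data$body_enrichment > 0 &
             .data$window_enrichment >= tau * .data$body_enrichment) %>%
    select("gene_id", "window_enrichment", "body_enrichment", "slowing")
  out
}

#' Compare splice-variant (or exon) counts between gene sets
#'
#' Two-sided Mann-Whitney rank-sum test on per-gene counts for a flagged
#' set against the remaining genes, with box-plot descriptives (median,
#' 25th/75th percentiles).
#'
#' @param world A `synthetic_world` (or gene tibble with `gene_id` plus the
#'   count column).
#' @param flagged Character vector of flagged gene ids.
#' @param variable Count column to compare: "n_variants" (splice variants,
#'   default) or "n_exons".
#' @return One-row tibble: `variable`, `statistic` (Mann-Whitney U), `p`,
#'   `n_flagged`, `n_rest`, and per-set mean/median/quartiles.
#' @export
splice_variant_test <- function(world, flagged,
                                variable = c("n_variants", "n_exons")) {
  variable <- match.arg(variable)
  genes <- if (inherits(world, "synthetic_world")) world$genes else world
  x <- genes[[variable]][genes$gene_id %in% flagged]
  y <- genes[[variable]][!genes$gene_id %in% flagged]
  if (length(x) < 3 || length(y) < 3) {
    abort("each gene set needs at least 3 members")
  }
  wt <- wilcox.test(x, y, exact = FALSE)
  tibble(variable = variable,
         statistic = unname(wt$statistic), p = wt$p.value,
         n_flagged = length(x), n_rest = length(y),
         mean_flagged = mean(x), mean_rest = mean(y),
         median_flagged = median(x), median_rest = median(y),
         q25_flagged = unname(quantile(x, 0.25)),
         q75_flagged = unname(quantile(x, 0.75)),
         q25_rest = unname(quantile(y, 0.25)),
         q75_rest = unname(quantile(y, 0.75)))
}
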