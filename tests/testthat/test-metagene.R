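# A minimal world with two genes (one per strand) on a 100-kb chromosome,
# built by hand so anchor arithmetic is fully known.
two_gene_world <- function() {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(20000L, 60000L), end = c(26000L, 66000L),
    strand = c("+", "-"), n_exons = 1L,
    exon_starts = list(20000L, 60000L), exon_ends = list(26000L, 66000L),
    utr5 = 200L, utr3 = 200L, class = "elongating",
    n_variants = 1L, slowing = FALSE) |>
    dplyr::mutate(tss = ifelse(strand == "+", start, end - 1L),
                  txend = ifelse(strand == "+", end - 1L, start))
  structure(list(
    genes = genes,
    transcripts = tibble::tibble(transcript_id = c("gp.t1", "gm.t1"),
                                 gene_id = c("gp", "gm"),
                                 tss = genes$tss, txend = genes$txend),
    transposons = tibble::tibble(),
    layout = c(chr1 = 100000L),
    expression = tibble::tibble(gene_id = c("gp", "gm"),
                                expression = c(5, 7))),
    class = "synthetic_world")
}

# track with a bump of amplitude `amp` in the bins containing tss+offset
bump_track <- function(world, offset, amp = 10, base = 1) {
  s <- rep(base, 2000)
  for (i in seq_len(nrow(world$genes))) {
    g <- world$genes[i, ]
    dir <- if (g$strand == "+") 1L else -1L
    pos <- g$tss + dir * offset
    s[pos %/% 50 + 1] <- amp
  }
  make_track(list(chr1 = s))
}

test_that("expression grouping is rank-based, stable, and size-balanced", {
  expr <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                         expression = rev(seq(0.5, 50, 0.5)))
  eg <- expression_groups(expr, 10)
  expect_true(all(table(eg$group) == 10))
  # highest-expressing genes land in group 10
  expect_equal(unique(eg$group[order(-eg$expression)][1:10]), 10L)
  # monotone relabeling leaves groups unchanged
  eg2 <- expression_groups(dplyr::mutate(expr, expression = log1p(expression)),
                           10)
  expect_identical(eg$group, eg2$group)
  # ties: all-equal values grouped deterministically by input order
  tied <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), expression = 1)
  tg <- expression_groups(tied, 4)
  expect_identical(tg$group, rep(1:4, each = 5))
  expect_error(expression_groups(tied, 30), "more groups")
})

test_that("a constant track yields an exactly flat profile", {
  w <- two_gene_world()
  tr <- make_track(list(chr1 = rep(3.5, 2000)))
  mp <- metagene(tr, w, anchor = "tss", trim = 0)
  expect_true(all(mp$mean == 3.5))
  # trim = 0 equals the arithmetic mean (2 genes, values equal)
  expect_equal(unique(mp$n_genes), 2)
})

test_that("a planted bump at TSS+200 is recovered at the right offset on both strands", {
  w <- two_gene_world()
  tr <- bump_track(w, 200)
  for (gid in c("gp", "gm")) {
    w1 <- w; w1$genes <- w$genes[w$genes$gene_id == gid, ]
    w1$transcripts <- w$transcripts[w$transcripts$gene_id == gid, ]
    mp <- metagene(tr, w1, anchor = "tss", trim = 0)
    peak <- mp$offset[which.max(mp$mean)]
    expect_lte(abs(peak - 200), 50)  # bin resolution of the track
  }
})

test_that("metagene profiles are invariant under strand mirroring", {
  w <- two_gene_world()
  tr <- bump_track(w, 300)
  mp <- metagene(tr, w, anchor = "tss", trim = 0)
  wm <- mirror_world(w)
  trm <- make_track(list(chr1 = rev(tr$scores$chr1)))
  mpm <- metagene(trm, wm, anchor = "tss", trim = 0)
  expect_equal(mpm$mean, mp$mean)
})

test_that("trimming shields the profile from a single outlier gene", {
  withr::with_seed(40, {
    # 30 genes at regular spacing on one strand; one carries a huge signal
    n <- 30
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
      start = seq(10000L, by = 10000L, length.out = n))
    genes <- genes |>
      dplyr::mutate(end = start + 6000L, strand = "+", n_exons = 1L,
                    exon_starts = as.list(start), exon_ends = as.list(end),
                    utr5 = 0L, utr3 = 0L, class = "none", n_variants = 1L,
                    slowing = FALSE, tss = start, txend = end - 1L)
    w <- structure(list(
      genes = genes,
      transcripts = tibble::tibble(transcript_id = paste0(genes$gene_id, ".t1"),
                                   gene_id = genes$gene_id, tss = genes$tss,
                                   txend = genes$txend),
      layout = c(chr1 = 400000L)), class = "synthetic_world")
    s <- rep(1, 8000)
    s[genes$tss[5] %/% 50 + 0:40] <- 1e6   # outlier gene
    tr <- make_track(list(chr1 = s))
    mp <- metagene(tr, w, anchor = "tss", trim = 0.05)
    expect_true(all(mp$mean <= 1 + 1e-9))  # outlier trimmed away
    mp0 <- metagene(tr, w, anchor = "tss", trim = 0)
    expect_gt(max(mp0$mean), 1000)
    # too-small groups cannot be trimmed
    w2 <- w; w2$genes <- w$genes[1:10, ]
    w2$transcripts <- w$transcripts[1:10, ]
    expect_error(metagene(tr, w2, anchor = "tss", trim = 0.05),
                 "too small")
  })
})

test_that("genes with multiple annotated TSSs contribute their anchor average", {
  w <- two_gene_world()
  # give gp a second TSS 400 bp downstream
  w$transcripts <- dplyr::bind_rows(
    w$transcripts,
    tibble::tibble(transcript_id = "gp.alt", gene_id = "gp",
                   tss = w$genes$tss[w$genes$gene_id == "gp"] + 400L,
                   txend = w$genes$txend[w$genes$gene_id == "gp"]))
  w$genes <- w$genes[w$genes$gene_id == "gp", ]
  tr <- make_track(list(chr1 = rep(1, 2000)))
  # bump only at the primary TSS: with two anchors the gene's value at
  # offset 0 is the mean over both anchors
  s <- rep(1, 2000)
  s[w$genes$tss[1] %/% 50 + 1] <- 11
  s[(w$genes$tss[1] + 400) %/% 50 + 1] <- 11
  mp <- metagene(make_track(list(chr1 = s)), w, anchor = "tss", trim = 0)
  # both anchors see their own bump at offset 0 -> mean 11; at +400 the
  # first anchor sees the second bump (11) and the second sees baseline
  expect_equal(mp$mean[mp$offset == 0], 11)
  expect_equal(mp$mean[mp$offset == 400], 6)
})

test_that("TSS window means are strand-oriented", {
  w <- two_gene_world()
  # score 9 strictly upstream (-500..-1) of each TSS, 2 downstream
  s <- rep(0, 2000)
  gp <- w$genes[1, ]; gm <- w$genes[2, ]
  s[(gp$tss - 500) %/% 50 + 1:10] <- 9
  s[gp$tss %/% 50 + 1:10] <- 2
  s[(gm$tss + 50) %/% 50 + 1:10] <- 9   # upstream of a minus gene is rightward
  s[(gm$tss - 450) %/% 50 + 1:10] <- 2
  tr <- make_track(list(chr1 = s))
  tw <- tss_window_means(list(H3K4me3 = tr), w,
                         spec = tss_window_spec()[1:2, ])
  expect_equal(tw$H3K4me3_U, c(9, 9))
  expect_equal(tw$H3K4me3_D, c(2, 2))
  expect_error(
    tss_window_means(list(H3K4me3 = tr), w,
                     spec = tibble::tibble(feature = "z", mark = "H3K4me3",
                                           from = 0, to = 0)),
    "width")
})

test_that("fold-of-change percentiles rank the knockdown/wild-type ratio", {
  expr <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                         wt = rep(10, 200), kd = rep(10, 200))
  # one strongly repressed gene -> percentile 1
  expr$kd[17] <- 1
  fc <- fold_change_percentiles(expr, n = 100)
  expect_equal(fc$percentile[17], 1L)
  # ties are deterministic under stable ordering
  fc2 <- fold_change_percentiles(expr, n = 100)
  expect_identical(fc$percentile, fc2$percentile)
  # planted 3% strongly repressed genes occupy percentiles 1-3
  withr::with_seed(41, {
    expr3 <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                            wt = rgamma(200, 5, 1) + 1)
    expr3$kd <- expr3$wt * exp(rnorm(200, 0, 0.05))
    rep_idx <- sample(200, 6)
    expr3$kd[rep_idx] <- expr3$wt[rep_idx] * 0.1
    fc3 <- fold_change_percentiles(expr3, n = 100)
    expect_true(all(fc3$percentile[rep_idx] <= 3))
  })
  # zero wild-type genes are excluded with a message
  expr$wt[5] <- 0
  expect_message(fcz <- fold_change_percentiles(expr, n = 100), "excluded")
  expect_false("g005" %in% fcz$gene_id)
})

test_that("gene features compute the documented quantities", {
  genes <- tibble::tibble(
    gene_id = c("host", "nested"), chrom = "chr1",
    start = c(10000L, 12000L), end = c(12000L + 0L, 13000L),
    strand = c("+", "-"), n_exons = c(4L, 1L),
    exon_starts = list(c(10000L, 10600L, 11100L, 11600L), 12000L),
    exon_ends = list(c(10400L, 11000L, 11500L, 12000L), 13000L),
    utr5 = 0L, utr3 = 0L, class = "none", n_variants = c(2L, 1L),
    slowing = FALSE) |>
    dplyr::mutate(tss = ifelse(strand == "+", start, end - 1L),
                  txend = ifelse(strand == "+", end - 1L, start))
  genes$end[1] <- 12000L
  w <- structure(list(genes = genes,
                      transposons = tibble::tibble(),
                      expression = tibble::tibble(gene_id = genes$gene_id,
                                                  expression = c(4, 2)),
                      layout = c(chr1 = 50000L)), class = "synthetic_world")
  gf <- gene_features(w, centromeres = c(chr1 = 0))
  host <- gf[gf$gene_id == "host", ]
  expect_equal(host$length, 2000)
  expect_equal(host$exon_density, 2)           # 4 exons / 2 kb
  expect_equal(host$embedded_sense, 0)
  expect_equal(host$embedded_antisense, 0)     # nested gene extends past end
  expect_equal(host$tx_density_body, 0)
  expect_equal(host$dist_centromere, 11000)
  # a gene fully inside another on the opposite strand
  genes2 <- genes
  genes2$start[2] <- 10500L
  genes2$end[2] <- 11900L
  genes2$exon_starts[[2]] <- 10500L
  genes2$exon_ends[[2]] <- 11900L
  genes2$tss[2] <- 11899L
  genes2$txend[2] <- 10500L
  w$genes <- genes2
  gf2 <- gene_features(w, centromeres = c(chr1 = 0))
  expect_equal(gf2$embedded_antisense[gf2$gene_id == "host"], 1)
  expect_equal(gf2$embedded_sense[gf2$gene_id == "host"], 0)
})
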