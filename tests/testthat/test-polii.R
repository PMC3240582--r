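# hand-built world with multi-exon genes for junction work
junction_world <- function() {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(10000L, 50000L), end = c(16000L, 56000L),
    strand = c("+", "-"), n_exons = 3L,
    exon_starts = list(c(10000L, 12000L, 14000L),
                       c(50000L, 52000L, 54000L)),
    exon_ends = list(c(11500L, 13500L, 16000L),
                     c(51500L, 53500L, 56000L)),
    utr5 = 100L, utr3 = 100L, class = "elongating",
    n_variants = c(3L, 1L), slowing = c(TRUE, FALSE)) |>
    dplyr::mutate(tss = ifelse(strand == "+", start, end - 1L),
                  txend = ifelse(strand == "+", end - 1L, start))
  structure(list(
    genes = genes,
    transcripts = tibble::tibble(transcript_id = paste0(genes$gene_id, ".t1"),
                                 gene_id = genes$gene_id, tss = genes$tss,
                                 txend = genes$txend),
    transposons = tibble::tibble(),
    layout = c(chr1 = 100000L),
    expression = tibble::tibble(gene_id = genes$gene_id,
                                expression = c(5, 5))),
    class = "synthetic_world")
}

test_that("junction sites are oriented by transcription direction", {
  w <- junction_world()
  jx <- junction_sites(w$genes, min_tss_dist = 0)
  gp <- jx[jx$gene_id == "gp", ]
  # plus gene: donors at exon ends (first intron base), acceptors at
  # exon starts
  expect_setequal(gp$pos[gp$type == "donor"], c(11500, 13500))
  expect_setequal(gp$pos[gp$type == "acceptor"], c(12000, 14000))
  gm <- jx[jx$gene_id == "gm", ]
  # minus gene: transcription right-to-left
  expect_setequal(gm$pos[gm$type == "donor"], c(53999, 51999))
  expect_setequal(gm$pos[gm$type == "acceptor"], c(53499, 51499))
  # TSS-proximal junctions excluded at a large exclusion radius
  jx2 <- junction_sites(w$genes, min_tss_dist = 3000)
  expect_true(all(abs(jx2$pos - w$genes$tss[match(jx2$gene_id,
                                                  w$genes$gene_id)]) >= 3000))
})

test_that("promoter and body scores follow the window definitions", {
  w <- junction_world()
  tr <- make_track(list(chr1 = rep(8, 2000)))
  rec <- promoter_body_scores(tr, w)
  expect_equal(rec$promoter_score, c(8, 8))
  expect_equal(rec$body_score, c(8, 8))
  expect_equal(rec$si, c(1, 1))
  # planted promoter 60, body 5 -> SI = 12
  s <- rep(0, 2000)
  g <- w$genes[1, ]
  prom_bins <- ((g$tss - 500) %/% 50):((g$tss + 499) %/% 50) + 1
  body_bins <- ((g$tss + 750) %/% 50):((g$tss + 2499) %/% 50) + 1
  s[prom_bins] <- 60; s[body_bins] <- 5
  rec2 <- promoter_body_scores(make_track(list(chr1 = s)), w)
  expect_equal(rec2$promoter_score[1], 60)
  expect_equal(rec2$body_score[1], 5)
  expect_equal(rec2$si[1], 12)
})

test_that("bins claimed by two genes' windows are masked from both", {
  # two plus-strand genes whose promoter windows overlap
  genes <- tibble::tibble(
    gene_id = c("a", "b"), chrom = "chr1",
    start = c(10000L, 10600L), end = c(15000L, 15600L), strand = "+",
    n_exons = 1L, exon_starts = list(10000L, 10600L),
    exon_ends = list(15000L, 15600L), utr5 = 0L, utr3 = 0L,
    class = "none", n_variants = 1L, slowing = FALSE) |>
    dplyr::mutate(tss = start, txend = end - 1L)
  w <- structure(list(genes = genes, layout = c(chr1 = 50000L)),
                 class = "synthetic_world")
  s <- seq_len(1000)  # strictly increasing scores identify bins uniquely
  tr <- make_track(list(chr1 = s))
  rec <- promoter_body_scores(tr, w)
  # hand computation: promoter windows cover bins 191-210 (gene a,
  # 9500-10500) and 203-222 (gene b, 10100-11100); the overlap 203-210 is
  # masked; gene bodies cover 216-250 / 228-262, overlap 228-250 masked;
  # promoter windows also collide with body windows where they intersect
  prom_a <- 191:210; prom_b <- 203:222
  body_a <- 216:250; body_b <- 228:262
  claimed <- c(prom_a, prom_b, body_a, body_b)
  masked <- as.integer(names(table(claimed))[table(claimed) > 1])
  expect_equal(rec$promoter_score[1], mean(s[setdiff(prom_a, masked)]))
  expect_equal(rec$promoter_score[2], mean(s[setdiff(prom_b, masked)]))
  expect_equal(rec$body_score[1], mean(s[setdiff(body_a, masked)]))
  expect_equal(rec$body_score[2], mean(s[setdiff(body_b, masked)]))
})

test_that("polII classification applies the stated thresholds", {
  rec <- tibble::tibble(
    gene_id = c("e", "s", "n", "u1", "u2", "sinf"),
    promoter_score = c(10, 60, 0.5, 6, 3, 7),
    body_score = c(5, 5, 0.5, 1.2, 0.2, 0),
    incomplete = FALSE) |>
    dplyr::mutate(si = ifelse(body_score > 0, promoter_score / body_score,
                              ifelse(promoter_score > 0, Inf, 0)))
  cl <- classify_polii(rec)
  expect_equal(cl$class,
               c("elongating", "stalled", "none", "unclassified",
                 "unclassified", "stalled"))
  # classes are exclusive and exhaustive
  expect_equal(sum(table(cl$class)), nrow(rec))
})

test_that("position histograms are near zero when ChIP equals mock", {
  w <- junction_world()
  tags <- simulate_control_tags(w$layout, 2e4, seed = 50,
                                emit_reads = FALSE)$origins
  ph <- position_histogram(tags, tags, anchor_positions(w, "tss"))
  expect_true(all(ph$value == 0))
})

test_that("doubling both library depths leaves the scaled histogram unchanged", {
  w <- junction_world()
  chip <- simulate_control_tags(w$layout, 1e4, seed = 51,
                                emit_reads = FALSE)$origins
  mock <- simulate_control_tags(w$layout, 1e4, seed = 52,
                                emit_reads = FALSE)$origins
  anchors <- anchor_positions(w, "tss")
  ph1 <- position_histogram(chip, mock, anchors)
  double <- function(t) dplyr::bind_rows(
    t, dplyr::mutate(t, read_id = paste0(read_id, "b")))
  ph2 <- position_histogram(double(chip), double(mock), anchors)
  expect_equal(ph1$value, ph2$value)
})

test_that("mode offset labels windows by their right edge and breaks ties toward the anchor", {
  h <- tibble::tibble(orientation = "sense",
                      offset = seq(-100, 100, by = 5), value = 0)
  h$value[h$offset == 35] <- 7  # the window covering +30..+34
  expect_equal(mode_offset(h, window = c(0, 100)), 35)
  # symmetric tie at +-40: equal distance takes the smaller offset
  h2 <- tibble::tibble(orientation = "sense",
                       offset = seq(-100, 100, by = 5), value = 0)
  h2$value[abs(h2$offset) == 40] <- 3
  expect_equal(mode_offset(h2, window = c(-100, 100)), -40)
  # a tie between +20 and +60 takes the closer-to-anchor window
  h2$value[h2$offset %in% c(20, 60)] <- 5
  expect_equal(mode_offset(h2, window = c(0, 100)), 20)
  expect_warning(m <- mode_offset(h, window = c(60, 80)), "undefined")
  expect_true(is.na(m))
})

test_that("a planted footprint is recovered at the labelled window", {
  cfg <- world_config(chrom_lengths = c(c1 = 5e5), n_genes = 30,
                      families = tibble::tibble(family = character(),
                                                n_copies = integer(),
                                                length = integer(),
                                                identity = numeric()),
                      class_fractions = c(stalled = 0.5, elongating = 0.5,
                                          none = 0))
  w <- build_world(cfg, seed = 12)
  model <- polii_model(w, background = 0.02)
  sim <- simulate_mark_tags(w, model, 2e5, seed = 53, emit_reads = FALSE)
  mock <- simulate_control_tags(w$layout, 2e5, seed = 54,
                                emit_reads = FALSE)$origins
  cls <- w$truth$classes
  tss <- anchor_positions(w, "tss") |>
    dplyr::inner_join(cls, by = "gene_id")
  ph_st <- position_histogram(sim$origins, mock,
                              tss[tss$class == "stalled", ])
  expect_equal(mode_offset(ph_st, window = c(0, 200)), 35)
  ph_el <- position_histogram(sim$origins, mock,
                              tss[tss$class == "elongating", ])
  expect_equal(mode_offset(ph_el, window = c(0, 200)), 45)
  # KS separation of the two populations' 5' end offsets
  rel_st <- chipscore:::relative_tag_offsets(
    sim$origins, tss[tss$class == "stalled", ], flank = 200)
  rel_el <- chipscore:::relative_tag_offsets(
    sim$origins, tss[tss$class == "elongating", ], flank = 200)
  ks <- ks_compare(rel_st$rel, rel_el$rel)
  expect_lt(ks$p, 0.01)
})

test_that("KS comparison is exact on identity and detects shifts", {
  withr::with_seed(55, {
    x <- rnorm(500, 0, 20)
    self <- ks_compare(x, x)
    expect_equal(self$D, 0)
    expect_equal(self$p, 1)
    sh <- ks_compare(x, x + 10)
    expect_lt(sh$p, 0.01)
    expect_warning(ks_compare(x[1:3], x), "unreliable")
    # null calibration: under identical parents the test rejects at about
    # its nominal rate (the two-sample KS p is discrete, hence the slack)
    ps <- vapply(1:200, function(i) {
      ks_compare(rnorm(60), rnorm(60))$p
    }, numeric(1))
    expect_lt(mean(ps < 0.05), 0.10)
    expect_gt(mean(ps < 0.5), 0.25)
  })
})

test_that("junction profiles recover planted exon-side enrichment and depletion", {
  cfg <- world_config(chrom_lengths = c(c1 = 2e6), n_genes = 60,
                      gene_length = c(4000, 8000), mean_exons = 4,
                      families = tibble::tibble(family = character(),
                                                n_copies = integer(),
                                                length = integer(),
                                                identity = numeric()),
                      class_fractions = c(stalled = 0, elongating = 0,
                                          none = 1))
  w <- build_world(cfg, seed = 15)
  model <- mark_model(
    background = 0.5,
    junctions = tibble::tibble(type = c("donor", "acceptor"),
                               offset = c(-90, -30), width = c(40, 20),
                               multiplier = c(8, 0.02)))
  sim_tags <- withr::with_seed(56, {
    land <- chipscore:::build_rate_landscape(w, model)
    chipscore:::draw_tags_from_landscape(land, w$layout, 1e6,
                                         frag_triangular(), 35L)
  })
  mock <- simulate_control_tags(w$layout, 1e6, seed = 57,
                                emit_reads = FALSE)$origins
  jx <- junction_sites(w$genes, min_tss_dist = 500)
  jp <- junction_profiles(sim_tags, mock, jx)
  don <- jp[jp$type == "donor" & jp$orientation == "sense", ]
  expect_equal(don$offset[which.max(don$value)], -90)
  acc <- jp[jp$type == "acceptor" & jp$orientation == "sense", ]
  expect_equal(acc$offset[which.min(acc$value)], -30)
  expect_lt(min(acc$value), 0)  # depletion is negative
  # a uniform model yields a comparatively flat profile
  unif <- simulate_control_tags(w$layout, 1e6, seed = 58,
                                emit_reads = FALSE)$origins
  jp0 <- junction_profiles(unif, mock, jx)
  expect_lt(max(abs(jp0$value)), max(don$value) / 2)
  expect_error(junction_profiles(sim_tags, mock, jx[0, ]), "no junctions")
})

test_that("slowing genes are detected against their body median", {
  w <- junction_world()
  model <- mark_model(
    background = 0.5,
    junctions = tibble::tibble(type = "donor", offset = -90, width = 40,
                               multiplier = 6),
    junction_genes = "gp")
  sim_tags <- withr::with_seed(59, {
    land <- chipscore:::build_rate_landscape(w, model)
    chipscore:::draw_tags_from_landscape(land, w$layout, 2e5,
                                         frag_triangular(), 35L)
  })
  mock <- simulate_control_tags(w$layout, 2e5, seed = 60,
                                emit_reads = FALSE)$origins
  det <- detect_slowing_genes(sim_tags, mock, w, tau = 2)
  expect_true(det$slowing[det$gene_id == "gp"])
  expect_false(det$slowing[det$gene_id == "gm"])
  # the planted gene's window enrichment clearly exceeds its body level
  expect_gt(det$window_enrichment[det$gene_id == "gp"],
            2 * det$body_enrichment[det$gene_id == "gp"])
  # tau = Inf flags nothing
  det_inf <- detect_slowing_genes(sim_tags, mock, w, tau = Inf)
  expect_false(any(det_inf$slowing))
})

test_that("the splice-variant comparison behaves as a Mann-Whitney test", {
  withr::with_seed(61, {
    mk_world <- function(extra) {
      n <- 300
      genes <- tibble::tibble(
        gene_id = sprintf("g%03d", 1:n), chrom = "chr1", start = 0L,
        end = 1000L, strand = "+", n_exons = 3L,
        exon_starts = list(0L), exon_ends = list(1000L), utr5 = 0L,
        utr3 = 0L, class = "none",
        n_variants = 1L + rpois(n, 0.8), slowing = FALSE,
        tss = 0L, txend = 999L)
      genes$n_variants[1:30] <- genes$n_variants[1:30] + extra
      genes
    }
    # planted +1 mean variants in the flagged set: significant
    hits <- 0
    for (i in 1:10) {
      g <- mk_world(extra = 1L + rpois(30, 0.5))
      res <- splice_variant_test(g, flagged = sprintf("g%03d", 1:30))
      if (res$p < 0.01) hits <- hits + 1
    }
    expect_gte(hits, 9)
    # identical distributions: p roughly uniform
    ps <- vapply(1:60, function(i) {
      g <- mk_world(extra = 0L)
      splice_variant_test(g, flagged = sample(g$gene_id, 30))$p
    }, numeric(1))
    expect_gt(mean(ps > 0.05), 0.8)
    g <- mk_world(0L)
    expect_error(splice_variant_test(g, flagged = g$gene_id[1:2]),
                 "at least 3")
    # exon counts are comparable through the same interface
    res_e <- splice_variant_test(g, flagged = g$gene_id[1:30],
                                 variable = "n_exons")
    expect_equal(res_e$variable, "n_exons")
  })
})

test_that("planted polII classes are recovered through the score pipeline", {
  cfg <- world_config(chrom_lengths = c(c1 = 1e6), n_genes = 60,
                      gene_length = c(4000, 8000),
                      families = tibble::tibble(family = character(),
                                                n_copies = integer(),
                                                length = integer(),
                                                identity = numeric()),
                      class_fractions = c(stalled = 1 / 3, elongating = 1 / 3,
                                          none = 1 / 3))
  w <- build_world(cfg, seed = 14)
  model <- polii_model(w)
  sim <- simulate_mark_tags(w, model, 2e5, seed = 62, emit_reads = FALSE)
  mock <- simulate_control_tags(w$layout, 2e5, seed = 63,
                                emit_reads = FALSE)$origins
  sm <- score_matrix(frag_triangular())
  e <- depth_normalize(score_tags(sim$origins, sm, "U", w$layout))
  c0 <- depth_normalize(score_tags(mock, sm, "U", w$layout))
  adj <- subtract_background(e, c0, 1)
  rec <- classify_polii(promoter_body_scores(adj, w))
  truth <- w$truth$classes$class
  got <- rec$class
  agree <- mean(got == truth | (truth == "unclassified"))
  expect_gte(mean(got[truth != "unclassified"] ==
                    truth[truth != "unclassified"]), 0.95)
})
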