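# Shared fixtures and independent oracles for the test suite.

# A small world reused across tests (built once per session).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- world_config(
        chrom_lengths = c(chrA = 3e5, chrB = 2e5),
        n_genes = 30,
        families = tibble::tibble(family = c("FamA", "FamB"),
                                  n_copies = 5L, length = 800L,
                                  identity = 0.95),
        class_fractions = c(stalled = 0.3, elongating = 0.4, none = 0.2),
        slowing_fraction = 0.2)
      cache <<- build_world(cfg, seed = 42)
    }
    cache
  }
})

# Brute-force Hamming mapper: exhaustive scan of every position on both
# strands; returns best-tier sites. Independent of the package's
# pigeonhole search.
oracle_map_read <- function(read, genome) {
  rl <- nchar(read)
  rc <- function(s) chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                                   collapse = ""))
  best <- Inf
  sites <- list()
  for (chrom in names(genome)) {
    gs <- as.character(genome[[chrom]])
    gl <- nchar(gs)
    gchars <- strsplit(gs, "")[[1]]
    rchars_f <- strsplit(read, "")[[1]]
    rchars_r <- strsplit(rc(read), "")[[1]]
    for (start in seq_len(gl - rl + 1)) {
      seg <- gchars[start:(start + rl - 1)]
      mmf <- sum(seg != rchars_f | rchars_f == "N")
      if (mmf <= best) {
        if (mmf < best) { best <- mmf; sites <- list() }
        sites[[length(sites) + 1]] <-
          list(chrom = chrom, pos = start - 1L, strand = "+", mm = mmf)
      }
      mmr <- sum(seg != rchars_r | rchars_r == "N")
      if (mmr <= best) {
        if (mmr < best) { best <- mmr; sites <- list() }
        sites[[length(sites) + 1]] <-
          list(chrom = chrom, pos = start + rl - 2L, strand = "-", mm = mmr)
      }
    }
  }
  sites <- sites[vapply(sites, function(s) s$mm == best, logical(1))]
  list(best = best, sites = dplyr::bind_rows(lapply(sites, tibble::as_tibble)))
}

# Construct a bin_track directly from per-chromosome score vectors.
make_track <- function(scores, bin = 50L, tag_total = 1e7, mode = "U+M",
                       mark = "test", depth_normalized = TRUE) {
  chipscore:::new_bin_track(scores, bin, tag_total, mode, mark,
                            depth_normalized)
}

# Mirror a world and a tag table: position p -> L - 1 - p, strands flipped.
mirror_tags <- function(tags, layout) {
  tags$pos <- layout[tags$chrom] - 1L - tags$pos
  tags$strand <- ifelse(tags$strand == "+", "-", "+")
  tags
}

mirror_genes <- function(genes, layout) {
  L <- layout[genes$chrom]
  out <- genes
  out$start <- L - genes$end
  out$end <- L - genes$start
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  out$tss <- L - 1L - genes$tss
  out$txend <- L - 1L - genes$txend
  out$exon_starts <- purrr::map2(genes$exon_ends, genes$chrom,
                                 function(e, ch) rev(layout[[ch]] - e))
  out$exon_ends <- purrr::map2(genes$exon_starts, genes$chrom,
                               function(s, ch) rev(layout[[ch]] - s))
  out
}

mirror_world <- function(world) {
  w <- world
  w$genes <- mirror_genes(world$genes, world$layout)
  L <- world$layout[world$genes$chrom]
  tx_gene <- match(world$transcripts$gene_id, world$genes$gene_id)
  w$transcripts <- world$transcripts
  w$transcripts$tss <- world$layout[world$genes$chrom[tx_gene]] - 1L -
    world$transcripts$tss
  w$transcripts$txend <- world$layout[world$genes$chrom[tx_gene]] - 1L -
    world$transcripts$txend
  w
}
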