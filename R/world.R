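#' Configuration for a synthetic genome world
#'
#' Parameters controlling [build_world()]: a small multi-chromosome genome
#' carrying protein-coding genes with exon/UTR structure and near-identical
#' transposon-family copies (the latter force genuine multiple-mapping
#' reads), per-gene expression levels, planted RNA polymerase II classes,
#' and a planted set of junction-slowing genes.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp), each >= 10 kb.
#' @param n_genes Number of genes to place.
#' @param gene_length Length-2 vector, min/max gene length (bp).
#' @param mean_exons Mean exon count per gene (1 + Poisson(mean_exons - 1)).
#' @param min_exon,min_intron Minimum exon / intron length (bp).
#' @param utr_length Length-2 vector: 5' and 3' UTR lengths (bp) carved from
#'   the transcript ends (capped at the terminal exon length).
#' @param families Tibble with columns `family`, `n_copies`, `length`,
#'   `identity` describing transposon families; each copy is the family
#'   consensus mutated at per-base rate `1 - identity`.
#' @param margin Minimum gap (bp) enforced between placed features.
#' @param class_fractions Named fractions of genes planted as `stalled`,
#'   `elongating`, `none` (remainder `unclassified`); defaults reflect the
#'   roughly 7-8% per class seen among fly genes with classifiable
#'   promoter-proximal polII.
#' @param slowing_fraction Fraction of multi-exon genes planted as
#'   junction-slowing (extra splice variants, exon-side polII enrichment).
#' @param extra_tss_fraction Fraction of genes given a second, offset TSS
#'   (exercises multi-anchor averaging in metagene profiles).
#' @param max_tries Placement rejection-sampling attempts per feature before
#'   a placement error is raised.
#' @return A `world_config` list.
#' @export
world_config <- function(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                         n_genes = 100,
                         gene_length = c(3000, 9000),
                         mean_exons = 3,
                         min_exon = 150,
                         min_intron = 80,
                         utr_length = c(200, 300),
                         families = tibble(
                           family = c("FamA", "FamB", "FamC"),
                           n_copies = 15L,
                           length = 1500L,
                           identity = 0.90
                         ),
                         margin = 1000,
                         class_fractions = c(stalled = 0.073,
                                             elongating = 0.084,
                                             none = 0.074),
                         slowing_fraction = 0.03,
                         extra_tss_fraction = 0,
                         max_tries = 500) {
  stopifnot(all(chrom_lengths >= 1e4), n_genes > 0,
            length(gene_length) == 2, gene_length[1] <= gene_length[2],
            all(families$n_copies >= 0), all(families$identity >= 0),
            all(families$identity <= 1),
            sum(class_fractions) <= 1, all(class_fractions >= 0))
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(list(
    chrom_lengths = chrom_lengths, n_genes = n_genes,
    gene_length = gene_length, mean_exons = mean_exons,
    min_exon = min_exon, min_intron = min_intron, utr_length = utr_length,
    families = families, margin = margin,
    class_fractions = class_fractions,
    slowing_fraction = slowing_fraction,
    extra_tss_fraction = extra_tss_fraction,
    max_tries = max_tries
  ), class = "world_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(alt, b), 1),
                         character(1))
  }
  chars
}

# Rejection-sample non-overlapping placements (0-based half-open), keeping a
# `margin` gap between features. Errors if a feature cannot be placed.
place_features <- function(lengths, chrom_lengths, margin, max_tries) {
  occupied <- lapply(chrom_lengths, function(x) IRanges::IRanges())
  out <- vector("list", length(lengths))
  chr_names <- names(chrom_lengths)
  probs <- chrom_lengths / sum(chrom_lengths)
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(length(chrom_lengths), 1, prob = probs)
      L <- chrom_lengths[ci]
      if (L < len + 2 * margin) next
      start <- sample.int(L - len - 2 * margin, 1) + margin  # 0-based
      cand <- IRanges::IRanges(start = start + 1 - margin,
                               end = start + len + margin)
      if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0) {
        occupied[[ci]] <- c(occupied[[ci]], cand)
        out[[i]] <- list(chrom = chr_names[ci], start = start,
                         end = start + len)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "could not place feature %d (length %d) without overlap; genome too crowded",
        i, len), class = "chipscore_placement_error")
    }
  }
  out
}

# Split a gene span into exon intervals (0-based genomic, half-open).
make_exons <- function(start, end, n_exons, min_exon, min_intron) {
  len <- end - start
  n_exons <- max(1L, min(n_exons, (len + min_intron) %/% (min_exon + min_intron)))
  if (n_exons == 1L) {
    return(list(starts = start, ends = end, n = 1L))
  }
  free <- len - n_exons * min_exon - (n_exons - 1L) * min_intron
  cuts <- sort(sample.int(free + 1L, 2L * n_exons - 2L, replace = TRUE) - 1L)
  widths <- diff(c(0L, cuts, free))
  exon_len <- min_exon + widths[seq(1, 2 * n_exons - 1, by = 2)]
  intron_len <- min_intron + widths[seq(2, 2 * n_exons - 2, by = 2)]
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- start
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + exon_len[i]
    pos <- ends[i] + if (i < n_exons) intron_len[i] else 0L
  }
  ends[n_exons] <- end  # absorb rounding into last exon
  list(starts = starts, ends = ends, n = n_exons)
}

#' Build a synthetic world: genome, annotation, expression, planted truth
#'
#' Generates random chromosome sequences, inserts transposon-family copies
#' (consensus mutated at per-base rate `1 - identity`, minus-strand copies
#' reverse-complemented), places genes with exon/UTR structure, draws
#' per-gene expression by planted polII class, and records the planted
#' truth used by downstream recovery tests. All coordinates are 0-based
#' half-open; TSS/TxEnd are 0-based positions of the first/last transcribed
#' base.
#'
#' @param config A [world_config()].
#' @param seed Integer seed; identical seeds give byte-identical worlds.
#' @return A `synthetic_world`: list with `genome` (DNAStringSet), `layout`
#'   (chromosome lengths), `genes`, `transcripts`, `transposons`,
#'   `expression` (tibbles), and `truth` (planted parameters).
#' @export
build_world <- function(config = world_config(), seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  withr::with_seed(as.integer(seed), build_world_impl(config, seed))
}

build_world_impl <- function(config, seed) {
  lens <- config$chrom_lengths
  chrom_chars <- lapply(lens, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })

  fam <- config$families
  fam_rows <- fam[rep(seq_len(nrow(fam)), fam$n_copies), , drop = FALSE]
  gene_len <- round(runif(config$n_genes, config$gene_length[1],
                          config$gene_length[2]))
  all_len <- c(fam_rows$length, gene_len)
  placed <- place_features(all_len, lens, config$margin, config$max_tries)

  consensus <- lapply(seq_len(nrow(fam)), function(i) {
    strsplit(random_dna(fam$length[i]), "")[[1]]
  })
  names(consensus) <- fam$family

  n_tx <- nrow(fam_rows)
  tx_list <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    p <- placed[[i]]
    fam_i <- fam_rows$family[i]
    copy <- mutate_dna(consensus[[fam_i]], 1 - fam_rows$identity[i])
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "-") {
      rev(chartr("ACGT", "TGCA", copy))
    } else copy
    chrom_chars[[p$chrom]][(p$start + 1):p$end] <- ins
    tx_list[[i]] <- tibble(copy_id = sprintf("%s_c%02d", fam_i, i),
                           family = fam_i, chrom = p$chrom,
                           start = p$start, end = p$end, strand = strand,
                           identity = fam_rows$identity[i])
  }
  transposons <- if (n_tx > 0) bind_rows(tx_list) else
    tibble(copy_id = character(), family = character(), chrom = character(),
           start = integer(), end = integer(), strand = character(),
           identity = numeric())

  # genes
  n_g <- config$n_genes
  cls <- sample(c(names(config$class_fractions), "unclassified"), n_g,
                replace = TRUE,
                prob = c(config$class_fractions,
                         1 - sum(config$class_fractions)))
  gene_rows <- vector("list", n_g)
  for (i in seq_len(n_g)) {
    p <- placed[[n_tx + i]]
    strand <- sample(c("+", "-"), 1)
    n_ex <- 1L + stats::rpois(1, max(0, config$mean_exons - 1))
    ex <- make_exons(p$start, p$end, n_ex, config$min_exon, config$min_intron)
    gene_rows[[i]] <- tibble(
      gene_id = sprintf("g%04d", i), chrom = p$chrom,
      start = p$start, end = p$end, strand = strand,
      n_exons = ex$n,
      exon_starts = list(ex$starts), exon_ends = list(ex$ends),
      utr5 = config$utr_length[1], utr3 = config$utr_length[2],
      class = cls[i]
    )
  }
  genes <- bind_rows(gene_rows) %>%
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      txend = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
    )

  # splice variants: baseline Poisson; planted slowing genes get more
  n_var <- 1L + stats::rpois(n_g, 0.8)
  multi <- which(genes$n_exons >= 2)
  n_slow <- round(config$slowing_fraction * length(multi))
  slowing <- if (n_slow > 0) sample(multi, n_slow) else integer(0)
  n_var[slowing] <- n_var[slowing] + 1L + stats::rpois(length(slowing), 1.5)
  genes$n_variants <- n_var
  genes$slowing <- seq_len(n_g) %in% slowing

  # expression by planted class (arbitrary linear units)
  expr <- numeric(n_g)
  expr[cls == "none"] <- 0
  expr[cls == "elongating"] <- stats::rlnorm(sum(cls == "elongating"), 4, 0.6)
  expr[cls == "stalled"] <- stats::rlnorm(sum(cls == "stalled"), 2, 1.2)
  expr[cls == "unclassified"] <- stats::rlnorm(sum(cls == "unclassified"), 1, 1)
  expression <- tibble(gene_id = genes$gene_id, expression = expr)

  # transcripts: one per splice variant; optional second TSS for some genes
  transcripts <- genes %>%
    select("gene_id", "tss", "txend", "n_variants") %>%
    tidyr::uncount(.data$n_variants, .id = "variant") %>%
    mutate(transcript_id = sprintf("%s.t%d", .data$gene_id, .data$variant)) %>%
    select("transcript_id", "gene_id", "tss", "txend")
  if (config$extra_tss_fraction > 0) {
    alt <- sample(n_g, round(config$extra_tss_fraction * n_g))
    for (i in alt) {
      dir <- if (genes$strand[i] == "+") 1L else -1L
      transcripts <- bind_rows(transcripts, tibble(
        transcript_id = paste0(genes$gene_id[i], ".alt"),
        gene_id = genes$gene_id[i],
        tss = genes$tss[i] + dir * 200L,
        txend = genes$txend[i]
      ))
    }
  }

  genome <- Biostrings::DNAStringSet(
    vapply(chrom_chars, paste, character(1), collapse = ""))
  names(genome) <- names(lens)

  structure(list(
    genome = genome,
    layout = lens,
    genes = genes,
    transcripts = transcripts,
    transposons = transposons,
    expression = expression,
    truth = list(
      classes = tibble(gene_id = genes$gene_id, class = cls),
      slowing_genes = genes$gene_id[genes$slowing],
      consensus = vapply(consensus, paste, character(1), collapse = ""),
      config = config, seed = seed
    )
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world>\n")
  cat("  chromosomes:", length(x$layout), "totalling",
      format(sum(x$layout), big.mark = ","), "bp\n")
  cat("  genes:", nrow(x$genes), " transposon copies:", nrow(x$transposons),
      "\n")
  cat("  planted polII classes:",
      paste(names(table(x$truth$classes$class)),
            table(x$truth$classes$class), collapse = ", "), "\n")
  invisible(x)
}

#' Anchor coordinates for gene-centric profiles
#'
#' Distinct per-gene anchor positions (0-based) for one of the three
#' alignment points. Genes with multiple annotated TSSs (or TxEnds)
#' contribute all distinct anchors.
#'
#' @param world A `synthetic_world`, or a list with `genes`/`transcripts`.
#' @param anchor One of "tss", "midpoint", "txend".
#' @return Tibble with `gene_id`, `chrom`, `strand`, `pos` (one row per
#'   distinct anchor).
#' @export
anchor_positions <- function(world, anchor = c("tss", "midpoint", "txend")) {
  anchor <- match.arg(anchor)
  g <- world$genes
  base <- g %>% select("gene_id", "chrom", "strand")
  if (anchor == "midpoint") {
    return(base %>% mutate(pos = (g$start + g$end) %/% 2L))
  }
  tx <- world$transcripts %>%
    select("gene_id", pos = all_of(if (anchor == "tss") "tss" else "txend")) %>%
    distinct()
  base %>% inner_join(tx, by = "gene_id")
}

#' Genomic sub-feature intervals of genes (UTRs, CDS, introns)
#'
#' Carves each gene's exon chain into 5' UTR, CDS and 3' UTR along the
#' transcription direction and reports introns, as 0-based half-open
#' genomic intervals.
#'
#' @param genes Gene tibble as in a `synthetic_world`.
#' @return Tibble with `gene_id`, `chrom`, `type`
#'   (utr5/cds/utr3/intron), `start`, `end`.
#' @export
gene_subfeatures <- function(genes) {
  rows <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$strand,
         genes$exon_starts, genes$exon_ends, genes$utr5, genes$utr3),
    function(gid, chrom, strand, es, ee, u5, u3) {
      n <- length(es)
      out <- list()
      if (n > 1) {
        out$intron <- tibble(type = "intron",
                             start = ee[-n], end = es[-1])
      }
      # walk exons in transcription order assigning utr5 | cds | utr3
      ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
      widths <- (ee - es)[ord]
      total <- sum(widths)
      u5 <- min(u5, max(0, total - 1))
      u3 <- min(u3, max(0, total - u5 - 1))
      cum_hi <- cumsum(widths)
      cum_lo <- cum_hi - widths
      pieces <- list()
      for (i in seq_len(n)) {
        lo <- cum_lo[i]; hi <- cum_hi[i]   # transcript bp interval of exon
        segs <- list(
          utr5 = c(0, u5), cds = c(u5, total - u3), utr3 = c(total - u3, total))
        for (ty in names(segs)) {
          a <- max(lo, segs[[ty]][1]); b <- min(hi, segs[[ty]][2])
          if (b > a) {
            # map transcript offsets back to genomic coords
            e_idx <- ord[i]
            if (strand == "+") {
              gs <- es[e_idx] + (a - lo); ge <- es[e_idx] + (b - lo)
            } else {
              ge <- ee[e_idx] - (a - lo); gs <- ee[e_idx] - (b - lo)
            }
            pieces[[length(pieces) + 1]] <-
              tibble(type = ty, start = gs, end = ge)
          }
        }
      }
      bind_rows(c(out, pieces)) %>%
        mutate(gene_id = gid, chrom = chrom, .before = 1)
    })
  bind_rows(rows)
}
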