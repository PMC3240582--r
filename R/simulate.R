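#' Mark-specific enrichment model for tag simulation
#'
#' Describes where a chromatin mark deposits sequencing tags: a genome-wide
#' background rate, a TSS-proximal footprint (offset/width/rate, oriented by
#' gene strand), an expression-scaled gene-body rate, per-family transposon
#' affinities, and splice-junction modifiers. All rates are per-bp in
#' arbitrary units; only their ratios matter because the sampler normalizes
#' the landscape into a probability distribution of fragment 5' positions.
#'
#' Planted footprint offsets name the 5-bp positioning window that should be
#' recovered (windows are labelled by their right edge, so "+35" is the
#' window covering +30..+34); the continuous peak is therefore centered at
#' `offset - 2.5`.
#'
#' @param name Mark label.
#' @param background Background rate per bp (>= 0).
#' @param tss_offset,tss_width,tss_rate TSS footprint: center offset (bp
#'   downstream of TSS in gene orientation), width (bp; the Gaussian sd is
#'   width/4), and per-bp amplitude at the center. Applied to all genes
#'   unless `tss_table` is given.
#' @param tss_table Optional per-gene override: tibble with `gene_id`,
#'   `offset`, `width`, `rate` (genes absent get no TSS footprint).
#' @param body_per_expr Gene-body rate per bp per expression unit.
#' @param body_genes Optional gene ids whose bodies receive signal
#'   (default: all genes).
#' @param family_affinity Named per-bp rates over transposon copies, by
#'   family label.
#' @param junctions Optional tibble with `type` ("donor" for exon-intron,
#'   "acceptor" for intron-exon), `offset`, `width`, `multiplier`: the local
#'   rate is multiplied by `1 + (multiplier - 1) * g(d)` with `g` a Gaussian
#'   bump at the (oriented) offset; multiplier < 1 plants a depletion.
#' @param junction_genes Optional gene ids whose junctions are modified.
#' @return A `mark_model` list.
#' @export
mark_model <- function(name = "mark",
                       background = 1,
                       tss_offset = 0, tss_width = 50, tss_rate = 0,
                       tss_table = NULL,
                       body_per_expr = 0, body_genes = NULL,
                       family_affinity = NULL,
                       junctions = NULL, junction_genes = NULL) {
  stopifnot(background >= 0, tss_rate >= 0, tss_width > 0,
            body_per_expr >= 0, is.finite(tss_offset))
  if (!is.null(family_affinity)) stopifnot(all(family_affinity >= 0))
  if (!is.null(junctions)) stopifnot(all(junctions$multiplier >= 0))
  structure(list(name = name, background = background,
                 tss_offset = tss_offset, tss_width = tss_width,
                 tss_rate = tss_rate, tss_table = tss_table,
                 body_per_expr = body_per_expr, body_genes = body_genes,
                 family_affinity = family_affinity,
                 junctions = junctions, junction_genes = junction_genes),
            class = "mark_model")
}

#' RNA polymerase II model with class-dependent TSS footprints
#'
#' Builds a [mark_model()] whose TSS footprints follow the planted polII
#' classes of a world: stalled genes carry a strong footprint at +35,
#' elongating genes a weaker one at +45 plus expression-scaled gene-body
#' signal, and silent (`none`) genes carry nothing.
#'
#' @param world A `synthetic_world`.
#' @param stalled_offset,elongating_offset Footprint window labels (bp).
#' @param stalled_rate Stalled footprint amplitude (per bp).
#' @param si_raw Target raw stalling index for elongating genes: each
#'   elongating gene's footprint amplitude is derived from its own
#'   expression-scaled body rate so that promoter / body score sits at this
#'   ratio before background subtraction, keeping the planted elongation
#'   strong across the expression range.
#' @param body_per_expr Gene-body rate per bp per expression unit, applied
#'   to elongating genes.
#' @param background Background rate per bp.
#' @param width Footprint width (bp); the Gaussian sd is width/4.
#' @inheritParams mark_model
#' @return A `mark_model`.
#' @export
polii_model <- function(world, stalled_offset = 35, elongating_offset = 45,
                        stalled_rate = 400, si_raw = 1.6,
                        body_per_expr = 0.1, background = 0.02,
                        width = 50, junctions = NULL, junction_genes = NULL) {
  cls <- world$truth$classes
  expr <- setNames(world$expression$expression, world$expression$gene_id)
  elong <- cls$gene_id[cls$class == "elongating"]
  # amplitude solving promoter/body = si_raw per gene: the promoter window
  # (20 bins of 50 bp) holds the whole footprint plus body signal over the
  # downstream half, so mass = 20 * (si_raw - 0.5) * (50 * body rate)
  body_bin <- 50 * body_per_expr * expr[elong]
  mass <- 20 * pmax(si_raw - 0.5, 0.1) * body_bin
  amp <- mass / ((width / 4) * sqrt(2 * pi))
  tt <- bind_rows(
    tibble(gene_id = cls$gene_id[cls$class == "stalled"],
           offset = stalled_offset, width = width, rate = stalled_rate),
    tibble(gene_id = elong, offset = elongating_offset, width = width,
           rate = unname(amp))
  )
  mark_model(name = "polII", background = background, tss_table = tt,
             body_per_expr = body_per_expr,
             body_genes = elong,
             junctions = junctions, junction_genes = junction_genes)
}

# Per-chromosome fragment-5'-rate vectors (position i = 0-based i-1).
build_rate_landscape <- function(world, model) {
  lens <- world$layout
  land <- lapply(lens, function(L) rep(model$background, L))
  genes <- world$genes
  expr <- setNames(world$expression$expression, world$expression$gene_id)

  add_bump <- function(vec, center, sd, amp, L) {
    lo <- max(1L, floor(center - 4 * sd)); hi <- min(L, ceiling(center + 4 * sd))
    if (hi < lo) return(vec)
    idx <- lo:hi
    vec[idx] <- vec[idx] + amp * exp(-((idx - center)^2) / (2 * sd^2))
    vec
  }

  # TSS footprints
  tt <- model$tss_table
  if (is.null(tt) && model$tss_rate > 0) {
    tt <- tibble(gene_id = genes$gene_id, offset = model$tss_offset,
                 width = model$tss_width, rate = model$tss_rate)
  }
  if (!is.null(tt) && nrow(tt) > 0) {
    gi <- genes[match(tt$gene_id, genes$gene_id), ]
    for (i in seq_len(nrow(tt))) {
      dir <- if (gi$strand[i] == "+") 1 else -1
      center <- gi$tss[i] + dir * (tt$offset[i] - 2.5) + 1  # 1-based vec index
      L <- lens[[gi$chrom[i]]]
      land[[gi$chrom[i]]] <- add_bump(land[[gi$chrom[i]]], center,
                                      tt$width[i] / 4, tt$rate[i], L)
    }
  }

  # expression-scaled gene bodies
  if (model$body_per_expr > 0) {
    idx <- if (is.null(model$body_genes)) seq_len(nrow(genes)) else
      which(genes$gene_id %in% model$body_genes)
    for (i in idx) {
      amp <- model$body_per_expr * expr[[genes$gene_id[i]]]
      if (amp > 0) {
        rng <- (genes$start[i] + 1):genes$end[i]
        land[[genes$chrom[i]]][rng] <- land[[genes$chrom[i]]][rng] + amp
      }
    }
  }

  # transposon-family affinities
  fa <- model$family_affinity
  if (!is.null(fa) && nrow(world$transposons) > 0) {
    tx <- world$transposons
    for (i in seq_len(nrow(tx))) {
      amp <- fa[tx$family[i]]
      if (!is.na(amp) && amp > 0) {
        rng <- (tx$start[i] + 1):tx$end[i]
        land[[tx$chrom[i]]][rng] <- land[[tx$chrom[i]]][rng] + amp
      }
    }
  }

  # junction modifiers (multiplicative bump/depletion)
  jm <- model$junctions
  if (!is.null(jm) && nrow(jm) > 0) {
    jx <- junction_sites(genes, min_tss_dist = 0)
    if (!is.null(model$junction_genes)) {
      jx <- jx %>% filter(.data$gene_id %in% model$junction_genes)
    }
    for (r in seq_len(nrow(jm))) {
      jr <- jx %>% filter(.data$type == jm$type[r])
      sdv <- jm$width[r] / 4
      for (i in seq_len(nrow(jr))) {
        dir <- if (jr$strand[i] == "+") 1 else -1
        center <- jr$pos[i] + dir * (jm$offset[r] - 2.5) + 1
        L <- lens[[jr$chrom[i]]]
        lo <- max(1L, floor(center - 4 * sdv))
        hi <- min(L, ceiling(center + 4 * sdv))
        if (hi >= lo) {
          idx <- lo:hi
          g <- exp(-((idx - center)^2) / (2 * sdv^2))
          land[[jr$chrom[i]]][idx] <-
            land[[jr$chrom[i]]][idx] * (1 + (jm$multiplier[r] - 1) * g)
        }
      }
    }
  }
  land
}

# Inverse-CDF categorical sampling of n positions from a rate vector.
# Returns 0-based positions. Exact multinomial (iid draws).
sample_rate_positions <- function(rate, n) {
  if (n == 0) return(integer(0))
  cum <- cumsum(rate)
  tot <- cum[length(cum)]
  if (tot <= 0) abort("rate landscape has zero total mass")
  findInterval(runif(n) * tot, cum) # 0-based position
}

draw_tags_from_landscape <- function(land, lens, n_tags, frag, read_len) {
  tot <- vapply(land, sum, numeric(1))
  n_chr <- as.vector(stats::rmultinom(1, n_tags, tot / sum(tot)))
  rows <- vector("list", length(land))
  for (ci in seq_along(land)) {
    n <- n_chr[ci]
    if (n == 0) next
    L <- lens[[ci]]
    pos <- sample_rate_positions(land[[ci]], n)
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    fl <- sample_frag_lengths(frag, n)
    # resample reads running off the chromosome end
    bad <- which((strand == "+" & pos + read_len > L) |
                   (strand == "-" & pos - read_len + 1 < 0))
    tries <- 0
    while (length(bad) > 0 && tries < 50) {
      pos[bad] <- sample_rate_positions(land[[ci]], length(bad))
      strand[bad] <- ifelse(runif(length(bad)) < 0.5, "+", "-")
      bad <- bad[(strand[bad] == "+" & pos[bad] + read_len > L) |
                   (strand[bad] == "-" & pos[bad] - read_len + 1 < 0)]
      tries <- tries + 1
    }
    if (length(bad) > 0) abort("cannot place reads within chromosome bounds")
    rows[[ci]] <- tibble(chrom = names(lens)[ci], pos = pos,
                         strand = strand, frag_len = fl)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(read_id = character(), chrom = character(), pos = integer(),
                  strand = character(), frag_len = integer(),
                  mismatches = integer(), k = integer()))
  }
  out %>%
    mutate(read_id = sprintf("tag%07d", row_number()),
           mismatches = 0L, k = 1L) %>%
    select("read_id", "chrom", "pos", "strand", "frag_len",
           "mismatches", "k")
}

extract_reads <- function(genome, origins, read_len, error_rate) {
  if (nrow(origins) == 0) {
    return(Biostrings::DNAStringSet())
  }
  plus <- origins$strand == "+"
  start1 <- ifelse(plus, origins$pos + 1L, origins$pos - read_len + 2L)
  seqs <- Biostrings::DNAStringSet(rep("", nrow(origins)))
  for (chrom in unique(origins$chrom)) {
    idx <- which(origins$chrom == chrom)
    v <- Biostrings::extractAt(
      genome[[chrom]],
      IRanges::IRanges(start = start1[idx], width = read_len))
    seqs[idx] <- v
  }
  minus <- which(!plus)
  if (length(minus) > 0) {
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }
  if (error_rate > 0) {
    chars <- strsplit(as.character(seqs), "")
    chars <- lapply(chars, mutate_dna, rate = error_rate)
    seqs <- Biostrings::DNAStringSet(
      vapply(chars, paste, character(1), collapse = ""))
  }
  names(seqs) <- origins$read_id
  seqs
}

#' Simulate mark-specific ChIP tags
#'
#' Draws fragment 5' positions from the mark's planted rate landscape, picks
#' a strand uniformly, samples a fragment length, and emits the first
#' `read_len` bases from the fragment's 5' end. Reads running off a
#' chromosome end are resampled. The true-origin table doubles as a tag
#' table (`k = 1`) so downstream scoring can bypass read mapping.
#'
#' @param world A `synthetic_world`.
#' @param model A [mark_model()].
#' @param n_tags Number of tags to draw.
#' @param frag A [frag_dist()]; its minimum length must be >= `read_len`.
#' @param read_len Read length in bp (default 35).
#' @param error_rate Per-base substitution error probability in emitted reads.
#' @param seed Integer seed (deterministic output).
#' @param emit_reads If FALSE, skip sequence extraction and return only the
#'   true-origin table (fast path for score-level simulations).
#' @return List with `origins` (tibble: read_id, chrom, pos, strand,
#'   frag_len, mismatches, k) and `reads` (named DNAStringSet, or NULL).
#' @export
simulate_mark_tags <- function(world, model, n_tags, frag = frag_triangular(),
                               read_len = 35L, error_rate = 0, seed = 1L,
                               emit_reads = TRUE) {
  stopifnot(inherits(world, "synthetic_world"), inherits(model, "mark_model"),
            n_tags >= 0)
  if (min(frag$length) < read_len) {
    abort("read_len exceeds the shortest supported fragment length",
          class = "chipscore_config_error")
  }
  withr::with_seed(as.integer(seed), {
    land <- build_rate_landscape(world, model)
    origins <- draw_tags_from_landscape(land, world$layout, n_tags, frag,
                                        read_len)
    reads <- if (emit_reads) {
      extract_reads(world$genome, origins, read_len, error_rate)
    } else NULL
    list(origins = origins, reads = reads)
  })
}

#' Simulate control (mock ChIP) tags
#'
#' Uniform genome-wide fragment 5' positions with an optional smooth
#' accessibility bias. Accepts a full world or a bare chromosome-length
#' layout (the fast path used for null calibrations, where no sequence is
#' needed).
#'
#' @param world A `synthetic_world` or a named vector of chromosome lengths.
#' @param bias Optional function `f(pos, len)` returning relative weights
#'   (recycled per chromosome) for a smooth accessibility bias.
#' @inheritParams simulate_mark_tags
#' @return As [simulate_mark_tags()].
#' @export
simulate_control_tags <- function(world, n_tags, frag = frag_triangular(),
                                  read_len = 35L, error_rate = 0, seed = 1L,
                                  bias = NULL, emit_reads = TRUE) {
  lens <- if (inherits(world, "synthetic_world")) world$layout else world
  if (length(lens) == 0 || sum(lens) == 0) {
    abort("genome layout is empty", class = "chipscore_config_error")
  }
  if (min(frag$length) < read_len) {
    abort("read_len exceeds the shortest supported fragment length",
          class = "chipscore_config_error")
  }
  if (emit_reads && !inherits(world, "synthetic_world")) {
    abort("emit_reads = TRUE requires a full world (sequences needed)")
  }
  withr::with_seed(as.integer(seed), {
    if (is.null(bias)) {
      n_chr <- as.vector(stats::rmultinom(1, n_tags, lens / sum(lens)))
      rows <- vector("list", length(lens))
      for (ci in seq_along(lens)) {
        n <- n_chr[ci]
        if (n == 0) next
        L <- lens[[ci]]
        pos <- floor(runif(n) * L)
        strand <- ifelse(runif(n) < 0.5, "+", "-")
        bad <- which((strand == "+" & pos + read_len > L) |
                       (strand == "-" & pos - read_len + 1 < 0))
        while (length(bad) > 0) {
          pos[bad] <- floor(runif(length(bad)) * L)
          strand[bad] <- ifelse(runif(length(bad)) < 0.5, "+", "-")
          bad <- bad[(strand[bad] == "+" & pos[bad] + read_len > L) |
                       (strand[bad] == "-" & pos[bad] - read_len + 1 < 0)]
        }
        rows[[ci]] <- tibble(chrom = names(lens)[ci], pos = as.integer(pos),
                             strand = strand,
                             frag_len = sample_frag_lengths(frag, n))
      }
      origins <- bind_rows(rows)
      if (nrow(origins) == 0) {
        origins <- tibble(read_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          frag_len = integer(), mismatches = integer(),
                          k = integer())
      } else {
        origins <- origins %>%
          mutate(read_id = sprintf("tag%07d", row_number()),
                 mismatches = 0L, k = 1L) %>%
          select("read_id", "chrom", "pos", "strand", "frag_len",
                 "mismatches", "k")
      }
    } else {
      land <- lapply(lens, function(L) bias(seq_len(L), L))
      origins <- draw_tags_from_landscape(land, lens, n_tags, frag, read_len)
    }
    reads <- if (emit_reads) {
      extract_reads(world$genome, origins, read_len, error_rate)
    } else NULL
    list(origins = origins, reads = reads)
  })
}
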