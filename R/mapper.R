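#' Map reads with iteratively relaxed mismatch allowance
#'
#' Exact best-tier Hamming search: mismatch rounds m = 0, 1, ... admit reads
#' whose best genomic hit has exactly m mismatches; iteration stops once the
#' mapped fraction exceeds `majority` or `max_mismatch` is reached. Both
#' strands are searched; every site at a read's minimal mismatch tier is
#' retained (no random site selection), and the number of sites k is
#' recorded so downstream scoring can weight multi-mapping tags by 1/k.
#' Reads with 5 or more ambiguous bases are dropped up front; remaining
#' ambiguous bases count as mismatches at every site. Indels are not
#' modelled.
#'
#' Candidate generation uses pigeonhole trusted bands: at tier m the read is
#' split into m + 1 segments, each used as an exact anchor with up to m
#' mismatches allowed outside it, which guarantees that every site with at
#' most m mismatches is seen; candidates are then verified by exact
#' mismatch counting.
#'
#' @param reads Named DNAStringSet of equal-length reads (or FASTQ path).
#' @param genome DNAStringSet of chromosomes (or FASTA path, or a
#'   `synthetic_world`).
#' @param max_mismatch Maximum mismatch allowance (default 5).
#' @param majority Mapped-fraction stopping rule (default 0.6: stop once
#'   more than 60% of input reads are mapped).
#' @param max_sites Optional cap on retained sites per read (default
#'   unlimited; reads exceeding the cap keep the first `max_sites` sites in
#'   genomic order).
#' @return List with `tags` (tibble: read_id, chrom, pos, strand,
#'   mismatches, k — one row per retained site; `pos` is the 0-based
#'   genomic position of the read's 5' base, for minus-strand hits the
#'   rightmost base of the match) and `stats` (a `mapping_stats` list).
#' @export
map_tags <- function(reads, genome, max_mismatch = 5L, majority = 0.6,
                     max_sites = Inf) {
  if (is.character(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
    names(reads) <- sub("\\s.*$", "", names(reads))
  }
  if (inherits(genome, "synthetic_world")) genome <- genome$genome
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    abort("genome is empty")
  }
  empty_tags <- tibble(read_id = character(), chrom = character(),
                       pos = integer(), strand = character(),
                       mismatches = integer(), k = integer())
  n_total <- length(reads)
  if (n_total == 0) {
    return(list(tags = empty_tags,
                stats = mapping_stats(0L, 0L, tibble(mismatch = integer(),
                                                     mapped_fraction = numeric()),
                                      NA_integer_, empty_tags)))
  }
  rl <- unique(Biostrings::width(reads))
  if (length(rl) != 1) abort("all reads must have equal length")

  # drop reads with >= 5 ambiguous bases
  n_amb <- Biostrings::letterFrequency(reads, "N")[, 1]
  dropped <- sum(n_amb >= 5)
  keep <- n_amb < 5
  reads <- reads[keep]
  read_chars <- strsplit(as.character(reads), "")
  # substitute ambiguity codes for candidate search; exact counts use the
  # original characters (N mismatches everything)
  clean <- Biostrings::DNAStringSet(chartr("NRYSWKMBDHV", "AAAAAAAAAAA",
                                           as.character(reads)))
  names(clean) <- names(reads)
  chrom_chars <- strsplit(as.character(genome), "")

  active <- rep(TRUE, length(reads))
  hits <- vector("list", max_mismatch + 1L)
  rounds <- tibble(mismatch = integer(), mapped_fraction = numeric())
  final_m <- NA_integer_

  for (m in 0:max_mismatch) {
    idx_active <- which(active)
    if (length(idx_active) > 0) {
      cand <- find_candidates(clean[idx_active], genome, m, rl)
      if (nrow(cand) > 0) {
        cand$mm <- count_site_mismatches(cand, read_chars[idx_active],
                                         chrom_chars, rl)
        cand <- cand[cand$mm == m, , drop = FALSE]
        if (nrow(cand) > 0) {
          cand <- distinct(cand[order(cand$read, cand$chrom, cand$pos,
                                      cand$strand), , drop = FALSE])
          if (is.finite(max_sites)) {
            rank_in_read <- sequence(rle(cand$read)$lengths)
            cand <- cand[rank_in_read <= max_sites, , drop = FALSE]
          }
          k_per <- rle(cand$read)$lengths
          gi <- idx_active[cand$read]
          hits[[m + 1L]] <- tibble(
            read_id = names(reads)[gi],
            chrom = names(genome)[cand$chrom],
            pos = cand$pos, strand = cand$strand,
            mismatches = m, k = rep.int(k_per, k_per))
          active[idx_active[unique(cand$read)]] <- FALSE
        }
      }
    }
    frac <- sum(!active) / n_total
    rounds <- bind_rows(rounds, tibble(mismatch = m, mapped_fraction = frac))
    final_m <- m
    if (frac > majority) break
  }

  tags <- bind_rows(hits)
  if (nrow(tags) == 0) tags <- empty_tags
  list(tags = tags,
       stats = mapping_stats(n_total, dropped, rounds, final_m, tags))
}

mapping_stats <- function(total, dropped, rounds, final_m, tags) {
  per_read <- tags %>% distinct(.data$read_id, .data$k)
  uniq <- sum(per_read$k == 1)
  multi <- sum(per_read$k > 1)
  structure(list(
    total_reads = total, dropped_ambiguous = dropped, rounds = rounds,
    final_allowance = final_m,
    mapped = uniq + multi,
    mapped_fraction = if (total > 0) (uniq + multi) / total else NA_real_,
    unique = uniq, multiple = multi,
    multiple_fraction = if (uniq + multi > 0) multi / (uniq + multi) else NA_real_
  ), class = "mapping_stats")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat("<mapping_stats>", x$mapped, "/", x$total_reads, "reads mapped (",
      round(100 * x$mapped_fraction, 1), "% ) at allowance",
      x$final_allowance, "\n")
  cat("  unique:", x$unique, " multiple:", x$multiple, "(",
      round(100 * x$multiple_fraction, 1), "% of mapped )\n")
  invisible(x)
}

#' @method glance mapping_stats
#' @export
glance.mapping_stats <- function(x, ...) {
  tibble(total_reads = x$total_reads, mapped = x$mapped,
         mapped_fraction = x$mapped_fraction,
         final_allowance = x$final_allowance,
         unique = x$unique, multiple = x$multiple,
         multiple_fraction = x$multiple_fraction,
         dropped_ambiguous = x$dropped_ambiguous)
}

# Pigeonhole candidate generation at tier m. Returns tibble(read, chrom,
# pos, strand): read = index into the supplied read set; pos = 0-based
# genomic position of the read 5' base.
find_candidates <- function(reads, genome, m, rl) {
  bounds <- floor(seq(0, rl, length.out = m + 2))
  segs <- cbind(start = bounds[-(m + 2)] + 1, end = bounds[-1])
  rc <- Biostrings::reverseComplement(reads)
  out <- list()
  for (si in seq_len(nrow(segs))) {
    pd_args <- if (m == 0) list(reads) else
      list(reads, tb.start = segs[si, 1], tb.end = segs[si, 2])
    pd_f <- do.call(Biostrings::PDict, pd_args)
    pd_args_rc <- if (m == 0) list(rc) else
      list(rc, tb.start = rl - segs[si, 2] + 1, tb.end = rl - segs[si, 1] + 1)
    pd_r <- do.call(Biostrings::PDict, pd_args_rc)
    for (ci in seq_along(genome)) {
      mf <- Biostrings::matchPDict(pd_f, genome[[ci]], max.mismatch = m)
      st <- Biostrings::startIndex(mf)
      nh <- lengths(st)
      if (sum(nh) > 0) {
        out[[length(out) + 1]] <- tibble(
          read = rep(seq_along(st), nh), chrom = ci,
          pos = unlist(st) - 1L, strand = "+")
      }
      mr <- Biostrings::matchPDict(pd_r, genome[[ci]], max.mismatch = m)
      st <- Biostrings::startIndex(mr)
      nh <- lengths(st)
      if (sum(nh) > 0) {
        # minus-strand 5' base = rightmost genomic base of the match
        out[[length(out) + 1]] <- tibble(
          read = rep(seq_along(st), nh), chrom = ci,
          pos = unlist(st) + rl - 2L, strand = "-")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(read = integer(), chrom = integer(), pos = integer(),
                  strand = character()))
  }
  distinct(bind_rows(out))
}

# Exact per-candidate mismatch counts on the original read characters
# (ambiguous bases mismatch everything since the genome is ACGT).
count_site_mismatches <- function(cand, read_chars, chrom_chars, rl) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(seq_len(nrow(cand)), function(i) {
    rc_ <- read_chars[[cand$read[i]]]
    if (cand$strand[i] == "+") {
      g <- chrom_chars[[cand$chrom[i]]][(cand$pos[i] + 1):(cand$pos[i] + rl)]
      sum(rc_ != g)
    } else {
      g <- chrom_chars[[cand$chrom[i]]][(cand$pos[i] + 1):(cand$pos[i] - rl + 2)]
      sum(rc_ != unname(comp[g]))
    }
  }, numeric(1))
}
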