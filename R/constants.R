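#' Euchromatic chromosome arm lengths of the D. melanogaster BDGP R5 assembly
#'
#' Lengths (bp) of the six euchromatic arms (X, 2L, 2R, 3L, 3R, 4) of the
#' BDGP Release 5 assembly. Tiling these arms into 50-bp windows, counting
#' the final partial window of each arm, yields 2,407,635 windows genome-wide.
#'
#' @format Named integer vector of length 6.
#' @export
dmel_r5_arms <- c(
  chrX  = 22422827L,
  chr2L = 23011544L,
  chr2R = 21146708L,
  chr3L = 24543557L,
  chr3R = 27905053L,
  chr4  = 1351857L
)

#' Count fixed-width tiling windows over a genome layout
#'
#' Each chromosome is tiled independently; a final partial window is counted.
#'
#' @param layout Named numeric vector of chromosome lengths (bp).
#' @param bin Window width in bp (default 50).
#' @return Integer: total number of windows across all chromosomes.
#' @examples
#' genome_window_count(dmel_r5_arms)  # 2407635
#' @export
genome_window_count <- function(layout, bin = 50L) {
  stopifnot(is.numeric(layout), all(layout > 0), bin >= 1)
  as.integer(sum(ceiling(layout / bin)))
}
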