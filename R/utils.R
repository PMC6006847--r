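trio_roles <- c("father", "mother", "child")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Pseudoautosomal regions of the X chromosome (hg19)
#'
#' Default PAR intervals used to route X-chromosome variants to the
#' autosomal classification rules.  Coordinates are 1-based inclusive on
#' the hg19 reference.
#'
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
par_regions_hg19 <- function() {
  data.frame(chrom = c("chrX", "chrX"),
             start = c(60001L, 154931044L),
             end   = c(2699520L, 155260560L),
             stringsAsFactors = FALSE)
}

#' Read pseudoautosomal intervals from a BED file
#'
#' @param path Path to a BED file (0-based half-open, as usual for BED).
#' @return A data.frame with columns `chrom`, `start`, `end` in 1-based
#'   inclusive coordinates, suitable for the `par_regions` arguments.
#' @export
read_par_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED files requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  data.frame(chrom = as.character(df$seqnames),
             start = as.integer(df$start),
             end   = as.integer(df$end),
             stringsAsFactors = FALSE)
}

# vectorised membership of (chrom, pos) in PAR intervals
is_par_site <- function(chrom, pos, par_regions) {
  out <- rep(FALSE, length(pos))
  if (is.null(par_regions) || nrow(par_regions) == 0L) return(out)
  for (i in seq_len(nrow(par_regions))) {
    out <- out | (chrom == par_regions$chrom[i] &
                    pos >= par_regions$start[i] &
                    pos <= par_regions$end[i])
  }
  out
}

# "X-nonPAR" or "autosome" for every site; PAR positions count as autosomal
chrom_class_of <- function(chrom, pos,
                           x_contigs = c("chrX", "X"),
                           par_regions = par_regions_hg19()) {
  data.table::fifelse(chrom %in% x_contigs & !is_par_site(chrom, pos, par_regions),
                      "X-nonPAR", "autosome")
}
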