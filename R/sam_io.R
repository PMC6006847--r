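# SAM/BAM interchange ---------------------------------------------------------
#
# Reads are written as plain SAM with the 10X-style BX barcode tag and,
# optionally, an integer HP haplotype tag; they are read back through
# Rsamtools (SAM is converted to BAM on the fly), so the emitted files
# are validated against htslib, not against our own writer.

#' Write reads as a SAM file
#'
#' Ungapped single-end records: the sequence is constant filler with
#' the read's observed bases substituted at variant positions (the
#' simulated genomes are abstract allele vectors, so only variant
#' positions carry information).
#'
#' @param reads Reads table (`read_id`, `chrom`, `start`, `end`,
#'   `barcode`, `mapq`).
#' @param obs Observation table supplying the per-read bases.
#' @param path Output path (`.sam`).
#' @param contigs data.frame `chrom`/`length` for the header.
#' @param base_quality Constant phred quality written for every base.
#' @param hp Optional integer vector (parallel to `reads`) written as
#'   the `HP` tag; 0/NA means untagged.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, obs, path, contigs, base_quality = 37,
                      hp = NULL) {
  r <- as.data.table(reads)
  o <- as.data.table(obs)[read_id %in% r$read_id]
  ord <- order(r$chrom, r$start)
  r <- r[ord]
  if (!is.null(hp)) hp <- hp[ord]
  w <- r$end - r$start + 1L
  seqs <- strrep("A", w)
  if (nrow(o)) {
    m <- match(o$read_id, r$read_id)
    off <- o$pos - r$start[m] + 1L
    for (i in seq_len(nrow(o)))
      substr(seqs[m[i]], off[i], off[i]) <- o$base[i]
  }
  qual <- strrep(rawToChar(as.raw(base_quality + 33L)), w)
  tags <- ifelse(is.na(r$barcode), "", paste0("\tBX:Z:", r$barcode))
  if (!is.null(hp)) {
    add <- !is.na(hp) & hp != 0L
    tags[add] <- paste0(tags[add], "\tHP:i:", hp[add])
  }
  body <- paste0(r$read_id, "\t0\t", r$chrom, "\t", r$start, "\t", r$mapq,
                 "\t", w, "M\t*\t0\t0\t", seqs, "\t", qual, tags)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$chrom, contigs$length))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read barcoded alignments and extract bases at sites
#'
#' Loads a SAM or BAM file through Rsamtools (SAM input is converted
#' to a temporary BAM first) and, when `sites` are given, extracts the
#' base and base quality each read shows at each covered site,
#' producing the `reads`/`obs` pair the rest of the package works on.
#' Existing `HP` tags are kept in an `hp` column (absent tag = 0,
#' undetermined).
#'
#' @param path SAM or BAM file.
#' @param sample Role label stored in the `sample` column.
#' @param sites Optional table of positions of interest (`chrom`,
#'   `pos`).
#' @return A list with `reads` and `obs` data.tables.
#' @export
read_linked_alignments <- function(path, sample, sites = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "mapq", "seq", "qual"),
    tag = c("BX", "HP"))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  reads <- data.table(read_id = x$qname,
                      sample = sample,
                      chrom = as.character(x$rname),
                      start = x$pos,
                      end = x$pos + x$qwidth - 1L,
                      barcode = x$tag$BX %||% rep(NA_character_, n),
                      mapq = x$mapq,
                      hp_tag = as.integer(x$tag$HP %||% rep(NA_integer_, n)))
  reads[, hp_tag := fifelse(is.na(hp_tag), 0L, hp_tag)]
  obs <- NULL
  if (!is.null(sites) && n > 0L) {
    s <- unique(as.data.table(sites)[, .(chrom, pos)])
    seq_chr <- as.character(x$seq)
    qual_chr <- as.character(x$qual)
    hits <- reads[, .(idx = .I, chrom, start, end)][
      s, on = .(chrom, start <= pos, end >= pos), nomatch = NULL,
      .(idx, chrom, pos = i.pos)]
    if (nrow(hits)) {
      off <- hits$pos - reads$start[hits$idx] + 1L
      b <- substring(seq_chr[hits$idx], off, off)
      qc <- substring(qual_chr[hits$idx], off, off)
      q <- vapply(qc, function(ch) utf8ToInt(ch) - 33L, integer(1L),
                  USE.NAMES = FALSE)
      obs <- data.table(read_id = reads$read_id[hits$idx],
                        sample = sample,
                        chrom = hits$chrom, pos = hits$pos,
                        base = b, baseq = q)
    }
  }
  if (is.null(obs))
    obs <- data.table(read_id = character(), sample = character(),
                      chrom = character(), pos = integer(),
                      base = character(), baseq = integer())
  list(reads = reads[], obs = obs)
}
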