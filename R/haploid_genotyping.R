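# Haplotype-resolved pileups and haploid genotype calls ----------------------

#' Pileup of tagged reads at candidate sites
#'
#' Counts, for every (sample, haplotype, site) combination, how many
#' quality-passing read bases equal the reference allele, the alternate
#' allele, or neither.  A combined `ALL` row per (sample, site) pools
#' the three haplotype partitions; it backs the hemizygous X calls,
#' where one physical haplotype is spread over all tags.
#'
#' @param reads Tagged reads (`hp` column; see [tag_reads()]).
#' @param obs Observation table (`read_id`, `chrom`, `pos`, `base`,
#'   `baseq`).
#' @param sites Table of candidate sites (`chrom`, `pos`, `ref`, `alt`).
#' @param min_baseq,min_mapq Quality filters on the counted bases
#'   (defaults: phred 13 and 0).
#' @return A data.table with columns `sample`, `hap` (`"HP1"`, `"HP2"`,
#'   `"HP0"`, `"ALL"`), `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`, `other_count`.  Sites never touched by a read get
#'   all-zero counts; a site on a chromosome absent from the alignments
#'   is therefore an all-zero column, not an error.
#' @export
pileup_at_sites <- function(reads, obs, sites, min_baseq = 13, min_mapq = 0) {
  r <- as.data.table(reads)
  stopifnot("hp" %in% names(r))
  s <- unique(as.data.table(sites)[, .(chrom, pos, ref, alt)])
  samples <- sort(unique(r$sample))
  grid <- CJ(sample = samples, hap = c("HP0", "HP1", "HP2", "ALL"),
             idx = seq_len(nrow(s)))
  grid <- cbind(grid[, .(sample, hap)], s[grid$idx])

  o <- as.data.table(obs)[baseq >= min_baseq]
  if (!"mapq" %in% names(r)) r[, mapq := 60L]
  o <- merge(o[, .(read_id, chrom, pos, base)],
             r[mapq >= min_mapq, .(read_id, sample, hp)], by = "read_id")
  p <- merge(o, s, by = c("chrom", "pos"))
  counts <- if (nrow(p)) {
    p[, cls := fifelse(base == ref, "ref_count",
                       fifelse(base == alt, "alt_count", "other_count"))]
    p[, hap := paste0("HP", hp)]
    tagged <- p[, .N, by = .(sample, hap, chrom, pos, ref, alt, cls)]
    pooled <- p[, .(hap = "ALL", .N), by = .(sample, chrom, pos, ref, alt, cls)]
    rbind(tagged, pooled, use.names = TRUE)
  } else NULL
  if (!is.null(counts)) {
    w <- dcast(counts, sample + hap + chrom + pos + ref + alt ~ cls,
               value.var = "N", fill = 0L)
    for (col in c("ref_count", "alt_count", "other_count"))
      if (!col %in% names(w)) w[, (col) := 0L]
    out <- merge(grid, w[, .(sample, hap, chrom, pos, ref, alt,
                             ref_count, alt_count, other_count)],
                 by = c("sample", "hap", "chrom", "pos", "ref", "alt"),
                 all.x = TRUE)
    for (col in c("ref_count", "alt_count", "other_count"))
      out[is.na(get(col)), (col) := 0L]
  } else {
    out <- copy(grid)
    for (col in c("ref_count", "alt_count", "other_count"))
      out[, (col) := 0L]
  }
  setorder(out, sample, hap, chrom, pos)
  out[]
}

#' Call a haploid genotype from allele counts
#'
#' Deterministic rule over the ref/alt evidence of one haplotype's
#' pileup column:
#' \itemize{
#'   \item depth (`ref_count + alt_count`) below `min_depth` ->
#'     `UNCOVERED`;
#'   \item both alleles supported -- minor count at least
#'     `min_minor_count` and minor fraction at least
#'     `min_minor_fraction` -- or an exact ref/alt tie -> `CONFLICT`
#'     (a haplotype is one sequence; seeing both alleles convincingly
#'     means the column is not a clean haploid);
#'   \item otherwise the majority allele's state, `REF` or `ALT`.
#' }
#' The defaults (`min_minor_count = 2`, `min_minor_fraction = 0.15`)
#' tolerate a single sequencing error at typical per-haplotype depths.
#' Bases matching neither allele never vote and are only reported.
#'
#' @param ref_count,alt_count Non-negative integer vectors.
#' @param min_depth Minimum depth for a call (default 2, i.e. more than
#'   1 read per haplotype).
#' @param min_minor_count,min_minor_fraction Minor-evidence rule.
#' @return Character vector of states `REF`/`ALT`/`CONFLICT`/`UNCOVERED`.
#' @export
call_haploid_genotype <- function(ref_count, alt_count, min_depth = 2,
                                  min_minor_count = 2,
                                  min_minor_fraction = 0.15) {
  stopifnot(min_depth >= 1, min_minor_fraction > 0, min_minor_fraction < 0.5)
  depth <- ref_count + alt_count
  minor <- pmin(ref_count, alt_count)
  both_pass <- minor >= min_minor_count & minor / pmax(depth, 1L) >= min_minor_fraction
  fcase(depth < min_depth, "UNCOVERED",
        both_pass | ref_count == alt_count, "CONFLICT",
        ref_count > alt_count, "REF",
        default = "ALT")
}

#' Call haploid genotypes over a pileup table
#'
#' @param pileup Output of [pileup_at_sites()].
#' @inheritParams call_haploid_genotype
#' @return The pileup with `state` and `depth` columns appended.
#' @export
call_haploid_genotypes <- function(pileup, min_depth = 2,
                                   min_minor_count = 2,
                                   min_minor_fraction = 0.15) {
  p <- as.data.table(pileup)
  p[, depth := ref_count + alt_count]
  p[, state := call_haploid_genotype(ref_count, alt_count, min_depth,
                                     min_minor_count, min_minor_fraction)]
  p[]
}
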