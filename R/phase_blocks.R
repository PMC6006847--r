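#' Phase blocks of one individual
#'
#' Collects the phased heterozygous sites of one trio member into phase
#' blocks: all sites sharing a phase-set identifier, with the allele
#' carried by each of the two haplotypes.  These are the voting sites
#' used to assign barcoded molecules to haplotypes.
#'
#' @param tv A `trio_variants` table (or any table with the
#'   role-prefixed genotype columns).
#' @param role `"father"`, `"mother"` or `"child"`.
#' @return A `phase_blocks` data.table with columns `owner`, `chrom`,
#'   `block_id`, `pos`, `hap1_allele`, `hap2_allele`, `hap1_base`,
#'   `hap2_base`, sorted by position.  At every site the two haplotype
#'   alleles differ (the sites are heterozygous by construction).
#' @export
phase_blocks <- function(tv, role) {
  role <- match.arg(role, trio_roles)
  tv <- as.data.table(tv)
  a1 <- tv[[paste0(role, "_a1")]]
  a2 <- tv[[paste0(role, "_a2")]]
  ph <- tv[[paste0(role, "_phased")]]
  ps <- tv[[paste0(role, "_ps")]]
  use <- !is.na(a1) & !is.na(a2) & a1 != a2 & ph %in% TRUE & !is.na(ps)
  out <- data.table(owner = role,
                    chrom = tv$chrom[use],
                    block_id = ps[use],
                    pos = tv$pos[use],
                    hap1_allele = a1[use],
                    hap2_allele = a2[use],
                    hap1_base = ifelse(a1[use] == 1L, tv$alt[use], tv$ref[use]),
                    hap2_base = ifelse(a2[use] == 1L, tv$alt[use], tv$ref[use]))
  setorder(out, chrom, pos)
  setattr(out, "class", unique(c("phase_blocks", class(out))))
  out[]
}
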