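library(data.table)

# small, fast simulation used by most unit tests
tiny_cfg <- function(...) {
  defaults <- list(genome_length = 5e4L, n_het_sites = 60L, n_dnms = 4L,
                   n_artifact_sites = 8L, mean_molecule_length = 1.5e4,
                   target_depth_per_haplotype = 6,
                   base_error_rate = 0, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# parse a "0/1"-style genotype independently of the package reader
gt_bits <- function(g) {
  phased <- grepl("|", g, fixed = TRUE)
  tok <- strsplit(g, "[/|]")[[1]]
  a <- suppressWarnings(as.integer(tok))
  list(a1 = a[1], a2 = if (length(a) >= 2) a[2] else NA_integer_,
       phased = phased)
}

# hand-build a trio_variants table from genotype strings
make_tv <- function(father, mother, child, pos = NULL, chrom = "chr1",
                    ref = "A", alt = "C",
                    f_ps = NA_character_, m_ps = NA_character_,
                    c_ps = NA_character_) {
  n <- length(child)
  pos <- pos %||% seq(100L, by = 100L, length.out = n)
  rep_out <- function(x) rep_len(x, n)
  tv <- data.table(chrom = rep_out(chrom), pos = as.integer(pos),
                   ref = rep_out(ref), alt = rep_out(alt))
  gts <- list(father = father, mother = mother, child = child)
  pss <- list(father = rep_out(f_ps), mother = rep_out(m_ps),
              child = rep_out(c_ps))
  for (r in names(gts)) {
    b <- lapply(gts[[r]], gt_bits)
    tv[, paste0(r, c("_a1", "_a2", "_phased", "_ps", "_dp")) := list(
      vapply(b, `[[`, integer(1), "a1"),
      vapply(b, `[[`, integer(1), "a2"),
      vapply(b, `[[`, logical(1), "phased"),
      ifelse(is.na(pss[[r]]), NA_character_, paste0(r, ":", pss[[r]])),
      10L)]
  }
  class(tv) <- unique(c("trio_variants", class(tv)))
  tv
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# hand-build a trio haploid profile table for the classifier
make_profile <- function(f1 = "REF", f2 = "REF", m1 = "REF", m2 = "REF",
                         c1 = "REF", c2 = "ALT", phased = TRUE,
                         chrom = "chr1", pos = 1000L,
                         chrom_class = "autosome",
                         sex = NA_character_,
                         fx = "REF", cx = "ALT",
                         alt_hap = "HP1", hp0 = TRUE) {
  n <- max(lengths(list(f1, f2, m1, m2, c1, c2, phased)))
  r <- function(x) rep_len(x, n)
  dt <- data.table(chrom = r(chrom), pos = as.integer(pos + seq_len(n) - 1L),
                   ref = "A", alt = "C",
                   child_a1 = 0L, child_a2 = 1L,
                   child_vcf_phased = r(phased), child_ps = "child:1",
                   father_hp1 = r(f1), father_hp2 = r(f2),
                   mother_hp1 = r(m1), mother_hp2 = r(m2),
                   child_hp1 = r(c1), child_hp2 = r(c2),
                   father_x = r(fx), child_x = r(cx),
                   d_father_hp1 = 5L, d_father_hp2 = 5L,
                   d_mother_hp1 = 5L, d_mother_hp2 = 5L,
                   d_child_hp1 = 5L, d_child_hp2 = 5L,
                   d_father_x = 10L, d_child_x = 10L,
                   child_phased = r(phased),
                   child_alt_haplotype = r(alt_hap),
                   hp0_supports = r(hp0),
                   chrom_class = r(chrom_class), child_sex = r(sex))
  class(dt) <- unique(c("trio_profiles", class(dt)))
  dt
}

# write VCF text to a temp file
tmp_vcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcf_head <- function(samples, contig = "chr1", len = 100000L) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, len),
    "##INFO=<ID=DQ,Number=1,Type=Float,Description=\"score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
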