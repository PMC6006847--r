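# Trio variant tables -------------------------------------------------------
#
# The central container of the variant layer is a "trio_variants"
# data.table with one row per biallelic site and, for each role
# (father/mother/child), columns <role>_a1, <role>_a2 (allele indices,
# 0 = ref, 1 = alt, NA = missing; a haploid/hemizygous call has a2 = NA),
# <role>_phased, <role>_ps (phase-set id namespaced "<role>:<id>" because
# phase sets are never comparable across individuals), and <role>_dp.

new_trio_variants <- function(dt) {
  setDT(dt)
  setattr(dt, "class", unique(c("trio_variants", class(dt))))
  dt[]
}

# parse a vector of VCF GT strings -> list(a1, a2, phased, valid)
parse_gt_strings <- function(g) {
  g[is.na(g)] <- "."
  valid <- grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", g)
  phased <- grepl("|", g, fixed = TRUE)
  sp <- data.table::tstrsplit(g, "[/|]")
  a1 <- suppressWarnings(as.integer(sp[[1]]))
  a2 <- if (length(sp) >= 2L) suppressWarnings(as.integer(sp[[2]]))
        else rep(NA_integer_, length(g))
  list(a1 = a1, a2 = a2, phased = phased & valid, valid = valid)
}

# remap raw allele indices of a multiallelic record to the k-th alt:
# 0 stays 0, k becomes 1, any other alt becomes missing
remap_allele <- function(a, k) {
  data.table::fifelse(is.na(a), NA_integer_,
                      data.table::fifelse(a == 0L, 0L,
                                          data.table::fifelse(a == k, 1L, NA_integer_)))
}

extract_fmt_safe <- function(v, element, as.numeric = FALSE) {
  tryCatch(suppressWarnings(vcfR::extract.gt(v, element = element,
                                             as.numeric = as.numeric)),
           error = function(e) NULL)
}

#' Read a multi-sample trio VCF
#'
#' Parses a VCF 4.2 file with (at least) the three trio samples and
#' returns one record per biallelic SNV.  Multiallelic records are
#' decomposed into one biallelic record per alternate allele, with
#' allele indices remapped (the decomposed alt becomes 1, other alts
#' become missing).  Non-SNV alleles are skipped unless
#' `include_indels = TRUE`.  Records with a malformed genotype string in
#' any trio sample are skipped with a warning.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param roles Named character vector mapping `father`, `mother` and
#'   `child` to sample names in the VCF, e.g.
#'   `c(father = "NA12891", mother = "NA12892", child = "NA12878")`.
#' @param include_indels Keep non-SNV alleles as well (default `FALSE`).
#' @param score_label Optional name of a per-record score to ingest
#'   (one of `"DQ"`, `"PP"`, `"GL"`, `"PL"`).  Looked up first in INFO,
#'   then in the child's FORMAT fields; stored in a `score` column.
#' @return A `trio_variants` data.table (see package overview).
#' @export
read_trio_vcf <- function(path, roles, include_indels = FALSE,
                          score_label = NULL) {
  stopifnot(all(trio_roles %in% names(roles)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  missing_samples <- setdiff(unname(roles[trio_roles]), colnames(gt))
  if (length(missing_samples))
    stop("sample(s) not present in VCF: ", paste(missing_samples, collapse = ", "))
  ps <- extract_fmt_safe(v, "PS")
  dp <- extract_fmt_safe(v, "DP", as.numeric = TRUE)

  sc <- NULL
  if (!is.null(score_label)) {
    score_label <- match.arg(score_label, c("DQ", "PP", "GL", "PL"))
    sc <- tryCatch(suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = score_label))),
      error = function(e) NULL)
    if (is.null(sc) || all(is.na(sc))) {
      m <- extract_fmt_safe(v, score_label, as.numeric = TRUE)
      if (!is.null(m)) sc <- as.numeric(m[, roles[["child"]]])
    }
    if (is.null(sc)) sc <- rep(NA_real_, nrow(fix))
  }

  parsed <- lapply(trio_roles, function(r) parse_gt_strings(gt[, roles[[r]]]))
  names(parsed) <- trio_roles
  ok <- Reduce(`&`, lapply(parsed, `[[`, "valid"))
  if (any(!ok))
    warning(sum(!ok), " record(s) skipped: malformed genotype field")

  base <- data.table(
    row = seq_len(nrow(fix)),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = toupper(fix[, "REF"]),
    alt_full = toupper(fix[, "ALT"])
  )[ok]
  if (nrow(base) == 0L) return(empty_trio_variants(score = !is.null(score_label)))

  # decompose multiallelics
  alts <- strsplit(base$alt_full, ",", fixed = TRUE)
  nk <- lengths(alts)
  long <- base[rep(seq_len(nrow(base)), nk)]
  long[, `:=`(alt = unlist(alts), k = unlist(lapply(nk, seq_len)))]
  if (!include_indels)
    long <- long[nchar(ref) == 1L & nchar(alt) == 1L & alt != "*"]
  if (nrow(long) == 0L) return(empty_trio_variants(score = !is.null(score_label)))

  out <- long[, .(chrom, pos, ref, alt)]
  for (r in trio_roles) {
    p <- parsed[[r]]
    i <- long$row; k <- long$k
    a1 <- remap_allele(p$a1[i], k)
    a2 <- remap_allele(p$a2[i], k)
    psv <- if (!is.null(ps)) ps[, roles[[r]]][i] else rep(NA_character_, length(i))
    psv <- ifelse(is.na(psv) | psv == ".", NA_character_, paste0(r, ":", psv))
    out[, paste0(r, c("_a1", "_a2", "_phased", "_ps", "_dp")) := list(
      a1, a2, p$phased[i],
      psv,
      if (!is.null(dp)) as.integer(dp[, roles[[r]]][i]) else NA_integer_)]
  }
  if (!is.null(score_label)) {
    out[, score := sc[long$row]]
    tv <- new_trio_variants(out)
    setattr(tv, "score_label", score_label)
    return(tv)
  }
  new_trio_variants(out)
}

empty_trio_variants <- function(score = FALSE) {
  out <- data.table(chrom = character(), pos = integer(),
                    ref = character(), alt = character())
  for (r in trio_roles)
    out[, paste0(r, c("_a1", "_a2", "_phased", "_ps", "_dp")) := list(
      integer(), integer(), logical(), character(), integer())]
  if (score) out[, score := numeric()]
  new_trio_variants(out)
}

#' Read a single-sample phased VCF
#'
#' @param path Path to the VCF.
#' @param role One of `"father"`, `"mother"`, `"child"`; output columns
#'   are prefixed with the role and the phase-set identifiers are
#'   namespaced `"<role>:<PS>"` so that phase sets from different
#'   individuals are never conflated.
#' @param sample Sample name to use; defaults to the first sample.
#' @param include_indels Keep non-SNV alleles (default `FALSE`).
#' @return A data.table with `chrom`, `pos`, `ref`, `alt` and the
#'   role-prefixed genotype columns.
#' @export
read_phased_vcf <- function(path, role, sample = NULL, include_indels = FALSE) {
  role <- match.arg(role, trio_roles)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(sample)) sample <- colnames(gt)[1L]
  if (!sample %in% colnames(gt))
    stop("sample not present in VCF: ", sample)
  roles <- setNames(rep(sample, 3L), trio_roles)
  # reuse the trio reader with all three roles pointing at the one sample,
  # then keep a single role's columns
  tv <- read_trio_vcf(path, roles, include_indels = include_indels)
  keep <- c("chrom", "pos", "ref", "alt",
            paste0(role, c("_a1", "_a2", "_phased", "_ps", "_dp")))
  # the reader namespaced PS by each role name; re-namespace for `role`
  src <- paste0(trio_roles[1L], c("_a1", "_a2", "_phased", "_ps", "_dp"))
  dst <- paste0(role, c("_a1", "_a2", "_phased", "_ps", "_dp"))
  out <- tv[, c("chrom", "pos", "ref", "alt", src), with = FALSE]
  setnames(out, src, dst)
  pscol <- paste0(role, "_ps")
  out[[pscol]] <- ifelse(is.na(out[[pscol]]), NA_character_,
                         sub("^[a-z]+:", paste0(role, ":"), out[[pscol]]))
  out[]
}

#' Merge per-individual phased VCFs into a trio table
#'
#' Takes the three independently phased single-sample VCFs of a trio and
#' merges them into one phased multi-sample table.  The union of sites
#' is kept; an individual without a record at a site has missing
#' genotype columns there.  Phase-set identifiers are preserved but
#' namespaced per individual, because haplotype 1 of one person's phase
#' block bears no relation to haplotype 1 of another's.
#'
#' @param father_vcf,mother_vcf,child_vcf Paths to the three VCFs.
#' @param samples Optional named character vector selecting the sample
#'   in each file (defaults to the first sample of each).
#' @param include_indels Keep non-SNV alleles (default `FALSE`).
#' @return A `trio_variants` data.table sorted by position.
#' @export
merge_phased_vcfs <- function(father_vcf, mother_vcf, child_vcf,
                              samples = NULL, include_indels = FALSE) {
  paths <- c(father = father_vcf, mother = mother_vcf, child = child_vcf)
  tabs <- lapply(trio_roles, function(r)
    read_phased_vcf(paths[[r]], role = r, sample = samples[[r]] %||% NULL,
                    include_indels = include_indels))
  names(tabs) <- trio_roles

  refs <- unique(rbindlist(lapply(tabs, function(t) t[, .(chrom, pos, ref)])))
  if (anyDuplicated(refs[, .(chrom, pos)]))
    stop("conflicting REF allele at the same position across the input VCFs")

  merged <- Reduce(function(x, y)
    merge(x, y, by = c("chrom", "pos", "ref", "alt"), all = TRUE), tabs)
  setorder(merged, chrom, pos, alt)
  new_trio_variants(merged)
}

#' Extract putative de novo mutation candidates
#'
#' A candidate DNM is a site where both parents are observed homozygous
#' reference and the child is heterozygous (alleles 0 and 1).  Records
#' with any missing parental genotype are never candidates.  On the
#' non-pseudoautosomal X with a male child the father is hemizygous and
#' is not consulted: the candidate rule there is mother 0/0 and the
#' child carrying the alternate allele.
#'
#' @param tv A `trio_variants` table.
#' @param child_sex `"male"`, `"female"`, or `NULL` (autosomal data).
#'   Required to evaluate sites on the non-pseudoautosomal X.
#' @param x_contigs Contig names treated as the X chromosome.
#' @param par_regions PAR intervals (treated as autosomal); see
#'   [par_regions_hg19()].
#' @return The subset of `tv` that are candidates, input order preserved.
#' @export
extract_candidate_dnms <- function(tv, child_sex = NULL,
                                   x_contigs = c("chrX", "X"),
                                   par_regions = par_regions_hg19()) {
  f1 <- tv$father_a1; f2 <- tv$father_a2
  m1 <- tv$mother_a1; m2 <- tv$mother_a2
  c1 <- tv$child_a1;  c2 <- tv$child_a2

  mother_homref <- !is.na(m1) & !is.na(m2) & m1 == 0L & m2 == 0L
  father_homref <- !is.na(f1) & !is.na(f2) & f1 == 0L & f2 == 0L
  father_hemi_ref <- !is.na(f1) & is.na(f2) & f1 == 0L
  child_het <- !is.na(c1) & !is.na(c2) & (c1 + c2 == 1L)

  xnp <- chrom_class_of(tv$chrom, tv$pos, x_contigs, par_regions) == "X-nonPAR"
  keep <- father_homref & mother_homref & child_het & !xnp
  if (any(xnp)) {
    if (is.null(child_sex))
      stop("child_sex is required to evaluate X-nonPAR sites")
    child_sex <- match.arg(child_sex, c("male", "female"))
    if (child_sex == "male") {
      child_alt <- (!is.na(c1) & is.na(c2) & c1 == 1L) |
        (!is.na(c1) & !is.na(c2) & (c1 + c2 >= 1L))
      keep <- keep | (xnp & mother_homref & child_alt)
    } else {
      keep <- keep | (xnp & mother_homref & child_het &
                        (father_homref | father_hemi_ref))
    }
  }
  out <- tv[keep]
  out <- new_trio_variants(out)
  if (!is.null(attr(tv, "score_label")))
    setattr(out, "score_label", attr(tv, "score_label"))
  out
}

#' Threshold candidates on an external caller's score
#'
#' Applies the per-program quality threshold (De Novo Quality,
#' Posterior Probability, or Genotype Likelihood) ingested from the
#' source VCF.  Records without a score are kept and counted in a
#' message, since the absence of a score is not evidence against a
#' candidate.
#'
#' @param candidates A `trio_variants` table with a `score` column
#'   (see the `score_label` argument of [read_trio_vcf()]).
#' @param score_label One of `"DQ"`, `"PP"`, `"GL"`, `"PL"`; must match
#'   the ingested label.
#' @param threshold Numeric threshold.
#' @param direction `"ge"` keeps records with score >= threshold,
#'   `"le"` keeps records with score <= threshold.
#' @return The filtered table, order preserved.
#' @export
apply_score_threshold <- function(candidates, score_label, threshold,
                                  direction = c("ge", "le")) {
  score_label <- match.arg(score_label, c("DQ", "PP", "GL", "PL"))
  direction <- match.arg(direction)
  have <- attr(candidates, "score_label")
  if (is.null(have) || !"score" %in% names(candidates))
    stop("no ingested scores on these candidates; read the VCF with score_label")
  if (!identical(have, score_label))
    stop("candidates carry ", have, " scores, not ", score_label)
  s <- candidates$score
  pass <- if (direction == "ge") s >= threshold else s <= threshold
  n_missing <- sum(is.na(s))
  if (n_missing > 0L)
    message(n_missing, " candidate(s) lack a ", score_label,
            " score and were kept")
  out <- candidates[is.na(s) | pass]
  out <- new_trio_variants(out)
  setattr(out, "score_label", have)
  out
}

# VCF writing ---------------------------------------------------------------

fmt_gt_field <- function(a1, a2, phased, ps, dp) {
  t1 <- ifelse(is.na(a1), ".", as.character(a1))
  t2 <- ifelse(is.na(a2), ".", as.character(a2))
  sep <- ifelse(phased, "|", "/")
  gt <- ifelse(!is.na(a1) & is.na(a2), t1, paste0(t1, sep, t2))
  psv <- ifelse(is.na(ps), ".", sub("^[a-z]+:", "", ps))
  dpv <- ifelse(is.na(dp), ".", as.character(dp))
  paste(gt, psv, dpv, sep = ":")
}

vcf_header_lines <- function(contigs, sample_names) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, contigs$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
}

default_contigs <- function(tv) {
  tv <- as.data.table(tv)
  tv[, .(length = max(pos) + 1000L), by = chrom][, .(chrom, length)]
}

#' Write a trio table as a multi-sample VCF
#'
#' Emits plain-text VCF 4.2 with `GT:PS:DP` FORMAT fields.  Per-role
#' phase-set namespacing is stripped on output (PS is per-sample in a
#' VCF already).
#'
#' @param tv A `trio_variants` table.
#' @param path Output path.
#' @param sample_names Sample names for the father, mother and child
#'   columns, in that order.
#' @param contigs Optional data.frame `chrom`/`length` for the header.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(tv, path,
                           sample_names = c("FATHER", "MOTHER", "CHILD"),
                           contigs = NULL) {
  tv <- as.data.table(tv)
  contigs <- contigs %||% default_contigs(tv)
  cols <- vapply(trio_roles, function(r)
    fmt_gt_field(tv[[paste0(r, "_a1")]], tv[[paste0(r, "_a2")]],
                 tv[[paste0(r, "_phased")]], tv[[paste0(r, "_ps")]],
                 tv[[paste0(r, "_dp")]]),
    character(nrow(tv)))
  if (nrow(tv) == 1L) cols <- matrix(cols, nrow = 1L)
  body <- paste(tv$chrom, tv$pos, ".", tv$ref, tv$alt, ".", ".", ".",
                "GT:PS:DP",
                if (nrow(tv)) cols[, 1L] else character(),
                if (nrow(tv)) cols[, 2L] else character(),
                if (nrow(tv)) cols[, 3L] else character(),
                sep = "\t")
  if (nrow(tv) == 0L) body <- character()
  writeLines(c(vcf_header_lines(contigs, sample_names), body), path)
  invisible(path)
}

#' Write one individual's phased genotypes as a single-sample VCF
#'
#' @param tv A table carrying `<role>_*` genotype columns (a
#'   `trio_variants` table or the output of [read_phased_vcf()]).
#' @param role Which individual to write.
#' @param path Output path.
#' @param sample_name Sample name in the header.
#' @param contigs Optional data.frame `chrom`/`length`.
#' @param drop_missing Drop records where this individual's genotype is
#'   entirely missing (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(tv, role, path, sample_name = toupper(role),
                             contigs = NULL, drop_missing = TRUE) {
  role <- match.arg(role, trio_roles)
  tv <- as.data.table(tv)
  contigs <- contigs %||% default_contigs(tv)
  a1 <- tv[[paste0(role, "_a1")]]
  if (drop_missing) tv <- tv[!is.na(a1)]
  gts <- fmt_gt_field(tv[[paste0(role, "_a1")]], tv[[paste0(role, "_a2")]],
                      tv[[paste0(role, "_phased")]], tv[[paste0(role, "_ps")]],
                      tv[[paste0(role, "_dp")]])
  body <- if (nrow(tv)) paste(tv$chrom, tv$pos, ".", tv$ref, tv$alt, ".", ".",
                              ".", "GT:PS:DP", gts, sep = "\t") else character()
  writeLines(c(vcf_header_lines(contigs, sample_name), body), path)
  invisible(path)
}
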