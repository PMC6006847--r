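# Trio haploid profiles and DNM classification -------------------------------

#' Assemble trio haploid profiles at candidate sites
#'
#' Combines the six haploid calls (father/mother/child x HP1/HP2) with
#' the child's phasing information into one row per candidate.  On the
#' non-pseudoautosomal X the father's single haplotype and a male
#' child's single X are taken from the pooled (`ALL`) pileup, since a
#' hemizygous chromosome is naturally phased and every read belongs to
#' its one haplotype.
#'
#' @param candidates Candidate `trio_variants` rows (see
#'   [extract_candidate_dnms()]).
#' @param calls Output of [call_haploid_genotypes()] at the candidate
#'   sites.
#' @param child_sex `"male"`, `"female"`, or `NULL` (required for
#'   X-nonPAR sites).
#' @param x_contigs,par_regions X-chromosome routing, as elsewhere.
#' @return A `trio_profiles` data.table: the six haploid states and
#'   depths, hemizygous `father_x`/`child_x` calls, `child_phased`,
#'   `child_alt_haplotype` (`"HP1"`/`"HP2"`/`NA`), HP0 support for the
#'   child's het call, `chrom_class` and `child_sex`.
#' @export
assemble_trio_profiles <- function(candidates, calls, child_sex = NULL,
                                   x_contigs = c("chrX", "X"),
                                   par_regions = par_regions_hg19()) {
  cand <- as.data.table(candidates)
  calls <- as.data.table(calls)
  prof <- cand[, .(chrom, pos, ref, alt,
                   child_a1, child_a2,
                   child_vcf_phased = child_phased, child_ps)]
  key <- c("chrom", "pos", "ref", "alt")
  parts <- list(
    list("father", "HP1", "father_hp1"), list("father", "HP2", "father_hp2"),
    list("mother", "HP1", "mother_hp1"), list("mother", "HP2", "mother_hp2"),
    list("child",  "HP1", "child_hp1"),  list("child",  "HP2", "child_hp2"),
    list("father", "ALL", "father_x"),   list("child",  "ALL", "child_x"),
    list("child",  "HP0", "child_hp0"))
  for (p in parts) {
    x <- calls[calls$sample == p[[1]] & calls$hap == p[[2]],
               c(key, "state", "depth", "ref_count", "alt_count"),
               with = FALSE]
    setnames(x, c("state", "depth", "ref_count", "alt_count"),
             paste0(p[[3]], c("", "_d", "_rc", "_ac")))
    prof <- merge(prof, x, by = key, all.x = TRUE, sort = FALSE)
  }
  het <- !is.na(prof$child_a1) & !is.na(prof$child_a2) &
    prof$child_a1 + prof$child_a2 == 1L
  prof[, child_phased := child_vcf_phased %in% TRUE & !is.na(child_ps) & het]
  prof[, child_alt_haplotype :=
         fifelse(child_phased & child_a1 == 1L, "HP1",
                 fifelse(child_phased & child_a2 == 1L, "HP2", NA_character_))]
  prof[, hp0_supports := child_hp0_rc >= 1L & child_hp0_ac >= 1L]
  prof[, chrom_class := chrom_class_of(chrom, pos, x_contigs, par_regions)]
  prof[, child_sex := if (is.null(child_sex)) NA_character_ else child_sex]
  drop <- grep("_rc$|_ac$", names(prof), value = TRUE)
  prof[, (drop) := NULL]
  setnames(prof,
           paste0(c("father_hp1", "father_hp2", "mother_hp1", "mother_hp2",
                    "child_hp1", "child_hp2", "father_x", "child_x"), "_d"),
           paste0("d_", c("father_hp1", "father_hp2", "mother_hp1",
                          "mother_hp2", "child_hp1", "child_hp2",
                          "father_x", "child_x")))
  setattr(prof, "class", unique(c("trio_profiles", class(prof))))
  prof[]
}

#' Is a profile a high-confidence site?
#'
#' TRUE when all six haploid calls are clean haploid genotypes
#' (`REF` or `ALT`): no conflicting haplotype and no haplotype below
#' the depth minimum.
#'
#' @param profiles A `trio_profiles` table (autosomal contract).
#' @return Logical vector.
#' @export
classify_site_confidence <- function(profiles) {
  p <- as.data.table(profiles)
  cols <- c("father_hp1", "father_hp2", "mother_hp1", "mother_hp2",
            "child_hp1", "child_hp2")
  Reduce(`&`, lapply(cols, function(cl) p[[cl]] %in% c("REF", "ALT")))
}

# shared rule engine over an arbitrary haploid set -----------------------------
# parental: matrix of parental haploid states; child: matrix of child states
# (one column for a hemizygous child); phased: logical (TRUE when the site
# is naturally phased). Returns list(label, reason).
classify_haploid_set <- function(parental, child, phased) {
  n <- nrow(parental)
  all_states <- cbind(parental, child)
  any_par_alt <- rowSums(parental == "ALT", na.rm = TRUE) > 0L
  any_conflict <- rowSums(all_states == "CONFLICT", na.rm = TRUE) > 0L
  child_callable <- rowSums(matrix(child %in% c("REF", "ALT"),
                                   nrow = n)) == ncol(child)
  child_pattern <- if (ncol(child) == 2L) {
    rowSums(child == "ALT", na.rm = TRUE) == 1L &
      rowSums(child == "REF", na.rm = TRUE) == 1L
  } else {
    child[, 1L] == "ALT"
  }
  any_unc <- rowSums(all_states == "UNCOVERED", na.rm = TRUE) > 0L

  label <- character(n); reason <- character(n)
  rem1 <- any_par_alt
  rem2 <- !rem1 & any_conflict
  rem3 <- !rem1 & !rem2 & child_callable & !child_pattern
  low1 <- !rem1 & !rem2 & !rem3 & any_unc
  low2 <- !rem1 & !rem2 & !rem3 & !low1 & !phased
  high <- !rem1 & !rem2 & !rem3 & !low1 & !low2
  label[rem1 | rem2 | rem3] <- "REMOVED"
  label[low1 | low2] <- "L"
  label[high] <- "H"
  reason[rem1] <- "parental-alt-haplotype"
  reason[rem2] <- "haploid-conflict"
  reason[rem3] <- "child-not-0-1"
  reason[low1] <- "uncovered-haplotype"
  reason[low2] <- "unphased"
  reason[high] <- ""
  list(label = label, reason = reason)
}

#' Classify autosomal candidate DNMs
#'
#' Applies the haploid decision rule to the six-haplotype profile of
#' each autosomal (or pseudoautosomal) candidate:
#' \itemize{
#'   \item `REMOVED` when any parental haploid carries the alternate
#'     allele, any haploid is in conflict, or the child's two callable
#'     haploids are not one `REF` and one `ALT` -- positive evidence of
#'     an inherited variant or a miscall (reason codes, in precedence
#'     order: `parental-alt-haplotype`, `haploid-conflict`,
#'     `child-not-0-1`);
#'   \item `L` (low confidence) when, absent such counter-evidence, at
#'     least one haplotype is uncovered, or the full high-confidence
#'     pattern is present but the child's variant is not phased --
#'     missing information, kept for further consideration;
#'   \item `H` (high confidence) when all six haploids are callable,
#'     all four parental haploids are `REF`, the child's haploids are
#'     exactly `REF` and `ALT`, and the child's variant is phased.
#' }
#'
#' @param profiles A `trio_profiles` table of autosomal candidates.
#' @return The table with `label` and `reason` columns appended.
#' @export
classify_autosomal_dnm <- function(profiles) {
  p <- as.data.table(profiles)
  parental <- as.matrix(p[, .(father_hp1, father_hp2, mother_hp1, mother_hp2)])
  child <- as.matrix(p[, .(child_hp1, child_hp2)])
  res <- classify_haploid_set(parental, child, p$child_phased %in% TRUE)
  p[, `:=`(label = res$label, reason = res$reason)]
  p[]
}

#' Classify candidate DNMs on the non-pseudoautosomal X
#'
#' A male's X is naturally phased, so hemizygous calls stand in for a
#' phase block.  With a female child the same rule as the autosomes is
#' applied over five haploids (the father contributes his single X);
#' with a male child only the mother's two haploids and the child's
#' single X are considered, and the high-confidence pattern is mother
#' `REF`/`REF` with the child's X called `ALT`.  Pseudoautosomal sites
#' must be routed to [classify_autosomal_dnm()] (see
#' [classify_dnms()]).
#'
#' @param profiles A `trio_profiles` table of X-nonPAR candidates with
#'   `child_sex` set.
#' @return The table with `label` and `reason` columns appended.
#' @export
classify_chrx_dnm <- function(profiles) {
  p <- as.data.table(profiles)
  if (nrow(p) == 0L) {
    p[, `:=`(label = character(), reason = character())]
    return(p[])
  }
  if (any(is.na(p$child_sex)))
    stop("child_sex is required to classify X-nonPAR candidates")
  lab <- character(nrow(p)); rea <- character(nrow(p))
  male <- p$child_sex == "male"
  if (any(male)) {
    parental <- as.matrix(p[male, .(mother_hp1, mother_hp2)])
    child <- as.matrix(p[male, .(child_x)])
    res <- classify_haploid_set(parental, child, rep(TRUE, sum(male)))
    lab[male] <- res$label; rea[male] <- res$reason
  }
  if (any(!male)) {
    parental <- as.matrix(p[!male, .(father_x, mother_hp1, mother_hp2)])
    child <- as.matrix(p[!male, .(child_hp1, child_hp2)])
    res <- classify_haploid_set(parental, child, p$child_phased[!male] %in% TRUE)
    lab[!male] <- res$label; rea[!male] <- res$reason
  }
  p[, `:=`(label = lab, reason = rea)]
  p[]
}

#' Classify all candidates, dispatching autosome vs X rules
#'
#' @param profiles A `trio_profiles` table.
#' @return The table with `label`, `reason` and a default
#'   `parent_of_origin = "unknown"` column appended; every candidate
#'   receives exactly one of the labels `H`, `L`, `REMOVED`.
#' @export
classify_dnms <- function(profiles) {
  p <- as.data.table(profiles)
  if (nrow(p) == 0L) {
    p[, `:=`(label = character(0), reason = character(0),
             parent_of_origin = character(0))]
    return(p[])
  }
  p[, orig_order := .I]
  auto <- p[chrom_class == "autosome"]
  xnp <- p[chrom_class == "X-nonPAR"]
  out <- rbind(if (nrow(auto)) classify_autosomal_dnm(auto) else NULL,
               if (nrow(xnp)) classify_chrx_dnm(xnp) else NULL,
               fill = TRUE)
  if (is.null(out) || nrow(out) == 0L) {
    p[, `:=`(label = character(0), reason = character(0),
             parent_of_origin = character(0))]
    return(p[])
  }
  setorder(out, orig_order)
  out[, orig_order := NULL]
  out[, parent_of_origin := "unknown"]
  out[]
}

#' Infer the parent-of-origin of a phased DNM
#'
#' The DNM sits on one of the child's two phased haplotypes.  Every
#' other phased heterozygous site in the same child phase block where
#' the allele carried by that haplotype could have been transmitted by
#' exactly one parent casts a vote for that parent; the majority
#' decides.  A tie, or no informative site, returns `"unknown"`.  On a
#' male child's X-nonPAR the answer is `"maternal"` by construction.
#'
#' @param tv The full `trio_variants` table (the inherited sites around
#'   the candidate supply the votes).
#' @param sites data.frame/table of candidate positions with columns
#'   `chrom`, `pos` and `child_alt_haplotype` (`"HP1"` or `"HP2"`).
#' @return Character vector (`"maternal"`, `"paternal"`, `"unknown"`),
#'   one per row of `sites`.
#' @export
infer_parent_of_origin <- function(tv, sites) {
  tv <- as.data.table(tv)
  s <- as.data.table(sites)
  n <- nrow(s)
  out <- rep("unknown", n)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    side <- s$child_alt_haplotype[i]
    if (is.na(side)) next
    rec <- tv[chrom == s$chrom[i] & pos == s$pos[i]]
    if (nrow(rec) == 0L || is.na(rec$child_ps[1L])) next
    block <- tv[chrom == s$chrom[i] & child_ps == rec$child_ps[1L] &
                  pos != s$pos[i] &
                  child_phased %in% TRUE &
                  !is.na(child_a1) & !is.na(child_a2) & child_a1 != child_a2]
    if (nrow(block) == 0L) next
    allele <- if (side == "HP1") block$child_a1 else block$child_a2
    f_obs <- !is.na(block$father_a1)
    m_obs <- !is.na(block$mother_a1)
    f_can <- f_obs & (block$father_a1 == allele |
                        (!is.na(block$father_a2) & block$father_a2 == allele))
    m_can <- m_obs & (block$mother_a1 == allele |
                        (!is.na(block$mother_a2) & block$mother_a2 == allele))
    informative <- f_obs & m_obs & xor(f_can, m_can)
    nm <- sum(informative & m_can)
    nf <- sum(informative & f_can)
    if (nm > nf) out[i] <- "maternal"
    else if (nf > nm) out[i] <- "paternal"
  }
  out
}

#' Write the DNM report
#'
#' The main flat file carries one row per high- or low-confidence
#' candidate (`H`/`L`), annotated with parent-of-origin, the six
#' haploid states and depths, and the reason code.  Removed candidates
#' never appear in the main file; they go to a companion audit file.
#'
#' @param classified Output of [classify_dnms()] (with
#'   `parent_of_origin` filled in).
#' @param prefix Output path prefix; writes `<prefix>.dnm.tsv` and
#'   `<prefix>.removed.tsv`.
#' @return Invisibly, a named list of the two paths.
#' @export
write_dnm_report <- function(classified, prefix) {
  cl <- as.data.table(classified)
  cols <- c("chrom", "pos", "ref", "alt", "label", "parent_of_origin",
            "father_hp1", "father_hp2", "mother_hp1", "mother_hp2",
            "child_hp1", "child_hp2",
            "d_father_hp1", "d_father_hp2", "d_mother_hp1", "d_mother_hp2",
            "d_child_hp1", "d_child_hp2", "hp0_supports", "reason")
  cols <- intersect(cols, names(cl))
  main_path <- paste0(prefix, ".dnm.tsv")
  removed_path <- paste0(prefix, ".removed.tsv")
  fwrite(cl[label %in% c("H", "L"), ..cols], main_path, sep = "\t")
  fwrite(cl[label == "REMOVED", ..cols], removed_path, sep = "\t")
  invisible(list(main = main_path, removed = removed_path))
}
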