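# End-to-end orchestration ----------------------------------------------------

#' Pipeline parameters
#'
#' One bag for every tunable of the workflow, with the package
#' defaults: per-haplotype depth minimum 2 (more than 1 read), the
#' haploid genotyper's minor-evidence rule, a 50 kb molecule gap,
#' phred 13 voting bases, and hg19 PAR intervals.
#'
#' @param min_depth Per-haplotype minimum depth for a haploid call.
#' @param min_minor_count,min_minor_fraction Minor-evidence rule of
#'   [call_haploid_genotype()].
#' @param gap_threshold Molecule gap threshold in bp.
#' @param min_baseq Minimum base quality for voting and pileup bases.
#' @param min_mapq Minimum mapping quality for pileup bases.
#' @param child_sex `"male"`, `"female"`, or `NULL` (no X-nonPAR
#'   sites expected).
#' @param x_contigs Contig names treated as chromosome X.
#' @param par_regions PAR intervals (data.frame `chrom`/`start`/`end`).
#' @param tag_mode `"recompute"` haplotype tags from phased VCFs
#'   (default) or `"trust"` existing HP tags in the alignments.
#' @return A named list of parameters.
#' @export
hapdenovo_params <- function(min_depth = 2, min_minor_count = 2,
                             min_minor_fraction = 0.15,
                             gap_threshold = 5e4, min_baseq = 13,
                             min_mapq = 0, child_sex = NULL,
                             x_contigs = c("chrX", "X"),
                             par_regions = par_regions_hg19(),
                             tag_mode = c("recompute", "trust")) {
  list(min_depth = min_depth, min_minor_count = min_minor_count,
       min_minor_fraction = min_minor_fraction,
       gap_threshold = gap_threshold, min_baseq = min_baseq,
       min_mapq = min_mapq, child_sex = child_sex, x_contigs = x_contigs,
       par_regions = par_regions, tag_mode = match.arg(tag_mode))
}

#' Run the full DNM filtering workflow in memory
#'
#' Chains the three stages: candidate extraction from the phased trio
#' table (plus an optional external-caller score threshold), molecule
#' grouping and haplotype tagging of the reads, haplotype-resolved
#' pileup and haploid genotyping at the candidate sites, and
#' classification with parent-of-origin inference.
#'
#' @param variants A phased `trio_variants` table (e.g. from
#'   [merge_phased_vcfs()] or [simulate_trio()]).
#' @param reads,obs Alignment tables for all three individuals (the
#'   `sample` column holds the role).
#' @param params A [hapdenovo_params()] list.
#' @param score_filter Optional `list(label=, threshold=, direction=)`
#'   applied to the candidates via [apply_score_threshold()].
#' @param candidates Optional pre-extracted candidate table (e.g. an
#'   external DNM caller's candidates read through [read_trio_vcf()]);
#'   default extracts them from `variants`.
#' @return A `hapdenovo_result` list: `candidates`, `profiles`,
#'   `classified` (labels, reasons, parent-of-origin) and per-stage
#'   `counts`.
#' @export
hapdenovo_run <- function(variants, reads, obs,
                          params = hapdenovo_params(),
                          score_filter = NULL, candidates = NULL) {
  tv <- as.data.table(variants)
  cand <- candidates %||%
    extract_candidate_dnms(tv, child_sex = params$child_sex,
                           x_contigs = params$x_contigs,
                           par_regions = params$par_regions)
  if (!is.null(score_filter))
    cand <- apply_score_threshold(cand, score_filter$label,
                                  score_filter$threshold,
                                  score_filter$direction %||% "ge")
  blocks <- rbindlist(lapply(trio_roles, function(r) phase_blocks(tv, r)))
  tagged <- tag_reads(reads, obs, blocks,
                      gap_threshold = params$gap_threshold,
                      min_baseq = params$min_baseq,
                      mode = params$tag_mode)
  pu <- pileup_at_sites(tagged, obs, cand,
                        min_baseq = params$min_baseq,
                        min_mapq = params$min_mapq)
  calls <- call_haploid_genotypes(pu, params$min_depth,
                                  params$min_minor_count,
                                  params$min_minor_fraction)
  prof <- assemble_trio_profiles(cand, calls,
                                 child_sex = params$child_sex,
                                 x_contigs = params$x_contigs,
                                 par_regions = params$par_regions)
  cls <- classify_dnms(prof)
  keep <- cls$label %in% c("H", "L")
  xmale <- cls$chrom_class == "X-nonPAR" &
    !is.na(cls$child_sex) & cls$child_sex == "male"
  poo <- rep("unknown", nrow(cls))
  if (any(keep & !xmale))
    poo[keep & !xmale] <- infer_parent_of_origin(tv, cls[keep & !xmale])
  poo[keep & xmale] <- "maternal"
  if (nrow(cls)) cls[, parent_of_origin := poo]
  counts <- c(n_variants = nrow(tv), n_candidates = nrow(cand),
              n_reads = nrow(as.data.table(reads)),
              n_hp1 = sum(tagged$hp == 1L), n_hp2 = sum(tagged$hp == 2L),
              n_hp0 = sum(tagged$hp == 0L),
              n_H = sum(cls$label == "H"), n_L = sum(cls$label == "L"),
              n_removed = sum(cls$label == "REMOVED"))
  message("candidates: ", counts[["n_candidates"]],
          " | H: ", counts[["n_H"]], " L: ", counts[["n_L"]],
          " removed: ", counts[["n_removed"]])
  structure(list(candidates = cand, tagged_reads = tagged,
                 calls = calls, profiles = prof, classified = cls,
                 counts = counts),
            class = "hapdenovo_result")
}

#' Run the workflow from standard files
#'
#' File-based front end: per-individual phased VCFs (and optionally a
#' separate multi-sample candidate VCF from any variant caller),
#' barcoded SAM/BAM alignments, and an output prefix.  Writes the
#' H/L report, the removed-candidate audit file, and a YAML manifest
#' of parameters, input checksums and package version; two runs with
#' equal manifests produce equal reports.
#'
#' @param phased_vcf_father,phased_vcf_mother,phased_vcf_child Paths
#'   to the per-individual phased VCFs.
#' @param bam_father,bam_mother,bam_child Paths to the barcoded
#'   alignments (SAM or BAM).
#' @param out_prefix Output path prefix.
#' @param trio_vcf Optional multi-sample VCF supplying the candidate
#'   set (defaults to candidates extracted from the merged phased
#'   VCFs).
#' @param roles Sample-name mapping for `trio_vcf` (see
#'   [read_trio_vcf()]).
#' @param params A [hapdenovo_params()] list.
#' @param score_filter Optional score threshold, as in
#'   [hapdenovo_run()]; when used, `trio_vcf` must have been read with
#'   the matching score label, so pass `score_label` too.
#' @param score_label Score to ingest from `trio_vcf`.
#' @return The `hapdenovo_result`, with `paths` of the written files
#'   attached.
#' @export
hapdenovo_run_files <- function(phased_vcf_father, phased_vcf_mother,
                                phased_vcf_child,
                                bam_father, bam_mother, bam_child,
                                out_prefix,
                                trio_vcf = NULL, roles = NULL,
                                params = hapdenovo_params(),
                                score_filter = NULL, score_label = NULL) {
  tv <- merge_phased_vcfs(phased_vcf_father, phased_vcf_mother,
                          phased_vcf_child)
  cand <- NULL
  if (!is.null(trio_vcf)) {
    ext <- read_trio_vcf(trio_vcf, roles = roles %||%
                           c(father = "FATHER", mother = "MOTHER",
                             child = "CHILD"),
                         score_label = score_label)
    cand <- extract_candidate_dnms(ext, child_sex = params$child_sex,
                                   x_contigs = params$x_contigs,
                                   par_regions = params$par_regions)
    # candidate phasing comes from the merged phased VCFs
    phase_cols <- c("child_a1", "child_a2", "child_phased", "child_ps")
    cand[tv, on = .(chrom, pos, ref, alt),
         (phase_cols) := mget(paste0("i.", phase_cols))]
  }
  bam_paths <- c(father = bam_father, mother = bam_mother, child = bam_child)
  sites <- unique(rbindlist(list(
    tv[, .(chrom, pos)],
    if (!is.null(cand)) cand[, .(chrom, pos)] else NULL)))
  aln <- lapply(trio_roles, function(r)
    read_linked_alignments(bam_paths[[r]], sample = r, sites = sites))
  reads <- rbindlist(lapply(aln, `[[`, "reads"))
  obs <- rbindlist(lapply(aln, `[[`, "obs"))
  if (params$tag_mode == "trust") setnames(reads, "hp_tag", "hp")
  res <- hapdenovo_run(tv, reads, obs, params = params,
                       score_filter = score_filter, candidates = cand)
  paths <- write_dnm_report(res$classified, out_prefix)
  inputs <- c(phased_vcf_father, phased_vcf_mother, phased_vcf_child,
              bam_father, bam_mother, bam_child, trio_vcf)
  manifest <- list(
    package = "haplodenovo",
    version = as.character(utils::packageVersion("haplodenovo")),
    parameters = params[setdiff(names(params), "par_regions")],
    par_regions = lapply(seq_len(nrow(params$par_regions)), function(i)
      as.list(params$par_regions[i, ])),
    inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                              basename(inputs))),
    counts = as.list(res$counts))
  paths$manifest <- paste0(out_prefix, ".manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  res$paths <- paths
  res
}
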