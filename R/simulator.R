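# Synthetic linked-read trio simulator ---------------------------------------
#
# Generates a trio with phased haplotypes, Mendelian transmission,
# planted child DNMs, inherited-het artifact sites with allele-specific
# evidence dropout, barcoded long molecules, and short reads with base
# errors -- together with complete ground truth, so the whole pipeline
# is testable without external data.
#
# The genomes are abstract allele vectors: variant positions carry
# ref/alt bases, everything in between is constant filler.  Reads are
# emitted pre-placed with coordinates (alignment is out of scope), but
# still round-trip through standard SAM/VCF files.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_trio()].  The
#' defaults are the package's reference study conditions: a 500 kb
#' chromosome, 300 phased het sites per parent, 20 de novo mutations,
#' 200 inherited-het artifact sites with evidence-dropout severity 0.9,
#' 8x coverage per haplotype from ~30 kb molecules, and a 0.5% base
#' error rate.
#'
#' @param genome_length Chromosome length in bp.
#' @param chrom Contig name.
#' @param n_het_sites Heterozygous sites planted per parent.
#' @param n_dnms De novo mutations planted on the child's haplotypes.
#' @param dnm_parent_split Fraction of DNMs arising on the maternally
#'   transmitted haplotype.
#' @param n_artifact_sites Inherited parental het sites subjected to
#'   allele-specific dropout of the alternate-allele evidence in the
#'   simulated diploid variant calls (the false-positive mechanism the
#'   classifier must catch).
#' @param dropout_severity Fraction of alt-bearing parental molecules
#'   whose reads are withheld from the diploid genotype call at each
#'   artifact site.  The reads remain in the emitted alignments: the
#'   dropout models the caller's allele-specific evidence loss, which
#'   is what makes an inherited het masquerade as a DNM while the
#'   haplotype-resolved pileup can still see the alternate haplotype.
#' @param het_min_alt Minimum surviving alt reads for the simulated
#'   diploid caller to call the artifact parent heterozygous.
#' @param mean_molecule_length Mean (exponential) molecule length, bp.
#' @param molecules_per_haplotype Molecule count per haplotype;
#'   `NULL` derives it from the target depth and
#'   `molecule_read_depth`.
#' @param molecule_read_depth Average read depth within a molecule.
#' @param read_length Read length, bp.
#' @param target_depth_per_haplotype Expected read depth per haplotype.
#' @param base_error_rate Per-base error probability (errors flip a
#'   base to a uniformly chosen other base).
#' @param base_quality Constant phred base quality of emitted bases.
#' @param chrx Simulate an X-nonPAR contig: the father is hemizygous
#'   and the child is sexed.
#' @param child_sex Child sex (used in `chrx` mode).
#' @param seed Integer seed; a fixed configuration (including the
#'   seed) reproduces the simulation exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 5e5L,
                       chrom = "chr1",
                       n_het_sites = 300L,
                       n_dnms = 20L,
                       dnm_parent_split = 0.5,
                       n_artifact_sites = 200L,
                       dropout_severity = 0.9,
                       het_min_alt = 3L,
                       mean_molecule_length = 3e4,
                       molecules_per_haplotype = NULL,
                       molecule_read_depth = 0.2,
                       read_length = 100L,
                       target_depth_per_haplotype = 8,
                       base_error_rate = 0.005,
                       base_quality = 37L,
                       chrx = FALSE,
                       child_sex = c("female", "male"),
                       seed = 1L) {
  child_sex <- match.arg(child_sex)
  cfg <- list(genome_length = as.integer(genome_length),
              chrom = if (chrx) "chrX" else chrom,
              n_het_sites = as.integer(n_het_sites),
              n_dnms = as.integer(n_dnms),
              dnm_parent_split = dnm_parent_split,
              n_artifact_sites = as.integer(n_artifact_sites),
              dropout_severity = dropout_severity,
              het_min_alt = as.integer(het_min_alt),
              mean_molecule_length = mean_molecule_length,
              molecules_per_haplotype = molecules_per_haplotype,
              molecule_read_depth = molecule_read_depth,
              read_length = as.integer(read_length),
              target_depth_per_haplotype = target_depth_per_haplotype,
              base_error_rate = base_error_rate,
              base_quality = as.integer(base_quality),
              chrx = isTRUE(chrx),
              child_sex = child_sex,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(genome_length > 0, n_het_sites >= 0, n_dnms >= 0,
              n_artifact_sites >= 0,
              dnm_parent_split >= 0, dnm_parent_split <= 1,
              dropout_severity >= 0, dropout_severity <= 1,
              base_error_rate >= 0, base_error_rate <= 1,
              mean_molecule_length > 0, read_length > 0,
              target_depth_per_haplotype > 0)
  })
  n_sites <- cfg$n_het_sites * 2L + cfg$n_dnms + cfg$n_artifact_sites
  if (n_sites > cfg$genome_length)
    stop("more variant sites requested than genome positions")
  if (is.null(cfg$molecules_per_haplotype))
    cfg$molecules_per_haplotype <- as.integer(ceiling(
      cfg$target_depth_per_haplotype * cfg$genome_length /
        (cfg$mean_molecule_length * cfg$molecule_read_depth)))
  class(cfg) <- "sim_config"
  cfg
}

#' Write / read a simulation configuration as YAML
#' @param config A `sim_config`.
#' @param path File path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Simulate the trio's haplotype (variant) layer
#'
#' Plants het sites on the four parental haplotypes, transmits one
#' haplotype per parent to the child (uniform Mendelian draw, no
#' recombination within the simulated contig), injects `n_dnms` child
#' DNMs absent from every parental haplotype, and plants
#' `n_artifact_sites` parental hets whose alternate allele sits on the
#' transmitted haplotype, so the child is het there -- the
#' configuration in which allele-specific dropout turns an inherited
#' variant into a fake DNM candidate.
#'
#' @param config A [sim_config()].
#' @return A `trio_truth` list: `sites` (per-haplotype allele table
#'   with `kind`, `dnm_origin`, `artifact_parent`), `transmission`, and
#'   the config.
#' @export
simulate_trio_haplotypes <- function(config) {
  set.seed(config$seed)
  sim_haplotypes_(config)
}

sim_haplotypes_ <- function(cfg) {
  n_f <- if (cfg$chrx) 0L else cfg$n_het_sites   # hemizygous father: no X hets
  n_m <- cfg$n_het_sites
  n_d <- cfg$n_dnms
  n_a <- cfg$n_artifact_sites
  n <- n_f + n_m + n_d + n_a
  pos <- sort(sample.int(cfg$genome_length, n, replace = FALSE))
  kind <- sample(rep(c("het_father", "het_mother", "dnm", "artifact"),
                     c(n_f, n_m, n_d, n_a)))
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")

  f_t <- sample(1:2, 1L)   # father transmits haplotype f_t
  m_t <- sample(1:2, 1L)

  s <- data.table(chrom = cfg$chrom, pos = pos, ref = ref, alt = alt,
                  kind = kind,
                  dnm_origin = NA_character_, artifact_parent = NA_character_,
                  f_h1 = 0L, f_h2 = if (cfg$chrx) NA_integer_ else 0L,
                  m_h1 = 0L, m_h2 = 0L,
                  c_h1 = 0L,   # maternal copy
                  c_h2 = if (cfg$chrx && cfg$child_sex == "male")
                    NA_integer_ else 0L)  # paternal copy

  plant_parent_het <- function(s, idx, parent, on_hap) {
    col <- paste0(substr(parent, 1, 1), "_h", on_hap)
    s[idx, (col) := 1L]
    s
  }
  # parental het sites: alt on a random haplotype of that parent
  for (parent in c("father", "mother")) {
    idx <- which(s$kind == paste0("het_", parent))
    if (!length(idx)) next
    haps <- if (parent == "father" && cfg$chrx) rep(1L, length(idx))
            else sample(1:2, length(idx), replace = TRUE)
    for (h in 1:2) {
      ih <- idx[haps == h]
      if (length(ih)) s <- plant_parent_het(s, ih, parent, h)
    }
  }
  # artifact sites: parental het with the alt on the *transmitted* haplotype
  idx <- which(s$kind == "artifact")
  if (length(idx)) {
    parents <- if (cfg$chrx) rep("mother", length(idx))
               else sample(c("father", "mother"), length(idx), replace = TRUE)
    s[idx, artifact_parent := parents]
    fa <- idx[parents == "father"]
    mo <- idx[parents == "mother"]
    if (length(fa)) s <- plant_parent_het(s, fa, "father",
                                          if (cfg$chrx) 1L else f_t)
    if (length(mo)) s <- plant_parent_het(s, mo, "mother", m_t)
  }
  # transmission: child haplotype 1 is the maternal copy, 2 the paternal
  s[, c_h1 := s[[paste0("m_h", m_t)]]]
  if (!(cfg$chrx && cfg$child_sex == "male")) {
    s[, c_h2 := if (cfg$chrx) s$f_h1 else s[[paste0("f_h", f_t)]]]
  }
  # DNMs: on the child only
  idx <- which(s$kind == "dnm")
  if (length(idx)) {
    maternal <- if (cfg$chrx && cfg$child_sex == "male")
      rep(TRUE, length(idx))
    else runif(length(idx)) < cfg$dnm_parent_split
    s[idx, dnm_origin := ifelse(maternal, "maternal", "paternal")]
    s[idx[maternal], c_h1 := 1L]
    if (any(!maternal)) s[idx[!maternal], c_h2 := 1L]
  }
  structure(list(sites = s[],
                 transmission = c(father = f_t, mother = m_t),
                 config = cfg),
            class = "trio_truth")
}

# allele column of `sites` for a given sample/haplotype
hap_col <- function(sample, hap) paste0(substr(sample, 1, 1), "_h", hap)

#' Simulate barcoded molecules and reads
#'
#' Samples exponential-length molecules per haplotype with a unique
#' barcode each, tiles reads along them to reach the target
#' per-haplotype depth in expectation, copies bases from the source
#' haplotype at every variant position (flipped to a random other base
#' with probability `base_error_rate`), and marks, at each artifact
#' site, a `dropout_severity` fraction of the alt-bearing parental
#' molecules as withheld from the diploid caller
#' (`caller_dropped`).
#'
#' @param truth A `trio_truth` from [simulate_trio_haplotypes()].
#' @param config The same [sim_config()].
#' @return A `linked_reads` list: `reads` (with true `hap` and
#'   `molecule`), `obs` (per-read bases at variant positions, with the
#'   `caller_dropped` flag), `molecules`.
#' @export
simulate_linked_reads <- function(truth, config) {
  set.seed(config$seed + 1L)
  sim_reads_(truth, config)
}

sim_reads_ <- function(truth, cfg) {
  s <- truth$sites
  L <- cfg$genome_length
  hap_sets <- list(father = if (cfg$chrx) 1L else 1:2,
                   mother = 1:2,
                   child = if (cfg$chrx && cfg$child_sex == "male") 1L else 1:2)
  mol_list <- list(); read_list <- list()
  mol_counter <- 0L; read_counter <- 0L
  for (samp in trio_roles) {
    for (h in hap_sets[[samp]]) {
      M <- cfg$molecules_per_haplotype
      # starts spill over both ends so interior depth is uniform
      raw_start <- floor(runif(M, 1 - 3 * cfg$mean_molecule_length, L))
      mlen <- pmax(ceiling(rexp(M, 1 / cfg$mean_molecule_length)),
                   cfg$read_length)
      m_start <- pmax(1, raw_start)
      m_end <- pmin(L, raw_start + mlen - 1)
      keep <- m_end >= m_start
      m_start <- m_start[keep]; m_end <- m_end[keep]
      nm <- length(m_start)
      mid <- mol_counter + seq_len(nm)
      mol_counter <- mol_counter + nm
      mols <- data.table(molecule = mid,
                         sample = samp, hap = h, chrom = cfg$chrom,
                         barcode = sprintf("BX%07d", mid),
                         start = as.integer(m_start),
                         end = as.integer(m_end))
      n_reads <- round(cfg$target_depth_per_haplotype * L / cfg$read_length)
      w <- (m_end - m_start + 1)
      ri <- sample.int(nm, n_reads, replace = TRUE, prob = w)
      span <- pmax(m_end[ri] - cfg$read_length + 1, m_start[ri])
      r_start <- floor(runif(n_reads, m_start[ri], span + 1))
      r_start <- pmin(r_start, span)
      r_end <- pmin(r_start + cfg$read_length - 1, m_end[ri])
      rid <- read_counter + seq_len(n_reads)
      read_counter <- read_counter + n_reads
      reads <- data.table(read_id = sprintf("r%08d", rid),
                          sample = samp, chrom = cfg$chrom,
                          start = as.integer(r_start),
                          end = as.integer(r_end),
                          barcode = mols$barcode[ri],
                          molecule = mid[ri], hap = h, mapq = 60L)
      mol_list[[length(mol_list) + 1L]] <- mols
      read_list[[length(read_list) + 1L]] <- reads
    }
  }
  molecules <- rbindlist(mol_list)
  reads <- rbindlist(read_list)
  setorder(reads, chrom, start, read_id)

  # per-read bases at every variant position the read covers
  site_keys <- s[, .(chrom, pos, ref, alt)]
  obs <- reads[site_keys,
               on = .(chrom, start <= pos, end >= pos),
               nomatch = NULL,
               .(read_id, sample, hap, molecule,
                 chrom, pos = i.pos, ref = i.ref, alt = i.alt)]
  # truth base: this haplotype's allele at the site
  for (samp in trio_roles) {
    for (h in hap_sets[[samp]]) {
      col <- hap_col(samp, h)
      sel <- obs$sample == samp & obs$hap == h
      if (!any(sel)) next
      allele <- s[[col]][match(obs$pos[sel], s$pos)]
      obs[sel, base := fifelse(allele == 1L, alt, ref)]
    }
  }
  # sequencing errors: flip to a uniformly chosen different base
  nerr <- nrow(obs)
  if (nerr > 0L && cfg$base_error_rate > 0) {
    err <- runif(nerr) < cfg$base_error_rate
    if (any(err)) {
      cur <- match(obs$base[err], BASES)
      shift <- sample.int(3L, sum(err), replace = TRUE)
      obs[err, base := BASES[((cur - 1L + shift) %% 4L) + 1L]]
    }
  }
  obs[, baseq := cfg$base_quality]
  obs[, caller_dropped := FALSE]

  # allele-specific dropout of alt evidence at artifact sites
  art <- s[kind == "artifact"]
  if (nrow(art) > 0L && cfg$dropout_severity > 0) {
    tr <- truth$transmission
    art[, alt_hap := fifelse(artifact_parent == "father",
                             if (cfg$chrx) 1L else tr[["father"]],
                             tr[["mother"]])]
    tgt <- merge(obs[, .(read_id, sample, hap, molecule, pos)],
                 art[, .(pos, artifact_parent, alt_hap)], by = "pos")
    tgt <- tgt[sample == artifact_parent & hap == alt_hap]
    if (nrow(tgt) > 0L) {
      mols_at <- unique(tgt[, .(pos, molecule)])
      mols_at[, dropped := runif(.N) < cfg$dropout_severity]
      tgt <- merge(tgt, mols_at, by = c("pos", "molecule"))
      drop_keys <- tgt[dropped == TRUE, .(read_id, pos)]
      if (nrow(drop_keys) > 0L)
        obs[drop_keys, on = .(read_id, pos), caller_dropped := TRUE]
    }
  }
  structure(list(reads = reads[], obs = obs[], molecules = molecules[]),
            class = "linked_reads")
}

# Phase blocks from molecule co-coverage: adjacent het sites belong to
# one block iff some molecule of the individual spans both.
blocks_from_molecules_ <- function(het_pos, mols) {
  np <- length(het_pos)
  if (np == 0L) return(integer(0))
  if (nrow(mols) == 0L) return(seq_len(np))
  ms <- sort(mols$start)
  me <- cummax(mols$end[order(mols$start)])
  linked <- rep(FALSE, np)
  if (np > 1L) {
    idx <- findInterval(het_pos[-np], ms)
    reach <- ifelse(idx == 0L, -Inf, me[pmax(idx, 1L)])
    linked[-1L] <- reach >= het_pos[-1L]
  }
  cumsum(!linked)   # block index per site
}

# Emitted (called) diploid genotypes + physical phasing for the trio.
# Truth genotypes everywhere except artifact sites, where the artifact
# parent's genotype is re-called from the post-dropout evidence.
sim_genotypes_ <- function(truth, lr, cfg) {
  set.seed(cfg$seed + 2L)
  s <- copy(truth$sites)
  obs <- lr$obs
  # surviving alt evidence at artifact sites, per parent
  art <- s[kind == "artifact", .(pos, artifact_parent, ref, alt)]
  miscalled <- rep(FALSE, nrow(s))
  if (nrow(art) > 0L) {
    ev <- merge(obs[caller_dropped == FALSE, .(sample, pos, base)],
                art, by = "pos")
    ev <- ev[sample == artifact_parent]
    n_alt_surv <- ev[, .(n_alt = sum(base == alt)), by = pos]
    surv <- n_alt_surv$n_alt[match(art$pos, n_alt_surv$pos)]
    surv[is.na(surv)] <- 0L
    miscalled[match(art$pos, s$pos)] <- surv < cfg$het_min_alt
  }
  s[, miscall := miscalled]

  # diploid depth per individual per site (all reads; DP is informational)
  dpt <- obs[, .N, by = .(sample, pos)]

  tv <- s[, .(chrom, pos, ref, alt)]
  hapmat <- list(father = c("f_h1", "f_h2"), mother = c("m_h1", "m_h2"),
                 child = c("c_h1", "c_h2"))
  flips <- list()
  for (role in trio_roles) {
    h1 <- s[[hapmat[[role]][1]]]
    h2 <- s[[hapmat[[role]][2]]]
    # artifact miscall: parent called hom-ref
    mis <- s$miscall & !is.na(s$artifact_parent) & s$artifact_parent == role
    a1c <- ifelse(mis, 0L, h1)
    a2c <- ifelse(mis, 0L, h2)
    hemi <- is.na(h2)
    het <- !hemi & !is.na(a1c) & a1c != a2c
    # physical phase blocks over the called het sites
    het_idx <- which(het)
    blk <- blocks_from_molecules_(s$pos[het_idx],
                                  lr$molecules[sample == role])
    ps <- rep(NA_character_, nrow(s))
    phased <- rep(FALSE, nrow(s))
    a1o <- a1c; a2o <- a2c
    if (length(het_idx)) {
      bl_sizes <- tabulate(blk)
      in_multi <- bl_sizes[blk] > 1L
      first_pos <- s$pos[het_idx][match(blk, blk)]  # first site of each block
      # orientation flip per block: VCF haplotype 1 is truth hap 2
      flip_block <- runif(max(blk)) < 0.5
    flp <- flip_block[blk] & in_multi
      sel <- het_idx[in_multi]
      ps[sel] <- paste0(role, ":", first_pos[in_multi])
      phased[sel] <- TRUE
      swap <- het_idx[flp]
      a1o[swap] <- a2c[swap]
      a2o[swap] <- a1c[swap]
      flips[[role]] <- data.table(pos = s$pos[het_idx],
                                  block = blk, flipped = flp)
    } else {
      flips[[role]] <- data.table(pos = integer(), block = integer(),
                                  flipped = logical())
    }
    dpv <- dpt[sample == role]
    tv[, paste0(role, c("_a1", "_a2", "_phased", "_ps", "_dp")) := list(
      as.integer(a1o), as.integer(a2o), phased, ps,
      {
        d <- dpv$N[match(s$pos, dpv$pos)]
        as.integer(ifelse(is.na(d), 0L, d))
      })]
  }
  list(variants = new_trio_variants(tv), flips = flips,
       miscalled = s[miscall == TRUE, pos])
}

#' Simulate a complete linked-read trio dataset
#'
#' Runs the variant layer, the molecule/read layer and the genotype
#' emission in sequence under the configuration's seed.  A fixed
#' configuration reproduces the dataset exactly.
#'
#' @param config A [sim_config()].
#' @return A `sim_trio` list: `config`, `truth`, `reads`, `obs`,
#'   `molecules`, `variants` (the called, phased trio table the
#'   pipeline consumes), `flips` (per-block VCF-vs-truth haplotype
#'   orientation) and `miscalled` (artifact positions the simulated
#'   diploid caller got wrong).
#' @export
simulate_trio <- function(config) {
  truth <- simulate_trio_haplotypes(config)
  lr <- simulate_linked_reads(truth, config)
  gt <- sim_genotypes_(truth, lr, config)
  structure(list(config = config, truth = truth,
                 reads = lr$reads, obs = lr$obs, molecules = lr$molecules,
                 variants = gt$variants, flips = gt$flips,
                 miscalled = gt$miscalled),
            class = "sim_trio")
}

#' Emit a simulated trio as standard files
#'
#' Writes per-individual phased VCFs, the multi-sample trio VCF, one
#' SAM file per individual with `BX` barcode tags (and true `HP` tags
#' on request, for trust-existing-tags testing), truth TSVs, and the
#' YAML configuration.  Everything parses back through the package's
#' own readers.
#'
#' @param sim A `sim_trio`.
#' @param dir Output directory (created if needed).
#' @param write_hp_tags Also write each read's true haplotype as an
#'   `HP` tag (default `FALSE`: alignments are emitted untagged).
#' @param write_read_truth Write the per-read truth TSV (can be large;
#'   default `TRUE`).
#' @return Invisibly, a named list of paths.
#' @export
emit_sim_files <- function(sim, dir, write_hp_tags = FALSE,
                           write_read_truth = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- sim$config
  contigs <- data.frame(chrom = cfg$chrom, length = cfg$genome_length)
  paths <- list()
  for (role in trio_roles) {
    p <- file.path(dir, paste0(role, ".phased.vcf"))
    write_phased_vcf(sim$variants, role, p, contigs = contigs)
    paths[[paste0(role, "_vcf")]] <- p
  }
  paths$trio_vcf <- file.path(dir, "trio.vcf")
  write_trio_vcf(sim$variants, paths$trio_vcf, contigs = contigs)
  for (role in trio_roles) {
    p <- file.path(dir, paste0(role, ".sam"))
    r <- sim$reads[sample == role]
    hp <- if (write_hp_tags) r$hap else NULL
    write_sam(r, sim$obs, p, contigs = contigs,
              base_quality = cfg$base_quality, hp = hp)
    paths[[paste0(role, "_sam")]] <- p
  }
  paths$truth_sites <- file.path(dir, "truth.sites.tsv")
  fwrite(sim$truth$sites, paths$truth_sites, sep = "\t")
  paths$truth_molecules <- file.path(dir, "truth.molecules.tsv")
  fwrite(sim$molecules, paths$truth_molecules, sep = "\t")
  if (write_read_truth) {
    paths$truth_reads <- file.path(dir, "truth.reads.tsv")
    fwrite(sim$reads[, .(read_id, sample, molecule, hap)],
           paths$truth_reads, sep = "\t")
  }
  paths$config <- file.path(dir, "config.yaml")
  write_sim_config(cfg, paths$config)
  invisible(paths)
}
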