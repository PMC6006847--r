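# Molecule reconstruction and haplotype tagging ------------------------------
#
# Alignments are held in two data.tables:
#   reads: read_id, sample, chrom, start, end, barcode, mapq (+ mol_uid, hp)
#   obs:   read_id, chrom, pos, base, baseq  -- one row per read base that
#          overlaps a variant position of interest
# The linked-read premise is that reads sharing a barcode and aligning
# near each other come from one long DNA molecule, hence one haplotype,
# so votes are pooled at molecule level.

#' Group barcoded reads into molecules
#'
#' Chains coordinate-sorted reads that share a barcode on the same
#' chromosome into molecules, starting a new molecule whenever
#' consecutive read starts are more than `gap_threshold` apart.  Reads
#' without a barcode become singleton molecules (their count is
#' reported in a message).
#'
#' @param reads A reads data.table (columns `read_id`, `sample`,
#'   `chrom`, `start`, `barcode` at minimum).
#' @param gap_threshold Maximum distance in bp between consecutive read
#'   starts of one molecule.  Default 50 kb, typical for linked-read
#'   molecule reconstruction.
#' @return A copy of `reads` with an integer `mol_uid` column; the
#'   original row order is preserved.
#' @export
group_reads_into_molecules <- function(reads, gap_threshold = 5e4) {
  r <- as.data.table(reads)
  r[, orig_order := .I]
  setorder(r, sample, chrom, barcode, start, na.last = TRUE)
  has_bx <- !is.na(r$barcode)
  r[, new_mol := TRUE]
  r[has_bx, new_mol := {
    d <- start - data.table::shift(start)
    is.na(d) | d > gap_threshold
  }, by = .(sample, chrom, barcode)]
  n_nobx <- sum(!has_bx)
  if (n_nobx > 0L)
    message(n_nobx, " read(s) without a barcode kept as singleton molecules")
  r[, mol_uid := cumsum(new_mol)]
  r[, new_mol := NULL]
  setorder(r, orig_order)
  r[, orig_order := NULL]
  r[]
}

#' Summarise reconstructed molecules
#'
#' @param reads Reads annotated with `mol_uid` (see
#'   [group_reads_into_molecules()]).
#' @return One row per molecule: sample, chrom, barcode, span, read count.
#' @export
summarise_molecules <- function(reads) {
  as.data.table(reads)[, .(sample = sample[1L], chrom = chrom[1L],
                           barcode = barcode[1L],
                           start = min(start), end = max(end),
                           n_reads = .N),
                       by = mol_uid][]
}

#' Assign molecules to haplotypes by majority vote
#'
#' Every base a molecule's reads show at a phased heterozygous site of
#' the owner's phase block is a vote for haplotype 1 or haplotype 2
#' (bases matching neither allele, or below `min_baseq`, do not vote).
#' The molecule is tagged HP1 if haplotype-1 votes outnumber
#' haplotype-2 votes, HP2 in the opposite case, and HP0 on any tie --
#' including zero informative votes or a molecule outside every block.
#' A molecule whose informative sites straddle two blocks is assigned
#' within the block holding the majority of its informative
#' observations; a tie between blocks also yields HP0.
#'
#' @param reads Reads annotated with `mol_uid`.
#' @param obs Observation table (`read_id`, `chrom`, `pos`, `base`,
#'   `baseq`).
#' @param blocks A `phase_blocks` table (may combine several owners;
#'   votes are matched on the read's `sample`).
#' @param min_baseq Minimum base quality for a voting observation
#'   (phred, default 13).
#' @return data.table with one row per molecule: `mol_uid`, `hp`
#'   (integer 0/1/2), `block_id`, `n1`, `n2`.
#' @export
assign_molecule_haplotypes <- function(reads, obs, blocks, min_baseq = 13) {
  r <- as.data.table(reads)
  stopifnot("mol_uid" %in% names(r))
  all_mols <- unique(r$mol_uid)
  empty <- data.table(mol_uid = all_mols, hp = 0L,
                      block_id = NA_character_, n1 = 0L, n2 = 0L)
  o <- as.data.table(obs)[baseq >= min_baseq]
  if (nrow(o) == 0L || nrow(blocks) == 0L) return(empty[])
  o <- merge(o[, .(read_id, chrom, pos, base)],
             r[, .(read_id, sample, mol_uid)], by = "read_id")
  b <- as.data.table(blocks)
  v <- merge(o, b[, .(owner, chrom, pos, block_id, hap1_base, hap2_base)],
             by.x = c("sample", "chrom", "pos"),
             by.y = c("owner", "chrom", "pos"),
             allow.cartesian = TRUE)
  v[, vote := fifelse(base == hap1_base, 1L,
                      fifelse(base == hap2_base, 2L, 0L))]
  v <- v[vote > 0L]
  if (nrow(v) == 0L) return(empty[])
  per_block <- v[, .(n1 = sum(vote == 1L), n2 = sum(vote == 2L)),
                 by = .(mol_uid, block_id)]
  per_block[, n_inf := n1 + n2]
  setorder(per_block, mol_uid, -n_inf, block_id)
  top <- per_block[, {
    amb <- .N > 1L && n_inf[2L] == n_inf[1L]
    .(block_id = block_id[1L], n1 = n1[1L], n2 = n2[1L], block_tie = amb)
  }, by = mol_uid]
  top[, hp := fifelse(block_tie, 0L,
                      fifelse(n1 > n2, 1L, fifelse(n2 > n1, 2L, 0L)))]
  out <- merge(empty[, .(mol_uid)], top[, .(mol_uid, hp, block_id, n1, n2)],
               by = "mol_uid", all.x = TRUE)
  out[is.na(hp), `:=`(hp = 0L, n1 = 0L, n2 = 0L)]
  out[]
}

#' Tag reads with their haplotype
#'
#' Convenience wrapper: reconstruct molecules (unless already present),
#' assign each molecule to a haplotype, and propagate the molecule tag
#' to every member read.  With `mode = "trust"`, an existing `hp`
#' column (e.g. tags computed upstream) is honoured instead of
#' recomputing; the default recomputes for self-containedness.
#'
#' @inheritParams assign_molecule_haplotypes
#' @inheritParams group_reads_into_molecules
#' @param mode `"recompute"` (default) or `"trust"`.
#' @param per_read Vote per read instead of per molecule (comparison
#'   mode; the linked-read premise favours molecule-level voting).
#' @return `reads` with integer `hp` column (0 = undetermined).
#' @export
tag_reads <- function(reads, obs, blocks, gap_threshold = 5e4,
                      min_baseq = 13, mode = c("recompute", "trust"),
                      per_read = FALSE) {
  mode <- match.arg(mode)
  r <- as.data.table(reads)
  if (mode == "trust") {
    if (!"hp" %in% names(r))
      stop("mode = 'trust' requires an existing hp column")
    r[, hp := fifelse(is.na(hp), 0L, as.integer(hp))]
    return(r[])
  }
  if (per_read) {
    r[, mol_uid := .I]
  } else if (!"mol_uid" %in% names(r)) {
    r <- group_reads_into_molecules(r, gap_threshold)
  }
  tags <- assign_molecule_haplotypes(r, obs, blocks, min_baseq)
  if ("hp" %in% names(r)) r[, hp := NULL]
  r <- merge(r, tags[, .(mol_uid, hp)], by = "mol_uid", sort = FALSE)
  r[]
}

#' Partition tagged reads by haplotype
#'
#' @param reads Reads with an `hp` column.
#' @return Named list `hp1`, `hp2`, `hp0`; together the three sets
#'   partition the input and each preserves the input order.
#' @export
split_by_tag <- function(reads) {
  r <- as.data.table(reads)
  stopifnot("hp" %in% names(r))
  list(hp1 = r[hp == 1L], hp2 = r[hp == 2L], hp0 = r[hp == 0L | is.na(hp)])
}
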