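make_reads <- function(start, barcode, chrom = "chr1", sample = "child",
                       len = 100L) {
  n <- length(start)
  data.table(read_id = sprintf("r%03d", seq_len(n)), sample = sample,
             chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(start + len - 1L),
             barcode = rep_len(barcode, n), mapq = 60L)
}

make_blocks <- function(pos, hap1_base, hap2_base, owner = "child",
                        chrom = "chr1", block_id = "child:1") {
  data.table(owner = owner, chrom = chrom, block_id = rep_len(block_id, length(pos)),
             pos = as.integer(pos),
             hap1_allele = ifelse(hap1_base == "C", 1L, 0L),
             hap2_allele = ifelse(hap2_base == "C", 1L, 0L),
             hap1_base = hap1_base, hap2_base = hap2_base)
}

make_obs <- function(read_id, pos, base, baseq = 30L, chrom = "chr1",
                     sample = "child") {
  data.table(read_id = read_id, sample = sample, chrom = chrom,
             pos = as.integer(pos), base = base,
             baseq = rep_len(as.integer(baseq), length(pos)))
}

test_that("reads chain into molecules within the gap threshold and split beyond it", {
  r <- make_reads(c(1e4, 2e4, 2.2e5, 5e5, 5.1e5), "BX1")
  g <- group_reads_into_molecules(r, gap_threshold = 5e4)
  expect_equal(length(unique(g$mol_uid)), 3L)
  expect_equal(g$mol_uid[1], g$mol_uid[2])      # 10 kb apart: one molecule
  expect_false(g$mol_uid[2] == g$mol_uid[3])    # 200 kb apart: new molecule
  expect_equal(g$mol_uid[4], g$mol_uid[5])
})

test_that("barcodeless reads become singleton molecules", {
  r <- make_reads(c(100, 200, 300), c("BX1", NA, NA))
  expect_message(g <- group_reads_into_molecules(r, 5e4), "without a barcode")
  expect_equal(length(unique(g$mol_uid)), 3L)
})

test_that("random read sets group exactly like the pairwise transitive-chaining oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 30L
    r <- make_reads(sort(sample.int(3e5, n)),
                    sample(paste0("BX", 1:4), n, TRUE),
                    chrom = sample(c("chr1", "chr2"), n, TRUE))
    gap <- sample(c(2e4, 5e4), 1L)
    g <- group_reads_into_molecules(r, gap)
    comp <- oracle_group(r, gap)
    # same partition: identical co-membership matrix
    expect_equal(outer(g$mol_uid, g$mol_uid, "=="),
                 outer(comp, comp, "=="))
  }
})

test_that("molecule votes follow the majority and ties yield HP0", {
  b <- make_blocks(c(100, 200, 300, 400), c("A", "A", "A", "A"),
                   c("C", "C", "C", "C"))
  r <- make_reads(c(50, 150, 250, 350), "BX1")
  r <- group_reads_into_molecules(r, 5e4)

  # unanimous haplotype-1 observations -> HP1
  o <- make_obs(r$read_id[1:3], c(100, 200, 300), c("A", "A", "A"))
  expect_equal(assign_molecule_haplotypes(r, o, b)$hp, 1L)

  # 2 vs 2 -> HP0
  o <- make_obs(r$read_id, c(100, 200, 300, 400), c("A", "A", "C", "C"))
  expect_equal(assign_molecule_haplotypes(r, o, b)$hp, 0L)

  # no informative observation at all -> HP0
  o <- make_obs(r$read_id[1], 100, "G")
  expect_equal(assign_molecule_haplotypes(r, o, b)$hp, 0L)

  # low-quality bases do not vote
  o <- make_obs(r$read_id[1:2], c(100, 200), c("C", "C"), baseq = c(30L, 5L))
  res <- assign_molecule_haplotypes(r, o, b, min_baseq = 13)
  expect_equal(res$n2, 1L)
  expect_equal(res$hp, 2L)
})

test_that("10000 random molecules match the exhaustive vote-counting oracle", {
  set.seed(99)
  n_mol <- 10000L
  sites <- seq(1000L, by = 1000L, length.out = 10L)
  b <- make_blocks(sites, rep("A", 10), rep("C", 10))
  k <- sample.int(10L, n_mol, replace = TRUE)
  obs_list <- lapply(seq_len(n_mol), function(i) {
    p <- sample(sites, k[i])
    data.table(read_id = sprintf("m%05d", i), sample = "child",
               chrom = "chr1", pos = p,
               base = sample(c("A", "C", "G"), k[i], TRUE,
                             prob = c(.4, .4, .2)),
               baseq = sample(c(30L, 5L), k[i], TRUE, prob = c(.9, .1)))
  })
  obs <- rbindlist(obs_list)
  reads <- data.table(read_id = sprintf("m%05d", seq_len(n_mol)),
                      sample = "child", chrom = "chr1",
                      start = 1L, end = 10000L,
                      barcode = sprintf("m%05d", seq_len(n_mol)),
                      mapq = 60L, mol_uid = seq_len(n_mol))
  res <- assign_molecule_haplotypes(reads, obs, b, min_baseq = 13)
  expected <- vapply(seq_len(n_mol), function(i) {
    o <- obs_list[[i]][baseq >= 13]
    oracle_vote(ifelse(o$base == "A", 1L, ifelse(o$base == "C", 2L, 0L))[
      ifelse(o$base == "A", 1L, ifelse(o$base == "C", 2L, 0L)) > 0])
  }, integer(1))
  expect_equal(res$hp[order(res$mol_uid)], expected)
})

test_that("swapping the block's haplotype labels swaps HP1 and HP2 and fixes HP0", {
  set.seed(7)
  sites <- seq(500L, by = 500L, length.out = 8L)
  b <- make_blocks(sites, rep("A", 8), rep("C", 8))
  b_swapped <- copy(b)[, `:=`(hap1_base = hap2_base, hap2_base = hap1_base,
                              hap1_allele = hap2_allele,
                              hap2_allele = hap1_allele)]
  n <- 200L
  reads <- data.table(read_id = sprintf("m%03d", 1:n), sample = "child",
                      chrom = "chr1", start = 1L, end = 5000L,
                      barcode = sprintf("m%03d", 1:n), mapq = 60L,
                      mol_uid = 1:n)
  obs <- rbindlist(lapply(1:n, function(i) {
    kk <- sample.int(6L, 1L)
    make_obs(reads$read_id[i], sample(sites, kk),
             sample(c("A", "C", "G"), kk, TRUE))
  }))
  a <- assign_molecule_haplotypes(reads, obs, b)
  s <- assign_molecule_haplotypes(reads, obs, b_swapped)
  swap <- c(`0` = 0L, `1` = 2L, `2` = 1L)
  expect_equal(s$hp, unname(swap[as.character(a$hp)]))
})

test_that("a molecule straddling two blocks is assigned in its majority block, tie -> HP0", {
  b <- rbind(make_blocks(c(100, 200), c("A", "A"), c("C", "C"),
                         block_id = "child:1"),
             make_blocks(c(10000, 10100, 10200), c("A", "A", "A"),
                         c("C", "C", "C"), block_id = "child:2"))
  reads <- data.table(read_id = "r1", sample = "child", chrom = "chr1",
                      start = 1L, end = 11000L, barcode = "BX1",
                      mapq = 60L, mol_uid = 1L)
  # 2 obs in block 1 (hap1), 3 in block 2 (hap2): block 2 wins -> HP2
  o <- make_obs("r1", c(100, 200, 10000, 10100, 10200),
                c("A", "A", "C", "C", "C"))
  res <- assign_molecule_haplotypes(reads, o, b)
  expect_equal(res$hp, 2L)
  expect_equal(res$block_id, "child:2")
  # 2 vs 2 across blocks -> HP0 even though each block is internally decisive
  o <- make_obs("r1", c(100, 200, 10000, 10100), c("A", "A", "C", "C"))
  expect_equal(assign_molecule_haplotypes(reads, o, b)$hp, 0L)
})

test_that("the three tag partitions conserve the read count and order", {
  set.seed(5)
  r <- make_reads(sort(sample.int(1e5, 60)), sample(paste0("BX", 1:6), 60, TRUE))
  r[, hp := sample(0:2, 60, TRUE)]
  parts <- split_by_tag(r)
  expect_equal(nrow(parts$hp1) + nrow(parts$hp2) + nrow(parts$hp0), nrow(r))
  expect_equal(parts$hp1$read_id, r$read_id[r$hp == 1L])
  expect_equal(parts$hp0$read_id, r$read_id[r$hp == 0L])
  # degenerate partition
  r[, hp := 0L]
  parts <- split_by_tag(r)
  expect_equal(nrow(parts$hp1), 0L)
  expect_equal(nrow(parts$hp0), nrow(r))
})

test_that("trusting pre-set tags reproduces the recomputed partition on clean data", {
  sim <- simulate_trio(tiny_cfg())
  blocks <- rbindlist(lapply(c("father", "mother", "child"),
                             function(r) phase_blocks(sim$variants, r)))
  recomputed <- tag_reads(sim$reads, sim$obs, blocks)
  trusted_in <- copy(sim$reads)[, hp := recomputed$hp[match(read_id, recomputed$read_id)]]
  trusted <- tag_reads(trusted_in, sim$obs, blocks, mode = "trust")
  expect_equal(trusted$hp[match(recomputed$read_id, trusted$read_id)],
               recomputed$hp)
})
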