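test_that("the canonical autosomal profiles get the expected labels", {
  # clean high-confidence pattern
  p <- make_profile()
  expect_equal(classify_autosomal_dnm(p)$label, "H")
  expect_true(classify_site_confidence(p))
  # an uncovered parental haplotype demotes to low confidence
  p <- make_profile(f2 = "UNCOVERED")
  r <- classify_autosomal_dnm(p)
  expect_equal(r$label, "L")
  expect_equal(r$reason, "uncovered-haplotype")
  expect_false(classify_site_confidence(p))
  # a parental alternate haplotype is hard evidence of inheritance
  p <- make_profile(f1 = "ALT")
  r <- classify_autosomal_dnm(p)
  expect_equal(r$label, "REMOVED")
  expect_equal(r$reason, "parental-alt-haplotype")
  # a conflicting haplotype is a miscall
  expect_equal(classify_autosomal_dnm(make_profile(c1 = "CONFLICT"))$reason,
               "haploid-conflict")
  # full pattern but unphased: missing information, not counter-evidence
  r <- classify_autosomal_dnm(make_profile(phased = FALSE))
  expect_equal(r$label, "L")
  expect_equal(r$reason, "unphased")
  # child callable but identical: contradicts the het call
  expect_equal(classify_autosomal_dnm(make_profile(c2 = "REF"))$reason,
               "child-not-0-1")
})

test_that("reason codes follow the fixed precedence order", {
  # parental ALT beats a conflict elsewhere
  p <- make_profile(f1 = "ALT", m1 = "CONFLICT", c1 = "CONFLICT")
  expect_equal(classify_autosomal_dnm(p)$reason, "parental-alt-haplotype")
  # conflict beats child-not-0-1
  p <- make_profile(m1 = "CONFLICT", c1 = "REF", c2 = "REF")
  expect_equal(classify_autosomal_dnm(p)$reason, "haploid-conflict")
  # removal evidence among covered haplotypes beats an uncovered one
  p <- make_profile(f1 = "ALT", f2 = "UNCOVERED")
  expect_equal(classify_autosomal_dnm(p)$label, "REMOVED")
})

test_that("every one of the 4^6 x {phased, unphased} profiles matches the rule oracle", {
  states <- c("REF", "ALT", "CONFLICT", "UNCOVERED")
  grid <- do.call(CJ, c(setNames(rep(list(states), 6),
                                 c("f1", "f2", "m1", "m2", "c1", "c2")),
                        list(phased = c(TRUE, FALSE))))
  p <- make_profile(f1 = grid$f1, f2 = grid$f2, m1 = grid$m1, m2 = grid$m2,
                    c1 = grid$c1, c2 = grid$c2, phased = grid$phased)
  got <- classify_autosomal_dnm(p)
  want <- t(mapply(oracle_autosomal, grid$f1, grid$f2, grid$m1, grid$m2,
                   grid$c1, grid$c2, grid$phased))
  expect_equal(got$label, unname(want[, 1]))
  expect_equal(got$reason, unname(want[, 2]))
  # the three labels partition the candidates
  expect_true(all(got$label %in% c("H", "L", "REMOVED")))
  # H implies a high-confidence site; L implies an uncovered haplotype or
  # missing phase; REMOVED always carries a reason
  expect_true(all(classify_site_confidence(got[label == "H"])))
  expect_true(all(nchar(got[label != "H"]$reason) > 0))
})

test_that("male-child X rules consider only mother and child X haploids", {
  # mother REF/REF, child X ALT at depth: high confidence
  p <- make_profile(chrom_class = "X-nonPAR", sex = "male", cx = "ALT",
                    f1 = "ALT", f2 = "ALT")  # father must be ignored
  expect_equal(classify_chrx_dnm(p)$label, "H")
  p <- make_profile(chrom_class = "X-nonPAR", sex = "male", m1 = "ALT")
  expect_equal(classify_chrx_dnm(p)$reason, "parental-alt-haplotype")
  p <- make_profile(chrom_class = "X-nonPAR", sex = "male", cx = "UNCOVERED")
  expect_equal(classify_chrx_dnm(p)$label, "L")
  expect_error(classify_chrx_dnm(make_profile(chrom_class = "X-nonPAR")),
               "child_sex")
})

test_that("female-child X rules include the father's single X haploid", {
  p <- make_profile(chrom_class = "X-nonPAR", sex = "female", fx = "REF")
  expect_equal(classify_chrx_dnm(p)$label, "H")
  p <- make_profile(chrom_class = "X-nonPAR", sex = "female", fx = "ALT")
  r <- classify_chrx_dnm(p)
  expect_equal(r$label, "REMOVED")
  expect_equal(r$reason, "parental-alt-haplotype")
})

test_that("PAR sites are routed to the autosomal classifier", {
  par1 <- par_regions_hg19()$start[1] + 10L
  expect_equal(haplodenovo:::chrom_class_of("chrX", par1), "autosome")
  expect_equal(haplodenovo:::chrom_class_of("chrX", 5e6), "X-nonPAR")
  expect_equal(haplodenovo:::chrom_class_of("chr7", 5e6), "autosome")
  p <- rbind(make_profile(chrom = "chrX", pos = par1, sex = "female",
                          chrom_class = haplodenovo:::chrom_class_of("chrX", par1)),
             make_profile(chrom = "chrX", pos = 5e6L, sex = "female",
                          chrom_class = "X-nonPAR", fx = "ALT"))
  got <- classify_dnms(p)
  expect_equal(got$label, c("H", "REMOVED"))  # PAR row ignores father_x
})

test_that("parent-of-origin follows the transmission vote in the child's phase block", {
  # DNM at pos 300 on child haplotype 1; three informative mother-het sites
  tv <- make_tv(
    father = c("0/0", "0/0", "0/0", "0/0", "0/0"),
    mother = c("0/1", "0/1", "0/0", "0/1", "0/0"),
    child  = c("1|0", "1|0", "1|0", "1|0", "0/0"),
    c_ps = c("1", "1", "1", "1", NA))
  s <- data.table(chrom = "chr1", pos = 300L, child_alt_haplotype = "HP1")
  expect_equal(infer_parent_of_origin(tv, s), "maternal")
  # same block, DNM allele on the other haplotype: the 0 allele at the
  # informative sites could come from either parent -> unknown
  s2 <- data.table(chrom = "chr1", pos = 300L, child_alt_haplotype = "HP2")
  expect_equal(infer_parent_of_origin(tv, s2), "unknown")
})

test_that("zero informative sites or a tie leave the origin unknown", {
  tv <- make_tv(father = c("0/0", "0/0"), mother = c("0/0", "0/0"),
                child = c("1|0", "1|0"), c_ps = c("1", "1"))
  s <- data.table(chrom = "chr1", pos = 100L, child_alt_haplotype = "HP1")
  expect_equal(infer_parent_of_origin(tv, s), "unknown")
  # a perfect tie: one paternal and one maternal informative site
  tv2 <- make_tv(father = c("0/1", "0/0", "0/0"),
                 mother = c("0/0", "0/1", "0/0"),
                 child = c("1|0", "1|0", "1|0"),
                 c_ps = "1")
  s3 <- data.table(chrom = "chr1", pos = 300L, child_alt_haplotype = "HP1")
  expect_equal(infer_parent_of_origin(tv2, s3), "unknown")
})

test_that("simulated trios recover the planted parent-of-origin", {
  sim <- simulate_trio(tiny_cfg(seed = 17, n_dnms = 8L))
  res <- suppressMessages(hapdenovo_run(sim$variants, sim$reads, sim$obs))
  cls <- res$classified
  dnm <- sim$truth$sites[kind == "dnm"]
  m <- match(dnm$pos, cls$pos)
  phased_h <- !is.na(m) & cls$label[m] == "H"
  expect_true(sum(phased_h) >= 6)
  expect_equal(cls$parent_of_origin[m[phased_h]],
               dnm$dnm_origin[phased_h])
})

test_that("the report keeps H/L rows in the main file and removed rows aside", {
  p <- rbind(make_profile(), make_profile(f1 = "ALT"),
             make_profile(f2 = "UNCOVERED"))
  cls <- classify_dnms(p)
  cls[, parent_of_origin := c("maternal", "unknown", "unknown")]
  prefix <- tempfile()
  paths <- write_dnm_report(cls, prefix)
  main <- fread(paths$main)
  removed <- fread(paths$removed)
  expect_equal(nrow(main), 2L)
  expect_equal(sort(main$label), c("H", "L"))
  expect_equal(nrow(removed), 1L)
  expect_equal(removed$reason, "parental-alt-haplotype")
  # empty input -> header-only files
  paths <- write_dnm_report(cls[0], tempfile())
  expect_equal(nrow(fread(paths$main)), 0L)
  expect_true(all(c("chrom", "pos", "label") %in% names(fread(paths$main))))
})
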