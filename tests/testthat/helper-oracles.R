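# Independently coded oracles: plain nested-if transcriptions of the
# written decision rules, kept deliberately separate from the package's
# vectorised implementations.

oracle_autosomal <- function(f1, f2, m1, m2, c1, c2, phased) {
  states <- c(f1, f2, m1, m2, c1, c2)
  if (any(c(f1, f2, m1, m2) == "ALT"))
    return(c("REMOVED", "parental-alt-haplotype"))
  if (any(states == "CONFLICT"))
    return(c("REMOVED", "haploid-conflict"))
  child_callable <- all(c(c1, c2) %in% c("REF", "ALT"))
  child_01 <- setequal(c(c1, c2), c("REF", "ALT")) &&
    sum(c(c1, c2) == "ALT") == 1L
  if (child_callable && !child_01)
    return(c("REMOVED", "child-not-0-1"))
  if (any(states == "UNCOVERED"))
    return(c("L", "uncovered-haplotype"))
  if (!phased)
    return(c("L", "unphased"))
  c("H", "")
}

oracle_x_male <- function(m1, m2, cx) {
  states <- c(m1, m2, cx)
  if (any(c(m1, m2) == "ALT")) return(c("REMOVED", "parental-alt-haplotype"))
  if (any(states == "CONFLICT")) return(c("REMOVED", "haploid-conflict"))
  if (cx == "REF") return(c("REMOVED", "child-not-0-1"))
  if (any(states == "UNCOVERED")) return(c("L", "uncovered-haplotype"))
  c("H", "")
}

oracle_x_female <- function(fx, m1, m2, c1, c2, phased) {
  states <- c(fx, m1, m2, c1, c2)
  if (any(c(fx, m1, m2) == "ALT"))
    return(c("REMOVED", "parental-alt-haplotype"))
  if (any(states == "CONFLICT")) return(c("REMOVED", "haploid-conflict"))
  child_callable <- all(c(c1, c2) %in% c("REF", "ALT"))
  child_01 <- sum(c(c1, c2) == "ALT") == 1L && sum(c(c1, c2) == "REF") == 1L
  if (child_callable && !child_01) return(c("REMOVED", "child-not-0-1"))
  if (any(states == "UNCOVERED")) return(c("L", "uncovered-haplotype"))
  if (!phased) return(c("L", "unphased"))
  c("H", "")
}

# exhaustive vote count over one molecule's informative observations
oracle_vote <- function(votes) {
  n1 <- sum(votes == 1L); n2 <- sum(votes == 2L)
  if (n1 > n2) 1L else if (n2 > n1) 2L else 0L
}

# transitive chaining over all read pairs (same barcode & chromosome,
# starts within the gap threshold), via connected components
oracle_group <- function(reads, gap) {
  n <- nrow(reads)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (is.na(reads$barcode[i]) || is.na(reads$barcode[j])) next
    if (reads$barcode[i] == reads$barcode[j] &&
        reads$chrom[i] == reads$chrom[j] &&
        abs(reads$start[i] - reads$start[j]) <= gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

oracle_haploid <- function(ref, alt, min_depth = 2, min_minor_count = 2,
                           min_minor_fraction = 0.15) {
  depth <- ref + alt
  if (depth < min_depth) return("UNCOVERED")
  minor <- min(ref, alt)
  if ((minor >= min_minor_count && minor / depth >= min_minor_fraction) ||
      ref == alt) return("CONFLICT")
  if (ref > alt) "REF" else "ALT"
}
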