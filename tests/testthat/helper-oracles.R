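# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive (per-record loops, exhaustive enumeration) and never
# call the package functions they check.

# one moderately sized cohort shared across test files
study_cohort <- simulate_cohort(cohort_spec(seed = 42L))

small_cohort <- simulate_cohort(cohort_spec(
  n_background_variants = 300L, n_block_sites = 10L, seed = 11L))

# -- quality predicate, re-derived record by record ---------------------------
oracle_quality_pass <- function(variants, genotypes, proband, q) {
  vapply(seq_len(nrow(variants)), function(i) {
    g <- genotypes[genotypes$sample == proband &
                     genotypes$id == variants$id[i], ]
    if (nrow(g) != 1) return(FALSE)
    if (g$gqx < q$gqx) return(FALSE)
    if (g$vf < q$vf) return(FALSE)
    if (g$gq < q$gq) return(FALSE)
    if (variants$class[i] != "snv" && g$r8 > q$r8) return(FALSE)
    if (g$sb > q$sb) return(FALSE)
    if (g$dp < q$dp) return(FALSE)
    TRUE
  }, logical(1))
}

# -- point-in-expanded-interval, no merging -----------------------------------
oracle_in_roi <- function(variants, intervals, flank) {
  vapply(seq_len(nrow(variants)), function(i) {
    any(intervals$chrom == variants$chrom[i] &
          variants$pos[i] >= intervals$start - flank &
          variants$pos[i] <= intervals$end + flank)
  }, logical(1))
}

oracle_effect_keep <- function(variants, retained, intronic = 8, exonic = 3) {
  vapply(seq_len(nrow(variants)), function(i) {
    off <- variants$boundary_offset[i]
    splice <- !is.na(off) &&
      ((off < 0 && -off <= intronic) || (off > 0 && off <= exonic))
    variants$effect[i] %in% retained || splice
  }, logical(1))
}

oracle_maf_keep <- function(variants, af, max_maf) {
  vapply(seq_len(nrow(variants)), function(i) {
    a <- af$af[af$id == variants$id[i]]
    length(a) == 0 || max(a) <= max_maf
  }, logical(1))
}

# -- exhaustive compound-het pair enumeration (trio) --------------------------
oracle_compound_het <- function(variants, genotypes, proband, father, mother) {
  dose_of <- function(s, id) {
    g <- genotypes[genotypes$sample == s & genotypes$id == id, ]
    if (nrow(g) != 1) return(NA_integer_)
    gt_dose(g$gt)
  }
  genes <- character()
  ids <- variants$id
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j || variants$gene[i] != variants$gene[j]) next
    oi <- origin(dose_of(proband, ids[i]), dose_of(father, ids[i]),
                 dose_of(mother, ids[i]))
    oj <- origin(dose_of(proband, ids[j]), dose_of(father, ids[j]),
                 dose_of(mother, ids[j]))
    if (identical(oi, "pat") && identical(oj, "mat"))
      genes <- c(genes, variants$gene[i])
  }
  sort(unique(genes))
}

origin <- function(dp, df, dm) {
  if (is.na(dp) || dp != 1L || is.na(df) || is.na(dm)) return(NA_character_)
  if (df >= 1L && dm == 0L) return("pat")
  if (dm >= 1L && df == 0L) return("mat")
  NA_character_  # absent from both, or ambiguous (both parents carry it)
}

# -- per-gene tallies ---------------------------------------------------------
oracle_shared_genes <- function(a, b) {
  out <- character()
  for (g in unique(c(a$gene, b$gene)))
    if (any(a$gene == g) && any(b$gene == g)) out <- c(out, g)
  sort(out)
}

oracle_shared_ch_genes <- function(a, b) {
  out <- character()
  for (g in unique(c(a$gene, b$gene)))
    if (sum(a$gene == g & a$zygosity == "het") >= 2 &&
        sum(b$gene == g & b$zygosity == "het") >= 2) out <- c(out, g)
  sort(out)
}

# -- rle-based homozygosity-run scan (het_tolerance = 0) ----------------------
oracle_blocks <- function(pos, g1, g2, min_length) {
  sh <- !is.na(g1) & !is.na(g2) & g1 == g2 & g1 != 1L
  r <- rle(sh)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = pos[starts[keep]], end = pos[ends[keep]])
  out[out$end - out$start >= min_length, , drop = FALSE]
}

# random small case variant sets for the shared-gene / compound-het oracles
random_case_set <- function(n, genes = paste0("G", 1:6)) {
  data.frame(
    id = paste0("v", seq_len(n), "_", sample(1e6, n)),
    gene = sample(genes, n, replace = TRUE),
    zygosity = sample(c("het", "hom"), n, replace = TRUE, prob = c(.8, .2)),
    stringsAsFactors = FALSE
  )
}

# random transcript + matching CDS (stop codon last) for translation tests
random_coding_codons <- local({
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste0, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

random_transcript_with_cds <- function() {
  n_exons <- sample(3:6, 1)
  widths <- sample(30:180, n_exons, replace = TRUE)
  if (sum(widths) %% 3 != 0)
    widths[n_exons] <- widths[n_exons] + (3 - sum(widths) %% 3)
  tx <- synthetic_transcript(widths, strand = sample(c("+", "-"), 1))
  n_cod <- sum(widths) / 3
  cds <- paste0("ATG",
                paste(sample(random_coding_codons, n_cod - 2, TRUE),
                      collapse = ""), "TAA")
  list(tx = tx, cds = cds, widths = widths)
}
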