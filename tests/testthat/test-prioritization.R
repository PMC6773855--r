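# helper to build a one-variant cohort fragment for predicate tests
call_row <- function(id = "chr1:100:A:T", sample = "P", gt = "0/1",
                     dp = 40, gq = 60, gqx = 50, vf = 0.5, sb = -40, r8 = 1) {
  data.frame(id = id, sample = sample, gt = gt, dp = dp, gq = gq, gqx = gqx,
             vf = vf, sb = sb, r8 = r8, stringsAsFactors = FALSE)
}

var_row <- function(id = "chr1:100:A:T", chrom = "chr1", pos = 100,
                    ref = "A", alt = "T", gene = "G1",
                    effect = "nonsynonymous", boundary_offset = 50,
                    class = "snv") {
  data.frame(id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = gene, effect = effect, boundary_offset = boundary_offset,
             class = class, stringsAsFactors = FALSE)
}

test_that("quality criteria are applied strictly as stated", {
  cfg <- filter_config()
  run1 <- function(...) {
    apply_quality_filters(var_row(), call_row(...), "P", cfg)
  }
  expect_equal(nrow(run1()$variants), 1)                 # all fields passing
  r <- run1(gqx = 5)
  expect_equal(nrow(r$variants), 0)
  expect_equal(unname(r$counts["LowGQX"]), 1)
  expect_equal(nrow(run1(gqx = 10)$variants), 1)         # boundary survives
  expect_equal(nrow(run1(dp = 19)$variants), 0)          # strict "<"
  expect_equal(nrow(run1(dp = 20)$variants), 1)
  expect_equal(nrow(run1(vf = 0.19)$variants), 0)
  expect_equal(nrow(run1(vf = 0.20)$variants), 1)
  expect_equal(nrow(run1(gq = 29)$variants), 0)
  expect_equal(nrow(run1(sb = -9)$variants), 0)          # SB > -10 trips
  expect_equal(nrow(run1(sb = -10)$variants), 1)
  # R8 applies to indels only
  v_indel <- var_row(ref = "A", alt = "AT", class = "indel")
  expect_equal(nrow(apply_quality_filters(
    v_indel, call_row(r8 = 9), "P", cfg)$variants), 0)
  expect_equal(nrow(apply_quality_filters(
    var_row(), call_row(r8 = 9), "P", cfg)$variants), 1)
  # missing field -> unevaluable, removed, counted separately
  r <- apply_quality_filters(var_row(), call_row(gq = NA), "P", cfg)
  expect_equal(nrow(r$variants), 0)
  expect_equal(unname(r$counts["unevaluable"]), 1)
})

test_that("quality filtering matches the record-by-record oracle on a cohort", {
  co <- small_cohort
  pb <- "FAM1_A1"
  got <- apply_quality_filters(co$variants, co$genotypes, pb, filter_config())
  keep <- oracle_quality_pass(co$variants, co$genotypes, pb,
                              filter_config()$quality)
  expect_identical(got$variants$id, co$variants$id[keep])
  expect_true(any(!keep))  # the planted failures exercise the filter
})

test_that("ROI restriction honors flanks exactly and matches the brute-force scan", {
  iv <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  at <- function(p) var_row(id = paste0("chr1:", p, ":A:T"), pos = p)
  expect_equal(nrow(restrict_to_roi(at(2010), iv, 10)), 1)   # end + flank
  expect_equal(nrow(restrict_to_roi(at(2011), iv, 10)), 0)
  expect_equal(nrow(restrict_to_roi(at(990), iv, 10)), 1)
  expect_equal(nrow(restrict_to_roi(at(1500), iv[0, ], 10)), 0) # empty set

  co <- small_cohort
  got <- restrict_to_roi(co$variants, co$roi, 10)
  keep <- oracle_in_roi(co$variants, co$roi, 10)
  expect_identical(got$id, co$variants$id[keep])
})

test_that("population-frequency filtering treats absence as rare", {
  v <- rbind(var_row(id = "a"), var_row(id = "b"), var_row(id = "c"))
  af <- data.frame(id = c("a", "b"), source = "exac", af = c(0.0007, 0.05))
  out <- filter_by_population_frequency(v, af, 0.01)
  expect_setequal(out$id, c("a", "c"))   # rare kept, common dropped, absent kept
  expect_error(filter_by_population_frequency(
    v, data.frame(id = "a", source = "x", af = 1.2), 0.01))
  # max_maf = 0: only variants absent from every source survive
  expect_identical(filter_by_population_frequency(v, af, 0)$id, "c")
})

test_that("splice-window predicate covers 8 intronic and 3 exonic bases", {
  expect_true(splice_window_hit(-1))
  expect_true(splice_window_hit(-8))
  expect_false(splice_window_hit(-9))
  expect_true(splice_window_hit(3))
  expect_false(splice_window_hit(4))
  expect_false(splice_window_hit(NA))
})

test_that("effect classification distinguishes LoF, missense, silent and in-frame", {
  tx <- synthetic_transcript(c(30, 30, 30))
  cds <- paste0("ATG", strrep("GAA", 28), "TAA")   # Met + 28 Glu + stop
  at <- function(pos, ref, alt) classify_effect("chrS", pos, ref, alt, tx, cds)
  g0 <- tx$exons$g_start[1]
  # GAA->TAA at codon 2 first base: stopgain
  expect_equal(at(g0 + 3, "G", "T"), "LoF")
  # GAA->GAG third base: synonymous
  expect_equal(at(g0 + 5, "A", "G"), "synonymous")
  # GAA->GCA second base: missense
  expect_equal(at(g0 + 4, "A", "C"), "nonsynonymous")
  # 3-bp deletion: inframe; 1-bp deletion: frameshift LoF
  expect_equal(at(g0 + 6, "GAAG", "G"), "inframe")
  expect_equal(at(g0 + 6, "GA", "G"), "LoF")
  # first intronic base past exon 1: splice region
  expect_equal(at(tx$exons$g_end[1] + 1, "G", "A"), "splice_region")
  expect_equal(at(tx$exons$g_end[1] + 9, "G", "A"), "noncoding")
})

test_that("trio inheritance callers implement the stated genotype patterns", {
  expect_equal(call_recessive_homozygous("1/1", "0/1", "0/1"), "candidate")
  expect_equal(call_recessive_homozygous("1/1", "0/0", "0/1"), "not_candidate")
  expect_equal(call_recessive_homozygous("0/1", "0/1", "0/1"), "not_candidate")
  expect_equal(call_recessive_homozygous("1/1", "./.", "0/1"), "unevaluable")

  expect_equal(call_de_novo("0/1", "0/0", "0/0"), "candidate")
  expect_equal(call_de_novo("0/1", "0/1", "0/0"), "not_candidate")
  expect_equal(call_de_novo("0/1", "0/0", "0/0", father_dp = 5), "unevaluable")
})

test_that("compound-het calling phases by transmission and excludes ambiguous sites", {
  v <- rbind(var_row(id = "a", gene = "G1"), var_row(id = "b", gene = "G1"),
             var_row(id = "c", gene = "G2"), var_row(id = "d", gene = "G2"))
  gts <- rbind(
    call_row("a", "P", "0/1"), call_row("a", "F", "0/1"), call_row("a", "M", "0/0"),
    call_row("b", "P", "0/1"), call_row("b", "F", "0/0"), call_row("b", "M", "0/1"),
    call_row("c", "P", "0/1"), call_row("c", "F", "0/0"), call_row("c", "M", "0/1"),
    call_row("d", "P", "0/1"), call_row("d", "F", "0/0"), call_row("d", "M", "0/1"))
  res <- call_compound_het(v, gts, "P", "F", "M")
  expect_identical(res$genes, "G1")      # trans in G1; cis (both maternal) in G2
  # ambiguous: both parents het -> excluded from pairing
  gts$gt[gts$id == "a" & gts$sample == "M"] <- "0/1"
  res2 <- call_compound_het(v, gts, "P", "F", "M")
  expect_identical(res2$genes, character(0))
  expect_identical(res2$excluded, "a")
})

test_that("compound-het calls equal exhaustive pair enumeration on random trios", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    v <- do.call(rbind, lapply(seq_len(n), function(i)
      var_row(id = paste0("v", i), gene = sample(paste0("G", 1:3), 1))))
    gts <- do.call(rbind, lapply(v$id, function(id) {
      rbind(call_row(id, "P", sample(c("0/0", "0/1"), 1)),
            call_row(id, "F", sample(c("0/0", "0/1", "1/1"), 1)),
            call_row(id, "M", sample(c("0/0", "0/1", "1/1"), 1)))
    }))
    expect_identical(call_compound_het(v, gts, "P", "F", "M")$genes,
                     oracle_compound_het(v, gts, "P", "F", "M"))
  }
})

test_that("the family pipeline recovers exactly the planted recessive variant", {
  co <- study_cohort
  for (fam in c("FAM1", "FAM2")) {
    res <- run_family_analysis(co, fam)
    expect_identical(res$candidates$recessive, co$truth$causal$id)
  }
})

test_that("pipeline stage counts match the predicate-conjunction oracle", {
  co <- small_cohort
  cfg <- filter_config()
  res <- run_family_analysis(co, "FAM1")
  pq <- oracle_quality_pass(co$variants, co$genotypes, "FAM1_A1", cfg$quality)
  pr <- oracle_in_roi(co$variants, co$roi, cfg$roi_flank)
  pe <- oracle_effect_keep(co$variants, cfg$retained_effects)
  pm <- oracle_maf_keep(co$variants, co$af, cfg$max_maf)
  expect_equal(unname(res$stage_counts),
               c(nrow(co$variants), sum(pq), sum(pq & pr),
                 sum(pq & pr & pe), sum(pq & pr & pe & pm)))
})

test_that("the surviving set is order-independent and monotone in thresholds", {
  co <- small_cohort
  cfg <- filter_config()
  pb <- "FAM1_A1"
  # composition order: quality then ROI vs ROI then quality
  a <- restrict_to_roi(
    apply_quality_filters(co$variants, co$genotypes, pb, cfg)$variants,
    co$roi, cfg$roi_flank)
  b <- apply_quality_filters(
    restrict_to_roi(co$variants, co$roi, cfg$roi_flank),
    co$genotypes, pb, cfg)$variants
  expect_setequal(a$id, b$id)
  # relaxing the depth threshold never shrinks the survivor set
  relaxed <- filter_config(quality = modifyList(cfg$quality, list(dp = 5)))
  sa <- apply_quality_filters(co$variants, co$genotypes, pb, cfg)$variants$id
  sb <- apply_quality_filters(co$variants, co$genotypes, pb, relaxed)$variants$id
  expect_true(all(sa %in% sb))
})

test_that("candidates intersected across affected siblings are a subset of each sibling's", {
  co <- small_cohort
  both <- run_family_analysis(co, "FAM1", require_all_affected = TRUE)
  one <- run_family_analysis(co, "FAM1", require_all_affected = FALSE)
  expect_true(all(both$candidates$recessive %in% one$candidates$recessive))
})
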