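site_row <- function(class = "snv", qd = 20, mq = 55, fs = 5,
                     haplotype_score = 2, mq_rank_sum = 0,
                     read_pos_rank_sum = 0, snp_cluster_count = 0) {
  data.frame(class = class, qd = qd, mq = mq, fs = fs,
             haplotype_score = haplotype_score, mq_rank_sum = mq_rank_sum,
             read_pos_rank_sum = read_pos_rank_sum,
             snp_cluster_count = snp_cluster_count)
}

test_that("PASS flagging applies class-specific hard filters", {
  expect_true(flag_pass(site_row()))
  expect_false(flag_pass(site_row(qd = 1.5)))
  expect_false(flag_pass(site_row(mq = 39.9)))
  expect_false(flag_pass(site_row(fs = 61)))
  expect_false(flag_pass(site_row(haplotype_score = 13.5)))
  expect_false(flag_pass(site_row(mq_rank_sum = -13)))
  expect_false(flag_pass(site_row(read_pos_rank_sum = -8.5)))
  expect_false(flag_pass(site_row(snp_cluster_count = 3)))
  # an FS of 150 fails the SNV threshold (60) but passes the indel one (200)
  expect_false(flag_pass(site_row(fs = 150)))
  expect_true(flag_pass(site_row(class = "indel", fs = 150)))
  expect_false(flag_pass(site_row(class = "indel", fs = 250)))
  # indels ignore the SNV-only criteria
  expect_true(flag_pass(site_row(class = "indel", mq = 10,
                                 haplotype_score = 20, read_pos_rank_sum = -10)))
  expect_false(flag_pass(site_row(class = "indel", read_pos_rank_sum = -21)))
})

test_that("high-quality genotype predicate uses strict inequalities", {
  expect_true(high_quality_genotype(5, 99, TRUE))
  expect_false(high_quality_genotype(4, 99, TRUE))
  expect_false(high_quality_genotype(5, 98, TRUE))
  expect_false(high_quality_genotype(5, 99, FALSE))
})

test_that("shared-variant classification requires homozygosity in both cases", {
  a <- data.frame(id = c("v1", "v2", "v3"), gene = "G",
                  zygosity = c("het", "hom", "hom"))
  b <- data.frame(id = c("v1", "v2", "v4"), gene = "G",
                  zygosity = c("het", "het", "hom"))
  res <- shared_variants(a, b)
  expect_equal(res$n_het, 2)   # v1 het-het, v2 hom in A only -> het class
  expect_equal(res$n_hom, 0)
  expect_false("v3" %in% res$shared$id)
  # symmetry
  res_ba <- shared_variants(b, a)
  expect_setequal(res_ba$shared$id, res$shared$id)
  expect_equal(res_ba$n_hom, res$n_hom)
})

test_that("a planted shared-hom among many shared-het decoys is counted (500, 1)", {
  n <- 500
  dec <- data.frame(id = paste0("d", 1:n), gene = paste0("G", 1:n),
                    zygosity = "het")
  hom <- data.frame(id = "causal", gene = "ABCC9", zygosity = "hom")
  res <- shared_variants(rbind(dec, hom), rbind(dec, hom))
  expect_equal(res$n_het, 500)
  expect_equal(res$n_hom, 1)
  expect_equal(res$shared$id[res$shared$zygosity == "hom"], "causal")
})

test_that("shared-gene and compound-het callers equal exhaustive tallies", {
  a0 <- data.frame(id = c("x1", "x2"), gene = c("GA", "GA"), zygosity = "het")
  b0 <- data.frame(id = c("y1", "y2"), gene = c("GA", "GA"), zygosity = "het")
  expect_identical(shared_genes_dominant(a0, b0), "GA")
  expect_identical(shared_compound_het_genes(a0, b0), "GA")
  expect_identical(shared_compound_het_genes(a0, b0[1, ]), character(0))

  set.seed(101)
  for (rep in 1:50) {
    a <- random_case_set(sample(3:20, 1))
    b <- random_case_set(sample(3:20, 1))
    expect_identical(shared_genes_dominant(a, b), oracle_shared_genes(a, b))
    expect_identical(shared_compound_het_genes(a, b),
                     oracle_shared_ch_genes(a, b))
    # compound-het genes are a subset of the dominant shared genes
    expect_true(all(shared_compound_het_genes(a, b) %in%
                      shared_genes_dominant(a, b)))
  }
})

test_that("kinship hits the pedigree expectations within 0.02 at 10k SNPs", {
  expected <- c(monozygotic = 0.5, parent_offspring = 0.25,
                full_sibs = 0.25, unrelated = 0)
  for (rel in names(expected)) {
    p <- simulate_genotype_panel(10000, rel, seed = 31L)
    expect_lt(abs(kinship(p$g1, p$g2) - expected[[rel]]), 0.02)
  }
  # duplicate-sample limit and symmetry
  g <- simulate_genotype_panel(2000, "unrelated", seed = 5L)
  expect_equal(kinship(g$g1, g$g1), 0.5)
  expect_equal(kinship(g$g1, g$g2), kinship(g$g2, g$g1))
  expect_error(kinship(c(0, 1), c(0, 1)), "too few")
})

test_that("shared homozygous blocks are maximal runs and match the rle oracle", {
  # both cases hom across 100-900, het at 950 -> block [100, 900]
  pos <- c(100, 300, 500, 700, 900, 950, 1200)
  g1 <- c(2, 2, 0, 2, 2, 1, 2)
  g2 <- c(2, 2, 0, 2, 2, 2, 2)
  bl <- shared_homozygous_blocks(pos, g1, g2, min_length = 100)
  expect_equal(bl$start[1], 100)
  expect_equal(bl$end[1], 900)
  # opposite homozygotes break a block
  g2b <- c(2, 2, 2, 0, 2, 2, 2)
  g1b <- c(2, 2, 2, 2, 2, 2, 2)
  blb <- shared_homozygous_blocks(pos, g1b, g2b, min_length = 10)
  expect_false(any(blb$start <= 700 & blb$end >= 700))
  expect_error(shared_homozygous_blocks(c(5, 1), c(2, 2), c(2, 2)), "sorted")

  set.seed(55)
  for (rep in 1:25) {
    n <- sample(50:400, 1)
    pos <- sort(sample.int(1e6, n))
    g1 <- sample(0:2, n, TRUE, prob = c(.35, .3, .35))
    g2 <- sample(0:2, n, TRUE, prob = c(.35, .3, .35))
    got <- shared_homozygous_blocks(pos, g1, g2, min_length = 5e4)
    want <- oracle_blocks(pos, g1, g2, min_length = 5e4)
    expect_equal(got[, c("start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("the planted shared block is recovered within one inter-variant gap", {
  co <- study_cohort
  g_of <- function(s) {
    g <- co$genotypes[co$genotypes$sample == s, ]
    g[match(co$variants$id, g$id), "gt"]
  }
  chr12 <- co$variants$chrom == "chr12"
  ord <- order(co$variants$pos[chr12])
  pos <- co$variants$pos[chr12][ord]
  d1 <- gt_dose(g_of("FAM1_A1")[chr12][ord])
  d2 <- gt_dose(g_of("FAM2_A1")[chr12][ord])
  bl <- shared_homozygous_blocks(pos, d1, d2, min_length = 1e6, chrom = "chr12")
  tb <- co$truth$block
  hit <- bl[bl$start <= tb$end & bl$end >= tb$start, ]
  expect_equal(nrow(hit), 1)
  # bounds within one inter-variant gap of the planted bounds
  inner <- range(co$variants$pos[co$variants$id %in% tb$site_ids])
  expect_lte(hit$start, inner[1])
  expect_gte(hit$end, inner[2])
  sh <- !is.na(d1) & !is.na(d2) & d1 == d2 & d1 != 1L
  gap_lo <- max(c(pos[pos < tb$start & !sh], 0))
  gap_hi <- min(c(pos[pos > tb$end & !sh], Inf))
  expect_gte(hit$start, gap_lo)
  expect_lte(hit$end, gap_hi)
})

test_that("the printed block coordinates give 3.8 Mb at one decimal", {
  len <- block_length(18326590, 22176010)
  expect_equal(len, 3849420)
  expect_equal(round(len / 1e6, 1), 3.8)
})

test_that("cross-family analysis finds the causal variant as unique shared hom", {
  co <- study_cohort
  res <- cross_family_analysis(co, "FAM1_A1", "FAM2_A1")
  hom <- res$shared$shared[res$shared$shared$zygosity == "hom", ]
  expect_equal(nrow(hom), 1)
  expect_equal(hom$id, co$truth$causal$id)
  expect_equal(hom$gene, "ABCC9")
})
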