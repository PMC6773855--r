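# Cross-family whole-genome stage: site PASS flagging, high-quality genotype
# selection, shared-variant / shared-gene / compound-het analyses between one
# case per family, KING-robust kinship, and shared homozygosity blocks.

#' Site-level PASS flag
#'
#' A site is PASS only if it meets none of the hard-filter criteria. SNVs:
#' QD < 2.0, MQ < 40.0, FS > 60.0, HaplotypeScore > 13.0, MQRankSum < -12.5,
#' ReadPosRankSum < -8.0, or >= 3 SNVs clustered in 35 bp. Indels: QD < 2.0,
#' FS > 200.0, ReadPosRankSum < -20.0. A missing statistic skips that
#' criterion.
#'
#' @param variants data.frame with `class` (`"snv"`/`"indel"`) and columns
#'   `qd`, `mq`, `fs`, `haplotype_score`, `mq_rank_sum`, `read_pos_rank_sum`,
#'   `snp_cluster_count` (any may be absent or NA).
#' @return logical vector, TRUE = PASS.
#' @export
flag_pass <- function(variants) {
  n <- nrow(variants)
  col <- function(nm) if (nm %in% names(variants)) variants[[nm]] else rep(NA_real_, n)
  trip <- function(x, cond) !is.na(x) & cond(x)
  qd <- col("qd"); fs <- col("fs"); rprs <- col("read_pos_rank_sum")
  snv <- variants$class == "snv"
  fail_snv <-
    trip(qd, function(x) x < 2.0) |
    trip(col("mq"), function(x) x < 40.0) |
    trip(fs, function(x) x > 60.0) |
    trip(col("haplotype_score"), function(x) x > 13.0) |
    trip(col("mq_rank_sum"), function(x) x < -12.5) |
    trip(rprs, function(x) x < -8.0) |
    trip(col("snp_cluster_count"), function(x) x >= 3)
  fail_indel <-
    trip(qd, function(x) x < 2.0) |
    trip(fs, function(x) x > 200.0) |
    trip(rprs, function(x) x < -20.0)
  ifelse(snv, !fail_snv, !fail_indel)
}

#' High-quality genotype predicate (whole-genome analysis)
#'
#' TRUE iff read depth > 4, the site is PASS, and genotype quality > 98
#' (all strict).
#'
#' @param dp read depth.
#' @param gq genotype quality.
#' @param pass logical site PASS flag.
#' @return logical vector.
#' @export
high_quality_genotype <- function(dp, gq, pass) {
  !is.na(dp) & !is.na(gq) & dp > 4 & pass & gq > 98
}

#' Qualifying variant set for one case (whole-genome mode)
#'
#' PASS sites with a high-quality non-reference genotype in the case,
#' restricted to the region of interest (default flank 100 bp), retained
#' effect / splice-window categories, and the population-frequency ceiling.
#'
#' @param cohort cohort list (`variants`, `genotypes`, `af`, `roi`).
#' @param case sample id.
#' @param config a [filter_config()]; use `roi_flank = 100` for the
#'   whole-genome convention.
#' @return variant data.frame with an added `zygosity` column
#'   (`"het"`/`"hom"`) for the case.
#' @export
case_qualifying_set <- function(cohort, case,
                                config = filter_config(roi_flank = 100L)) {
  v <- cohort$variants
  gts <- cohort$genotypes[cohort$genotypes$sample == case, , drop = FALSE]
  gts <- gts[match(v$id, gts$id), , drop = FALSE]
  dose <- gt_dose(gts$gt)
  keep <- flag_pass(v) & high_quality_genotype(gts$dp, gts$gq, TRUE) &
    !is.na(dose) & dose >= 1L
  v <- v[keep, , drop = FALSE]
  v$zygosity <- ifelse(dose[keep] == 2L, "hom", "het")
  v <- restrict_to_roi(v, cohort$roi, config$roi_flank)
  eff <- v$effect %in% config$retained_effects |
    splice_window_hit(v$boundary_offset, config$splice_intronic,
                      config$splice_exonic)
  v <- v[eff, , drop = FALSE]
  filter_by_population_frequency(v, cohort$af, config$max_maf)
}

#' Shared variants between two cases
#'
#' A variant is shared iff the identical (chrom, pos, ref, alt) record
#' qualifies in both cases. Zygosity class is `"hom"` only when homozygous in
#' both cases, else `"het"`.
#'
#' @param a,b qualifying variant data.frames with a `zygosity` column
#'   (see [case_qualifying_set()]).
#' @return list: `shared` (data.frame with `id`, `gene`, `zygosity`),
#'   `n_het`, `n_hom`.
#' @export
shared_variants <- function(a, b) {
  ids <- intersect(a$id, b$id)
  za <- a$zygosity[match(ids, a$id)]
  zb <- b$zygosity[match(ids, b$id)]
  zy <- ifelse(za == "hom" & zb == "hom", "hom", "het")
  shared <- data.frame(id = ids, gene = a$gene[match(ids, a$id)],
                       zygosity = zy, stringsAsFactors = FALSE)
  list(shared = shared,
       n_het = sum(zy == "het"), n_hom = sum(zy == "hom"))
}

#' Genes with qualifying variants in both cases (dominant model)
#'
#' A gene is included iff at least one qualifying variant hits it in each
#' case; the variants need not be identical.
#'
#' @param a,b qualifying variant data.frames.
#' @return sorted character vector of gene ids.
#' @export
shared_genes_dominant <- function(a, b) {
  sort(intersect(unique(a$gene), unique(b$gene)))
}

#' Genes compound-het-compatible in both cases
#'
#' Case-only mode: without parental genotypes the trans configuration cannot
#' be established, so a gene qualifies when it carries >= 2 qualifying
#' heterozygous variants in each case.
#'
#' @param a,b qualifying variant data.frames with `zygosity`.
#' @return sorted character vector of gene ids.
#' @export
shared_compound_het_genes <- function(a, b) {
  two_het <- function(v) {
    t <- table(v$gene[v$zygosity == "het"])
    names(which(t >= 2))
  }
  sort(intersect(as.character(two_het(a)), as.character(two_het(b))))
}

#' Pairwise kinship coefficient (KING-robust)
#'
#' Within-pair, allele-frequency-free estimator based on heterozygote
#' concordance and opposite homozygotes:
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(1)} + N_{Aa}^{(2)}}}
#' Expected values: 0.5 for duplicates/monozygotic twins, 0.25 for
#' parent-offspring and full siblings, 0 for unrelated pairs.
#'
#' @param g1,g2 integer dosage vectors (0/1/2, NA allowed) at the same sites.
#' @param min_sites minimum number of jointly called sites.
#' @return kinship estimate (unitless).
#' @export
kinship <- function(g1, g2, min_sites = 100L) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < min_sites) stop("too few overlapping sites")
  g1 <- g1[ok]; g2 <- g2[ok]
  n_hethet <- sum(g1 == 1L & g2 == 1L)
  n_opp <- sum((g1 == 0L & g2 == 2L) | (g1 == 2L & g2 == 0L))
  n_het1 <- sum(g1 == 1L); n_het2 <- sum(g2 == 1L)
  if (n_het1 + n_het2 == 0) stop("no heterozygous sites in either sample")
  (n_hethet - 2 * n_opp) / (n_het1 + n_het2)
}

#' Length of a homozygosity block, as reported
#'
#' Reported as `end - start` bp; the block chr12:18,326,590-22,176,010 is
#' 3,849,420 bp, i.e. 3.8 Mb at one decimal.
#'
#' @param start,end 1-based inclusive bounds.
#' @return length in bp.
#' @export
block_length <- function(start, end) {
  stopifnot(all(end >= start))
  end - start
}

#' Shared homozygous blocks between two samples
#'
#' Scans position-sorted genotypes on one chromosome for maximal runs where
#' both samples are homozygous for the same allele, allowing up to
#' `het_tolerance` interrupting non-shared-homozygous sites per block. Blocks
#' shorter than `min_length` (by [block_length()]) are dropped.
#'
#' @param pos sorted positions.
#' @param g1,g2 dosage vectors (0/1/2) at `pos`.
#' @param min_length minimum block length in bp (default 1e6).
#' @param het_tolerance tolerated interrupting sites per block (default 0).
#' @param chrom chromosome label for the output.
#' @return data.frame `chrom`, `start`, `end`, `n_sites`, `length`.
#' @export
shared_homozygous_blocks <- function(pos, g1, g2, min_length = 1e6,
                                     het_tolerance = 0L, chrom = "chr") {
  stopifnot(length(pos) == length(g1), length(g1) == length(g2))
  if (is.unsorted(pos, strictly = FALSE)) stop("positions must be sorted")
  shared_hom <- !is.na(g1) & !is.na(g2) & g1 == g2 & g1 != 1L
  blocks <- list()
  i <- 1L; n <- length(pos)
  while (i <= n) {
    if (!shared_hom[i]) { i <- i + 1L; next }
    j <- i; hets <- 0L; last_hom <- i
    while (j < n) {
      nxt <- j + 1L
      if (shared_hom[nxt]) { j <- nxt; last_hom <- nxt }
      else if (hets < het_tolerance) { hets <- hets + 1L; j <- nxt }
      else break
    }
    blocks[[length(blocks) + 1L]] <-
      data.frame(chrom = chrom, start = pos[i], end = pos[last_hom],
                 n_sites = sum(shared_hom[i:last_hom]))
    i <- last_hom + 1L
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_sites = integer())
  out$length <- block_length(out$start, out$end)
  out[out$length >= min_length, , drop = FALSE]
}

#' Full cross-family comparison of two cases
#'
#' @param cohort cohort list.
#' @param case_a,case_b one case per family.
#' @param config [filter_config()] (whole-genome defaults).
#' @return list with the qualifying sets, shared-variant result, dominant
#'   shared genes, compound-het shared genes.
#' @export
cross_family_analysis <- function(cohort, case_a, case_b,
                                  config = filter_config(roi_flank = 100L)) {
  a <- case_qualifying_set(cohort, case_a, config)
  b <- case_qualifying_set(cohort, case_b, config)
  sv <- shared_variants(a, b)
  list(case_a = a, case_b = b, shared = sv,
       dominant_genes = shared_genes_dominant(a, b),
       compound_het_genes = shared_compound_het_genes(a, b))
}
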