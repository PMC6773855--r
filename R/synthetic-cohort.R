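# Seeded synthetic-cohort generator.
#
# Emulates the study design the pipeline assumes: two nominally unrelated
# nuclear families carrying the same rare founder haplotype, with a planted
# homozygous splice-site variant inside a shared homozygous block, a rare-
# skewed background frequency spectrum, trio-consistent genotypes with
# realistic quality fields, and a configurable fraction of records that
# deliberately fail each filter so every filter is exercised in both
# directions. Every run emits a machine-readable truth ledger.

#' Cohort simulation specification
#'
#' Defaults mirror the study conditions: two families (four affected
#' children; two affected plus one unaffected), a causal splice variant at
#' chr12:22,063,090 C>T inside the shared homozygous block
#' chr12:18,326,590-22,176,010, and a Beta-shaped rare-variant background
#' spectrum on 0-0.5.
#'
#' @param n_families number of nuclear families.
#' @param family_structures list of `list(n_affected=, n_unaffected=)` per
#'   family (two genotyped parents are always generated; specs with affected
#'   children and fewer than two parents are rejected).
#' @param n_background_variants background variant count across the genome.
#' @param causal_locus list `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `boundary_offset` (default -1: first intronic base of a donor).
#' @param shared_block `c(start, end)` on the causal chromosome, containing
#'   the causal position.
#' @param n_block_sites additional shared-haplotype sites planted inside the
#'   block (homozygous in all affected individuals of every family).
#' @param background_af `c(shape1, shape2)` of the Beta spectrum, scaled to
#'   0-0.5.
#' @param fail_fraction fraction of background records planted to fail each
#'   quality criterion.
#' @param roi_miss_fraction fraction of coding background variants left
#'   outside the region of interest.
#' @param n_de_novo de novo variants planted per family proband (default 0).
#' @param dp_mu,dp_size negative-binomial read-depth model.
#' @param gq_hi probability a genotype quality is the 99 cap.
#' @param seed integer; fully determines the output.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_families = 2L,
    family_structures = list(list(n_affected = 4L, n_unaffected = 0L),
                             list(n_affected = 2L, n_unaffected = 1L)),
    n_background_variants = 4000L,
    causal_locus = list(chrom = "chr12", pos = 22063090L, ref = "C",
                        alt = "T", gene = "ABCC9", boundary_offset = -1L),
    shared_block = c(start = 18326590, end = 22176010),
    n_block_sites = 40L,
    background_af = c(shape1 = 0.25, shape2 = 2.5),
    fail_fraction = 0.02,
    roi_miss_fraction = 0.15,
    n_de_novo = 0L,
    dp_mu = 35, dp_size = 15, gq_hi = 0.9,
    seed = 1L) {
  stopifnot(n_families == length(family_structures),
            shared_block["start"] <= causal_locus$pos,
            causal_locus$pos <= shared_block["end"],
            fail_fraction >= 0, fail_fraction < 1)
  for (fs in family_structures) {
    if ((fs$n_affected %||% 0) > 0 && !is.null(fs$n_parents) && fs$n_parents != 2)
      stop("affected children require two genotyped parents")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

gt_string <- function(dose) c("0/0", "0/1", "1/1")[dose + 1L]

#' Simulate a multi-family cohort with a planted causal variant
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cohort` with `variants`, `genotypes` (long form),
#'   `pedigree`, `af` (population-frequency annotations), `roi` (intervals),
#'   and `truth` (planted causal variant, block bounds and sites, de novo
#'   ids, seed).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(spec$seed, {
    chroms <- paste0("chr", 1:22)
    n_bg <- spec$n_background_variants
    cl <- spec$causal_locus

    # -- sites ---------------------------------------------------------------
    bg_chrom <- sample(chroms, n_bg, replace = TRUE)
    bg_pos <- sample.int(1.3e8, n_bg)
    blk <- spec$shared_block
    blk_pos <- sort(sample(seq(blk["start"], blk["end"]), spec$n_block_sites))
    blk_pos <- setdiff(blk_pos, cl$pos)
    clash <- bg_chrom == cl$chrom & bg_pos %in% c(blk_pos, cl$pos)
    bg_chrom <- bg_chrom[!clash]; bg_pos <- bg_pos[!clash]
    n_bg <- length(bg_pos)

    bases <- c("A", "C", "G", "T")
    n_blk <- length(blk_pos)
    n_v <- n_bg + n_blk + 1L
    ref <- sample(bases, n_v, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    is_indel <- stats::runif(n_v) < 0.08
    alt[is_indel] <- paste0(ref[is_indel], sample(bases, sum(is_indel), TRUE))

    chrom <- c(bg_chrom, rep(cl$chrom, n_blk), cl$chrom)
    pos <- c(bg_pos, blk_pos, cl$pos)
    idx_blk <- n_bg + seq_len(n_blk)
    idx_causal <- n_v
    ref[idx_causal] <- cl$ref; alt[idx_causal] <- cl$alt
    is_indel[idx_causal] <- FALSE

    # drop accidental duplicate (chrom,pos) against planted sites
    dup <- duplicated(paste(chrom, pos))
    stopifnot(!dup[idx_causal])

    gene_bucket <- paste0("G", match(chrom, chroms), "_", pos %/% 2e6 + 1L)
    gene <- gene_bucket
    gene[idx_causal] <- cl$gene

    eff_pool <- c("nonsynonymous", "synonymous", "noncoding", "inframe",
                  "LoF", "splice_region")
    eff_p <- c(0.30, 0.30, 0.20, 0.07, 0.05, 0.08)
    effect <- sample(eff_pool, n_v, replace = TRUE, prob = eff_p)
    effect[idx_blk] <- sample(c("synonymous", "noncoding"), n_blk,
                              replace = TRUE)
    effect[idx_causal] <- "splice_region"
    boundary_offset <- ifelse(effect == "splice_region",
                              -sample(1:8, n_v, replace = TRUE),
                              ifelse(effect == "noncoding",
                                     NA_integer_,
                                     sample(4:200, n_v, replace = TRUE)))
    boundary_offset[idx_causal] <- cl$boundary_offset %||% -1L

    # true (simulation) allele frequencies
    p <- 0.5 * stats::rbeta(n_v, spec$background_af["shape1"],
                            spec$background_af["shape2"])
    p[idx_blk] <- stats::runif(n_blk, 0.05, 0.40)  # common haplotype tags
    p[idx_causal] <- 4e-4

    # site-level statistics; a fail_fraction of background sites trips one
    # PASS criterion
    class <- ifelse(is_indel, "indel", "snv")
    variants <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      id = variant_id(chrom, pos, ref, alt),
      gene = gene, effect = effect, boundary_offset = boundary_offset,
      class = class, sim_af = p,
      qd = stats::runif(n_v, 8, 30), mq = stats::runif(n_v, 50, 60),
      fs = stats::runif(n_v, 0, 8),
      haplotype_score = stats::runif(n_v, 0, 4),
      mq_rank_sum = stats::rnorm(n_v, 0, 1),
      read_pos_rank_sum = stats::rnorm(n_v, 0, 1),
      snp_cluster_count = sample(0:2, n_v, replace = TRUE, prob = c(.8, .15, .05)),
      qual = round(stats::runif(n_v, 500, 3000), 1),
      stringsAsFactors = FALSE
    )
    n_fail_site <- round(spec$fail_fraction * n_bg)
    if (n_fail_site > 0) {
      pick <- sample(seq_len(n_bg), n_fail_site)
      which_crit <- sample(c("qd", "mq", "fs", "rprs"), n_fail_site, TRUE)
      variants$qd[pick[which_crit == "qd"]] <- stats::runif(sum(which_crit == "qd"), 0.2, 1.9)
      variants$mq[pick[which_crit == "mq"]] <- stats::runif(sum(which_crit == "mq"), 20, 39)
      variants$fs[pick[which_crit == "fs"]] <- stats::runif(sum(which_crit == "fs"), 61, 120)
      variants$read_pos_rank_sum[pick[which_crit == "rprs"]] <-
        stats::runif(sum(which_crit == "rprs"), -15, -8.5)
    }

    # -- pedigree ------------------------------------------------------------
    ped <- list(); samples <- list()
    for (f in seq_len(spec$n_families)) {
      fs <- spec$family_structures[[f]]
      fid <- paste0("FAM", f)
      fa <- paste0(fid, "_FA"); mo <- paste0(fid, "_MO")
      kids_a <- if (fs$n_affected > 0) paste0(fid, "_A", seq_len(fs$n_affected)) else character()
      kids_u <- if (fs$n_unaffected > 0) paste0(fid, "_U", seq_len(fs$n_unaffected)) else character()
      ped[[f]] <- data.frame(
        fid = fid,
        iid = c(fa, mo, kids_a, kids_u),
        pat = c("0", "0", rep(fa, length(kids_a) + length(kids_u))),
        mat = c("0", "0", rep(mo, length(kids_a) + length(kids_u))),
        sex = c(1L, 2L, sample(1:2, length(kids_a) + length(kids_u), TRUE)),
        phenotype = c(1L, 1L, rep(2L, length(kids_a)), rep(1L, length(kids_u))),
        stringsAsFactors = FALSE
      )
      samples[[f]] <- list(fa = fa, mo = mo, affected = kids_a,
                           unaffected = kids_u)
    }
    pedigree <- do.call(rbind, ped)

    planted <- c(idx_blk, idx_causal)   # founder-haplotype sites
    de_novo_ids <- character()

    # -- genotypes -----------------------------------------------------------
    geno <- list()
    for (f in seq_len(spec$n_families)) {
      sm <- samples[[f]]
      draw <- function() stats::rbinom(n_v, 1L, p)
      fa1 <- draw(); fa2 <- draw(); mo1 <- draw(); mo2 <- draw()
      # founder haplotype: both parents carry exactly one shared alt allele
      fa1[planted] <- 1L; fa2[planted] <- 0L
      mo1[planted] <- 1L; mo2[planted] <- 0L
      doses <- list()
      doses[[sm$fa]] <- fa1 + fa2
      doses[[sm$mo]] <- mo1 + mo2
      transmit <- function(a1, a2) ifelse(stats::runif(n_v) < 0.5, a1, a2)
      for (kid in c(sm$affected, sm$unaffected)) {
        d <- transmit(fa1, fa2) + transmit(mo1, mo2)
        if (kid %in% sm$affected) {
          d[planted] <- 2L                       # homozygous shared haplotype
        } else {
          d[planted][d[planted] == 2L] <- 1L     # unaffected never hom causal
        }
        doses[[kid]] <- d
      }
      if (spec$n_de_novo > 0) {
        pb <- sm$affected[1]
        cand <- which(doses[[sm$fa]] == 0L & doses[[sm$mo]] == 0L &
                        doses[[pb]] == 0L & seq_len(n_v) <= n_bg)
        dn <- sample(cand, min(spec$n_de_novo, length(cand)))
        doses[[pb]][dn] <- 1L
        de_novo_ids <- c(de_novo_ids, variants$id[dn])
      }
      for (s in names(doses)) {
        d <- doses[[s]]
        dp <- stats::rnbinom(n_v, mu = spec$dp_mu, size = spec$dp_size)
        gq <- ifelse(stats::runif(n_v) < spec$gq_hi, 99L,
                     sample(30:98, n_v, replace = TRUE))
        gqx <- pmax(gq - sample(0:5, n_v, replace = TRUE), 0L)
        vf <- ifelse(d == 0L, stats::runif(n_v, 0, 0.02),
                     ifelse(d == 1L,
                            pmin(pmax(stats::rnorm(n_v, 0.5, 0.05), 0.25), 0.75),
                            stats::runif(n_v, 0.97, 1)))
        sb <- stats::runif(n_v, -60, -20)
        r8 <- stats::runif(n_v, 0, 6)
        geno[[length(geno) + 1L]] <- data.frame(
          id = variants$id, sample = s, gt = gt_string(d),
          dp = dp, gq = gq, gqx = gqx,
          vf = round(vf, 3), sb = round(sb, 2), r8 = round(r8, 2),
          stringsAsFactors = FALSE
        )
      }
    }
    genotypes <- do.call(rbind, geno)
    rownames(genotypes) <- NULL
    # the causal site is a clean, well-covered call in every sample: its
    # discoverability is part of the planted truth, not left to sampling noise
    at_causal <- genotypes$id == variants$id[idx_causal]
    genotypes$dp[at_causal] <- pmax(genotypes$dp[at_causal], 30L)
    genotypes$gq[at_causal] <- 99L
    genotypes$gqx[at_causal] <- 99L

    # plant per-criterion genotype-filter failures on proband calls of
    # background variants (the causal and block sites always pass)
    probands <- vapply(samples, function(s) s$affected[1], character(1))
    n_fail <- round(spec$fail_fraction * n_bg)
    if (n_fail > 0) {
      for (pb in probands) {
        rows <- which(genotypes$sample == pb &
                        genotypes$id %in% variants$id[seq_len(n_bg)])
        pick <- sample(rows, n_fail)
        crit <- sample(c("gqx", "vf", "gq", "sb", "dp", "r8"), n_fail, TRUE)
        genotypes$gqx[pick[crit == "gqx"]] <- round(stats::runif(sum(crit == "gqx"), 0, 9.5), 1)
        genotypes$vf[pick[crit == "vf"]] <- round(stats::runif(sum(crit == "vf"), 0.05, 0.19), 3)
        genotypes$gq[pick[crit == "gq"]] <- sample(5:29, sum(crit == "gq"), TRUE)
        genotypes$sb[pick[crit == "sb"]] <- round(stats::runif(sum(crit == "sb"), -9, 0), 2)
        genotypes$dp[pick[crit == "dp"]] <- sample(5:19, sum(crit == "dp"), TRUE)
        genotypes$r8[pick[crit == "r8"]] <- round(stats::runif(sum(crit == "r8"), 8.5, 20), 2)
      }
    }

    # -- population-frequency annotations ------------------------------------
    sources <- c("exac", "g1000", "dbsnp")
    annotated <- stats::runif(n_v) < 0.85
    annotated[idx_causal] <- FALSE          # handled explicitly below
    af_rows <- lapply(which(annotated), function(i) {
      src <- sample(sources, sample(1:3, 1))
      af <- pmin(pmax(p[i] * exp(stats::rnorm(length(src), 0, 0.15)), 0), 1)
      data.frame(id = variants$id[i], source = src, af = af,
                 stringsAsFactors = FALSE)
    })
    af <- do.call(rbind, af_rows)
    af <- rbind(af, data.frame(
      id = variants$id[idx_causal],
      source = c("gnomad_fin", "gnomad_nfe"),
      af = c(allele_frequency(18, 24850), allele_frequency(5, 128232))
    ))
    rownames(af) <- NULL

    # -- region of interest ---------------------------------------------------
    coding <- variants$effect != "noncoding" & !is.na(variants$boundary_offset)
    in_roi <- coding & stats::runif(n_v) >= spec$roi_miss_fraction
    in_roi[idx_causal] <- TRUE
    off <- ifelse(is.na(variants$boundary_offset), 0L, variants$boundary_offset)
    # intronic variants sit `|offset|` bp beyond the interval end, so the
    # splice-window and ROI-flank semantics are both exercised
    roi <- data.frame(
      chrom = variants$chrom[in_roi],
      start = variants$pos[in_roi] - sample(20:80, sum(in_roi), TRUE),
      end = ifelse(off[in_roi] < 0,
                   variants$pos[in_roi] + off[in_roi],
                   variants$pos[in_roi] + sample(10:40, sum(in_roi), TRUE))
    )

    truth <- list(
      causal = variants[idx_causal, c("id", "chrom", "pos", "ref", "alt", "gene")],
      block = list(chrom = cl$chrom, start = unname(blk["start"]),
                   end = unname(blk["end"]),
                   site_ids = variants$id[c(idx_blk, idx_causal)]),
      de_novo = de_novo_ids,
      n_variants = n_v,
      seed = spec$seed
    )

    structure(list(variants = variants, genotypes = genotypes,
                   pedigree = pedigree, af = af, roi = roi, truth = truth,
                   spec = spec),
              class = "cohort")
  })
}

#' Simulate a genotype pair under a known relationship
#'
#' Sites are drawn under Hardy-Weinberg equilibrium at frequencies sampled
#' uniformly from `af_range`; the second sample is derived from the first by
#' the relationship's transmission rules (for `full_sibs` both samples are
#' children of the same simulated parents).
#'
#' @param n_snps number of independent biallelic sites.
#' @param relationship one of `"monozygotic"`, `"parent_offspring"`,
#'   `"full_sibs"`, `"unrelated"`.
#' @param af_range allele-frequency range (common SNPs by default, as used
#'   for relatedness estimation).
#' @param seed integer.
#' @return list `g1`, `g2` (dosage vectors), `af`, `relationship`.
#' @export
simulate_genotype_panel <- function(n_snps, relationship = c("monozygotic",
                                      "parent_offspring", "full_sibs",
                                      "unrelated"),
                                    af_range = c(0.1, 0.5), seed = 1L) {
  stopifnot(n_snps >= 1)
  relationship <- match.arg(relationship)
  local_seed(seed, {
    p <- stats::runif(n_snps, af_range[1], af_range[2])
    hw <- function() stats::rbinom(n_snps, 1L, p) + stats::rbinom(n_snps, 1L, p)
    pick <- function(dose) ifelse(dose == 1L, stats::rbinom(n_snps, 1L, 0.5),
                                  dose / 2L)
    g1 <- g2 <- NULL
    if (relationship == "monozygotic") {
      g1 <- hw(); g2 <- g1
    } else if (relationship == "parent_offspring") {
      g1 <- hw()
      g2 <- pick(g1) + stats::rbinom(n_snps, 1L, p)
    } else if (relationship == "full_sibs") {
      pa <- hw(); ma <- hw()
      g1 <- pick(pa) + pick(ma)
      g2 <- pick(pa) + pick(ma)
    } else {
      g1 <- hw(); g2 <- hw()
    }
    list(g1 = as.integer(g1), g2 = as.integer(g2), af = p,
         relationship = relationship)
  })
}
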