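# Per-family (trio) candidate-variant prioritization.
#
# Variant sets are plain data.frames, one row per decomposed biallelic site:
#   chrom, pos, ref, alt, id, gene, effect, boundary_offset, class, ...
# Genotype calls live in a long data.frame keyed by (id, sample):
#   id, sample, gt, dp, gq, gqx, vf, sb, r8
# Population frequencies: data.frame(id, source, af).
#
# boundary_offset convention: signed distance (bp) to the nearest intron-exon
# boundary, negative = intronic, positive = exonic, the boundary-adjacent base
# being 1 in either direction. NA = far from any boundary / not annotated.

#' Filter configuration for variant prioritization
#'
#' Thresholds default to the panel-analysis criteria: a call is discarded when
#' GQX < 10, variant read fraction < 0.20, GQ < 30, R8 > 8 (indels only),
#' SB > -10, or DP < 20 — all strict inequalities, applied exactly as stated.
#'
#' @param max_maf population-frequency ceiling (default 0.01).
#' @param roi_flank bp added to each side of every region-of-interest
#'   interval (panel default 10; use 100 for whole-genome runs).
#' @param splice_intronic,splice_exonic splice-window half-widths in bp
#'   (defaults 8 intronic / 3 exonic).
#' @param retained_effects effect categories kept by the coding-effect stage;
#'   splice-region status is always decided by the splice-window predicate on
#'   `boundary_offset`.
#' @param quality named list of thresholds `gqx`, `vf`, `gq`, `r8`, `sb`, `dp`.
#' @param denovo_dp_floor minimum parental depth for a de novo call to be
#'   evaluable.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(max_maf = 0.01, roi_flank = 10L,
                          splice_intronic = 8L, splice_exonic = 3L,
                          retained_effects = c("LoF", "nonsynonymous", "inframe"),
                          quality = list(gqx = 10, vf = 0.20, gq = 30,
                                         r8 = 8, sb = -10, dp = 20),
                          denovo_dp_floor = 10L) {
  stopifnot(max_maf >= 0, max_maf <= 1, roi_flank >= 0,
            splice_intronic >= 0, splice_exonic >= 0)
  structure(list(max_maf = max_maf, roi_flank = roi_flank,
                 splice_intronic = splice_intronic,
                 splice_exonic = splice_exonic,
                 retained_effects = retained_effects,
                 quality = quality, denovo_dp_floor = denovo_dp_floor),
            class = "filter_config")
}

# which quality criteria trip for a set of calls; returns a logical matrix
# (rows = calls, cols = criteria). NA field => criterion unevaluable (NA).
quality_trips <- function(calls, q) {
  is_indel <- calls$class != "snv"
  cbind(
    LowGQX        = calls$gqx < q$gqx,
    LowVariantFreq = calls$vf < q$vf,
    LowGQ         = calls$gq < q$gq,
    R8            = ifelse(is_indel, calls$r8 > q$r8, FALSE),
    SB            = calls$sb > q$sb,
    LowDP         = calls$dp < q$dp
  )
}

#' Apply per-call quality filters
#'
#' A record is removed iff at least one enabled criterion trips for the
#' proband's call (strict inequalities, e.g. DP = 20 survives `LowDP < 20`).
#' Calls with a missing required field are unevaluable and removed, counted
#' separately.
#'
#' @param variants variant data.frame (see file header).
#' @param genotypes long genotype data.frame.
#' @param proband sample id whose call is evaluated.
#' @param config a [filter_config()].
#' @return list: `variants` (survivors, input order preserved), `removed`
#'   (ids), `counts` (named per-criterion trip counts among removed records,
#'   plus `unevaluable` and `removed` totals).
#' @export
apply_quality_filters <- function(variants, genotypes, proband, config = filter_config()) {
  calls <- genotypes[genotypes$sample == proband, , drop = FALSE]
  calls <- calls[match(variants$id, calls$id), , drop = FALSE]
  calls$class <- variants$class %||% rep("snv", nrow(variants))
  trips <- quality_trips(calls, config$quality)
  uneval <- apply(trips, 1L, function(r) anyNA(r))
  tripped <- apply(trips, 1L, function(r) isTRUE(any(r)))
  drop <- uneval | tripped
  counts <- colSums(trips[drop, , drop = FALSE], na.rm = TRUE)
  counts <- c(counts, unevaluable = sum(uneval), removed = sum(drop))
  list(variants = variants[!drop, , drop = FALSE],
       removed = variants$id[drop],
       counts = counts)
}

#' Merge intervals and expand by a flank
#' @keywords internal
merge_intervals <- function(intervals, flank = 0L) {
  stopifnot(all(intervals$end >= intervals$start))
  out <- do.call(rbind, lapply(split(intervals, intervals$chrom), function(iv) {
    iv <- iv[order(iv$start), , drop = FALSE]
    s <- iv$start - flank; e <- iv$end + flank
    keep_s <- s[1]; res_s <- c(); res_e <- c(); cur_e <- e[1]
    if (length(s) > 1) for (k in 2:length(s)) {
      if (s[k] <= cur_e + 1) cur_e <- max(cur_e, e[k])
      else { res_s <- c(res_s, keep_s); res_e <- c(res_e, cur_e)
             keep_s <- s[k]; cur_e <- e[k] }
    }
    data.frame(chrom = iv$chrom[1], start = c(res_s, keep_s),
               end = c(res_e, cur_e))
  }))
  rownames(out) <- NULL
  out
}

#' Restrict records to a region of interest
#'
#' A record is retained iff its position lies inside any interval after each
#' interval is expanded by `flank_bp` on both sides.
#'
#' @param variants variant data.frame.
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param flank_bp flank added to both sides of every interval.
#' @return surviving variants, order preserved.
#' @export
restrict_to_roi <- function(variants, intervals, flank_bp = 10L) {
  if (nrow(intervals) == 0) return(variants[0, , drop = FALSE])
  merged <- merge_intervals(intervals, flank = flank_bp)
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    iv <- merged[merged$chrom == variants$chrom[i], , drop = FALSE]
    any(variants$pos[i] >= iv$start & variants$pos[i] <= iv$end)
  }, logical(1))
  variants[keep, , drop = FALSE]
}

#' Filter by population allele frequency
#'
#' Removed iff any source reports a frequency above `max_maf`; a variant
#' absent from every source is treated as unobserved (frequency 0) and
#' retained — the rare-variant discovery convention.
#'
#' @param variants variant data.frame.
#' @param af data.frame `id`, `source`, `af`.
#' @param max_maf ceiling (default 0.01).
#' @return surviving variants.
#' @export
filter_by_population_frequency <- function(variants, af, max_maf = 0.01) {
  if (nrow(af) > 0 && any(af$af < 0 | af$af > 1)) stop("AF outside [0,1]")
  max_by_id <- tapply(af$af, af$id, max)
  observed <- max_by_id[variants$id]
  keep <- is.na(observed) | observed <= max_maf
  variants[keep, , drop = FALSE]
}

#' Splice-window membership of a boundary offset
#'
#' TRUE iff the position lies within 8 intronic bp or 3 exonic bp of the
#' nearest intron-exon boundary (window widths configurable). Offsets are
#' signed: negative = intronic, positive = exonic, boundary-adjacent base = 1.
#'
#' @param boundary_offset signed integer offset(s); NA returns FALSE.
#' @param intronic,exonic window half-widths.
#' @return logical vector.
#' @examples
#' splice_window_hit(-1) # first intronic base (e.g. a +1 donor variant): TRUE
#' splice_window_hit(-9) # FALSE
#' @export
splice_window_hit <- function(boundary_offset, intronic = 8L, exonic = 3L) {
  ifelse(is.na(boundary_offset), FALSE,
         ifelse(boundary_offset < 0, -boundary_offset <= intronic,
                boundary_offset <= exonic & boundary_offset > 0))
}

#' Classify the coding effect of a variant on a transcript
#'
#' Categories: `LoF` (frameshift, stopgain, startloss, stoploss),
#' `nonsynonymous`, `synonymous`, `inframe`, `splice_region`, `noncoding`.
#' Splice-region status is decided first, by [splice_window_hit()] on the
#' intronic side; coding substitutions are classified by translating the
#' affected codon of the supplied CDS.
#'
#' @param chrom,pos,ref,alt the decomposed variant.
#' @param tx a [transcript_model()].
#' @param cds CDS nucleotide sequence of `tx` (character).
#' @param intronic,exonic splice-window widths.
#' @return one category string.
#' @export
classify_effect <- function(chrom, pos, ref, alt, tx, cds,
                            intronic = 8L, exonic = 3L) {
  stopifnot(inherits(tx, "transcript_model"), nchar(cds) == tx$cds_length)
  ex <- tx$exons
  inside <- which(pos >= ex$g_start & pos <= ex$g_end)
  if (length(inside) == 0) {
    # intronic: distance to nearest exon boundary
    d <- min(abs(c(pos - ex$g_end, ex$g_start - pos))[
      c(pos - ex$g_end, ex$g_start - pos) > 0])
    return(if (splice_window_hit(-d, intronic, exonic)) "splice_region" else "noncoding")
  }
  i <- inside[1]
  cpos <- if (tx$strand == "+") ex$c_start[i] + (pos - ex$g_start[i])
          else ex$c_start[i] + (ex$g_end[i] - pos)
  if (nchar(ref) != nchar(alt)) {
    indel_nt <- abs(nchar(ref) - nchar(alt))
    return(if (indel_nt %% 3 == 0) "inframe" else "LoF")
  }
  # SNV: translate reference and alternate codon
  codon_i <- (cpos - 1) %/% 3 + 1
  codon <- substr(cds, 3 * codon_i - 2, 3 * codon_i)
  within <- (cpos - 1) %% 3 + 1
  base <- if (tx$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  alt_codon <- codon
  substr(alt_codon, within, within) <- base
  aa_ref <- codon_aa(codon); aa_alt <- codon_aa(alt_codon)
  if (identical(aa_ref, aa_alt)) return("synonymous")
  if (codon_i == 1 && aa_ref == "M") return("LoF")           # startloss
  if (aa_alt == "*") return("LoF")                           # stopgain
  if (aa_ref == "*") return("LoF")                           # stoploss
  "nonsynonymous"
}

#' Recessive-homozygous trio call
#'
#' Candidate iff the proband is homozygous for the alternate allele and both
#' parents are heterozygous.
#'
#' @param proband,father,mother genotype strings at one site.
#' @return `"candidate"`, `"not_candidate"` or `"unevaluable"` (missing
#'   member).
#' @export
call_recessive_homozygous <- function(proband, father, mother) {
  d <- gt_dose(c(proband, father, mother))
  if (anyNA(d)) return("unevaluable")
  if (d[1] == 2L && d[2] == 1L && d[3] == 1L) "candidate" else "not_candidate"
}

#' De novo trio call
#'
#' Candidate iff the proband carries an alternate allele absent from both
#' parents; parental calls below the depth floor make the site unevaluable.
#'
#' @param proband,father,mother genotype strings.
#' @param father_dp,mother_dp parental read depths.
#' @param dp_floor minimum parental depth.
#' @return `"candidate"`, `"not_candidate"` or `"unevaluable"`.
#' @export
call_de_novo <- function(proband, father, mother,
                         father_dp = Inf, mother_dp = Inf, dp_floor = 10) {
  d <- gt_dose(c(proband, father, mother))
  if (anyNA(d)) return("unevaluable")
  if (father_dp < dp_floor || mother_dp < dp_floor) return("unevaluable")
  if (d[1] >= 1L && d[2] == 0L && d[3] == 0L) "candidate" else "not_candidate"
}

#' Compound-heterozygous candidate genes in a trio
#'
#' Variants are phased by transmission: a proband het with the alternate
#' allele in exactly one parent is assigned that parental origin; sites where
#' both parents are het are ambiguous and excluded from pairing. A gene is a
#' candidate iff the proband carries at least one qualifying het from each
#' parent (trans configuration).
#'
#' @param variants qualifying variant data.frame (columns `id`, `gene`).
#' @param genotypes long genotype data.frame.
#' @param proband,father,mother sample ids.
#' @return list: `genes` (candidate gene ids), `excluded` (ambiguous variant
#'   ids).
#' @export
call_compound_het <- function(variants, genotypes, proband, father, mother) {
  g <- function(s) gt_dose(genotypes$gt[genotypes$sample == s][
    match(variants$id, genotypes$id[genotypes$sample == s])])
  dp <- g(proband); df <- g(father); dm <- g(mother)
  het <- !is.na(dp) & dp == 1L
  from_f <- het & !is.na(df) & !is.na(dm) & df >= 1L & dm == 0L
  from_m <- het & !is.na(df) & !is.na(dm) & dm >= 1L & df == 0L
  ambiguous <- het & !is.na(df) & !is.na(dm) & df >= 1L & dm >= 1L
  tab_f <- unique(variants$gene[from_f])
  tab_m <- unique(variants$gene[from_m])
  list(genes = sort(intersect(tab_f, tab_m)),
       excluded = variants$id[ambiguous])
}

#' Run the full per-family prioritization pipeline
#'
#' Applies, in order: quality filters, region-of-interest restriction,
#' coding-effect / splice-window classification, population-frequency
#' ceiling, then the three trio inheritance models on the survivors. With
#' several affected siblings, candidates are intersected across them
#' (`require_all_affected = TRUE`) or taken from the proband alone.
#'
#' @param cohort list with `variants`, `genotypes`, `pedigree`, `af`, `roi`
#'   (as produced by [simulate_cohort()] or assembled from files).
#' @param family family id in the pedigree.
#' @param config a [filter_config()].
#' @param require_all_affected intersect candidates across affected siblings.
#' @return list with `stage_counts` (records surviving each stage, in order),
#'   `candidates` (per inheritance model), `quality_counts`, `compound_het`.
#' @export
run_family_analysis <- function(cohort, family, config = filter_config(),
                                require_all_affected = TRUE) {
  ped <- cohort$pedigree[cohort$pedigree$fid == family, , drop = FALSE]
  if (nrow(ped) == 0) stop("unknown family id")
  affected <- ped$iid[ped$phenotype == 2L]
  if (length(affected) == 0) stop("family has no affected individual")
  missing_s <- setdiff(ped$iid, unique(cohort$genotypes$sample))
  if (length(missing_s) > 0)
    stop("pedigree/VCF sample mismatch: ", paste(missing_s, collapse = ", "))
  probands <- if (require_all_affected) affected else affected[1]

  per_proband <- lapply(probands, function(pb) {
    father <- ped$pat[ped$iid == pb]; mother <- ped$mat[ped$iid == pb]
    if (father == "0" || mother == "0")
      stop("affected individual without two genotyped parents")
    v0 <- cohort$variants
    qf <- apply_quality_filters(v0, cohort$genotypes, pb, config)
    v1 <- qf$variants
    v2 <- restrict_to_roi(v1, cohort$roi, config$roi_flank)
    eff_keep <- v2$effect %in% config$retained_effects |
      splice_window_hit(v2$boundary_offset,
                        config$splice_intronic, config$splice_exonic)
    v3 <- v2[eff_keep, , drop = FALSE]
    v4 <- filter_by_population_frequency(v3, cohort$af, config$max_maf)

    gt_of <- function(s) cohort$genotypes$gt[cohort$genotypes$sample == s][
      match(v4$id, cohort$genotypes$id[cohort$genotypes$sample == s])]
    dp_of <- function(s) cohort$genotypes$dp[cohort$genotypes$sample == s][
      match(v4$id, cohort$genotypes$id[cohort$genotypes$sample == s])]
    gp <- gt_of(pb); gf <- gt_of(father); gm <- gt_of(mother)
    dpf <- dp_of(father); dpm <- dp_of(mother)
    rec <- v4$id[vapply(seq_along(gp), function(i)
      call_recessive_homozygous(gp[i], gf[i], gm[i]), character(1)) == "candidate"]
    dnv <- v4$id[vapply(seq_along(gp), function(i)
      call_de_novo(gp[i], gf[i], gm[i], dpf[i], dpm[i],
                   config$denovo_dp_floor), character(1)) == "candidate"]
    ch <- call_compound_het(v4, cohort$genotypes, pb, father, mother)
    list(stage_counts = c(input = nrow(v0), quality = nrow(v1),
                          roi = nrow(v2), effect = nrow(v3), maf = nrow(v4)),
         quality_counts = qf$counts,
         recessive = rec, de_novo = dnv, compound_het = ch)
  })

  inter <- function(field) Reduce(intersect, lapply(per_proband, `[[`, field))
  list(
    family = family,
    probands = probands,
    stage_counts = per_proband[[1]]$stage_counts,
    quality_counts = per_proband[[1]]$quality_counts,
    candidates = list(
      recessive = inter("recessive"),
      de_novo = inter("de_novo"),
      compound_het = Reduce(intersect,
                            lapply(per_proband, function(x) x$compound_het$genes))
    ),
    compound_het = per_proband[[1]]$compound_het
  )
}
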