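# Plain-text serialization of the cohort: VCF 4.2 (FORMAT GT:DP:GQ:GQX:VF:SB:R8,
# per-site INFO statistics), 6-column PED, BED intervals, JSON truth ledger.
# Output is deterministic: identical cohort => identical bytes.

#' Write a cohort's variants and genotypes as VCF 4.2
#'
#' @param cohort a cohort list (see [simulate_cohort()]).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_cohort_vcf <- function(cohort, file) {
  v <- cohort$variants
  ord <- order(match(v$chrom, paste0("chr", 1:22)), v$pos)
  v <- v[ord, , drop = FALSE]
  samples <- unique(cohort$genotypes$sample)
  gt_by_sample <- lapply(samples, function(s) {
    g <- cohort$genotypes[cohort$genotypes$sample == s, , drop = FALSE]
    g[match(v$id, g$id), , drop = FALSE]
  })
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sur2lof-simulate_cohort",
    paste0("##contig=<ID=chr", 1:22, ">"),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias (phred)\">",
    "##INFO=<ID=HS,Number=1,Type=Float,Description=\"Haplotype score\">",
    "##INFO=<ID=MQRS,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=RPRS,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=SNPC,Number=1,Type=Integer,Description=\"SNVs within 35 bp\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect category\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=GQX,Number=1,Type=Integer,Description=\"Min of GQ and site QUAL\">",
    "##FORMAT=<ID=VF,Number=1,Type=Float,Description=\"Variant read fraction\">",
    "##FORMAT=<ID=SB,Number=1,Type=Float,Description=\"Strand bias score\">",
    "##FORMAT=<ID=R8,Number=1,Type=Float,Description=\"Homopolymer indel metric\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info <- sprintf("QD=%.2f;MQ=%.2f;FS=%.2f;HS=%.2f;MQRS=%.2f;RPRS=%.2f;SNPC=%d;GENE=%s;EFF=%s",
                  v$qd, v$mq, v$fs, v$haplotype_score, v$mq_rank_sum,
                  v$read_pos_rank_sum, v$snp_cluster_count, v$gene, v$effect)
  fmt_cols <- lapply(gt_by_sample, function(g)
    sprintf("%s:%d:%d:%d:%.3f:%.2f:%.2f",
            g$gt, as.integer(g$dp), as.integer(g$gq), as.integer(g$gqx),
            g$vf, g$sb, g$r8))
  body <- do.call(paste, c(
    list(v$chrom, v$pos, v$id, v$ref, v$alt, sprintf("%.1f", v$qual),
         ".", info, "GT:DP:GQ:GQX:VF:SB:R8"),
    fmt_cols, sep = "\t"))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Write a PLINK 6-column PED pedigree
#'
#' Columns: family id, individual id, paternal id, maternal id, sex
#' (1 male / 2 female), phenotype (1 unaffected / 2 affected).
#'
#' @param pedigree pedigree data.frame.
#' @param file output path.
#' @export
write_ped <- function(pedigree, file) {
  utils::write.table(
    pedigree[, c("fid", "iid", "pat", "mat", "sex", "phenotype")],
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a PLINK 6-column PED pedigree
#' @param file path.
#' @return pedigree data.frame.
#' @export
read_ped <- function(file) {
  ped <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "phenotype"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "integer"))
  ped
}

#' Write intervals as BED (0-based half-open)
#'
#' Internal interval arithmetic is 1-based inclusive; on disk the standard
#' BED convention (start - 1, end) is used.
#'
#' @param intervals data.frame `chrom`, `start`, `end` (1-based inclusive).
#' @param file output path.
#' @export
write_bed <- function(intervals, file) {
  utils::write.table(
    data.frame(intervals$chrom, intervals$start - 1L, intervals$end),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED file into 1-based inclusive intervals
#' @param file path.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(file) {
  b <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(b) <- c("chrom", "start", "end")
  b$start <- b$start + 1L
  b
}

#' Write the truth ledger of a simulation as JSON
#' @param truth truth list (from a simulator).
#' @param file output path.
#' @export
write_truth <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
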