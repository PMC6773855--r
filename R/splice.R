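# Exon-skipping consequence prediction in HGVS c./r./p. coordinates.
#
# A transcript is modelled as its ordered coding exons; all arithmetic is done
# in cDNA (c.) space, where position 1 is the A of the initiator ATG and the
# residue index of cDNA position n is ceiling(n / 3). Genomic coordinates are
# mapped into c. space first, so strand never enters the arithmetic.

#' Construct a coding-transcript model from genomic exon intervals
#'
#' @param exons data.frame with columns `start`, `end` (1-based inclusive
#'   genomic coordinates of the coding part of each exon). Exons must not
#'   overlap.
#' @param strand `"+"` or `"-"`. Exons are placed in transcription order
#'   (increasing genomic position on `"+"`, decreasing on `"-"`) before cDNA
#'   coordinates are assigned.
#' @param gene,chrom labels carried through to reports.
#' @return object of class `transcript_model`: a list with `$exons` (one row
#'   per coding exon in transcription order, genomic `g_start`/`g_end` and
#'   cDNA `c_start`/`c_end`) and `$cds_length`.
#' @export
transcript_model <- function(exons, strand = "+", gene = "GENE", chrom = "chr") {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            strand %in% c("+", "-"))
  if (any(exons$end < exons$start)) stop("malformed exon (end < start)")
  ord <- order(exons$start)
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons")
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  w <- exons$end - exons$start + 1L
  c_end <- cumsum(w)
  c_start <- c_end - w + 1L
  tx <- list(
    gene = gene, chrom = chrom, strand = strand,
    exons = data.frame(
      exon = seq_along(w),
      g_start = exons$start, g_end = exons$end,
      c_start = c_start, c_end = c_end, width = w
    ),
    cds_length = sum(w)
  )
  class(tx) <- "transcript_model"
  tx
}

#' Build a synthetic transcript from exon widths
#'
#' Convenience constructor for simulation and testing: places exons of the
#' given widths on a synthetic chromosome separated by fixed-size introns.
#'
#' @param widths integer vector of coding-exon widths (transcription order).
#' @param intron_bp intron size between consecutive exons.
#' @param strand,gene,chrom,offset passed through / genomic anchor.
#' @return a [transcript_model()].
#' @export
synthetic_transcript <- function(widths, intron_bp = 500L, strand = "+",
                                 gene = "GENE", chrom = "chrS", offset = 1000L) {
  stopifnot(all(widths >= 1))
  starts <- offset + cumsum(c(0L, utils::head(widths, -1) + intron_bp))
  ends <- starts + widths - 1L
  ex <- data.frame(start = starts, end = ends)
  if (strand == "-") {
    # mirror so that transcription order (given by `widths`) is preserved
    span <- max(ends) + offset
    ex <- data.frame(start = span - ends, end = span - starts)
  }
  transcript_model(ex, strand = strand, gene = gene, chrom = chrom)
}

#' Locate a genomic variant relative to a splice-donor site
#'
#' Finds the exon whose donor (5' end of the downstream intron) the variant
#' hits, and returns the HGVS c. label `c.<last exonic base>+<offset>`.
#'
#' @param tx a [transcript_model()].
#' @param pos genomic position of the variant.
#' @param donor_window how many intronic bases downstream of an exon count as
#'   the donor region (default 8, matching the splice-window filter).
#' @return list with `c_notation`, `exon` (index in transcription order) and
#'   intronic `offset` (+1 = first intronic base).
#' @export
locate_donor_variant <- function(tx, pos, donor_window = 8L) {
  stopifnot(inherits(tx, "transcript_model"))
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2) stop("transcript has no donor sites")
  for (i in seq_len(n - 1L)) {        # last exon has no donor
    off <- if (tx$strand == "+") pos - ex$g_end[i] else ex$g_start[i] - pos
    if (off >= 1 && off <= donor_window) {
      return(list(
        c_notation = sprintf("c.%d+%d", ex$c_end[i], off),
        exon = ex$exon[i], offset = off
      ))
    }
  }
  stop("variant outside donor window of every internal exon")
}

#' Transcript- and protein-level consequence of skipping one exon
#'
#' Removing an internal coding exon deletes its cDNA interval
#' (`r.<c_start>_<c_end>del`). If the deleted length is a multiple of 3 the
#' transcript stays in frame; when the exon boundaries are codon-aligned the
#' protein loses exactly `deleted_nt / 3` residues, spanning residues
#' `ceiling(c_start/3)` to `c_end/3`. An in-frame but codon-straddling skip
#' additionally creates one novel junction residue, annotated separately.
#'
#' @param tx a [transcript_model()].
#' @param exon index (transcription order) of the exon to skip; must be
#'   internal.
#' @param cds optional CDS nucleotide sequence (character); when supplied,
#'   deleted boundary residues are named with three-letter codes in `hgvs_p`.
#' @return object of class `skip_consequence` with fields `r_deletion`,
#'   `deleted_nt`, `in_frame`, `codon_aligned`, `p_deletion`, `deleted_aa`,
#'   `junction_substitution`, `hgvs_r`, `hgvs_p`.
#' @examples
#' tx <- synthetic_transcript(c(300, 864, 156, 300))
#' exon_skip_consequence(tx, 3) # skips c.1165-1320: in-frame, 52 residues
#' @export
exon_skip_consequence <- function(tx, exon, cds = NULL) {
  stopifnot(inherits(tx, "transcript_model"))
  ex <- tx$exons
  if (!exon %in% ex$exon) stop("no such exon")
  if (exon == 1L) stop("start_lost: exon contains the initiator codon")
  if (exon == nrow(ex)) stop("terminal exon has no donor; skip undefined")
  row <- ex[ex$exon == exon, ]
  c1 <- row$c_start; c2 <- row$c_end
  nt <- c2 - c1 + 1L
  in_frame <- nt %% 3L == 0L
  aligned <- (c1 %% 3L == 1L) && (c2 %% 3L == 0L)
  first_res <- ceiling(c1 / 3)
  last_res <- ceiling(c2 / 3)
  out <- list(
    exon = exon,
    r_deletion = c(first = c1, last = c2),
    deleted_nt = nt,
    in_frame = in_frame,
    codon_aligned = in_frame && aligned,
    hgvs_r = sprintf("r.%d_%ddel", c1, c2)
  )
  if (!in_frame) {
    out$p_deletion <- NULL
    out$deleted_aa <- NA_integer_
    out$junction_substitution <- FALSE
    out$frameshift <- sprintf("p.%dfs", first_res)
    out$hgvs_p <- out$frameshift
  } else {
    out$p_deletion <- c(first = first_res, last = last_res)
    out$deleted_aa <- nt %/% 3L
    out$junction_substitution <- !aligned
    out$frameshift <- NULL
    if (!is.null(cds) && aligned) {
      aa1 <- aa3(codon_aa(substr(cds, 3 * first_res - 2, 3 * first_res)))
      aa2 <- aa3(codon_aa(substr(cds, 3 * last_res - 2, 3 * last_res)))
      out$hgvs_p <- sprintf("p.%s%d_%s%ddel", aa1, first_res, aa2, last_res)
    } else {
      out$hgvs_p <- sprintf("p.%d_%ddel", first_res, last_res)
    }
  }
  class(out) <- "skip_consequence"
  out
}

#' @export
print.skip_consequence <- function(x, ...) {
  cat(sprintf("exon %d skip: %s (%d nt, %s)\n", x$exon, x$hgvs_r, x$deleted_nt,
              if (x$in_frame) "in-frame" else "frameshift"))
  cat(sprintf("  protein: %s%s\n", x$hgvs_p,
              if (isTRUE(x$junction_substitution)) " + junction substitution" else ""))
  invisible(x)
}

#' Translation oracle for exon-skip consequences
#'
#' Translates a CDS with and without a skipped interval (via
#' `Biostrings::translate`) and reports the aligned residue-level difference.
#' Independent of the coordinate arithmetic in [exon_skip_consequence()]:
#' for an in-frame skip, `n_removed - n_inserted` must equal the predicted
#' residue loss.
#'
#' @param cds CDS nucleotide sequence (character; length a multiple of 3,
#'   including the stop codon).
#' @param skip integer pair `c(first, last)` of deleted cDNA positions; use
#'   `NULL` to skip nothing.
#' @return list with `removed` (`c(from, to)` residue interval in the full
#'   protein, or `NULL`), `n_removed`, `n_inserted`, `stop_gained`.
#' @export
verify_by_translation <- function(cds, skip = NULL) {
  stopifnot(is.character(cds), nchar(cds) %% 3 == 0)
  full <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  if (is.null(skip)) {
    return(list(removed = NULL, n_removed = 0L, n_inserted = 0L,
                stop_gained = FALSE))
  }
  stopifnot(length(skip) == 2, skip[1] >= 1, skip[2] <= nchar(cds),
            skip[1] <= skip[2])
  kept <- paste0(substr(cds, 1, skip[1] - 1), substring(cds, skip[2] + 1))
  if (nchar(kept) %% 3 != 0)
    kept <- substr(kept, 1, 3 * (nchar(kept) %/% 3))
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(kept), no.init.codon = TRUE))
  stop_gained <- grepl("\\*", substr(prot, 1, nchar(prot) - 1))
  f <- strsplit(full, "")[[1]]
  s <- strsplit(prot, "")[[1]]
  # longest common prefix, then longest common suffix of the remainder
  p <- 0L
  while (p < length(f) && p < length(s) && f[p + 1L] == s[p + 1L]) p <- p + 1L
  q <- 0L
  while (q < length(f) - p && q < length(s) - p &&
         f[length(f) - q] == s[length(s) - q]) q <- q + 1L
  n_rm <- length(f) - p - q
  n_ins <- length(s) - p - q
  removed <- if (n_rm > 0) c(from = p + 1L, to = length(f) - q) else NULL
  list(removed = removed, n_removed = n_rm, n_inserted = n_ins,
       stop_gained = stop_gained)
}

# single-codon translation (DNA alphabet); used for residue naming and
# effect classification
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

aa3 <- function(aa) {
  tab <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val", `*` = "Ter")
  unname(tab[aa])
}
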