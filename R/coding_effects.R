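#' Classify the coding effect of interval variants
#'
#' Classifies every biallelic variant of a gene interval against the
#' interval's gene model: SNPs inside the CDS are translated through the
#' standard codon table for both alleles (`synonymous` /
#' `nonsynonymous`); InDels inside the CDS are `frameshift` when their
#' length is not a multiple of 3, otherwise `inframe-indel`; intronic
#' positions within 2 bp of a CDS boundary internal to the transcript are
#' `splice-site-adjacent`; other positions inside introns are `intronic`;
#' positions inside the transcript but outside the CDS span are `UTR`;
#' positions outside the transcript are `intergenic`. InDels overlapping a
#' CDS boundary are flagged `unclassified`. Classification is strand-aware:
#' reverse-complementing the gene and its variants yields identical calls.
#'
#' @param table an [interval_variant_table()] with a gene model and
#'   reference sequence.
#' @return data.frame with columns `pos`, `type`, `effect`, and for coding
#'   SNPs `ref_aa`, `alt_aa`.
#' @export
classify_coding_effect <- function(table) {
  stopifnot(inherits(table, "interval_variant_table"))
  gm <- table$gene_model
  if (is.null(gm) || is.null(table$ref_seq)) {
    stop("gene model and reference sequence are required", call. = FALSE)
  }
  ref <- strsplit(table$ref_seq, "")[[1]]
  cds <- gm$cds
  tx <- gm$transcript
  minus <- identical(gm$strand, "-")

  ## genomic positions of the spliced CDS, ordered 5'->3' on the coding strand
  cds_pos <- unlist(lapply(seq_len(nrow(cds)),
                           function(i) cds$start[i]:cds$end[i]))
  if (minus) cds_pos <- rev(cds_pos)
  if (length(cds_pos) %% 3 != 0) stop("CDS length not a multiple of 3")

  ## internal CDS boundaries: junction edges not at the transcript ends
  internal <- c()
  if (nrow(cds) > 1L) {
    internal <- c(cds$end[-nrow(cds)], cds$start[-1])
  }
  in_cds <- function(p) any(p >= cds$start & p <= cds$end)

  base_at <- function(p) ref[p]
  comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)
  code <- Biostrings::GENETIC_CODE

  out <- lapply(seq_len(nrow(table$variants)), function(i) {
    v <- table$variants[i, ]
    p <- v$pos
    row <- data.frame(pos = p, type = v$type, effect = NA_character_,
                      ref_aa = NA_character_, alt_aa = NA_character_,
                      stringsAsFactors = FALSE)
    if (v$type == "InDel") {
      len <- abs(nchar(v$alt) - nchar(v$ref))
      span <- p:(p + max(nchar(v$ref) - 1L, 0L))
      inside <- vapply(span, in_cds, TRUE)
      if (any(inside) && !all(inside)) {
        row$effect <- "unclassified"     # overlaps a CDS boundary
        return(row)
      }
      if (all(inside)) {
        row$effect <- if (len %% 3 != 0) "frameshift" else "inframe-indel"
        return(row)
      }
    }
    if (v$type == "SNP" && in_cds(p)) {
      ci <- match(p, cds_pos)
      codon_i <- (ci - 1L) %/% 3L
      cpos <- cds_pos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
      ref_codon <- base_at(cpos)
      alt_codon <- ref_codon
      slot <- match(p, cpos)
      alt_codon[slot] <- v$alt
      if (minus) {
        ref_codon <- comp(ref_codon)
        alt_codon <- comp(alt_codon)
      }
      ref_aa <- code[[paste(toupper(ref_codon), collapse = "")]]
      alt_aa <- code[[paste(toupper(alt_codon), collapse = "")]]
      row$effect <- if (identical(ref_aa, alt_aa)) "synonymous" else
        "nonsynonymous"
      row$ref_aa <- ref_aa; row$alt_aa <- alt_aa
      return(row)
    }
    ## non-coding positions
    if (length(internal) && min(abs(p - internal)) <= 2 && !in_cds(p)) {
      row$effect <- "splice-site-adjacent"
    } else if (p >= min(cds$start) && p <= max(cds$end) && !in_cds(p)) {
      row$effect <- "intronic"
    } else if (p >= tx[1] && p <= tx[2]) {
      row$effect <- "UTR"
    } else {
      row$effect <- "intergenic"
    }
    row
  })
  do.call(rbind, out)
}
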