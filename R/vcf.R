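#' Export a presence matrix as a symbolic-allele VCF
#'
#' Writes one VCF 4.2 record per site with symbolic alternate alleles
#' (`<INS>` or `<DEL>` per alternate allele), `SVTYPE`, `END` and per-alt
#' `SVLEN` INFO keys, and one sample column per accession. Founders are
#' inbred homozygotes, so genotypes are `0/0` (reference) or `k/k`
#' (alternate allele k). Coordinates are converted from the internal
#' 0-based half-open convention to the 1-based VCF convention.
#'
#' @param pm a [build_presence_matrix()] result.
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
export_sites_vcf <- function(pm, path) {
  stopifnot(inherits(pm, "presence_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pandiallel",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of reference span\">",
    "##INFO=<ID=SVLEN,Number=A,Type=Integer,Description=\"Length of each alternate allele\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pm$founders), collapse = "\t")
  ), con)
  ins_types <- c("insertion", "repeat_expansion", "tandem_expansion")
  for (i in seq_len(nrow(pm$geno))) {
    alt <- pm$alt[[i]]
    ins <- alt$type %in% ins_types
    alt_str <- paste(ifelse(ins, "<INS>", "<DEL>"), collapse = ",")
    svlen <- paste(ifelse(ins, round(alt$size), -round(alt$size)),
                   collapse = ",")
    svtype <- if (all(ins)) "INS" else if (all(!ins)) "DEL" else "MIXED"
    pos <- pm$sites$start[i] + 1L
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%s", svtype,
                    as.integer(max(pm$sites$end[i], pm$sites$start[i] + 1L)),
                    svlen)
    gt <- sprintf("%d/%d", pm$geno[i, ], pm$geno[i, ])
    writeLines(paste(c(pm$sites$chrom[i], pos, sprintf("site%06d", i), "N",
                       alt_str, ".", "PASS", info, "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a symbolic-allele site VCF back into a presence matrix
#'
#' Parses (via \pkg{vcfR}) a VCF written by [export_sites_vcf()] — or any
#' VCF with symbolic SV alleles and homozygous `GT` calls — and rebuilds
#' the site x accession allele-index matrix.
#'
#' @param path VCF file path.
#' @return An object of class `presence_matrix` (the `alt` tables carry the
#'   `SVLEN`-derived sizes and INS/DEL types).
#' @export
import_sites_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  founders <- colnames(gt)
  idx <- apply(gt, 2, function(col) {
    as.integer(sub("[/|].*$", "", col))
  })
  idx <- matrix(idx, nrow = nrow(gt), dimnames = dimnames(gt))
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    sub(paste0(key, "="), "", m)
  }
  info <- if (is.matrix(fix)) fix[, "INFO"] else fix["INFO"]
  alt_col <- if (is.matrix(fix)) fix[, "ALT"] else fix["ALT"]
  alt <- lapply(seq_along(info), function(i) {
    svlen <- as.numeric(strsplit(info_field(info[i], "SVLEN"), ",")[[1]])
    kinds <- strsplit(alt_col[i], ",")[[1]]
    data.frame(size = abs(svlen),
               type = ifelse(grepl("INS", kinds), "insertion", "deletion"),
               stringsAsFactors = FALSE)
  })
  pos <- as.integer(if (is.matrix(fix)) fix[, "POS"] else fix["POS"])
  ends <- as.integer(info_field(info, "END"))
  meta <- data.frame(
    chrom = if (is.matrix(fix)) fix[, "CHROM"] else fix["CHROM"],
    start = pos - 1L, end = ends,
    sv_class = ifelse(vapply(alt, function(a) max(a$size), 0) > 2000,
                      "large_sv", "short_indel"),
    n_alt = vapply(alt, nrow, 1L), stringsAsFactors = FALSE)
  meta$biallelic <- meta$n_alt == 1L
  rownames(meta) <- NULL
  structure(list(geno = unname(idx) |>
                   `dimnames<-`(list(NULL, founders)),
                 sites = meta, alt = alt, founders = founders),
            class = "presence_matrix")
}

#' Export site spans as BED
#'
#' Writes the reference span of every site as a BED interval (0-based
#' half-open, matching the internal convention).
#'
#' @param pm a [build_presence_matrix()] result.
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
export_sites_bed <- function(pm, path) {
  stopifnot(inherits(pm, "presence_matrix"))
  bed <- data.frame(pm$sites$chrom, pm$sites$start,
                    pmax(pm$sites$end, pm$sites$start + 1L),
                    sprintf("site%06d", seq_len(nrow(pm$sites))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
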