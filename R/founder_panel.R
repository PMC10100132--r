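#' Define a founder panel
#'
#' A founder panel describes the inbred accessions whose genomes are compared
#' against a common reference: accession identifiers, a two-level
#' subpopulation assignment (emulating the two cultivated melon subspecies),
#' and per-chromosome genome lengths. The defaults mirror a 25-founder core
#' collection split 17/8 between the two subpopulations over 12 chromosomes
#' of 30 Mb each (the melon karyotype at reduced scale).
#'
#' @param founders character vector of accession identifiers (>= 2, unique).
#' @param subpop named character vector mapping every founder to one of two
#'   subpopulation labels. Defaults to `"melo"` for the first 17 founders and
#'   `"agrestis"` for the rest (proportionally for other panel sizes).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @return An object of class `founder_panel`.
#' @examples
#' fp <- founder_panel()
#' length(fp$founders)  # 25
#' @export
founder_panel <- function(founders = sprintf("ACC%02d", seq_len(25)),
                          subpop = NULL,
                          chrom_lengths = stats::setNames(rep(30e6, 12),
                                                          sprintf("chr%02d", 1:12))) {
  founders <- as.character(founders)
  if (length(founders) < 2L) stop("need >= 2 founders", call. = FALSE)
  if (anyDuplicated(founders)) stop("duplicate founder identifiers", call. = FALSE)
  if (is.null(subpop)) {
    n1 <- max(1L, round(length(founders) * 17 / 25))
    if (n1 >= length(founders)) n1 <- length(founders) - 1L
    subpop <- stats::setNames(
      rep(c("melo", "agrestis"), c(n1, length(founders) - n1)), founders)
  }
  if (!all(founders %in% names(subpop))) {
    stop("every founder needs a subpopulation label", call. = FALSE)
  }
  subpop <- subpop[founders]
  if (length(unique(subpop)) > 2L) {
    stop("at most two subpopulation labels are supported", call. = FALSE)
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%02d", seq_along(chrom_lengths))
  }
  structure(list(founders = founders, subpop = subpop,
                 chrom_lengths = chrom_lengths),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d founders (%s), %d chromosomes, %.0f Mb total\n",
              length(x$founders),
              paste(sprintf("%d %s", as.vector(table(x$subpop)),
                            names(table(x$subpop))), collapse = " + "),
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6))
  invisible(x)
}
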