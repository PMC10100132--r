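#' Substitution mapping over a recombinant panel
#'
#' Narrows a binary trait locus to the smallest marker interval consistent
#' with every recombinant line, under a declared single-locus model
#' (default: dominant mutant allele carried by parent B, matching a
#' dominant-mutant mapping design; switchable to recessive).
#'
#' Each line's genotype at a marker predicts its phenotype if the locus
#' were there; a candidate locus position (a marker, or the gap between two
#' adjacent markers) is feasible when every line's phenotype is explained.
#' The reported interval is delimited by the flanking markers just outside
#' the feasible region; with no recombinants in the region it spans the
#' whole marker set, and when no position is feasible an empty interval is
#' returned together with the lines violating the best candidate
#' (non-parental/phenotyping-error candidates).
#'
#' @param geno lines x markers character matrix, codes A/H/B, columns in
#'   map order.
#' @param phenotype binary vector (1 = mutant class), one value per line.
#' @param mutant_allele `"B"` (default) or `"A"`: parent carrying the
#'   mutant allele.
#' @param dominance `"dominant"` (default) or `"recessive"` mutant allele.
#' @return list with `left_flank`, `right_flank` (marker names; NA for an
#'   empty interval), `feasible_markers` (markers perfectly co-segregating),
#'   `consistent` (TRUE when some position is feasible), `violators`
#'   (line indices inconsistent with the best candidate).
#' @export
substitution_map <- function(geno, phenotype,
                             mutant_allele = c("B", "A"),
                             dominance = c("dominant", "recessive")) {
  mutant_allele <- match.arg(mutant_allele)
  dominance <- match.arg(dominance)
  geno <- as.matrix(geno)
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% 0:1)) stop("phenotype must be binary", call. = FALSE)
  if (nrow(geno) != length(phenotype)) {
    stop("one phenotype per line required", call. = FALSE)
  }
  m <- ncol(geno)
  markers <- colnames(geno)
  if (is.null(markers)) markers <- sprintf("m%d", seq_len(m))

  mutant_codes <- if (dominance == "dominant") c(mutant_allele, "H") else
    mutant_allele
  predicted <- matrix(as.integer(geno %in% mutant_codes), nrow = nrow(geno))
  compat <- predicted == phenotype          # lines x markers

  ## candidate positions: markers (odd) and inter-marker gaps (even)
  cand_ok <- vector("list", 2L * m - 1L)
  for (i in seq_len(m)) cand_ok[[2L * i - 1L]] <- compat[, i]
  if (m > 1L) for (i in seq_len(m - 1L)) {
    cand_ok[[2L * i]] <- compat[, i] | compat[, i + 1L]
  }
  feasible <- vapply(cand_ok, all, TRUE)

  if (!any(feasible)) {
    cover <- vapply(cand_ok, sum, numeric(1))
    best <- which.max(cover)
    return(list(left_flank = NA_character_, right_flank = NA_character_,
                feasible_markers = character(),
                consistent = FALSE,
                violators = which(!cand_ok[[best]])))
  }
  lo <- min(which(feasible)); hi <- max(which(feasible))
  ## candidate index -> flanking marker just outside the feasible region
  left <- if (lo %% 2L == 0L) lo %/% 2L else max(1L, (lo + 1L) %/% 2L - 1L)
  right <- if (hi %% 2L == 0L) hi %/% 2L + 1L else
    min(m, (hi + 1L) %/% 2L + 1L)
  list(left_flank = markers[left], right_flank = markers[right],
       feasible_markers = markers[which(feasible[seq(1, 2L * m - 1L, 2L)])],
       consistent = TRUE, violators = integer())
}
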