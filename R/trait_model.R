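#' Declare a genetic trait architecture
#'
#' A trait model is a declarative description of a genetic architecture used
#' both to simulate phenotypes and to derive Mendelian expectations: a small
#' set of major loci with additive/dominance effects, optional epistatic
#' masking rules, an optional polygenic additive background, Gaussian noise
#' on the latent scale, and an optional threshold turning the latent value
#' into a binary trait.
#'
#' Genotypes are coded relative to the two cross parents: `A` = homozygous
#' parent-A allele, `H` = heterozygous, `B` = homozygous parent-B allele.
#' A locus with effects `(a, d)` contributes `-a`, `d`, `+a` for genotypes
#' `A`, `H`, `B`. An epistasis rule `(masker, genotype, masked)` forces the
#' masked locus's contribution to its recessive (low homozygote) state
#' whenever the masking locus carries the masking genotype class — the
#' recessive-masking pattern that yields 9:7 ratios in an F2.
#'
#' @param loci data.frame with columns `chrom`, `bp`, `a`, `d` (one row per
#'   major locus; effects on the trait scale).
#' @param epistasis optional data.frame with columns `masker`, `genotype`
#'   (one of "A", "H", "B"), `masked` (locus row indices into `loci`).
#' @param polygenic optional list `list(n_loci =, effect =)`: additional
#'   unlinked additive loci of equal effect, placed uniformly on the map at
#'   simulation time.
#' @param noise_sd Gaussian noise standard deviation (trait units, >= 0).
#' @param type `"quantitative"` or `"binary"`; binary traits are thresholded
#'   at `threshold` on the latent scale.
#' @param threshold latent-scale cutpoint for binary traits (default 0).
#' @return An object of class `trait_model`.
#' @examples
#' # single dominant mottling locus (binary)
#' tm <- trait_model(loci = data.frame(chrom = "chr02", bp = 5e6, a = 1, d = 1),
#'                   type = "binary")
#' @export
trait_model <- function(loci,
                        epistasis = NULL,
                        polygenic = NULL,
                        noise_sd = 0,
                        type = c("quantitative", "binary"),
                        threshold = 0) {
  type <- match.arg(type)
  stopifnot(is.data.frame(loci), all(c("chrom", "bp", "a", "d") %in% names(loci)))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(epistasis)) {
    stopifnot(all(c("masker", "genotype", "masked") %in% names(epistasis)))
    if (!all(epistasis$genotype %in% c("A", "H", "B"))) {
      stop("epistasis genotype classes must be A, H or B", call. = FALSE)
    }
    loc_idx <- seq_len(nrow(loci))
    if (!all(epistasis$masker %in% loc_idx) ||
        !all(epistasis$masked %in% loc_idx)) {
      stop("epistasis rules must reference declared loci", call. = FALSE)
    }
  }
  if (!is.null(polygenic)) {
    stopifnot(is.list(polygenic), all(c("n_loci", "effect") %in% names(polygenic)))
  }
  structure(list(loci = loci, epistasis = epistasis, polygenic = polygenic,
                 noise_sd = noise_sd, type = type, threshold = threshold),
            class = "trait_model")
}

## Latent genetic value for a matrix of locus genotypes ("A"/"H"/"B",
## individuals x loci, major loci first then polygenic). Epistasis rules are
## applied after locus effects, noise is added by the caller last.
trait_latent <- function(geno, model, poly_effect = NULL) {
  n_major <- nrow(model$loci)
  contrib <- matrix(0, nrow(geno), n_major)
  for (j in seq_len(n_major)) {
    a <- model$loci$a[j]; d <- model$loci$d[j]
    contrib[, j] <- c(A = -a, H = d, B = a)[geno[, j]]
  }
  if (!is.null(model$epistasis)) {
    for (k in seq_len(nrow(model$epistasis))) {
      rule <- model$epistasis[k, ]
      hit <- geno[, rule$masker] == rule$genotype
      contrib[hit, rule$masked] <- -model$loci$a[rule$masked]
    }
  }
  value <- rowSums(contrib)
  if (!is.null(model$polygenic) && ncol(geno) > n_major) {
    eff <- if (is.null(poly_effect)) model$polygenic$effect else poly_effect
    poly <- geno[, (n_major + 1):ncol(geno), drop = FALSE]
    score <- (poly == "B") * 1 + (poly == "H") * 0 + (poly == "A") * -1
    value <- value + rowSums(score) * eff
  }
  value
}
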