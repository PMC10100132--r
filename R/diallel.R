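#' Enumerate the crosses of a half-diallel
#'
#' A half-diallel crosses n parents in all n(n-1)/2 unordered pairwise
#' combinations, without selfs or reciprocals. Pairs are returned in
#' lexicographically canonical order (parent_a < parent_b).
#'
#' @param founders character vector of >= 2 distinct parent identifiers.
#' @return data.frame with columns `cross_id`, `parent_a`, `parent_b`;
#'   exactly `choose(n, 2)` rows (300 for 25 founders, 190 for 20).
#' @examples
#' nrow(enumerate_crosses(sprintf("P%02d", 1:25)))  # 300
#' @export
enumerate_crosses <- function(founders) {
  founders <- as.character(founders)
  if (length(founders) < 2L) stop("need >= 2 founders", call. = FALSE)
  if (anyDuplicated(founders)) {
    stop("duplicate founder identifiers", call. = FALSE)
  }
  founders <- sort(founders)
  pairs <- utils::combn(founders, 2L)
  data.frame(cross_id = sprintf("%s_x_%s", pairs[1, ], pairs[2, ]),
             parent_a = pairs[1, ], parent_b = pairs[2, ],
             stringsAsFactors = FALSE)
}

#' Project site polymorphism onto a cross
#'
#' A site is polymorphic in a cross iff its two parents carry different
#' allele indices there (reference counts as index 0, so alt-vs-reference
#' and alt-vs-different-alt both count). With `biallelic_only`,
#' multi-allelic sites are excluded before comparison, matching analyses
#' restricted to the bi-allelic site set. Totals are reported overall, per
#' chromosome, and per fixed-width bin from the chromosome start.
#'
#' @param pm a [build_presence_matrix()] result.
#' @param parent_a,parent_b accession identifiers (matrix columns).
#' @param biallelic_only restrict to bi-allelic sites (default FALSE).
#' @param bin_size bin width in bp (default 1 Mb).
#' @return An object of class `cross_profile`: list with `cross_id`,
#'   `polymorphic` (logical per retained site), `site_index` (row indices of
#'   retained sites), `total`, `per_chrom` (named vector), `per_bin`
#'   (data.frame chrom/bin/count).
#' @export
project_polymorphism <- function(pm, parent_a, parent_b,
                                 biallelic_only = FALSE, bin_size = 1e6) {
  stopifnot(inherits(pm, "presence_matrix"))
  for (p in c(parent_a, parent_b)) {
    if (!p %in% colnames(pm$geno)) {
      stop("parent not in matrix: ", p, call. = FALSE)
    }
  }
  keep <- if (biallelic_only) which(pm$sites$biallelic) else
    seq_len(nrow(pm$geno))
  poly <- pm$geno[keep, parent_a] != pm$geno[keep, parent_b]
  meta <- pm$sites[keep, , drop = FALSE]
  per_chrom <- tapply(poly, meta$chrom, sum)
  per_chrom <- stats::setNames(as.integer(per_chrom), names(per_chrom))
  bin <- floor(meta$start / bin_size)
  agg <- stats::aggregate(list(count = as.integer(poly)),
                          by = list(chrom = meta$chrom, bin = bin), FUN = sum)
  agg <- agg[order(agg$chrom, agg$bin), ]
  rownames(agg) <- NULL
  structure(list(cross_id = sprintf("%s_x_%s", min(parent_a, parent_b),
                                    max(parent_a, parent_b)),
                 polymorphic = unname(poly), site_index = keep,
                 total = sum(poly), per_chrom = per_chrom, per_bin = agg),
            class = "cross_profile")
}

#' Project polymorphism onto every cross of the half-diallel
#'
#' Convenience wrapper applying [project_polymorphism()] to every pairwise
#' cross of the matrix's accessions.
#'
#' @inheritParams project_polymorphism
#' @param crosses optional data.frame from [enumerate_crosses()].
#' @return data.frame with one row per cross: `cross_id`, `parent_a`,
#'   `parent_b`, `n_polymorphic`.
#' @export
project_all_crosses <- function(pm, crosses = NULL, biallelic_only = FALSE) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (is.null(crosses)) crosses <- enumerate_crosses(pm$founders)
  keep <- if (biallelic_only) pm$sites$biallelic else
    rep(TRUE, nrow(pm$geno))
  g <- pm$geno[keep, , drop = FALSE]
  crosses$n_polymorphic <- vapply(seq_len(nrow(crosses)), function(i) {
    sum(g[, crosses$parent_a[i]] != g[, crosses$parent_b[i]])
  }, numeric(1))
  crosses
}

#' Pairwise genetic distance from a marker genotype table
#'
#' One minus the identity-by-state proportion over markers non-missing in
#' both accessions of a pair. The diagonal is 0; the matrix is symmetric.
#' A pair with no shared non-missing markers gets `NA` with a warning.
#'
#' @param genotypes founder x marker matrix (any atomic codes; `NA` =
#'   missing).
#' @return symmetric numeric distance matrix.
#' @export
genetic_distance_matrix <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (n < 2L) stop("need >= 2 founders", call. = FALSE)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("F%d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(genotypes[i, ]) & !is.na(genotypes[j, ])
    if (!any(ok)) {
      warning(sprintf("no shared non-missing markers for %s/%s", ids[i], ids[j]))
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- mean(genotypes[i, ok] != genotypes[j, ok])
    }
  }
  d
}

#' Correlate parental genetic distance with cross polymorphism
#'
#' Pearson correlation, across crosses, between parental genetic distance
#' and the number of polymorphic sites in the cross, with the p-value from
#' the t transform of r.
#'
#' @param distances symmetric founder distance matrix
#'   ([genetic_distance_matrix()]).
#' @param profiles data.frame from [project_all_crosses()].
#' @return list with `r`, `n`, `p`, `degenerate` flag, and the per-cross
#'   `scatter` data.frame (distance, n_polymorphic).
#' @export
distance_vs_polymorphism <- function(distances, profiles) {
  if (nrow(profiles) < 3L) stop("need >= 3 crosses", call. = FALSE)
  d <- vapply(seq_len(nrow(profiles)), function(i) {
    distances[profiles$parent_a[i], profiles$parent_b[i]]
  }, numeric(1))
  scatter <- data.frame(cross_id = profiles$cross_id, distance = d,
                        n_polymorphic = profiles$n_polymorphic)
  if (stats::sd(d) == 0 || stats::sd(profiles$n_polymorphic) == 0) {
    warning("degenerate input: constant distances or polymorphism totals")
    return(list(r = NA_real_, n = nrow(profiles), p = NA_real_,
                degenerate = TRUE, scatter = scatter))
  }
  ct <- stats::cor.test(d, profiles$n_polymorphic, method = "pearson")
  list(r = unname(ct$estimate), n = nrow(profiles), p = ct$p.value,
       degenerate = FALSE, scatter = scatter)
}
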