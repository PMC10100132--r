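#' Allele-frequency spectrum over a presence matrix
#'
#' Counts sites by the number of carrier accessions (an accession carries a
#' site when it holds any alternate allele there). The histogram covers
#' carrier counts 1..N and sums to the number of sites in the selected
#' class.
#'
#' @param pm a [build_presence_matrix()] result.
#' @param site_class `"all"`, `"biallelic"`, `"short_indel"` or `"large_sv"`.
#' @return named integer vector of length N (carrier count 1..N).
#' @export
allele_frequency_spectrum <- function(pm, site_class = c("all", "biallelic",
                                                         "short_indel",
                                                         "large_sv")) {
  stopifnot(inherits(pm, "presence_matrix"))
  site_class <- match.arg(site_class)
  keep <- switch(site_class,
                 all = rep(TRUE, nrow(pm$geno)),
                 biallelic = pm$sites$biallelic,
                 short_indel = pm$sites$sv_class == "short_indel",
                 large_sv = pm$sites$sv_class == "large_sv")
  carriers <- rowSums(pm$geno[keep, , drop = FALSE] > 0L)
  n <- ncol(pm$geno)
  spec <- tabulate(carriers, nbins = n)
  stats::setNames(spec, seq_len(n))
}

#' Classify rare (singleton) sites
#'
#' A site is rare when it is carried by exactly one accession of the panel.
#'
#' @param pm a [build_presence_matrix()] result.
#' @return list with `rare` (logical per site), `n_rare`, `n_shared`,
#'   `rare_fraction`.
#' @export
classify_rare <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  carriers <- rowSums(pm$geno > 0L)
  rare <- carriers == 1L
  list(rare = rare, n_rare = sum(rare), n_shared = sum(carriers >= 2L),
       rare_fraction = if (length(rare)) mean(rare) else NA_real_)
}

#' Pan-variant rarefaction curve
#'
#' For each of `n_permutations` random orderings of the accessions, counts
#' the cumulative number of distinct sites carried by the first g
#' accessions, g = 1..N. Reports, per g, the mean over permutations and two
#' central percentile bands: the interval containing 50% of permutation
#' values (25th-75th percentiles) and the one containing 99% (0.5th-99.5th),
#' with linear interpolation between order statistics. When N <= 6 (or
#' `exact = TRUE`) all N! orderings are enumerated instead of sampled.
#'
#' @param pm a [build_presence_matrix()] result.
#' @param n_permutations number of random orderings (default 1000).
#' @param seed integer seed; required (ignored for exact enumeration).
#' @param exact force exhaustive enumeration of all orderings.
#' @return An object of class `rarefaction_curve`: data.frame with columns
#'   `g`, `mean`, `p25`, `p75`, `p0.5`, `p99.5`; attributes
#'   `n_permutations`, `seed`, `pan_total`.
#' @export
rarefaction <- function(pm, n_permutations = 1000, seed,
                        exact = ncol(pm$geno) <= 6L) {
  stopifnot(inherits(pm, "presence_matrix"))
  n <- ncol(pm$geno)
  carried <- pm$geno > 0L
  cum_counts <- function(ord) {
    ## cumulative distinct carried sites along one founder ordering
    seen <- rep(FALSE, nrow(carried))
    out <- numeric(n)
    for (g in seq_len(n)) {
      seen <- seen | carried[, ord[g]]
      out[g] <- sum(seen)
    }
    out
  }
  if (exact) {
    perms <- permutations_of(n)
    counts <- vapply(perms, cum_counts, numeric(n))
    n_used <- length(perms)
  } else {
    n_permutations <- stopifnot_count(n_permutations, "n_permutations")
    counts <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) cum_counts(sample.int(n)),
             numeric(n))
    })
    n_used <- n_permutations
  }
  counts <- matrix(counts, nrow = n)  # g x permutations
  qs <- apply(counts, 1, stats::quantile,
              probs = c(0.25, 0.75, 0.005, 0.995), type = 7)
  curve <- data.frame(g = seq_len(n), mean = rowMeans(counts),
                      p25 = qs[1, ], p75 = qs[2, ],
                      p0.5 = qs[3, ], p99.5 = qs[4, ])
  rownames(curve) <- NULL
  structure(curve, class = c("rarefaction_curve", "data.frame"),
            n_permutations = n_used,
            seed = if (exact) NA_integer_ else as.integer(seed),
            pan_total = sum(rowSums(carried) > 0L))
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(permutations_of(n - 1L), function(p) c(i, (seq_len(n)[-i])[p]))
  }))
}

#' Closed-form expected rarefaction curve
#'
#' Independent analytical check for the permutation curve: the probability
#' that a site with c carriers is absent from a random subset of g of N
#' accessions is C(N-c, g)/C(N, g), so
#' E[distinct sites at g] = sum over sites of (1 - C(N-c_s, g)/C(N, g)).
#'
#' @param pm a [build_presence_matrix()] result.
#' @return numeric vector of expected cumulative counts for g = 1..N.
#' @export
expected_rarefaction <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  n <- ncol(pm$geno)
  carriers <- rowSums(pm$geno > 0L)
  carriers <- carriers[carriers > 0L]
  vapply(seq_len(n), function(g) {
    sum(1 - exp(lchoose(n - carriers, g) - lchoose(n, g)))
  }, numeric(1))
}

#' Saturation point of a rarefaction curve
#'
#' Smallest panel size g whose mean cumulative site count reaches
#' `fraction` of the pan total.
#'
#' @param curve a [rarefaction()] result.
#' @param fraction target fraction of the pan total (0 < fraction <= 1).
#' @return integer g.
#' @export
saturation_point <- function(curve, fraction) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  pan <- attr(curve, "pan_total")
  g <- which(curve$mean >= fraction * pan - 1e-9)
  if (!length(g)) stop("curve never reaches the requested fraction",
                       call. = FALSE)
  as.integer(curve$g[g[1]])
}
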