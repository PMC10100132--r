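#' Mode-of-inheritance classification for one cross
#'
#' Classifies the inheritance of a quantitative trait in one hybrid
#' combination from replicated parent and F1 measurements, by the
#' dominance degree d/a: a = half the parental difference, d = deviation of
#' the F1 mean from the mid-parent value. Classification bands (config,
#' declared rather than inferred from any published scheme):
#' |d/a| <= 0.2 additive; (0.2, 0.8] partial dominance; (0.8, 1.2]
#' dominant; > 1.2 over-/underdominant by the sign of d relative to the
#' high parent. Significance gating: when the F1 mean is not significantly
#' different from the mid-parent value (one-sample t-test at `alpha`), the
#' call is additive.
#'
#' @param parent_a,parent_b numeric replicate values per parent.
#' @param f1 numeric replicate values for the F1.
#' @param alpha gating significance level (default 0.05).
#' @param bands numeric length-3 vector of |d/a| class boundaries.
#' @param cross_id optional label.
#' @return list of class `inheritance_call`: `cross_id`, `mean_a`,
#'   `mean_b`, `midparent`, `f1_mean`, `a`, `d`, `da_ratio`, `class`,
#'   `gated` (TRUE when the additive call came from the significance gate),
#'   `flag` (notes, e.g. zero a with nonzero d).
#' @export
mode_of_inheritance <- function(parent_a, parent_b, f1, alpha = 0.05,
                                bands = c(0.2, 0.8, 1.2), cross_id = NA) {
  mean_a <- mean(parent_a); mean_b <- mean(parent_b)
  midparent <- (mean_a + mean_b) / 2
  f1_mean <- mean(f1)
  a <- abs(mean_a - mean_b) / 2
  d <- f1_mean - midparent
  flag <- NA_character_
  gated <- FALSE
  if (a == 0) {
    ratio <- NA_real_
    if (d == 0) {
      cls <- "additive"
    } else {
      cls <- if (d > 0) "overdominant" else "underdominant"
      flag <- "zero parental difference with nonzero d; class by sign of d"
    }
  } else {
    ratio <- d / a
    r <- abs(ratio)
    cls <- if (r <= bands[1]) "additive"
      else if (r <= bands[2]) "partial dominance"
      else if (r <= bands[3]) "dominant"
      else if (ratio > 0) "overdominant" else "underdominant"
    if (cls != "additive" && length(f1) >= 2 && stats::sd(f1) > 0) {
      p <- stats::t.test(f1, mu = midparent)$p.value
      if (p > alpha) {
        cls <- "additive"
        gated <- TRUE
      }
    }
  }
  structure(list(cross_id = cross_id, mean_a = mean_a, mean_b = mean_b,
                 midparent = midparent, f1_mean = f1_mean, a = a, d = d,
                 da_ratio = ratio, class = cls, gated = gated, flag = flag),
            class = "inheritance_call")
}

#' Mid-parent regression across a diallel
#'
#' Pearson correlation, across the crosses of a (half-)diallel, between the
#' mid-parent trait value and the F1 mean. A correlation near 1 indicates
#' mostly additive inheritance of the trait across the diversity.
#'
#' @param midparent numeric vector of per-cross mid-parent values.
#' @param f1_mean numeric vector of per-cross F1 means (same order).
#' @return list with `r`, `n`, `p`, `degenerate` flag and the `scatter`
#'   data.frame.
#' @export
midparent_regression <- function(midparent, f1_mean) {
  if (length(midparent) != length(f1_mean)) {
    stop("midparent and f1_mean lengths differ", call. = FALSE)
  }
  if (length(midparent) < 3L) stop("need >= 3 crosses", call. = FALSE)
  scatter <- data.frame(midparent = midparent, f1_mean = f1_mean)
  if (stats::sd(midparent) == 0 || stats::sd(f1_mean) == 0) {
    warning("degenerate input: constant values")
    return(list(r = NA_real_, n = length(midparent), p = NA_real_,
                degenerate = TRUE, scatter = scatter))
  }
  ct <- stats::cor.test(midparent, f1_mean, method = "pearson")
  list(r = unname(ct$estimate), n = length(midparent), p = ct$p.value,
       degenerate = FALSE, scatter = scatter)
}

#' Select tail segregant families across two generations
#'
#' For bulk-segregant (QTL-seq style) designs: a family enters the high
#' (low) tail iff it lies in the top (bottom) q-quantile of family means in
#' BOTH generations. Ties are broken deterministically by stable sort on
#' (value, family identifier). The high and low tails are disjoint by
#' construction for q < 0.5.
#'
#' @param gen1,gen2 named numeric vectors of family means, identically
#'   indexed (names = family identifiers).
#' @param q tail fraction, 0 < q < 0.5. The per-generation tail size is
#'   `floor(q * n)`.
#' @return list with `high`, `low` (character vectors of family ids),
#'   `k` (per-generation tail size), `correlation` (Pearson r between
#'   generations).
#' @export
select_tails <- function(gen1, gen2, q) {
  if (is.null(names(gen1)) || !identical(sort(names(gen1)),
                                         sort(names(gen2)))) {
    stop("gen1 and gen2 must be named vectors over the same families",
         call. = FALSE)
  }
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)", call. = FALSE)
  gen2 <- gen2[names(gen1)]
  n <- length(gen1)
  k <- floor(q * n + 1e-9)
  if (k < 1L) stop("q too small: empty tails", call. = FALSE)
  tail_ids <- function(x, side) {
    ord <- if (side == "low") order(x, names(x)) else order(-x, names(x))
    names(x)[ord[seq_len(k)]]
  }
  high <- intersect(tail_ids(gen1, "high"), tail_ids(gen2, "high"))
  low <- intersect(tail_ids(gen1, "low"), tail_ids(gen2, "low"))
  list(high = sort(high), low = sort(low), k = k,
       correlation = stats::cor(gen1, gen2))
}
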