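#' Construct a genetic map
#'
#' A genetic map lists ordered markers per chromosome with both physical (bp)
#' and genetic (cM) positions. Positions must be strictly increasing in both
#' units within a chromosome, and the two orders must agree.
#'
#' @param map data.frame with columns `chrom`, `marker`, `bp`, `cM`.
#' @return The validated data.frame with class `genetic_map`.
#' @examples
#' gm <- genetic_map(data.frame(chrom = "chr01",
#'                              marker = c("m1", "m2", "m3"),
#'                              bp = c(1e6, 2e6, 3e6),
#'                              cM = c(0, 5, 12)))
#' @export
genetic_map <- function(map) {
  req <- c("chrom", "marker", "bp", "cM")
  if (!all(req %in% names(map))) {
    stop("map needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(map$marker)) stop("duplicate marker names", call. = FALSE)
  map <- map[order(map$chrom, map$bp), req, drop = FALSE]
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (any(diff(m$bp) <= 0) || any(diff(m$cM) <= 0)) {
      stop(sprintf("marker positions on %s must be strictly increasing in bp and cM",
                   ch), call. = FALSE)
    }
  }
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Evenly spaced default map
#'
#' Convenience constructor: `n_markers` per chromosome, evenly spaced in bp,
#' at a fixed recombination density (cM/Mb).
#'
#' @param panel a [founder_panel()] supplying chromosome lengths.
#' @param n_markers markers per chromosome.
#' @param cm_per_mb genetic-to-physical rate (default 3 cM/Mb).
#' @return a [genetic_map()].
#' @export
default_map <- function(panel, n_markers = 10, cm_per_mb = 3) {
  stopifnot(inherits(panel, "founder_panel"))
  rows <- lapply(names(panel$chrom_lengths), function(ch) {
    bp <- round(seq(1e5, panel$chrom_lengths[[ch]] - 1e5,
                    length.out = n_markers))
    data.frame(chrom = ch,
               marker = sprintf("%s_m%02d", ch, seq_len(n_markers)),
               bp = bp, cM = bp / 1e6 * cm_per_mb,
               stringsAsFactors = FALSE)
  })
  genetic_map(do.call(rbind, rows))
}

#' Haldane map function and its inverse
#'
#' `haldane_r()` converts a genetic distance in cM to a recombination
#' fraction under the no-interference (Haldane) model,
#' r = (1 - exp(-2d)) / 2 with d in Morgans; `haldane_cm()` inverts it.
#'
#' @param cm genetic distance in centiMorgans.
#' @param r recombination fraction in [0, 0.5).
#' @return numeric vector.
#' @examples
#' haldane_r(10)        # ~0.0906
#' haldane_cm(haldane_r(10))
#' @export
haldane_r <- function(cm) 0.5 * (1 - exp(-2 * cm / 100))

#' @rdname haldane_r
#' @export
haldane_cm <- function(r) -50 * log(1 - 2 * r)
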