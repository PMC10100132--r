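#' Simulate founder structural-variant panels
#'
#' Draws a panel of InDel sites segregating across the founders of a panel,
#' with the statistical structure observed in assembly-based pan-genomes:
#' a large excess of rare (singleton) variants, a log-uniform size
#' distribution inside the short-InDel range, and a fraction of sites fixed
#' differentially between the two subpopulations (emulating the large
#' subspecies-differential rearrangements seen in real panels).
#'
#' Each simulated site carries one alternate allele; a founder either carries
#' that allele (1) or the reference (0). Per-founder call tables in the
#' Assemblytics output dialect are emitted alongside the presence matrix so
#' that the whole downstream integration pipeline can be exercised from
#' parsed text files.
#'
#' @param panel a [founder_panel()].
#' @param n_sites number of variant sites to draw (>= 1).
#' @param size_range numeric length-2, inclusive InDel size range in bp
#'   (default the short-InDel marker range 15-2000 bp).
#' @param rare_fraction proportion of non-divergent sites that are
#'   singletons (carried by exactly one founder). Default 0.47: in the real
#'   panel almost half of the bi-allelic short InDels are rare.
#' @param subpop_divergence proportion of sites fixed-different between the
#'   two subpopulations (all founders of one subpopulation carry the allele,
#'   none of the other). Default 0.02.
#' @param seed integer seed; required.
#' @param shared_geom geometric decay parameter for the carrier count of
#'   shared (non-singleton, non-divergent) sites; larger values skew the
#'   spectrum towards low-frequency variants.
#' @return An object of class `founder_sv_sim`: a list with elements
#'   `presence` (site x founder 0/1 integer matrix), `sites` (data.frame of
#'   site metadata: chrom, start, end, size, type), `alleles` (named list of
#'   per-founder Assemblytics-dialect data.frames), `panel`, and `params`.
#' @examples
#' sim <- simulate_founders(founder_panel(), n_sites = 500, seed = 1)
#' mean(rowSums(sim$presence) == 1)  # ~ rare_fraction
#' @export
simulate_founders <- function(panel, n_sites,
                              size_range = c(15, 2000),
                              rare_fraction = 0.47,
                              subpop_divergence = 0.02,
                              seed,
                              shared_geom = 0.35) {
  stopifnot(inherits(panel, "founder_panel"))
  n_sites <- stopifnot_count(n_sites, "n_sites")
  stopifnot_prop(rare_fraction, "rare_fraction")
  stopifnot_prop(subpop_divergence, "subpop_divergence")
  if (length(size_range) != 2L || size_range[1] > size_range[2]) {
    stop("size_range must be c(min, max) with min <= max", call. = FALSE)
  }
  if (size_range[1] < 1) stop("InDel sizes must be >= 1 bp", call. = FALSE)
  founders <- panel$founders
  n <- length(founders)
  subpops <- split(founders, panel$subpop)

  with_seed(seed, {
    ## site coordinates: chromosomes weighted by length, positions uniform
    chrom <- sample(names(panel$chrom_lengths), n_sites, replace = TRUE,
                    prob = panel$chrom_lengths)
    pos <- floor(stats::runif(n_sites) * (panel$chrom_lengths[chrom] - 5000)) + 1000
    size <- round(exp(stats::runif(n_sites, log(size_range[1]), log(size_range[2]))))
    size <- pmin(pmax(size, size_range[1]), size_range[2])
    type <- sample(c("deletion", "insertion", "repeat_expansion",
                     "repeat_contraction", "tandem_expansion",
                     "tandem_contraction"),
                   n_sites, replace = TRUE,
                   prob = c(0.42, 0.42, 0.04, 0.04, 0.04, 0.04))

    ## site classes: divergent / singleton / shared
    u <- stats::runif(n_sites)
    divergent <- u < subpop_divergence & length(subpops) == 2L
    singleton <- !divergent & stats::runif(n_sites) < rare_fraction

    presence <- matrix(0L, nrow = n_sites, ncol = n,
                       dimnames = list(NULL, founders))
    for (i in seq_len(n_sites)) {
      if (divergent[i]) {
        grp <- subpops[[sample.int(2L, 1L)]]
        presence[i, grp] <- 1L
      } else if (singleton[i]) {
        presence[i, sample.int(n, 1L)] <- 1L
      } else {
        ## shared: 2..n carriers, geometric decay towards low frequency
        k <- 2L + stats::rgeom(1L, shared_geom)
        k <- min(k, n)
        presence[i, sample.int(n, k)] <- 1L
      }
    }

    ## order sites by (chrom, start) for stable downstream behaviour
    ord <- order(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]; size <- size[ord]; type <- type[ord]
    presence <- presence[ord, , drop = FALSE]

    deletion_like <- type %in% c("deletion", "repeat_contraction",
                                 "tandem_contraction")
    start0 <- as.integer(pos)
    end0 <- as.integer(ifelse(deletion_like, pos + size, pos))
    sites <- data.frame(chrom = chrom, start = start0, end = end0,
                        size = as.integer(size), type = type,
                        stringsAsFactors = FALSE)

    alleles <- lapply(founders, function(f) {
      idx <- which(presence[, f] == 1L)
      assemblytics_rows(sites[idx, , drop = FALSE], accession = f)
    })
    names(alleles) <- founders

    structure(list(presence = presence, sites = sites, alleles = alleles,
                   panel = panel,
                   params = list(n_sites = n_sites, size_range = size_range,
                                 rare_fraction = rare_fraction,
                                 subpop_divergence = subpop_divergence,
                                 shared_geom = shared_geom, seed = seed)),
              class = "founder_sv_sim")
  })
}

## Render internal 0-based site rows as a 1-based Assemblytics-dialect table.
assemblytics_rows <- function(sites, accession) {
  if (nrow(sites) == 0L) {
    return(data.frame(reference = character(), ref_start = integer(),
                      ref_stop = integer(), ID = character(), size = integer(),
                      strand = character(), type = character(),
                      ref_gap_size = integer(), query_gap_size = integer(),
                      query_coordinates = character(), method = character(),
                      stringsAsFactors = FALSE))
  }
  type_out <- c(deletion = "Deletion", insertion = "Insertion",
                repeat_expansion = "Repeat_expansion",
                repeat_contraction = "Repeat_contraction",
                tandem_expansion = "Tandem_expansion",
                tandem_contraction = "Tandem_contraction")[sites$type]
  deletion_like <- sites$type %in% c("deletion", "repeat_contraction",
                                     "tandem_contraction")
  data.frame(
    reference = sites$chrom,
    ref_start = sites$start + 1L,           # 1-based inclusive
    ref_stop = ifelse(deletion_like, sites$end, sites$start + 1L),
    ID = sprintf("%s_%s_%d", accession, sites$chrom, sites$start),
    size = sites$size,
    strand = "+",
    type = type_out,
    ref_gap_size = ifelse(deletion_like, sites$size, 0L),
    query_gap_size = ifelse(deletion_like, 0L, sites$size),
    query_coordinates = sprintf("%s:%d-%d:+", sites$chrom,
                                sites$start + 1L, sites$end + sites$size),
    method = "between_alignments",
    stringsAsFactors = FALSE
  )
}
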