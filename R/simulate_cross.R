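#' Simulate a biparental cross
#'
#' Simulates F1, F2 or recombinant-inbred (RIL) progeny of two fully inbred
#' parents over the markers of a genetic map, with gametes formed by
#' recombination under the Haldane (no-interference) map function on
#' adjacent-marker cM distances. F2 individuals are intercrosses of two
#' independent F1 gametes; `"RIL-k"` denotes the F_k generation reached by
#' single-seed-descent selfing from the F2 (so `"RIL-7"` matches a classical
#' F7 RIL population, with expected per-marker heterozygosity 0.5^(k-1)).
#'
#' Phenotypes, when a [trait_model()] is supplied, are computed from the
#' genotypes at the model's loci (simulated alongside the markers, linked
#' through the same map): locus effects first, epistatic masking second,
#' Gaussian noise last, thresholding for binary traits.
#'
#' @param parent_a,parent_b named character vectors of homozygous marker
#'   alleles (one allele symbol per marker; heterozygous parents are
#'   rejected). Names must match markers on `map`.
#' @param generation `"F1"`, `"F2"`, or `"RIL-k"` with k >= 3.
#' @param n_individuals number of progeny to simulate.
#' @param map a [genetic_map()] covering all parent markers.
#' @param model optional [trait_model()]. Its loci may carry optional
#'   `allele_a`/`allele_b` columns ("A"/"B") giving each parent's allelic
#'   state at the locus; defaults are `"A"` for parent A and `"B"` for
#'   parent B. Two parents sharing the dominant allele at a binary locus
#'   therefore yield 100% mutant-class progeny.
#' @param seed integer seed; required.
#' @return An object of class `marker_panel`: list with `geno` (individuals x
#'   markers, codes "A"/"H"/"B"), `phenotype` (numeric vector, or 0/1 for
#'   binary traits; NULL without a model), `map`, `generation`,
#'   `locus_geno` (individuals x model loci, codes "A"/"H"/"B").
#' @examples
#' gm <- genetic_map(data.frame(chrom = "chr01", marker = c("m1", "m2"),
#'                              bp = c(1e6, 4.4e6), cM = c(0, 10)))
#' pa <- c(m1 = "A", m2 = "A"); pb <- c(m1 = "B", m2 = "B")
#' f2 <- simulate_cross(pa, pb, "F2", 200, gm, seed = 1)
#' table(f2$geno[, "m1"])
#' @export
simulate_cross <- function(parent_a, parent_b, generation, n_individuals,
                           map, model = NULL, seed) {
  stopifnot(inherits(map, "genetic_map"))
  n_individuals <- stopifnot_count(n_individuals, "n_individuals")
  markers <- names(parent_a)
  if (is.null(markers) || !identical(sort(markers), sort(names(parent_b)))) {
    stop("parents must be named vectors over the same markers", call. = FALSE)
  }
  if (!all(markers %in% map$marker)) {
    stop("markers not on map: ",
         paste(setdiff(markers, map$marker), collapse = ", "), call. = FALSE)
  }
  is_het <- function(p) any(p == "H" | grepl("/|\\|", p) & {
    sp <- strsplit(p, "[/|]"); vapply(sp, function(x) length(unique(x)) > 1, TRUE)
  })
  if (is_het(parent_a) || is_het(parent_b)) {
    stop("parents must be homozygous at all markers", call. = FALSE)
  }
  gen <- parse_generation(generation)

  with_seed(seed, {
    ## assemble the simulated position set: map markers + trait loci
    pmap <- map[map$marker %in% markers, , drop = FALSE]
    loci_pos <- NULL
    if (!is.null(model)) {
      stopifnot(inherits(model, "trait_model"))
      loci <- model$loci
      if (!is.null(model$polygenic) && model$polygenic$n_loci > 0) {
        pg_chrom <- sample(unique(map$chrom), model$polygenic$n_loci,
                           replace = TRUE)
        pg_bp <- vapply(pg_chrom, function(ch) {
          rng <- range(map$bp[map$chrom == ch])
          stats::runif(1, rng[1], rng[2])
        }, numeric(1))
        loci <- rbind(loci[, c("chrom", "bp", "a", "d")],
                      data.frame(chrom = pg_chrom, bp = pg_bp,
                                 a = model$polygenic$effect, d = 0))
      }
      loci_pos <- data.frame(chrom = loci$chrom, bp = loci$bp,
                             id = sprintf(".locus%d", seq_len(nrow(loci))),
                             stringsAsFactors = FALSE)
    }
    pos <- data.frame(chrom = pmap$chrom, bp = pmap$bp, id = pmap$marker,
                      cM = pmap$cM, stringsAsFactors = FALSE)
    if (!is.null(loci_pos)) {
      loci_pos$cM <- interp_cm(loci_pos, map)
      pos <- rbind(pos, loci_pos[, names(pos)])
    }
    pos <- pos[order(pos$chrom, pos$bp, pos$id), , drop = FALSE]

    ## per-chromosome adjacent recombination fractions
    chroms <- unique(pos$chrom)
    r_by_chrom <- lapply(chroms, function(ch) {
      haldane_r(pmax(diff(pos$cM[pos$chrom == ch]), 0))
    })
    names(r_by_chrom) <- chroms
    m <- nrow(pos)

    gamete_phase <- function(n) {
      ## n x m matrix of 0/1 haplotype phases, recombining within chromosomes
      out <- matrix(0L, n, m)
      col0 <- 1L
      for (ch in chroms) {
        idx <- which(pos$chrom == ch)
        ph <- matrix(0L, n, length(idx))
        ph[, 1] <- stats::rbinom(n, 1L, 0.5)
        r <- r_by_chrom[[ch]]
        if (length(idx) > 1L) {
          sw <- matrix(stats::rbinom(n * (length(idx) - 1L), 1L,
                                     rep(r, each = n)),
                       n, length(idx) - 1L)
          for (j in seq_along(r)) ph[, j + 1L] <- bitwXor(ph[, j], sw[, j])
        }
        out[, idx] <- ph
        col0 <- col0 + length(idx)
      }
      out
    }

    ## haplotypes coded by parental origin: 0 = parent A, 1 = parent B.
    if (gen$type == "F1") {
      h1 <- matrix(0L, n_individuals, m)
      h2 <- matrix(1L, n_individuals, m)
    } else {
      h1 <- gamete_phase(n_individuals)   # F2 gametes from the F1
      h2 <- gamete_phase(n_individuals)
      if (gen$type == "RIL") {
        for (s in seq_len(gen$k - 2L)) {  # single-seed descent selfing
          ph1 <- gamete_phase(n_individuals)
          ph2 <- gamete_phase(n_individuals)
          g1 <- ifelse(ph1 == 0L, h1, h2)
          g2 <- ifelse(ph2 == 0L, h1, h2)
          h1 <- g1; h2 <- g2
        }
      }
    }

    origin_code <- matrix("H", n_individuals, m)
    origin_code[h1 == 0L & h2 == 0L] <- "A"
    origin_code[h1 == 1L & h2 == 1L] <- "B"
    colnames(origin_code) <- pos$id

    marker_idx <- match(markers, pos$id)
    geno <- origin_code[, marker_idx, drop = FALSE]
    colnames(geno) <- markers
    ## monomorphic markers: both parents carry the same allele
    mono <- markers[parent_a[markers] == parent_b[markers]]
    if (length(mono)) geno[, mono] <- "A"

    phenotype <- NULL; locus_geno <- NULL
    if (!is.null(model)) {
      lid <- sprintf(".locus%d", seq_len(nrow(loci_pos)))
      locus_geno <- origin_code[, match(lid, pos$id), drop = FALSE]
      n_major <- nrow(model$loci)
      ## map parental origin to allelic state at each major locus
      al_a <- if ("allele_a" %in% names(model$loci)) model$loci$allele_a else
        rep("A", n_major)
      al_b <- if ("allele_b" %in% names(model$loci)) model$loci$allele_b else
        rep("B", n_major)
      for (j in seq_len(n_major)) {
        a1 <- ifelse(h1[, match(lid[j], pos$id)] == 0L, al_a[j], al_b[j])
        a2 <- ifelse(h2[, match(lid[j], pos$id)] == 0L, al_a[j], al_b[j])
        locus_geno[, j] <- ifelse(a1 == a2, a1, "H")
      }
      latent <- trait_latent(locus_geno, model)
      if (model$noise_sd > 0) {
        latent <- latent + stats::rnorm(n_individuals, 0, model$noise_sd)
      }
      phenotype <- if (model$type == "binary") {
        as.integer(latent > model$threshold)
      } else latent
      colnames(locus_geno) <- sprintf("locus%d", seq_len(ncol(locus_geno)))
    }

    structure(list(geno = geno, phenotype = phenotype, map = map,
                   generation = generation, locus_geno = locus_geno,
                   parents = list(a = parent_a, b = parent_b),
                   seed = seed),
              class = "marker_panel")
  })
}

parse_generation <- function(generation) {
  if (identical(generation, "F1")) return(list(type = "F1"))
  if (identical(generation, "F2")) return(list(type = "F2"))
  if (grepl("^RIL-[0-9]+$", generation)) {
    k <- as.integer(sub("^RIL-", "", generation))
    if (k < 3L) stop("RIL-k requires k >= 3 (F3 or later)", call. = FALSE)
    return(list(type = "RIL", k = k))
  }
  stop("generation must be 'F1', 'F2' or 'RIL-k'", call. = FALSE)
}

## interpolate cM for arbitrary bp positions from the map (per chromosome,
## linear, clamped at map ends)
interp_cm <- function(pos, map) {
  vapply(seq_len(nrow(pos)), function(i) {
    m <- map[map$chrom == pos$chrom[i], ]
    if (nrow(m) == 0L) return(0)  # unlinked: own pseudo-chromosome
    if (nrow(m) == 1L) return(m$cM[1])
    stats::approx(m$bp, m$cM, xout = pos$bp[i], rule = 2)$y
  }, numeric(1))
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d individuals x %d markers (%s)%s\n",
              nrow(x$geno), ncol(x$geno), x$generation,
              if (!is.null(x$phenotype)) ", phenotyped" else ""))
  invisible(x)
}
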