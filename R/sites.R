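#' Collapse variant alleles across accessions into multi-allelic sites
#'
#' Pools the per-accession InDel/SV calls of a panel and converges them into
#' reference sites. Two alleles join the same site when they lie on the same
#' chromosome, share breakpoint polarity (insertion-like: insertion /
#' repeat_expansion / tandem_expansion vs deletion-like), and their
#' reference start breakpoints are within `breakpoint_tol` bp
#' (single-linkage clustering, the standard multi-sample SV-merging rule;
#' the start breakpoint anchors a site so that alleles of different length
#' at one locus converge to the same site). Within a site,
#' two member alleles are treated as the same alternate allele when their
#' sizes agree within `size_similarity` (relative) or `breakpoint_tol` bp
#' (absolute), whichever is larger; otherwise the site is multi-allelic.
#'
#' Exact duplicate calls (same accession, chromosome, start, type, size)
#' are deduplicated with a message. If one accession contributes two
#' distinct alleles to one site (tandem nearby calls), the larger allele is
#' kept and a message is emitted.
#'
#' The result is invariant to input row order: alleles are canonically
#' sorted before clustering.
#'
#' @param alleles data.frame of variant alleles (as from
#'   [parse_assemblytics()], all accessions pooled).
#' @param breakpoint_tol breakpoint tolerance in bp (>= 0, default 10).
#' @param size_similarity relative size tolerance (>= 0, default 0.1).
#' @param large_threshold sizes above this are classed `large_sv`.
#' @return An object of class `variant_sites`: a list of site records
#'   (`chrom`, `start`, `end`, `sv_class`, `alt` data.frame of alternate
#'   alleles with representative `size`/`type`, `presence` named integer
#'   vector accession -> allele index), sorted by (chrom, start), with
#'   attribute `n_alleles` = member-allele count after deduplication.
#' @export
collapse_to_sites <- function(alleles, breakpoint_tol = 10,
                              size_similarity = 0.1,
                              large_threshold = 2000) {
  if (breakpoint_tol < 0 || size_similarity < 0) {
    stop("tolerances must be >= 0", call. = FALSE)
  }
  if (nrow(alleles) == 0L) {
    out <- structure(list(), class = "variant_sites")
    attr(out, "n_alleles") <- 0L
    return(out)
  }
  ins_like <- alleles$type %in% c("insertion", "repeat_expansion",
                                  "tandem_expansion")
  alleles$polarity <- ifelse(ins_like, "ins", "del")

  dup <- duplicated(alleles[, c("accession", "chrom", "start", "type", "size")])
  if (any(dup)) {
    message(sum(dup), " duplicate call(s) deduplicated")
    alleles <- alleles[!dup, , drop = FALSE]
  }
  ## canonical order: clustering result independent of input row order
  alleles <- alleles[order(alleles$chrom, alleles$polarity, alleles$start,
                           alleles$end, alleles$size, alleles$accession), ,
                     drop = FALSE]
  rownames(alleles) <- NULL

  sites <- list()
  for (grp in split(seq_len(nrow(alleles)),
                    paste(alleles$chrom, alleles$polarity, sep = "\r"))) {
    a <- alleles[grp, , drop = FALSE]
    comp <- single_linkage(a$start, breakpoint_tol)
    for (members in split(seq_len(nrow(a)), comp)) {
      sites[[length(sites) + 1L]] <-
        make_site(a[members, , drop = FALSE], breakpoint_tol,
                  size_similarity, large_threshold)
    }
  }
  ord <- order(vapply(sites, `[[`, character(1), "chrom"),
               vapply(sites, `[[`, numeric(1), "start"))
  out <- structure(sites[ord], class = "variant_sites")
  attr(out, "n_alleles") <- sum(vapply(out, function(s) s$n_members, 0L))
  out
}

## single-linkage components: i ~ j iff |start_i - start_j| <= tol; with
## input sorted by start the components are maximal chains of adjacent
## starts at most tol apart.
single_linkage <- function(start, tol) {
  n <- length(start)
  if (n == 0L) return(integer())
  brk <- c(FALSE, diff(start) > tol)
  cumsum(brk) + 1L
}

make_site <- function(a, breakpoint_tol, size_similarity, large_threshold) {
  ## one accession with two distinct member alleles: keep the larger
  if (anyDuplicated(a$accession)) {
    message("accession with multiple alleles at one site: larger kept")
    a <- a[order(a$accession, -a$size), , drop = FALSE]
    a <- a[!duplicated(a$accession), , drop = FALSE]
  }
  n_members <- nrow(a)
  ## alternate-allele grouping by size, single linkage
  grp <- size_linkage(a$size, breakpoint_tol, size_similarity)
  reps <- vapply(split(a$size, grp), function(s) stats::median(s), numeric(1))
  ord <- order(reps)  # alt alleles ordered by representative size
  relabel <- match(grp, as.integer(names(reps))[ord])
  alt <- data.frame(
    size = as.numeric(reps[ord]),
    type = vapply(as.integer(names(reps))[ord], function(g) {
      tt <- table(a$type[grp == g]); names(tt)[which.max(tt)]
    }, character(1)),
    stringsAsFactors = FALSE)
  presence <- stats::setNames(relabel, a$accession)
  list(chrom = a$chrom[1], start = min(a$start), end = max(a$end),
       sv_class = if (max(a$size) > large_threshold) "large_sv" else "short_indel",
       alt = alt, presence = presence, n_members = n_members)
}

size_linkage <- function(size, tol_abs, tol_rel) {
  n <- length(size)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) for (i in 2:n) for (j in 1:(i - 1L)) {
    tol <- max(tol_abs, tol_rel * max(size[i], size[j]))
    if (abs(size[i] - size[j]) <= tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' @export
print.variant_sites <- function(x, ...) {
  n_alt <- vapply(x, function(s) nrow(s$alt), 1L)
  cat(sprintf("variant_sites: %d sites from %d alleles (%d bi-allelic, %d multi-allelic)\n",
              length(x), attr(x, "n_alleles"),
              sum(n_alt == 1L), sum(n_alt > 1L)))
  invisible(x)
}

#' Build the site x accession presence matrix
#'
#' Tabulates, for every collapsed site, the alternate-allele index carried
#' by each accession (0 = reference). Site metadata records the reference
#' span, size class, alternate-allele count and the bi-allelic flag
#' (exactly one alternate allele).
#'
#' @param sites a [collapse_to_sites()] result.
#' @param founders character vector of panel accessions; must cover every
#'   accession seen in `sites`.
#' @return An object of class `presence_matrix`: list with `geno` (site x
#'   accession integer matrix), `sites` (metadata data.frame with columns
#'   `chrom`, `start`, `end`, `sv_class`, `n_alt`, `biallelic`), `alt`
#'   (per-site alternate-allele tables) and `founders`.
#' @export
build_presence_matrix <- function(sites, founders) {
  stopifnot(inherits(sites, "variant_sites"))
  founders <- as.character(founders)
  seen <- unique(unlist(lapply(sites, function(s) names(s$presence))))
  if (!all(seen %in% founders)) {
    stop("accession(s) in sites but not in founder list: ",
         paste(setdiff(seen, founders), collapse = ", "), call. = FALSE)
  }
  n <- length(sites)
  geno <- matrix(0L, nrow = n, ncol = length(founders),
                 dimnames = list(NULL, founders))
  for (i in seq_len(n)) {
    geno[i, names(sites[[i]]$presence)] <- as.integer(sites[[i]]$presence)
  }
  meta <- data.frame(
    chrom = vapply(sites, `[[`, character(1), "chrom"),
    start = vapply(sites, `[[`, numeric(1), "start"),
    end = vapply(sites, `[[`, numeric(1), "end"),
    sv_class = vapply(sites, `[[`, character(1), "sv_class"),
    n_alt = vapply(sites, function(s) nrow(s$alt), 1L),
    stringsAsFactors = FALSE)
  meta$biallelic <- meta$n_alt == 1L
  structure(list(geno = geno, sites = meta,
                 alt = lapply(sites, `[[`, "alt"), founders = founders),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d sites x %d accessions (%d bi-allelic)\n",
              nrow(x$geno), ncol(x$geno), sum(x$sites$biallelic)))
  invisible(x)
}

#' Re-derive per-accession allele calls from a presence matrix
#'
#' Inverse of the collapse step for exact-coordinate data: emits one allele
#' row per nonzero matrix cell, using the site span and the carried
#' alternate allele's representative size and type. Collapsing the result
#' reproduces the original matrix (idempotence of the round trip).
#'
#' @param pm a [build_presence_matrix()] result.
#' @return data.frame of variant alleles (columns as [parse_assemblytics()]).
#' @export
matrix_to_alleles <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  rows <- lapply(seq_len(nrow(pm$geno)), function(i) {
    carriers <- which(pm$geno[i, ] > 0L)
    if (!length(carriers)) return(NULL)
    alt <- pm$alt[[i]][pm$geno[i, carriers], , drop = FALSE]
    data.frame(accession = pm$founders[carriers],
               chrom = pm$sites$chrom[i],
               start = pm$sites$start[i], end = pm$sites$end[i],
               type = alt$type, size = as.integer(round(alt$size)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_alleles() else out
}
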