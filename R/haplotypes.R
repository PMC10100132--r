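#' Build a gene-interval variant table
#'
#' Container for the polymorphisms of one gene interval across a panel:
#' variant rows (position within the interval, ref/alt allele, SNP or
#' InDel) with per-accession genotype columns (0 = ref, 1 = alt, NA =
#' missing call), plus an optional gene model (CDS segments and strand, for
#' coding-effect classification) and the interval reference sequence.
#'
#' @param variants data.frame with columns `pos`, `ref`, `alt`, `type`
#'   (`"SNP"` or `"InDel"`).
#' @param geno variants x accessions matrix of 0/1/NA.
#' @param gene_model optional list: `strand` ("+"/"-"), `cds` data.frame
#'   with `start`, `end` (1-based inclusive, interval coordinates),
#'   `transcript` length-2 vector (transcript span; default the CDS span).
#'   CDS segment lengths must sum to a multiple of 3.
#' @param ref_seq optional interval reference sequence (single character
#'   string, 1-based positions matching `pos`).
#' @return object of class `interval_variant_table`.
#' @export
interval_variant_table <- function(variants, geno, gene_model = NULL,
                                   ref_seq = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("pos", "ref", "alt", "type") %in% names(variants)))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants)) {
    stop("geno must have one row per variant", call. = FALSE)
  }
  if (nrow(variants) < 1L || ncol(geno) < 2L) {
    stop("need >= 1 variant and >= 2 accessions", call. = FALSE)
  }
  if (!is.null(gene_model)) {
    stopifnot(all(c("strand", "cds") %in% names(gene_model)))
    cds_len <- sum(gene_model$cds$end - gene_model$cds$start + 1)
    if (cds_len %% 3 != 0) {
      stop("CDS segment lengths must sum to a multiple of 3", call. = FALSE)
    }
    if (is.null(gene_model$transcript)) {
      gene_model$transcript <- c(min(gene_model$cds$start),
                                 max(gene_model$cds$end))
    }
    gene_model$cds <- gene_model$cds[order(gene_model$cds$start), ,
                                     drop = FALSE]
  }
  structure(list(variants = variants, geno = geno, gene_model = gene_model,
                 ref_seq = ref_seq),
            class = "interval_variant_table")
}

#' Group accessions into gene haplotypes
#'
#' Exact-match grouping on allele vectors: accessions with identical
#' non-missing genotype vectors share a haplotype. Accessions whose missing
#' fraction exceeds `max_missing` are dropped. An accession with missing
#' calls joins an existing (complete-vector) group iff it is compatible
#' with exactly one group; if compatible with several it is left ungrouped
#' and flagged; if compatible with none it founds its own group. Haplotype
#' labels `H1`, `H2`, ... are assigned by group size, descending (ties by
#' first accession).
#'
#' @param table an [interval_variant_table()].
#' @param max_missing maximum tolerated missing-call fraction per accession.
#' @return list of class `haplotype_grouping`: `assignment` (named
#'   character, accession -> haplotype label or NA), `haplotypes` (label x
#'   variant allele matrix), `sizes`, `dropped`, `ambiguous`.
#' @export
call_haplotypes <- function(table, max_missing = 0.5) {
  stopifnot(inherits(table, "interval_variant_table"))
  stopifnot_prop(max_missing, "max_missing")
  g <- table$geno
  miss_frac <- colMeans(is.na(g))
  dropped <- colnames(g)[miss_frac > max_missing]
  keep <- setdiff(colnames(g), dropped)
  g <- g[, keep, drop = FALSE]

  complete <- keep[colSums(is.na(g[, keep, drop = FALSE])) == 0L]
  partial <- setdiff(keep, complete)

  ## base groups from complete vectors
  key <- apply(g[, complete, drop = FALSE], 2, paste, collapse = ",")
  groups <- split(complete, key)
  defs <- lapply(groups, function(acc) g[, acc[1]])

  ambiguous <- character()
  for (acc in partial) {
    v <- g[, acc]
    ok <- !is.na(v)
    compat <- which(vapply(defs, function(d) all(d[ok] == v[ok]), TRUE))
    if (length(compat) == 1L) {
      groups[[compat]] <- c(groups[[compat]], acc)
    } else if (length(compat) > 1L) {
      ambiguous <- c(ambiguous, acc)
    } else {
      groups[[length(groups) + 1L]] <- acc
      defs[[length(defs) + 1L]] <- v
    }
  }

  sizes <- lengths(groups)
  ord <- order(-sizes, vapply(groups, function(x) sort(x)[1], ""))
  labels <- sprintf("H%d", seq_along(ord))
  assignment <- stats::setNames(rep(NA_character_, ncol(table$geno)),
                                colnames(table$geno))
  hap_mat <- matrix(NA_real_, nrow = length(ord), ncol = nrow(table$variants),
                    dimnames = list(labels, NULL))
  for (i in seq_along(ord)) {
    assignment[groups[[ord[i]]]] <- labels[i]
    hap_mat[i, ] <- defs[[ord[i]]]
  }
  structure(list(assignment = assignment, haplotypes = hap_mat,
                 sizes = stats::setNames(sizes[ord], labels),
                 dropped = dropped, ambiguous = ambiguous),
            class = "haplotype_grouping")
}

#' @export
print.haplotype_grouping <- function(x, ...) {
  cat(sprintf("haplotype_grouping: %d haplotypes (%s)%s\n",
              length(x$sizes),
              paste(sprintf("%s:%d", names(x$sizes), x$sizes), collapse = ", "),
              if (length(x$ambiguous))
                sprintf("; %d ambiguous", length(x$ambiguous)) else ""))
  invisible(x)
}

#' Haplotype-trait association by exact tests
#'
#' Fisher exact tests of a binary trait against a haplotype grouping:
#' the overall haplotype x trait table, each haplotype one-vs-rest, and —
#' to support the "no single polymorphism explains it" comparison — each
#' underlying variant one-vs-rest (variant alleles recovered from the
#' haplotype definitions). Two-sided, no mid-p correction.
#'
#' @param grouping a [call_haplotypes()] result.
#' @param trait named binary vector (0/1) over the grouped accessions.
#' @return list with `overall_p` (NA when fewer than 2 haplotypes),
#'   `per_haplotype` (data.frame label/p), `per_variant` (data.frame
#'   variant index/p), `table` (haplotype x trait counts).
#' @export
haplotype_trait_association <- function(grouping, trait) {
  stopifnot(inherits(grouping, "haplotype_grouping"))
  acc <- names(grouping$assignment)[!is.na(grouping$assignment)]
  if (!all(acc %in% names(trait))) {
    stop("every grouped accession needs a trait value", call. = FALSE)
  }
  hap <- grouping$assignment[acc]
  tr <- as.integer(trait[acc])
  tab <- table(hap, factor(tr, levels = 0:1))
  if (nrow(tab) < 2L || length(unique(tr)) < 2L) {
    overall_p <- if (nrow(tab) < 2L) NA_real_ else 1
  } else {
    overall_p <- stats::fisher.test(tab)$p.value
  }
  per_hap <- data.frame(
    haplotype = rownames(tab),
    p = vapply(rownames(tab), function(h) {
      t2 <- table(factor(hap == h, levels = c(FALSE, TRUE)),
                  factor(tr, levels = 0:1))
      stats::fisher.test(t2)$p.value
    }, numeric(1)), row.names = NULL)
  n_var <- ncol(grouping$haplotypes)
  per_var <- data.frame(
    variant = seq_len(n_var),
    p = vapply(seq_len(n_var), function(v) {
      allele <- grouping$haplotypes[hap, v]
      if (length(unique(allele[!is.na(allele)])) < 2L) return(1)
      t2 <- table(factor(allele, levels = 0:1), factor(tr, levels = 0:1))
      stats::fisher.test(t2)$p.value
    }, numeric(1)))
  list(overall_p = overall_p, per_haplotype = per_hap,
       per_variant = per_var, table = tab)
}
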