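# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive expectations by brute force / closed form,
# separately from the package implementation they check.

# wrap a plain 0/1 (or allele-index) matrix as a presence_matrix
pm_from_geno <- function(geno, chrom = "chr01", start = NULL,
                         alt = NULL) {
  n <- nrow(geno)
  if (is.null(start)) start <- seq_len(n) * 1000L
  n_alt <- apply(geno, 1, function(r) max(1L, max(r)))
  if (is.null(alt)) {
    alt <- lapply(n_alt, function(k) data.frame(
      size = seq_len(k) * 50, type = rep("deletion", k),
      stringsAsFactors = FALSE))
  }
  meta <- data.frame(chrom = rep(chrom, length.out = n), start = start,
                     end = start + 50L, sv_class = "short_indel",
                     n_alt = as.integer(n_alt),
                     biallelic = n_alt == 1L, stringsAsFactors = FALSE)
  structure(list(geno = geno, sites = meta, alt = alt,
                 founders = colnames(geno)),
            class = "presence_matrix")
}

# brute-force single-linkage clustering of alleles into sites (graph
# connected components), plus within-site size-linkage into alt alleles.
# Returns a sorted canonical signature: one string per site listing alt
# groups ("acc|acc,acc"), for exact comparison with collapse_to_sites().
oracle_collapse_signature <- function(alleles, tol = 10, simil = 0.1) {
  ins <- alleles$type %in% c("insertion", "repeat_expansion",
                             "tandem_expansion")
  pol <- ifelse(ins, "ins", "del")
  n <- nrow(alleles)
  linked <- function(i, j) {
    alleles$chrom[i] == alleles$chrom[j] && pol[i] == pol[j] &&
      abs(alleles$start[i] - alleles$start[j]) <= tol
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && linked(i, j)) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sig <- vapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    sz <- alleles$size[idx]
    g <- seq_along(idx)
    repeat {
      ch <- FALSE
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        t2 <- max(tol, simil * max(sz[a], sz[b]))
        if (g[a] != g[b] && abs(sz[a] - sz[b]) <= t2) {
          g[g == max(g[a], g[b])] <- min(g[a], g[b])
          ch <- TRUE
        }
      }
      if (!ch) break
    }
    grps <- vapply(unique(g), function(gg) {
      paste(sort(alleles$accession[idx[g == gg]]), collapse = ",")
    }, "")
    paste(sort(grps), collapse = "|")
  }, "")
  sort(sig)
}

# same signature from the implementation's output
sites_signature <- function(sites) {
  sig <- vapply(sites, function(s) {
    grps <- vapply(sort(unique(s$presence)), function(k) {
      paste(sort(names(s$presence)[s$presence == k]), collapse = ",")
    }, "")
    paste(sort(grps), collapse = "|")
  }, "")
  sort(sig)
}

# random allele pools with clustered breakpoints and distinct accessions
random_allele_pool <- function(n, seed) {
  set.seed(seed)
  base <- sample(seq(100, 5000, by = 100), 8)
  start <- sample(base, n, replace = TRUE) + sample(-8:8, n, replace = TRUE)
  type <- sample(c("deletion", "insertion"), n, replace = TRUE)
  size <- sample(c(20, 22, 50, 55, 300, 320, 1500), n, replace = TRUE)
  data.frame(accession = sprintf("acc%02d", seq_len(n)),
             chrom = sample(c("chr01", "chr02"), n, replace = TRUE),
             start = start,
             end = ifelse(type == "deletion", start + size, start),
             type = type, size = size, stringsAsFactors = FALSE)
}

# all permutations of 1..n (independent of the package's internal helper)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in all_perms(n - 1L)) out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

# exhaustive rarefaction mean curve from a 0/1 matrix
oracle_rarefaction_mean <- function(geno) {
  n <- ncol(geno)
  perms <- all_perms(n)
  counts <- sapply(perms, function(ord) {
    seen <- rep(FALSE, nrow(geno))
    vapply(seq_len(n), function(g) {
      seen <<- seen | (geno[, ord[g]] > 0)
      sum(seen)
    }, numeric(1))
  })
  rowMeans(counts)
}

# F2 two-marker joint genotype probabilities under recombination fraction r
# (gametes: parental (1-r)/2 each, recombinant r/2 each; two independent
# gametes per individual). Rows/cols in order A, H, B.
f2_two_marker_probs <- function(r) {
  gam <- c(AA = (1 - r) / 2, AB = r / 2, BA = r / 2, BB = (1 - r) / 2)
  states <- names(gam)
  joint <- matrix(0, 3, 3, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
  for (g1 in states) for (g2 in states) {
    a1 <- substr(g1, 1, 1); a2 <- substr(g2, 1, 1)
    b1 <- substr(g1, 2, 2); b2 <- substr(g2, 2, 2)
    gA <- if (a1 == a2) a1 else "H"
    gB <- if (b1 == b2) b1 else "H"
    joint[gA, gB] <- joint[gA, gB] + gam[g1] * gam[g2]
  }
  joint
}

# ML estimate of r from an observed 3x3 F2 two-marker table
estimate_r_ml <- function(tab) {
  nll <- function(r) {
    p <- f2_two_marker_probs(r)
    -sum(tab * log(p))
  }
  stats::optimize(nll, c(1e-4, 0.49))$minimum
}

# full-CDS retranslation oracle for SNP coding effects: substitute the
# variant base into the genomic sequence, rebuild and translate the whole
# CDS for both alleles, and compare proteins.
oracle_snp_effect <- function(ref_seq, cds, strand, pos, alt) {
  splice <- function(s) {
    bases <- strsplit(s, "")[[1]]
    parts <- unlist(lapply(seq_len(nrow(cds)),
                           function(i) bases[cds$start[i]:cds$end[i]]))
    if (strand == "-") {
      parts <- rev(chartr("ACGT", "TGCA", parts))
    }
    paste(parts, collapse = "")
  }
  translate <- function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  in_cds <- any(pos >= cds$start & pos <= cds$end)
  if (!in_cds) return(NA_character_)
  altseq <- ref_seq
  substr(altseq, pos, pos) <- alt
  if (translate(splice(ref_seq)) == translate(splice(altseq))) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
}

# random gene fixture: 3-exon gene inside an interval
random_gene <- function(seed, strand = "+") {
  set.seed(seed)
  ref_seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
  cds <- data.frame(start = c(101, 221, 341), end = c(160, 280, 412))
  stopifnot(sum(cds$end - cds$start + 1) %% 3 == 0)
  list(ref_seq = ref_seq, cds = cds, strand = strand,
       transcript = c(51, 500))
}
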