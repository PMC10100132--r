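make_hap_table <- function(assign, defs, missing = NULL) {
  geno <- sapply(assign, function(i) defs[[i]])
  colnames(geno) <- sprintf("A%02d", seq_along(assign))
  if (!is.null(missing)) geno[missing] <- NA
  interval_variant_table(
    data.frame(pos = seq_len(nrow(geno)) * 10, ref = "A", alt = "G",
               type = "SNP"), geno)
}

test_that("haplotype grouping is exact-match and size-ordered", {
  defs <- list(c(0, 0, 0, 0, 0), c(1, 1, 0, 1, 0), c(1, 1, 1, 1, 1))
  assign <- rep(1:3, c(8, 10, 7))
  hg <- call_haplotypes(make_hap_table(assign, defs))
  expect_length(hg$sizes, 3)
  expect_equal(unname(hg$sizes), c(10, 8, 7))  # descending
  expect_true(all(table(hg$assignment) == c(H1 = 10, H2 = 8, H3 = 7)))
  expect_lte(length(hg$sizes), 25)

  # identical accessions give one haplotype
  hg1 <- call_haplotypes(make_hap_table(rep(1, 6), defs))
  expect_length(hg1$sizes, 1)

  # grouping is invariant to accession order
  perm <- sample(25)
  tab <- make_hap_table(assign, defs)
  tab2 <- interval_variant_table(tab$variants, tab$geno[, perm])
  hg2 <- call_haplotypes(tab2)
  expect_equal(sort(names(hg2$assignment)), sort(names(hg$assignment)))
  expect_identical(hg$assignment[sort(names(hg$assignment))],
                   hg2$assignment[sort(names(hg2$assignment))])
})

test_that("missing calls are tolerated, merged or flagged", {
  defs <- list(c(0, 0, 0, 0, 0), c(1, 1, 0, 1, 0))
  tab <- make_hap_table(c(1, 1, 2, 2, 1), defs)
  g <- tab$geno
  g[, "A05"] <- NA                                  # all missing: dropped
  g[1, "A03"] <- NA                                 # compatible only with H2
  tab2 <- interval_variant_table(tab$variants, g)
  hg <- call_haplotypes(tab2, max_missing = 0.5)
  expect_equal(hg$dropped, "A05")
  expect_equal(unname(hg$assignment["A03"]), unname(hg$assignment["A04"]))

  # ambiguous: compatible with both groups
  g2 <- tab$geno
  g2[c(1, 2, 4), "A05"] <- NA    # remaining positions identical across groups
  tab3 <- interval_variant_table(tab$variants, g2)
  hg2 <- call_haplotypes(tab3, max_missing = 0.8)
  expect_equal(hg2$ambiguous, "A05")
  expect_true(is.na(hg2$assignment["A05"]))
})

test_that("a perfect haplotype split gives the hypergeometric Fisher p", {
  defs <- list(c(0, 0, 0, 0, 0), c(1, 1, 0, 1, 0), c(1, 1, 1, 1, 1))
  assign <- rep(1:3, c(8, 10, 7))
  hg <- call_haplotypes(make_hap_table(assign, defs))
  trait <- setNames(as.integer(assign == 3), sprintf("A%02d", 1:25))
  res <- haplotype_trait_association(hg, trait)
  expect_equal(res$overall_p, 1 / choose(25, 7), tolerance = 1e-10)
  expect_lt(abs(res$overall_p - 2.1e-6), 1e-7)
  # the variants unique to the resistant haplotype separate perfectly
  expect_equal(min(res$per_variant$p), 1 / choose(25, 7), tolerance = 1e-10)

  # constant trait: p = 1
  res0 <- haplotype_trait_association(hg, setNames(rep(1L, 25),
                                                   names(trait)))
  expect_equal(res0$overall_p, 1)

  # one discordant accession weakens the association
  trait2 <- trait
  trait2[which(assign == 3)[1]] <- 0L
  res2 <- haplotype_trait_association(hg, trait2)
  expect_gt(res2$overall_p, res$overall_p)

  expect_error(haplotype_trait_association(hg, trait[1:3]), "trait value")
})

test_that("substitution mapping returns the flanking-marker interval", {
  # recombinants bracketing a locus strictly between m3 and m4
  geno <- rbind(c("A", "A", "A", "B", "B"),   # phenotype from the B side
                c("B", "B", "B", "A", "A"),   # phenotype from the B side
                c("A", "A", "A", "A", "B"),
                c("B", "B", "B", "B", "A"))
  colnames(geno) <- paste0("m", 1:5)
  ph <- c(1, 1, 0, 1)
  res <- substitution_map(geno, ph)
  expect_true(res$consistent)
  expect_equal(c(res$left_flank, res$right_flank), c("m3", "m4"))

  # no recombinants: the whole region
  geno2 <- rbind(rep("A", 5), rep("B", 5)); colnames(geno2) <- paste0("m", 1:5)
  res2 <- substitution_map(geno2, c(0, 1))
  expect_equal(c(res2$left_flank, res2$right_flank), c("m1", "m5"))

  # inconsistent line reported as an error candidate
  geno3 <- rbind(geno, rep("A", 5))
  res3 <- substitution_map(geno3, c(ph, 1))
  expect_false(res3$consistent)
  expect_true(5 %in% res3$violators)
})

test_that("the mapped interval always contains the causal marker", {
  # exhaustive single-breakpoint configurations for 3..8 markers
  for (m in 3:8) {
    lines <- do.call(rbind, lapply(1:(m - 1), function(bp) {
      rbind(c(rep("A", bp), rep("B", m - bp)),
            c(rep("B", bp), rep("A", m - bp)))
    }))
    colnames(lines) <- paste0("m", seq_len(m))
    for (locus in seq_len(m)) {
      ph <- as.integer(lines[, locus] == "B")  # dominant B, all homozygous
      res <- substitution_map(lines, ph)
      expect_true(res$consistent)
      li <- match(res$left_flank, colnames(lines))
      ri <- match(res$right_flank, colnames(lines))
      expect_lte(li, locus)
      expect_gte(ri, locus)
      # exhaustive interval-scan oracle: the feasible markers are exactly
      # those perfectly co-segregating
      perfect <- which(apply(lines == "B", 2, function(g) {
        all(as.integer(g) == ph)
      }))
      expect_equal(match(res$feasible_markers, colnames(lines)),
                   unname(perfect))
    }
  }
})

test_that("recessive and dominant declared models differ on heterozygotes", {
  geno <- rbind(c("H", "H"), c("B", "B"), c("A", "A"))
  colnames(geno) <- c("m1", "m2")
  ph_dom <- c(1, 1, 0)
  ph_rec <- c(0, 1, 0)
  expect_true(substitution_map(geno, ph_dom, dominance = "dominant")$consistent)
  expect_true(substitution_map(geno, ph_rec, dominance = "recessive")$consistent)
  expect_false(substitution_map(geno, ph_rec, dominance = "dominant")$consistent)
})

test_that("coding effects match the codon table on canonical cases", {
  # ATG GCT CTT ... with a 2-exon model and flanking UTR
  ref <- paste0(strrep("T", 50), "ATGGCTCTT", strrep("A", 21),
                "GGGTTTTAG", strrep("C", 40))
  # CDS: 51-59 (ATG GCT CTT) + 81-89 (GGG TTT TAG) = 18 bases
  gm <- list(strand = "+", cds = data.frame(start = c(51, 81),
                                            end = c(59, 89)),
             transcript = c(31, 120))
  vars <- data.frame(
    pos = c(53, 59, 45, 61, 70, 100, 55, 56),
    ref = c("G", "T", "T", "A", "A", "C", "C", "T"),
    alt = c("A", "C", "G", "G", "G", "G", "CAAA", "TA"),
    type = c("SNP", "SNP", "SNP", "SNP", "SNP", "SNP", "InDel", "InDel"))
  tab <- interval_variant_table(vars, matrix(0:1, 8, 2), gm, ref)
  eff <- classify_coding_effect(tab)
  expect_equal(eff$effect,
               c("nonsynonymous",        # ATG->ATA is M->I at codon 1
                 "synonymous",           # CTT->CTC stays Leu
                 "UTR",                  # upstream of the CDS, in transcript
                 "splice-site-adjacent", # intron base 2 bp from the junction
                 "intronic",
                 "UTR",                  # downstream of the CDS
                 "inframe-indel",        # +3 bases in CDS
                 "frameshift"))          # +1 base in CDS
  expect_equal(eff$ref_aa[1], "M"); expect_equal(eff$alt_aa[1], "I")
})

test_that("random SNP classifications equal full-CDS retranslation", {
  for (strand in c("+", "-")) {
    gene <- random_gene(71, strand)
    set.seed(72)
    cds_pos <- unlist(lapply(1:3, function(i) {
      gene$cds$start[i]:gene$cds$end[i]
    }))
    pos <- sample(cds_pos, 100, replace = FALSE)
    refb <- substring(gene$ref_seq, pos, pos)
    alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                           1), "")
    vars <- data.frame(pos = pos, ref = refb, alt = alt, type = "SNP")
    tab <- interval_variant_table(vars, matrix(0:1, 100, 2),
                                  gene_model = list(strand = strand,
                                                    cds = gene$cds,
                                                    transcript = gene$transcript),
                                  ref_seq = gene$ref_seq)
    eff <- classify_coding_effect(tab)
    oracle <- vapply(seq_along(pos), function(i) {
      oracle_snp_effect(gene$ref_seq, gene$cds, strand, pos[i], alt[i])
    }, "")
    expect_equal(eff$effect, oracle)
  }
})

test_that("effect calls are strand-symmetric under reverse complement", {
  gene <- random_gene(73, "+")
  L <- nchar(gene$ref_seq)
  set.seed(74)
  pos <- sample(90:430, 60)
  refb <- substring(gene$ref_seq, pos, pos)
  alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                         1), "")
  fwd <- interval_variant_table(
    data.frame(pos = pos, ref = refb, alt = alt, type = "SNP"),
    matrix(0:1, 60, 2),
    gene_model = list(strand = "+", cds = gene$cds,
                      transcript = gene$transcript),
    ref_seq = gene$ref_seq)

  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  rc_cds <- data.frame(start = rev(L - gene$cds$end + 1),
                       end = rev(L - gene$cds$start + 1))
  rc <- interval_variant_table(
    data.frame(pos = L - pos + 1, ref = chartr("ACGT", "TGCA", refb),
               alt = chartr("ACGT", "TGCA", alt), type = "SNP"),
    matrix(0:1, 60, 2),
    gene_model = list(strand = "-", cds = rc_cds,
                      transcript = rev(L - gene$transcript + 1)),
    ref_seq = revcomp(gene$ref_seq))
  expect_equal(classify_coding_effect(rc)$effect,
               classify_coding_effect(fwd)$effect)
})
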