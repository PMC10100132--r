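#' Write a named scenario bundle of synthetic input files
#'
#' Emits, under `outdir`, every plain-text file a downstream analysis stage
#' needs for one of the canned study scenarios, plus a YAML manifest
#' recording the scenario, seed, parameters and file list. Output is fully
#' deterministic: re-running with the same seed writes byte-identical files.
#'
#' Scenarios:
#' \describe{
#'   \item{pan_small}{6 founders, 400 sites: SV call tables (Assemblytics
#'     dialect) + presence matrix, for pan/rarefaction analyses at a size
#'     where exact permutation enumeration is feasible.}
#'   \item{diallel_25}{25 founders, 2000 sites: one SV table per founder and
#'     the site presence matrix, for diallel projection.}
#'   \item{epistasis_f2}{2000 F2 individuals segregating for a dominant
#'     locus recessively masked by a second locus (9:7 expectation):
#'     genotype + phenotype TSVs and the genetic map.}
#'   \item{substitution_panel}{120 RIL-7 lines over 9 ordered markers with a
#'     binary locus at the 5th marker: genotype/phenotype TSVs + map.}
#'   \item{tails}{208 families measured in two successive generations of a
#'     sweetness-like quantitative trait: family-mean TSV.}
#' }
#'
#' @param outdir output directory (created if needed).
#' @param scenario one of the scenario names above.
#' @param seed integer seed; required.
#' @return (invisibly) the manifest as a list.
#' @export
write_fixture_bundle <- function(outdir, scenario, seed) {
  scenario <- match.arg(scenario, c("pan_small", "diallel_25", "epistasis_f2",
                                    "substitution_panel", "tails"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  params <- list()

  emit_founder_files <- function(n_founders, n_sites, rare_fraction) {
    panel <- founder_panel(sprintf("ACC%02d", seq_len(n_founders)))
    sim <- simulate_founders(panel, n_sites = n_sites,
                             rare_fraction = rare_fraction, seed = seed)
    for (f in panel$founders) {
      p <- file.path(outdir, sprintf("sv_%s.tsv", f))
      write_tsv_stable(sim$alleles[[f]], p)
      files <<- c(files, basename(p))
    }
    pm <- data.frame(sim$sites, sim$presence, check.names = FALSE)
    p <- file.path(outdir, "presence_matrix.tsv")
    write_tsv_stable(pm, p)
    files <<- c(files, basename(p))
    params <<- c(params, list(n_founders = n_founders, n_sites = n_sites,
                              rare_fraction = rare_fraction))
  }

  emit_panel_files <- function(panel, prefix) {
    g <- data.frame(individual = sprintf("ind%04d", seq_len(nrow(panel$geno))),
                    panel$geno, check.names = FALSE)
    p1 <- file.path(outdir, paste0(prefix, "_genotypes.tsv"))
    write_tsv_stable(g, p1)
    ph <- data.frame(individual = g$individual, trait = panel$phenotype)
    p2 <- file.path(outdir, paste0(prefix, "_phenotypes.tsv"))
    write_tsv_stable(ph, p2)
    p3 <- file.path(outdir, paste0(prefix, "_map.tsv"))
    write_tsv_stable(as.data.frame(panel$map), p3)
    files <<- c(files, basename(c(p1, p2, p3)))
  }

  if (scenario == "pan_small") {
    emit_founder_files(6L, 400L, rare_fraction = 0.47)
  } else if (scenario == "diallel_25") {
    emit_founder_files(25L, 2000L, rare_fraction = 0.47)
  } else if (scenario == "epistasis_f2") {
    gm <- genetic_map(data.frame(
      chrom = c("chr02", "chr04"), marker = c("mt", "aprr"),
      bp = c(5e6, 8e6), cM = c(15, 24)))
    model <- trait_model(
      loci = data.frame(chrom = c("chr02", "chr04"), bp = c(5e6, 8e6),
                        a = c(1, 0), d = c(1, 0)),
      epistasis = data.frame(masker = 2L, genotype = "A", masked = 1L),
      type = "binary")
    pa <- c(mt = "A", aprr = "A"); pb <- c(mt = "B", aprr = "B")
    panel <- simulate_cross(pa, pb, "F2", 2000L, gm, model, seed = seed)
    emit_panel_files(panel, "epistasis_f2")
    params <- c(params, list(n_individuals = 2000L, expected_ratio = "9:7"))
  } else if (scenario == "substitution_panel") {
    gm <- genetic_map(data.frame(
      chrom = "chr02", marker = sprintf("m%02d", 1:9),
      bp = seq(1e6, 9e6, by = 1e6), cM = seq(0, 40, by = 5)))
    model <- trait_model(loci = data.frame(chrom = "chr02", bp = 5e6,
                                           a = 1, d = 1),
                         type = "binary")
    pa <- stats::setNames(rep("A", 9), gm$marker)
    pb <- stats::setNames(rep("B", 9), gm$marker)
    panel <- simulate_cross(pa, pb, "RIL-7", 120L, gm, model, seed = seed)
    emit_panel_files(panel, "substitution_panel")
    params <- c(params, list(n_lines = 120L, causal_marker = "m05"))
  } else if (scenario == "tails") {
    fam <- with_seed(seed, {
      g <- stats::rnorm(208, mean = 10, sd = 2)     # family genetic value, Bx-like
      data.frame(family = sprintf("fam%03d", 1:208),
                 gen1 = round(g + stats::rnorm(208, 0, 0.8), 3),
                 gen2 = round(g + stats::rnorm(208, 0, 0.8), 3))
    })
    p <- file.path(outdir, "tails_family_means.tsv")
    write_tsv_stable(fam, p)
    files <- c(files, basename(p))
    params <- c(params, list(n_families = 208L, genetic_sd = 2,
                             residual_sd = 0.8))
  }

  manifest <- list(scenario = scenario, seed = as.integer(seed),
                   params = params, files = as.list(sort(files)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
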