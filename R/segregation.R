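#' Declare a one- or two-locus segregation model
#'
#' A compact description of a Mendelian architecture used to derive F2
#' expectations: locus count, dominance per locus (TRUE = the mutant allele
#' is dominant), which loci are phenotypic (a purely modifier locus
#' contributes no class of its own), and an optional recessive-masking
#' epistasis rule: when the masking locus carries the masking genotype
#' class, the masked locus is forced to its unexpressed (recessive) state.
#'
#' @param n_loci 1 or 2.
#' @param dominant logical vector, one value per locus.
#' @param phenotypic logical vector, one value per locus (default all TRUE).
#' @param epistasis optional list with elements `masker`, `genotype`
#'   (one of "A", "H", "B"), `masked` (only valid for 2 loci).
#' @return object of class `segregation_model`.
#' @examples
#' # dominant mottling locus masked by a recessive second locus: 9:7
#' m <- segregation_model(2, dominant = c(TRUE, TRUE),
#'                        phenotypic = c(TRUE, FALSE),
#'                        epistasis = list(masker = 2, genotype = "A",
#'                                         masked = 1))
#' expected_f2_ratio(m)
#' @export
segregation_model <- function(n_loci, dominant = rep(TRUE, n_loci),
                              phenotypic = rep(TRUE, n_loci),
                              epistasis = NULL) {
  if (!n_loci %in% 1:2) stop("only 1- or 2-locus models are supported",
                             call. = FALSE)
  stopifnot(length(dominant) == n_loci, length(phenotypic) == n_loci)
  if (!is.null(epistasis)) {
    if (n_loci != 2L) stop("epistasis is only defined for 2 loci", call. = FALSE)
    stopifnot(all(c("masker", "genotype", "masked") %in% names(epistasis)))
    if (!epistasis$genotype %in% c("A", "H", "B")) {
      stop("masking genotype class must be A, H or B", call. = FALSE)
    }
    if (!all(c(epistasis$masker, epistasis$masked) %in% seq_len(n_loci))) {
      stop("epistasis rule must reference declared loci", call. = FALSE)
    }
  }
  structure(list(n_loci = n_loci, dominant = dominant,
                 phenotypic = phenotypic, epistasis = epistasis),
            class = "segregation_model")
}

#' Expected F2 phenotype-class proportions
#'
#' Exhaustive enumeration of the equiprobable F2 genotype combinations
#' (4 gamete combinations for one locus, 16 for two; genotype probabilities
#' 1/4 : 1/2 : 1/4 per locus), classified by the model. Proportions sum
#' to 1. A single dominant locus yields 3/4 : 1/4; a dominant locus masked
#' by a homozygous-recessive second locus yields 9/16 : 7/16; two
#' independent dominant phenotypic loci yield 9:3:3:1.
#'
#' @param model a [segregation_model()].
#' @return named numeric vector of class proportions. Class labels
#'   concatenate per-phenotypic-locus states, `M` (mutant/expressed) or `W`
#'   (wild).
#' @export
expected_f2_ratio <- function(model) {
  stopifnot(inherits(model, "segregation_model"))
  geno_states <- c("A", "H", "B")
  geno_prob <- c(A = 0.25, H = 0.5, B = 0.25)
  grid <- do.call(expand.grid,
                  c(rep(list(geno_states), model$n_loci),
                    list(stringsAsFactors = FALSE)))
  prob <- apply(grid, 1, function(g) prod(geno_prob[g]))
  expressed <- sapply(seq_len(model$n_loci), function(j) {
    g <- grid[[j]]
    if (model$dominant[j]) g %in% c("H", "B") else g == "B"
  })
  expressed <- matrix(expressed, nrow = nrow(grid))
  if (!is.null(model$epistasis)) {
    e <- model$epistasis
    hit <- grid[[e$masker]] == e$genotype
    expressed[hit, e$masked] <- FALSE
  }
  ph <- expressed[, model$phenotypic, drop = FALSE]
  label <- apply(ph, 1, function(x) paste(ifelse(x, "M", "W"), collapse = ""))
  out <- tapply(prob, label, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  sort(out, decreasing = TRUE)
}

#' Goodness of fit to expected class proportions
#'
#' Chi-square goodness-of-fit test of observed class counts against
#' model-derived expected proportions (df = classes - 1, no Yates
#' correction: the expectations come from an explicit model, not from
#' marginals). An exact multinomial p-value is computed when requested and
#' feasible (n <= 200, <= 4 classes), and is selected automatically
#' whenever any expected count falls below 5.
#'
#' @param observed integer vector of class counts (sum >= 1).
#' @param expected numeric vector of expected proportions (sums to 1).
#' @param exact `"auto"` (default), `TRUE` or `FALSE`.
#' @return list of class `contingency_result`: `observed`, `expected`
#'   (counts), `statistic`, `df`, `p.value`, `exact_p` (NA when not
#'   computed), `method`.
#' @examples
#' goodness_of_fit(c(90, 10), c(3, 1) / 4)  # chi-square 12, p ~ 5.3e-4
#' @export
goodness_of_fit <- function(observed, expected, exact = "auto") {
  n <- sum(observed)
  if (n < 1) stop("need at least one observation", call. = FALSE)
  if (length(observed) != length(expected)) {
    stop("observed and expected lengths differ", call. = FALSE)
  }
  if (abs(sum(expected) - 1) > 1e-8) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  exp_counts <- n * expected
  if (any(exp_counts == 0 & observed > 0)) {
    warning("observed counts in a zero-expectation class; exact test used")
    exact <- TRUE
  }
  stat <- sum((observed - exp_counts)^2 / exp_counts,
              na.rm = any(exp_counts == 0))
  df <- length(observed) - 1L
  p_chi <- stats::pchisq(stat, df, lower.tail = FALSE)
  want_exact <- isTRUE(exact) ||
    (identical(exact, "auto") && any(exp_counts < 5))
  exact_p <- NA_real_
  method <- "chi-square"
  if (want_exact && n <= 200 && length(observed) <= 4L) {
    exact_p <- exact_multinomial_p(observed, expected)
    method <- "exact multinomial"
  }
  structure(list(observed = observed, expected = exp_counts,
                 statistic = stat, df = df, p.value = p_chi,
                 exact_p = exact_p, method = method),
            class = "contingency_result")
}

## Exact multinomial goodness-of-fit p-value: total probability of all
## outcome tables no more probable than the observed one.
exact_multinomial_p <- function(observed, expected) {
  n <- sum(observed)
  k <- length(observed)
  comps <- compositions(n, k)
  logp <- apply(comps, 1, function(x) stats::dmultinom(x, prob = expected,
                                                       log = TRUE))
  obs_logp <- stats::dmultinom(observed, prob = expected, log = TRUE)
  sum(exp(logp[logp <= obs_logp + 1e-9]))
}

compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- lapply(0:n, function(i) cbind(i, compositions(n - i, k - 1L)))
  do.call(rbind, out)
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s test: X-squared = %.4g, df = %d, p = %.4g",
              x$method, x$statistic, x$df, x$p.value))
  if (!is.na(x$exact_p)) cat(sprintf(" (exact p = %.4g)", x$exact_p))
  cat("\n")
  invisible(x)
}

#' Marker-trait contingency analysis
#'
#' Tests the association between a marker (codes A/H/B, NA = missing) and a
#' binary trait in a segregating panel: the full 3 x 2 independence
#' chi-square, plus a dominant-model collapse (H+B vs A by default, or H+A
#' vs B) with its own test and the count of individuals misclassified by
#' the dominant single-locus prediction. Fisher's exact test replaces the
#' chi-square when any expected cell is below 5.
#'
#' @param marker character vector of genotype codes.
#' @param trait binary vector (0/1 or logical), 1 = mutant class.
#' @param dominant_class `"B"` (mutant allele is B: H and B predicted
#'   mutant) or `"A"`.
#' @return list with `table` (3 x 2 observed), `overall`
#'   (htest, independence), `dominant` (htest on the collapsed 2 x 2),
#'   `misclassified` (count under the dominant prediction).
#' @export
marker_trait_contingency <- function(marker, trait, dominant_class = "B") {
  keep <- !is.na(marker) & !is.na(trait)
  marker <- marker[keep]; trait <- as.integer(trait[keep])
  if (!length(marker)) stop("all-missing marker", call. = FALSE)
  if (!all(marker %in% c("A", "H", "B"))) {
    stop("marker codes must be A/H/B/NA", call. = FALSE)
  }
  if (!all(trait %in% 0:1)) stop("trait must be binary", call. = FALSE)
  tab <- table(factor(marker, levels = c("A", "H", "B")),
               factor(trait, levels = 0:1))
  overall <- indep_test(tab[rowSums(tab) > 0, , drop = FALSE])
  carrier <- if (dominant_class == "B") marker %in% c("H", "B") else
    marker %in% c("H", "A")
  tab2 <- table(factor(carrier, levels = c(FALSE, TRUE)),
                factor(trait, levels = 0:1))
  dominant <- indep_test(tab2)
  misclassified <- sum(as.integer(carrier) != trait)
  list(table = tab, overall = overall, dominant = dominant,
       misclassified = misclassified)
}

indep_test <- function(tab) {
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_tab < 5)) {
    stats::fisher.test(tab)
  } else {
    stats::chisq.test(tab, correct = FALSE)
  }
}

#' Allelism test on F2 phenotypes
#'
#' When two mutant parents carry allelic mutations, the F2 of their cross
#' should show zero wild-type (complementation) segregants. The test flags
#' consistency with allelism and reports the largest complementation-model
#' segregation fraction excluded at the given confidence: with x
#' exceptional segregants in n, the exact one-sided binomial upper bound
#' on the segregation fraction (for x = 0, solve (1-f)^n = alpha).
#'
#' @param n_mutant,n_wild F2 counts in the mutant and wild (exceptional)
#'   classes.
#' @param tolerance number of exceptional segregants still scored
#'   consistent (phenotyping-error allowance; default 0).
#' @param alpha confidence level for the exclusion bound (default 0.05).
#' @return list with `consistent` flag, `n`, `n_wild`,
#'   `mutant_fraction`, `max_excluded_fraction`.
#' @examples
#' allelism_test(100, 0)  # consistent; excludes fractions >= ~0.0295
#' @export
allelism_test <- function(n_mutant, n_wild, tolerance = 0, alpha = 0.05) {
  n <- n_mutant + n_wild
  if (n == 0) stop("n = 0: no segregants scored", call. = FALSE)
  upper <- stats::qbeta(1 - alpha, n_wild + 1, n - n_wild)
  list(consistent = n_wild <= tolerance, n = n, n_wild = n_wild,
       mutant_fraction = n_mutant / n,
       max_excluded_fraction = upper)
}
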