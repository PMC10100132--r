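## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' All stochastic operations in the package take an explicit integer seed and
#' restore the caller's RNG state afterwards, so simulations never perturb a
#' user's session and identical seeds give identical output.
#'
#' @param seed integer scalar; required (reproducibility is mandatory).
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || is.na(seed) || !is.numeric(seed)) {
    stop("a single integer 'seed' is required", call. = FALSE)
  }
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## scalar checks -------------------------------------------------------------

stopifnot_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

stopifnot_prop <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

## stable TSV writer: fixed formatting so identical inputs are byte-identical
write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
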