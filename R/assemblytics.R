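#' Parse an Assemblytics-dialect SV call table
#'
#' Reads the tab-separated variant table produced by assembly-vs-reference
#' InDel calling for one accession (header line, optionally prefixed with
#' `#`; columns for reference, reference start/stop, call ID, size, strand,
#' type, reference/query gap sizes, query coordinates and method) and
#' returns one variant-allele row per retained call.
#'
#' Types are normalized to the six-type vocabulary (`insertion`, `deletion`,
#' `repeat_expansion`, `repeat_contraction`, `tandem_expansion`,
#' `tandem_contraction`); rows of other types are dropped with a message.
#' Coordinates are converted from the table's 1-based inclusive convention
#' to 0-based half-open: deletions span `start < end`; pure insertions have
#' `start == end`. Rows with non-positive size are dropped with a message.
#'
#' @param path path to the TSV file.
#' @param accession accession identifier attached to every returned allele.
#' @return data.frame of variant alleles with columns `accession`, `chrom`,
#'   `start`, `end`, `type`, `size`.
#' @export
parse_assemblytics <- function(path, accession) {
  header <- readLines(path, n = 1L)
  header <- sub("^#\\s*", "", header)
  cols <- strsplit(header, "\t")[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, comment.char = "",
                          stringsAsFactors = FALSE)
  req <- c("reference", "ref_start", "ref_stop", "size", "type")
  missing_cols <- setdiff(req, cols)
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(empty_alleles())
  }

  type_map <- c(Insertion = "insertion", Deletion = "deletion",
                Repeat_expansion = "repeat_expansion",
                Repeat_contraction = "repeat_contraction",
                Tandem_expansion = "tandem_expansion",
                Tandem_contraction = "tandem_contraction")
  known <- df$type %in% names(type_map)
  if (any(!known)) {
    message(sum(!known), " row(s) of non-InDel-convertible types dropped")
  }
  bad_size <- known & df$size < 1
  if (any(bad_size)) {
    message(sum(bad_size), " row(s) with non-positive size dropped")
  }
  df <- df[known & !bad_size, , drop = FALSE]
  if (nrow(df) == 0L) return(empty_alleles())

  type <- unname(type_map[df$type])
  ins_like <- type %in% c("insertion", "repeat_expansion", "tandem_expansion")
  start <- df$ref_start - 1L                     # 0-based half-open
  end <- ifelse(ins_like, start, df$ref_stop)
  out <- data.frame(accession = accession, chrom = df$reference,
                    start = as.integer(start), end = as.integer(end),
                    type = type, size = as.integer(df$size),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_alleles <- function() {
  data.frame(accession = character(), chrom = character(),
             start = integer(), end = integer(),
             type = character(), size = integer(),
             stringsAsFactors = FALSE)
}

#' Filter variant alleles by structural-variant size class
#'
#' `short_indel` keeps alleles with sizes inside the PCR-markerable range
#' (15-2000 bp by default, both bounds inclusive); `large_sv` keeps alleles
#' strictly larger than the upper bound. Input order is preserved.
#'
#' @param alleles data.frame as returned by [parse_assemblytics()].
#' @param sv_class `"short_indel"` or `"large_sv"`.
#' @param min_size,max_size bounds of the short-InDel class in bp.
#' @return the retained subset, original row order.
#' @export
filter_by_size <- function(alleles, sv_class = c("short_indel", "large_sv"),
                           min_size = 15, max_size = 2000) {
  sv_class <- match.arg(sv_class)
  keep <- if (sv_class == "short_indel") {
    alleles$size >= min_size & alleles$size <= max_size
  } else {
    alleles$size > max_size
  }
  out <- alleles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
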