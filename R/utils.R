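# Shared containers and plain-text readers/writers.
#
# All tabular interchange is tab-separated text; matrices carry a '#scale='
# header line so the FOT / log2FOT state survives a round trip.

#' Construct an abundance matrix
#'
#' Container for quantitative omics matrices: features in rows, samples in
#' columns, plus a scale tag and a missingness mask. On the FOT scale values
#' are fractions of total iBAQ multiplied by 1e5 and floored at 1e-5; on the
#' log2FOT scale values are log2-transformed after imputation.
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param scale one of "FOT" or "log2FOT".
#' @param missing logical matrix of the same shape marking entries that were
#'   not observed (imputed or absent). Defaults to `is.na(values)`.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, scale = c("FOT", "log2FOT"),
                             missing = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values)) stop("values must be a matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("values must have feature rownames and sample colnames")
  if (is.null(missing)) missing <- is.na(values)
  if (!identical(dim(missing), dim(values)))
    stop("missing mask must match values in shape")
  structure(list(values = values, scale = scale,
                 missing = missing),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d features x %d samples [%s], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Write an abundance matrix as TSV
#'
#' The first line is `#scale=<scale>`; missing entries are written as NA.
#'
#' @param am an `abundance_matrix`.
#' @param path output file.
#' @export
write_abundance_tsv <- function(am, path) {
  stopifnot(inherits(am, "abundance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scale=%s", am$scale), con)
  v <- am$values
  v[am$missing & am$scale == "FOT"] <- NA
  df <- data.frame(feature = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(format(df, digits = 15, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Read an abundance matrix written by [write_abundance_tsv()]
#' @param path input file.
#' @return an `abundance_matrix`.
#' @export
read_abundance_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- sub("^#scale=", "", first)
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df$feature
  abundance_matrix(v, scale = scale)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: tab-separated lines `name<TAB>description<TAB>members...`.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) character(0) else unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
}

#' Read a SEG-style segment table
#'
#' Expects columns sample, chrom, start, end, log2_ratio. External SEG files
#' are conventionally 1-based inclusive and are converted to the package's
#' 0-based half-open convention on read; files written by this package carry
#' a `#coords=0based` header and are read back unchanged.
#'
#' @param path input TSV.
#' @return data.frame with 0-based half-open `start`, `end`.
#' @export
read_segments <- function(path) {
  first <- readLines(path, n = 1L)
  zero_based <- identical(first, "#coords=0based")
  df <- read.table(path, sep = "\t", header = TRUE,
                   skip = if (zero_based) 1L else 0L,
                   stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(df)))
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  if (!zero_based) {
    df$start <- df$start - 1L  # 1-based inclusive -> 0-based half-open
  }
  df
}

#' Write a segment table (0-based half-open, self-describing header)
#' @param segments data.frame with sample, chrom, start, end, log2_ratio.
#' @param path output file.
#' @export
write_segments <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords=0based", con)
  write.table(segments, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

# deterministic per-stage seed derivation from one top-level seed;
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, stage) {
  offsets <- c(cohort = 1L, split = 2L, cv = 3L, nes = 4L, nmf = 5L,
               misc = 6L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off * 7919) %% 2147483647)
}

# stable two-sided binomial-style check helper used in tests (not exported)
.clamp01 <- function(x) pmin(pmax(x, 0), 1)
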