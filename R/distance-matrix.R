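#' Construct a validated distance matrix
#'
#' A `mcnet_dist` object is a full (square, symmetric) matrix of pairwise
#' dissimilarities with taxon labels as `dimnames`. All downstream functions
#' (ordering search, split weighting) take this object as input.
#'
#' @param values numeric n x n matrix of pairwise dissimilarities. Small
#'   asymmetries (up to `asym_tol`) are averaged away; larger ones are an
#'   error, since they indicate corrupted input rather than rounding.
#' @param labels character vector of n unique taxon names. Defaults to the
#'   rownames of `values`, or `t1..tn` when absent.
#' @param asym_tol maximum tolerated absolute asymmetry before erroring.
#' @return a `mcnet_dist` object (a classed numeric matrix).
#' @examples
#' d <- distance_matrix(rbind(c(0, 1, 2, 1), c(1, 0, 1, 2),
#'                            c(2, 1, 0, 1), c(1, 2, 1, 0)),
#'                      labels = c("a", "b", "c", "d"))
#' tour_energy(d, 1:4)
#' @export
distance_matrix <- function(values, labels = NULL, asym_tol = 1e-6) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) != ncol(values)) {
    stop("`values` must be a square numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  if (n < 4L) stop("at least 4 taxa are required, got ", n, call. = FALSE)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("t", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("`labels` has length ", length(labels), " but matrix has ", n,
         " rows", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("distance matrix contains NA values", call. = FALSE)
  asym <- max(abs(values - t(values)))
  if (asym > asym_tol) {
    stop("distance matrix is asymmetric (max |d_ij - d_ji| = ",
         format(asym), ")", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (any(abs(diag(values)) > 1e-9)) {
    stop("diagonal entries must be zero", call. = FALSE)
  }
  diag(values) <- 0
  if (any(values < 0)) stop("distances must be non-negative", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  class(values) <- c("mcnet_dist", "matrix", "array")
  values
}

#' @export
print.mcnet_dist <- function(x, ...) {
  cat("Distance matrix over", nrow(x), "taxa\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Number of taxa of a distance matrix
#' @param d a `mcnet_dist` object.
#' @return integer number of taxa.
#' @export
n_taxa <- function(d) nrow(d)

#' Taxon labels of a distance matrix
#' @param d a `mcnet_dist` object.
#' @return character vector of labels.
#' @export
taxa_labels <- function(d) rownames(d)

is_dist <- function(d) inherits(d, "mcnet_dist")

check_dist <- function(d) {
  if (!is_dist(d)) stop("expected a `mcnet_dist` distance matrix", call. = FALSE)
  invisible(d)
}

#' Read a distance matrix from PHYLIP or NEXUS
#'
#' Reads a square PHYLIP distance matrix (count line followed by one labelled
#' row per taxon, whitespace-delimited or with strict 10-character labels), or
#' a NEXUS file with TAXA and DISTANCES blocks (`triangle=both` or `lower`).
#'
#' @param path path to the input file.
#' @param format `"phylip"`, `"nexus"`, or `"auto"` (sniffs a `#NEXUS` header
#'   versus a leading taxon count).
#' @return a [distance_matrix()] object, labels in file order.
#' @export
read_distance_matrix <- function(path, format = c("auto", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- grep("\\S", lines, value = TRUE)[1]
    if (is.na(first)) stop("empty file: ", path, call. = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE))
      "nexus" else "phylip"
  }
  switch(format,
         phylip = parse_phylip_dist(lines, path),
         nexus  = parse_nexus_dist(lines, path))
}

parse_phylip_dist <- function(lines, path) {
  lines <- lines[grepl("\\S", lines)]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1]))
  if (is.na(n)) {
    stop("parse error in ", path,
         ", line 1: expected the number of taxa", call. = FALSE)
  }
  body <- lines[-1]
  # One labelled row per taxon; a row's values may wrap onto following lines.
  labels <- character(n)
  vals <- matrix(NA_real_, n, n)
  li <- 0L
  for (i in seq_len(n)) {
    li <- li + 1L
    if (li > length(body)) {
      stop("parse error in ", path, ": expected ", n,
           " matrix rows, found ", i - 1L, call. = FALSE)
    }
    hdr <- phylip_row_tokens(body[li])
    labels[i] <- hdr[1]
    toks <- hdr[-1]
    while (length(toks) < n && li < length(body)) {
      li <- li + 1L
      toks <- c(toks, strsplit(trimws(body[li]), "\\s+")[[1]])
    }
    if (length(toks) != n) {
      stop("parse error in ", path, ", matrix row ", i, " ('", labels[i],
           "'): expected ", n, " values, found ", length(toks), call. = FALSE)
    }
    row <- suppressWarnings(as.numeric(toks))
    if (anyNA(row)) {
      stop("parse error in ", path, ", matrix row ", i, " ('", labels[i],
           "'): non-numeric value '", toks[which(is.na(row))[1]], "'",
           call. = FALSE)
    }
    vals[i, ] <- row
  }
  distance_matrix(vals, labels)
}

# Split a PHYLIP matrix row into label + value tokens, accepting both
# whitespace-delimited labels and the strict 10-character label field
# (which may itself contain spaces).
phylip_row_tokens <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(toks) >= 2 &&
      !is.na(suppressWarnings(as.numeric(toks[2])))) {
    return(toks)
  }
  # strict width: first 10 characters are the label
  if (nchar(line) > 10) {
    lab <- trimws(substr(line, 1, 10))
    rest <- strsplit(trimws(substr(line, 11, nchar(line))), "\\s+")[[1]]
    if (nzchar(lab) && length(rest)) return(c(lab, rest))
  }
  toks
}

parse_nexus_dist <- function(lines, path) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", " ", txt)  # strip NEXUS comments
  lab <- nexus_taxlabels(txt)
  blk <- nexus_block(txt, "distances")
  if (is.null(blk)) stop("parse error in ", path,
                         ": no DISTANCES block", call. = FALSE)
  triangle <- "both"
  diagonal <- TRUE
  fmt <- regmatches(blk, regexpr("(?is)format[^;]*;", blk, perl = TRUE))
  if (length(fmt)) {
    tri <- regmatches(fmt, regexpr("(?i)triangle\\s*=\\s*\\w+", fmt, perl = TRUE))
    if (length(tri)) triangle <- tolower(sub("(?i)triangle\\s*=\\s*", "", tri, perl = TRUE))
    if (grepl("(?i)no\\s*diagonal", fmt, perl = TRUE)) diagonal <- FALSE
  }
  mat <- regmatches(blk, regexpr("(?is)matrix(.*?);", blk, perl = TRUE))
  if (!length(mat)) stop("parse error in ", path,
                         ": DISTANCES block has no MATRIX", call. = FALSE)
  mat <- sub("(?is)^matrix", "", mat, perl = TRUE)
  mat <- sub(";\\s*$", "", mat)
  rows <- strsplit(trimws(mat), "\n")[[1]]
  rows <- rows[grepl("\\S", rows)]
  labels <- character(0)
  rowvals <- list()
  for (r in rows) {
    toks <- nexus_row_tokens(r)
    labels <- c(labels, toks$label)
    rowvals <- c(rowvals, list(toks$values))
  }
  n <- length(labels)
  if (n < 4L) stop("parse error in ", path, ": fewer than 4 taxa", call. = FALSE)
  vals <- matrix(0, n, n)
  for (i in seq_len(n)) {
    v <- rowvals[[i]]
    expected <- switch(triangle,
                       both = n,
                       lower = if (diagonal) i else i - 1L,
                       upper = if (diagonal) n - i + 1L else n - i)
    if (length(v) != expected) {
      stop("parse error in ", path, ", matrix row ", i, " ('", labels[i],
           "'): expected ", expected, " values, found ", length(v),
           call. = FALSE)
    }
    if (triangle == "both") {
      vals[i, ] <- v
    } else if (triangle == "lower") {
      cols <- if (diagonal) seq_len(i) else seq_len(i - 1L)
      vals[i, cols] <- v
      vals[cols, i] <- v
    } else {
      cols <- if (diagonal) i:n else if (i < n) (i + 1L):n else integer(0)
      vals[i, cols] <- v
      vals[cols, i] <- v
    }
  }
  if (!is.null(lab) && !setequal(lab, labels)) {
    stop("parse error in ", path,
         ": DISTANCES row labels do not match TAXLABELS", call. = FALSE)
  }
  distance_matrix(vals, labels)
}

nexus_block <- function(txt, name) {
  pat <- paste0("(?is)begin\\s+", name, "\\s*;(.*?)end\\s*;")
  m <- regmatches(txt, regexpr(pat, txt, perl = TRUE))
  if (!length(m)) return(NULL)
  m[[1]]
}

nexus_taxlabels <- function(txt) {
  blk <- nexus_block(txt, "taxa")
  if (is.null(blk)) return(NULL)
  m <- regmatches(blk, regexpr("(?is)taxlabels(.*?);", blk, perl = TRUE))
  if (!length(m)) return(NULL)
  body <- sub("(?is)^taxlabels", "", m, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  toks <- regmatches(body, gregexpr("'[^']*'|\\S+", body))[[1]]
  gsub("^'|'$", "", toks)
}

nexus_row_tokens <- function(row) {
  row <- trimws(row)
  if (startsWith(row, "'")) {
    end <- regexpr("'", substring(row, 2), fixed = TRUE)
    label <- substr(row, 2, end)
    rest <- substring(row, end + 2)
  } else {
    sp <- regexpr("\\s", row)
    label <- if (sp > 0) substr(row, 1, sp - 1) else row
    rest <- if (sp > 0) substring(row, sp + 1) else ""
  }
  toks <- strsplit(trimws(rest), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    stop("parse error: non-numeric value '", toks[which(is.na(vals))[1]],
         "' in row '", label, "'", call. = FALSE)
  }
  list(label = label, values = vals)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d a `mcnet_dist` object.
#' @param path output path.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(d, path, digits = 10) {
  check_dist(d)
  n <- n_taxa(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  for (i in seq_len(n)) {
    writeLines(paste(c(taxa_labels(d)[i],
                       formatC(d[i, ], digits = digits, format = "g")),
                     collapse = " "), con)
  }
  invisible(path)
}
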