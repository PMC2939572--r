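#' Write a weighted split system as a SplitsTree-readable NEXUS file
#'
#' Emits a TAXA block and a SPLITS block in the SplitsTree4 dialect: a
#' FORMAT line, a CYCLE statement giving the circular ordering as 1-based
#' taxon indices, and a MATRIX with one row per split (weight followed by
#' the 1-based member indices of the side containing taxon 1). SplitsTree4
#' can open the file directly and draw the split network.
#'
#' @param system an `mcnet_splits` object; all weights must be positive
#'   (apply [filter_splits()] first).
#' @param path output path.
#' @param digits significant digits for weights.
#' @return `path`, invisibly.
#' @export
write_splits_nexus <- function(system, path, digits = 12) {
  stopifnot(inherits(system, "mcnet_splits"))
  if (length(system$weights) && any(system$weights <= 0)) {
    stop("all split weights must be positive; run filter_splits() first",
         call. = FALSE)
  }
  labels <- system$labels
  n <- length(labels)
  if (length(system$cycle) != n) {
    stop("cycle length does not match the taxon set", call. = FALSE)
  }
  ns <- length(system$splits)
  out <- c(
    "#NEXUS",
    "",
    "BEGIN Taxa;",
    sprintf("DIMENSIONS ntax=%d;", n),
    "TAXLABELS",
    sprintf("[%d] '%s'", seq_len(n), labels),
    ";",
    "END; [Taxa]",
    "",
    "BEGIN Splits;",
    sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, ns),
    "FORMAT labels=no weights=yes confidences=no intervals=no;",
    sprintf("CYCLE %s;", paste(system$cycle, collapse = " ")),
    "MATRIX"
  )
  if (ns) {
    rows <- vapply(seq_len(ns), function(k) {
      side <- setdiff(seq_len(n), system$splits[[k]])  # the side with taxon 1
      sprintf("[%d, size=%d] \t %s \t %s,", k, length(side),
              formatC(system$weights[k], digits = digits, format = "g"),
              paste(side, collapse = " "))
    }, character(1))
    out <- c(out, rows)
  }
  out <- c(out, ";", "END; [Splits]")
  writeLines(out, path)
  invisible(path)
}

#' Read a weighted split system from a NEXUS SPLITS block
#'
#' Counterpart of [write_splits_nexus()]; parses the TAXA and SPLITS blocks
#' (FORMAT, CYCLE, weighted MATRIX) and returns the split system in the
#' package's canonical form. No design matrix or distance vector is attached
#' (the file does not carry the input distances).
#'
#' @param path path to a NEXUS file with TAXA and SPLITS blocks.
#' @return an `mcnet_splits` object with `splits`, `weights`, `cycle`, and
#'   `labels` (`design`/`dvec` set to `NULL`).
#' @export
read_splits_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", " ", txt)
  labels <- nexus_taxlabels(txt)
  if (is.null(labels)) stop("parse error in ", path, ": no TAXA block",
                            call. = FALSE)
  n <- length(labels)
  blk <- nexus_block(txt, "splits")
  if (is.null(blk)) stop("parse error in ", path, ": no SPLITS block",
                         call. = FALSE)
  cyc <- regmatches(blk, regexpr("(?is)cycle[^;]*;", blk, perl = TRUE))
  cycle <- if (length(cyc)) {
    as.integer(strsplit(trimws(gsub("(?is)cycle|;", " ", cyc, perl = TRUE)),
                        "\\s+")[[1]])
  } else seq_len(n)
  mat <- regmatches(blk, regexpr("(?is)matrix(.*?);", blk, perl = TRUE))
  if (!length(mat)) stop("parse error in ", path,
                         ": SPLITS block has no MATRIX", call. = FALSE)
  body <- sub("(?is)^matrix", "", mat, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(trimws(body), ",")[[1]]
  rows <- rows[grepl("\\S", rows)]
  splits <- vector("list", length(rows))
  weights <- numeric(length(rows))
  for (k in seq_along(rows)) {
    toks <- strsplit(trimws(rows[k]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      stop("parse error in ", path, ": non-numeric token in split row ", k,
           call. = FALSE)
    }
    weights[k] <- vals[1]
    splits[[k]] <- canonical_split(as.integer(vals[-1]), n)
  }
  structure(list(splits = splits, weights = weights,
                 cycle = canonical_ordering(cycle),
                 design = NULL, dvec = NULL, labels = labels),
            class = "mcnet_splits")
}
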