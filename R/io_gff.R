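#' Read a GFF3 file into a feature table
#'
#' Returns a plain data frame ("FeatureTable") with one row per feature and
#' columns `seqid, source, type, start, end, score, strand, phase,
#' attributes, ID, Parent, dangling_parent`. Coordinates are kept verbatim
#' in GFF3 convention (1-based, inclusive); this is the single coordinate
#' convention used throughout the package. A feature whose `Parent`
#' attribute names an ID absent from the file is flagged via
#' `dangling_parent = TRUE` rather than dropped.
#'
#' @param path path to a GFF3 file.
#' @return a data frame of class `FeatureTable`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 9L)) {
    bad <- keep[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated columns, got %d",
                 bad, nfield[which(nfield != 9L)[1L]]))
  }
  if (!length(keep)) {
    out <- data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      phase = character(), attributes = character(),
                      ID = character(), Parent = character(),
                      dangling_parent = logical(), stringsAsFactors = FALSE)
    class(out) <- c("FeatureTable", "data.frame")
    return(out)
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- keep[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("malformed GFF3 line %d: non-numeric coordinate", bad))
  }
  if (any(start > end)) {
    bad <- keep[which(start > end)[1L]]
    stop(sprintf("invalid GFF3 line %d: start > end", bad))
  }
  attr_field <- m[, 9L]
  get_attr <- function(a, key) {
    hit <- regmatches(a, regexpr(sprintf("(^|;)\\s*%s=[^;]*", key), a))
    if (!length(hit)) return(NA_character_)
    sub(sprintf("^.*%s=", key), "", hit)
  }
  ids <- vapply(attr_field, get_attr, "", key = "ID", USE.NAMES = FALSE)
  parents <- vapply(attr_field, get_attr, "", key = "Parent",
                    USE.NAMES = FALSE)
  out <- data.frame(seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
                    start = start, end = end, score = m[, 6L],
                    strand = m[, 7L], phase = m[, 8L],
                    attributes = attr_field, ID = ids, Parent = parents,
                    stringsAsFactors = FALSE)
  out$dangling_parent <- !is.na(out$Parent) &
    !vapply(strsplit(out$Parent, ",", fixed = TRUE),
            function(p) all(p %in% ids), logical(1L))
  class(out) <- c("FeatureTable", "data.frame")
  out
}

#' Write a feature table as GFF3
#'
#' @param ft a `FeatureTable` (see [read_gff3()]).
#' @param path output path.
#' @export
write_gff3 <- function(ft, path) {
  stopifnot(is.data.frame(ft))
  lines <- c("##gff-version 3",
             paste(ft$seqid, ft$source, ft$type, ft$start, ft$end, ft$score,
                   ft$strand, ft$phase, ft$attributes, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Convert feature intervals to BED text (0-based half-open)
#'
#' The only place in the package where coordinates leave the 1-based
#' inclusive convention.
#'
#' @param ft a `FeatureTable` or data frame with `seqid`, `start`, `end`
#'   (1-based inclusive) and optionally `ID`/`strand`.
#' @param path output path.
#' @export
write_bed <- function(ft, path) {
  name <- if (!is.null(ft$ID)) ifelse(is.na(ft$ID), ".", ft$ID) else "."
  strand <- if (!is.null(ft$strand)) ft$strand else "."
  lines <- paste(ft$seqid, ft$start - 1L, ft$end, name, 0L, strand,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
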