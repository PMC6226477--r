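#' Write pG4 hits as BED6
#'
#' One line per hit, 0-based half-open coordinates, name `pG4`, score =
#' number of G tracts, strand `+` (transcript-space scans are on the given
#' strand).
#'
#' @param hits Hit table from [scan_pg4()].
#' @param path Output file.
#' @param strand Strand character recorded for every hit.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path, strand = "+") {
  if (nrow(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- vapply(hits$tract_starts, length, 0L)
  lines <- sprintf("%s\t%d\t%d\tpG4\t%d\t%s",
                   hits$transcript_id, hits$start, hits$end, score, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of motif intervals
#'
#' Inverse of [write_bed()] for the interval fields; list columns
#' (tract starts, loop lengths) are not stored in BED and come back empty.
#'
#' @param path BED file.
#' @return data.frame with `transcript_id`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 6L))
    stop("malformed BED6 line (fewer than 6 fields)")
  data.frame(
    transcript_id = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    name = vapply(parts, `[[`, "", 4L),
    score = as.integer(vapply(parts, `[[`, "", 5L)),
    strand = vapply(parts, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
}
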