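#' Parse a nucmer show-coords table of assembly-to-reference hits
#'
#' Reads the tab-separated `show-coords -T` dialect: columns S1, E1, S2, E2,
#' LEN1, LEN2, %IDY, ref_id, qry_id. Header and preamble lines (anything
#' whose first field is not a number) are tolerated and skipped. Reference
#' coordinates are 1-based inclusive on the forward strand; a hit with
#' S2 > E2 aligns the query in reverse, which leaves the reference interval
#' unaffected.
#'
#' @param path Path to the coords table, or a character vector of its lines.
#' @return A data.frame of alignment hits: `ref_id`, `ref_start`, `ref_end`
#'   (1-based inclusive), `qry_id`, `qry_start`, `qry_end`, `len1`, `len2`,
#'   `pct_identity`, `qry_reversed`.
#' @export
parse_coords <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path)
  } else {
    as.character(path)
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (suppressWarnings(is.na(as.numeric(fields[1L])))) next  # header
    if (length(fields) < 9L) {
      stop("coords line ", i, ": expected 9 tab-separated columns, got ",
           length(fields))
    }
    num <- suppressWarnings(as.numeric(fields[1:7]))
    if (anyNA(num)) {
      stop("coords line ", i, ": non-numeric coordinate field")
    }
    rows[[i]] <- data.frame(
      ref_id = fields[8L], ref_start = as.integer(num[1L]),
      ref_end = as.integer(num[2L]), qry_id = fields[9L],
      qry_start = as.integer(num[3L]), qry_end = as.integer(num[4L]),
      len1 = as.integer(num[5L]), len2 = as.integer(num[6L]),
      pct_identity = num[7L], stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits) || nrow(hits) == 0L) stop("no alignment hits in input")
  if (any(hits$ref_start > hits$ref_end)) {
    stop("reference interval with start > end (reference coordinates are ",
         "always forward-strand)")
  }
  if (any(hits$ref_start < 1L)) stop("reference coordinates are 1-based")
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("percent identity outside [0, 100]")
  }
  hits$qry_reversed <- hits$qry_start > hits$qry_end
  rownames(hits) <- NULL
  hits
}

#' Serialise alignment hits back to the show-coords tab dialect
#'
#' @param hits A data.frame as returned by [parse_coords()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(hits, path) {
  header <- c("assembly reference", "NUCMER", "",
              paste("[S1]", "[E1]", "[S2]", "[E2]", "[LEN 1]", "[LEN 2]",
                    "[% IDY]", "[TAGS]", sep = "\t"))
  body <- sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
                  hits$ref_start, hits$ref_end, hits$qry_start,
                  hits$qry_end, hits$len1, hits$len2, hits$pct_identity,
                  hits$ref_id, hits$qry_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Merge overlapping reference hits of each assembly contig
#'
#' Hits are grouped by (query contig, reference sequence); within a group,
#' intervals sharing at least one base are merged transitively into their
#' union. Bookended intervals (0 bases shared) are not merged. Hits from the
#' same query to different reference sequences stay separate, and intervals
#' derived from different queries are never merged, even when identical.
#' Each maximal merged interval becomes one artificial-contig interval.
#'
#' @param hits A data.frame of hits from [parse_coords()] (only `qry_id`,
#'   `ref_id`, `ref_start`, `ref_end` are used).
#' @return A data.frame of intervals sorted by (qry_id, ref_id, ref_start):
#'   `contig_id` (`<qry_id>.<serial>`, serials in that order), `qry_id`,
#'   `ref_id`, `ref_start`, `ref_end` (0-based half-open).
#' @export
merge_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) stop("no hits to merge")
  groups <- split(hits, list(hits$qry_id, hits$ref_id), drop = TRUE)
  out <- lapply(groups, function(h) {
    r <- IRanges::reduce(IRanges::IRanges(start = h$ref_start,
                                          end = h$ref_end),
                         min.gapwidth = 0L)
    data.frame(qry_id = h$qry_id[1L], ref_id = h$ref_id[1L],
               ref_start = IRanges::start(r) - 1L,
               ref_end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$qry_id, out$ref_id, out$ref_start), , drop = FALSE]
  serial <- stats::ave(seq_len(nrow(out)), out$qry_id,
                       FUN = seq_along)
  out <- cbind(contig_id = sprintf("%s.%d", out$qry_id, serial), out)
  rownames(out) <- NULL
  out
}

#' Cut artificial contigs out of the reference
#'
#' Each merged interval yields the forward-strand reference substring, so an
#' artificial contig is always an exact, error-free slice of the reference
#' regardless of the orientation of the original alignment.
#'
#' @param intervals Intervals from [merge_hits()] (columns `contig_id`,
#'   `ref_id`, `ref_start`, `ref_end`; 0-based half-open).
#' @param reference Reference sequences, see [as_seq_set()].
#' @return A list with `contigs` (`DNAStringSet`) and `placements`
#'   (data.frame: contig_id, ref_id, ref_start, ref_end).
#' @export
extract_contigs <- function(intervals, reference) {
  reference <- as_seq_set(reference)
  missing <- setdiff(intervals$ref_id, names(reference))
  if (length(missing)) {
    stop("intervals refer to unknown reference sequence(s): ",
         paste(missing, collapse = ", "))
  }
  len <- Biostrings::width(reference)[match(intervals$ref_id,
                                            names(reference))]
  if (any(intervals$ref_start < 0L | intervals$ref_end > len |
            intervals$ref_start >= intervals$ref_end)) {
    stop("interval exceeds reference bounds")
  }
  contigs <- Biostrings::DNAStringSet(
    mapply(function(rid, s, e) {
      Biostrings::subseq(reference[[rid]], start = s + 1L, end = e)
    }, intervals$ref_id, intervals$ref_start, intervals$ref_end,
    SIMPLIFY = FALSE))
  names(contigs) <- intervals$contig_id
  placements <- intervals[, c("contig_id", "ref_id", "ref_start", "ref_end")]
  rownames(placements) <- NULL
  list(contigs = contigs, placements = placements)
}

#' Build artificial contigs from a coords table and the reference
#'
#' Convenience pipeline: [parse_coords()] (unless `hits` is already a
#' data.frame), [merge_hits()], [extract_contigs()]. Assembly contigs with
#' no alignment hit cannot produce an artificial contig; when `query_ids`
#' is supplied, such contigs are dropped with a warning.
#'
#' @param hits Path to a show-coords table or a parsed hits data.frame.
#' @param reference Reference sequences.
#' @param query_ids Optional: all assembly contig ids, used to warn about
#'   contigs without any hit.
#' @return As [extract_contigs()].
#' @export
artificial_contigs <- function(hits, reference, query_ids = NULL) {
  if (!is.data.frame(hits)) hits <- parse_coords(hits)
  if (!is.null(query_ids)) {
    lost <- setdiff(query_ids, unique(hits$qry_id))
    if (length(lost)) {
      warning(length(lost), " assembly contig(s) had no reference hit and ",
              "were dropped: ", paste(lost, collapse = ", "))
    }
  }
  extract_contigs(merge_hits(hits), reference)
}
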