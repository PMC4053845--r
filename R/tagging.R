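#' Default tag length ladder
#'
#' Candidate tag lengths tried in order until a tag is found that occurs
#' exactly once in the contig set and exactly once in the reference.
#'
#' @return Integer vector of tag lengths in bp.
#' @export
default_tag_ladder <- function() {
  c(50L, 100L, 200L, 400L, 600L, 1000L, 2000L, 5000L)
}

.check_ladder <- function(ladder) {
  ladder <- as.integer(ladder)
  if (length(ladder) == 0L || any(ladder <= 0L) ||
        any(diff(ladder) <= 0L)) {
    stop("tag length ladder must be strictly increasing and positive")
  }
  ladder
}

#' Centered candidate tag of a contig
#'
#' The candidate of length l is the contig slice starting at
#' `floor((len - l) / 2)` (left-biased on odd remainders); for l equal to
#' the contig length this is the whole contig.
#'
#' @param contig A single sequence (character, `DNAString` or a length-one
#'   `DNAStringSet`).
#' @param length Tag length in bp; must not exceed the contig length.
#' @return A list with `offset` (0-based) and `bases`.
#' @export
candidate_tag <- function(contig, length) {
  contig <- .as_single_sequence(contig)
  n <- Biostrings::nchar(contig)
  if (length > n) {
    stop("candidate tag length (", length, ") exceeds contig length (",
         n, "); tag ladder exhausted for this contig")
  }
  offset <- (n - as.integer(length)) %/% 2L
  list(offset = offset,
       bases = as.character(Biostrings::subseq(contig, start = offset + 1L,
                                               width = length)))
}

#' Find the smallest unique sequence tag of one contig
#'
#' Walks the length ladder; at each rung the centered candidate is searched
#' exactly (both strands) against the whole contig set and against the
#' reference, and kept when it occurs exactly once in each — the contig's
#' own locus. Rungs longer than the contig are skipped; when the contig is
#' shorter than the first rung, the whole contig is tried as the candidate.
#' A reverse-complement-palindromic candidate matches its own locus on both
#' strands and therefore fails uniqueness and escalates the ladder.
#'
#' @param contig_id Id of the contig to tag; must be present in `contigs`.
#' @param contigs All contigs of the dataset (`DNAStringSet`).
#' @param reference Reference sequences (`DNAStringSet`).
#' @param ladder Tag length ladder, see [default_tag_ladder()].
#' @return A list with `tag_offset`, `tag_length`, `tag_bases`, or `NULL`
#'   when no ladder length yields a unique tag.
#' @export
find_unique_tag <- function(contig_id, contigs, reference,
                            ladder = default_tag_ladder()) {
  contigs <- as_seq_set(contigs)
  reference <- as_seq_set(reference)
  ladder <- .check_ladder(ladder)
  if (!contig_id %in% names(contigs)) {
    stop("contig ", contig_id, " not found in the contig set")
  }
  contig <- contigs[[contig_id]]
  n <- Biostrings::nchar(contig)
  lengths <- ladder[ladder <= n]
  if (length(lengths) == 0L) lengths <- n
  for (l in lengths) {
    cand <- candidate_tag(contig, l)
    if (grepl("N", cand$bases, fixed = TRUE)) next  # tags must be ungapped
    in_contigs <- nrow(count_occurrences(cand$bases, contigs,
                                         both_strands = TRUE))
    if (in_contigs != 1L) next
    in_ref <- nrow(count_occurrences(cand$bases, reference,
                                     both_strands = TRUE))
    if (in_ref != 1L) next
    return(list(tag_offset = cand$offset, tag_length = as.integer(l),
                tag_bases = cand$bases))
  }
  NULL
}

#' Tag every contig of a dataset
#'
#' Applies [find_unique_tag()] to each placed contig. Contigs for which no
#' ladder length yields a unique tag are excluded from the evaluation set
#' with a warning; exclusion happens before scaffolding input is written, so
#' potential-join accounting stays consistent.
#'
#' @param contigs Contigs to tag (`DNAStringSet`).
#' @param reference Reference sequences (`DNAStringSet`).
#' @param placements data.frame with `contig_id`, `ref_id`, `ref_start`
#'   (0-based start of the contig on the reference forward strand), as
#'   produced by [tile_reference()] or [extract_contigs()].
#' @param ladder Tag length ladder.
#' @return The tag manifest: a data.frame with `contig_id`, `tag_offset`,
#'   `tag_length`, `ref_id`, `ref_tag_start` (0-based start of the tag on
#'   the reference) and `tag_bases`; excluded contig ids in attribute
#'   `"excluded"`.
#' @export
tag_contigs <- function(contigs, reference, placements,
                        ladder = default_tag_ladder()) {
  contigs <- as_seq_set(contigs)
  reference <- as_seq_set(reference)
  stopifnot(all(c("contig_id", "ref_id", "ref_start") %in%
                  colnames(placements)))
  if (anyDuplicated(placements$contig_id)) {
    stop("duplicate contig_id in placements")
  }
  missing <- setdiff(placements$contig_id, names(contigs))
  if (length(missing)) {
    stop("placements refer to contigs absent from the set: ",
         paste(missing, collapse = ", "))
  }
  rows <- vector("list", nrow(placements))
  excluded <- character(0)
  for (i in seq_len(nrow(placements))) {
    cid <- placements$contig_id[i]
    tag <- find_unique_tag(cid, contigs, reference, ladder)
    if (is.null(tag)) {
      excluded <- c(excluded, cid)
      next
    }
    rows[[i]] <- data.frame(
      contig_id = cid, tag_offset = tag$tag_offset,
      tag_length = tag$tag_length, ref_id = placements$ref_id[i],
      ref_tag_start = placements$ref_start[i] + tag$tag_offset,
      tag_bases = tag$tag_bases, stringsAsFactors = FALSE)
  }
  if (length(excluded)) {
    warning("no unique tag at any ladder length; excluded from the ",
            "evaluation set: ", paste(excluded, collapse = ", "))
  }
  manifest <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(manifest)) stop("no contig could be tagged")
  rownames(manifest) <- NULL
  attr(manifest, "excluded") <- excluded
  manifest
}

#' Assemble the truth layout from a tag manifest
#'
#' Orders tags along each reference sequence and computes the number of
#' potential joins: each reference sequence represented by n tags
#' contributes n - 1 adjacencies, so potential_joins = n_tags - n_sequences.
#'
#' @param manifest data.frame with at least `contig_id`, `ref_id`,
#'   `ref_tag_start`; extra columns are carried through.
#' @return A `truth_layout` list: `tags` (the manifest sorted by
#'   (ref_id, ref_tag_start) with a 0-based `layout_index` per sequence),
#'   `n_tags`, `n_sequences`, `potential_joins`.
#' @export
build_truth_layout <- function(manifest) {
  stopifnot(all(c("contig_id", "ref_id", "ref_tag_start") %in%
                  colnames(manifest)))
  if (anyDuplicated(manifest$contig_id)) {
    stop("duplicate contig_id in tag manifest")
  }
  tags <- manifest[order(manifest$ref_id, manifest$ref_tag_start), ,
                   drop = FALSE]
  tags$layout_index <- stats::ave(seq_len(nrow(tags)), tags$ref_id,
                                  FUN = seq_along) - 1L
  rownames(tags) <- NULL
  n_tags <- nrow(tags)
  n_sequences <- length(unique(tags$ref_id))
  structure(list(tags = tags, n_tags = n_tags, n_sequences = n_sequences,
                 potential_joins = n_tags - n_sequences),
            class = "truth_layout")
}

#' @export
print.truth_layout <- function(x, ...) {
  cat("truth layout:", x$n_tags, "tags on", x$n_sequences,
      "reference sequence(s);", x$potential_joins, "potential joins\n")
  invisible(x)
}

#' Write a tag manifest (with layout indices) to TSV
#'
#' @param layout A `truth_layout` from [build_truth_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_manifest <- function(layout, path) {
  stopifnot(methods::is(layout, "truth_layout"))
  cols <- c("contig_id", "tag_offset", "tag_length", "ref_id",
            "ref_tag_start", "layout_index", "tag_bases")
  cols <- intersect(cols, colnames(layout$tags))
  utils::write.table(layout$tags[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tag manifest TSV and rebuild the truth layout
#'
#' @param path Path to a TSV written by [write_tag_manifest()].
#' @return A `truth_layout`.
#' @export
read_tag_manifest <- function(path) {
  tags <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_truth_layout(tags)
}
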