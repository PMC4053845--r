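#' Locate every tag in a set of scaffolds
#'
#' Each tag is searched exactly (both strands) across all scaffolds. A tag
#' with no occurrence is lost (its contig is completely absent from the
#' output, e.g. because a scaffolder broke the contig mid-tag). A tag with
#' several occurrences is placed deterministically at its leftmost
#' occurrence in the lexicographically smallest scaffold id, with a
#' multi-hit warning.
#'
#' @param scaffolds Scaffolder output sequences, see [as_seq_set()]; gap
#'   characters (N) never match a tag base.
#' @param layout A `truth_layout` from [build_truth_layout()] whose tags
#'   carry `tag_bases`, or a manifest data.frame with `contig_id` and
#'   `tag_bases`.
#' @return A list with `hits` (data.frame: contig_id, scaffold_id, start
#'   (0-based), strand) and `lost` (contig ids of lost tags).
#' @export
locate_tags <- function(scaffolds, layout) {
  scaffolds <- as_seq_set(scaffolds)
  tags <- if (methods::is(layout, "truth_layout")) layout$tags else layout
  stopifnot(all(c("contig_id", "tag_bases") %in% colnames(tags)))
  hits <- vector("list", nrow(tags))
  lost <- character(0)
  multi <- character(0)
  for (i in seq_len(nrow(tags))) {
    occ <- count_occurrences(tags$tag_bases[i], scaffolds,
                             both_strands = TRUE)
    if (nrow(occ) == 0L) {
      lost <- c(lost, tags$contig_id[i])
      next
    }
    if (nrow(occ) > 1L) multi <- c(multi, tags$contig_id[i])
    hits[[i]] <- data.frame(contig_id = tags$contig_id[i],
                            scaffold_id = occ$subject_id[1L],
                            start = occ$start[1L], strand = occ$strand[1L],
                            stringsAsFactors = FALSE)
  }
  if (length(multi)) {
    warning("tag(s) with multiple scaffold occurrences placed at their ",
            "leftmost hit: ", paste(multi, collapse = ", "))
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(contig_id = character(0), scaffold_id = character(0),
                       start = integer(0), strand = character(0),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  list(hits = hits, lost = lost)
}

#' Classify every join implied by located tags
#'
#' Within each scaffold, located tags are sorted by position and each
#' consecutive pair (u, v) is judged in order: (1) tags from different
#' reference sequences are an incorrect join (`different_sequence`);
#' (2) differing strands are incorrect (`orientation`); (3) on shared
#' strand s, the truth layout index must increase along the scaffold when
#' s = "+" and decrease when s = "-", else incorrect (`order`); (4) the
#' midpoint-to-midpoint distance in the scaffold must differ from the true
#' reference distance by less than `frag_tolerance`, else incorrect
#' (`distance`) — this applies equally to joins that skip tags, judged
#' against the skip-inclusive reference distance; (5) otherwise the join is
#' correct when the tags are layout-adjacent, and a skipping join jumping
#' k = |index difference| - 1 tags otherwise.
#'
#' @param hits Tag hits from [locate_tags()].
#' @param layout A `truth_layout`.
#' @param frag_tolerance Distance tolerance in bp (> 0): a join's distance
#'   error must be strictly less than the library fragment length. With
#'   several libraries, use the largest fragment mean.
#' @return A list with `verdicts` (data.frame: scaffold_id, left, right,
#'   category in \{correct, incorrect, skipping\}, reason in \{orientation,
#'   different_sequence, distance, order\} for incorrect joins,
#'   skipped_count, and the scaffold coordinates `left_tag_end` /
#'   `right_tag_start` flanking the joint) and `counts` (correct_joins,
#'   incorrect_joins, skipping_joins, skipped_tags, joins_made).
#' @export
classify_joins <- function(hits, layout, frag_tolerance) {
  stopifnot(methods::is(layout, "truth_layout"), frag_tolerance > 0)
  tags <- layout$tags
  unknown <- setdiff(hits$contig_id, tags$contig_id)
  if (length(unknown)) {
    stop("hit(s) reference contigs absent from the truth layout: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(hits$contig_id, tags$contig_id)
  h <- cbind(hits,
             ref_id = tags$ref_id[idx],
             layout_index = tags$layout_index[idx],
             tag_length = tags$tag_length[idx],
             ref_mid = tags$ref_tag_start[idx] + tags$tag_length[idx] / 2)
  h$scaf_mid <- h$start + h$tag_length / 2

  verdicts <- NULL
  for (sid in unique(h$scaffold_id)) {
    s <- h[h$scaffold_id == sid, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) {
      u <- s[i, ]
      v <- s[i + 1L, ]
      verdicts <- rbind(verdicts, .judge_pair(u, v, frag_tolerance))
    }
  }
  if (is.null(verdicts)) {
    verdicts <- data.frame(scaffold_id = character(0), left = character(0),
                           right = character(0), category = character(0),
                           reason = character(0), skipped_count = integer(0),
                           left_tag_end = integer(0),
                           right_tag_start = integer(0),
                           stringsAsFactors = FALSE)
  }
  rownames(verdicts) <- NULL
  counts <- list(
    correct_joins = sum(verdicts$category == "correct"),
    incorrect_joins = sum(verdicts$category == "incorrect"),
    skipping_joins = sum(verdicts$category == "skipping"),
    skipped_tags = sum(verdicts$skipped_count),
    joins_made = nrow(verdicts))
  list(verdicts = verdicts, counts = counts)
}

.judge_pair <- function(u, v, frag_tolerance) {
  category <- NA_character_
  reason <- NA_character_
  skipped <- 0L
  d <- v$layout_index - u$layout_index
  if (u$ref_id != v$ref_id) {
    category <- "incorrect"; reason <- "different_sequence"
  } else if (u$strand != v$strand) {
    category <- "incorrect"; reason <- "orientation"
  } else if ((u$strand == "+" && d <= 0) || (u$strand == "-" && d >= 0)) {
    category <- "incorrect"; reason <- "order"
  } else if (abs(abs(v$scaf_mid - u$scaf_mid) - abs(v$ref_mid - u$ref_mid))
             >= frag_tolerance) {
    category <- "incorrect"; reason <- "distance"
  } else if (abs(d) == 1) {
    category <- "correct"
  } else {
    category <- "skipping"
    skipped <- abs(d) - 1L
  }
  data.frame(scaffold_id = u$scaffold_id, left = u$contig_id,
             right = v$contig_id, category = category, reason = reason,
             skipped_count = skipped,
             left_tag_end = u$start + u$tag_length,
             right_tag_start = v$start, stringsAsFactors = FALSE)
}

#' Length-weighted median scaffold length (N50)
#'
#' @param lengths Scaffold lengths in bp.
#' @return The largest length L such that scaffolds of length >= L hold at
#'   least half the total length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1L]]
}

#' N50 and corrected N50 of a scaffold set
#'
#' The corrected N50 is the N50 recomputed after splitting each scaffold at
#' the midpoint between the inner tag ends of every incorrect join, so that
#' inflated continuity bought by wrong joins is discounted.
#'
#' @param scaffolds Scaffold sequences.
#' @param verdicts Verdict data.frame from [classify_joins()].
#' @return A list with `n50` and `corrected_n50` in bp.
#' @export
corrected_n50 <- function(scaffolds, verdicts) {
  scaffolds <- as_seq_set(scaffolds)
  lens <- Biostrings::width(scaffolds)
  names(lens) <- names(scaffolds)
  plain <- n50(lens)
  bad <- verdicts[verdicts$category == "incorrect", , drop = FALSE]
  pieces <- unlist(lapply(names(lens), function(sid) {
    b <- bad[bad$scaffold_id == sid, , drop = FALSE]
    if (nrow(b) == 0L) return(lens[[sid]])
    cuts <- sort(unique(
      (b$left_tag_end + b$right_tag_start) %/% 2L))
    diff(c(0L, cuts, lens[[sid]]))
  }))
  list(n50 = plain, corrected_n50 = n50(pieces))
}

#' Summarise join classification into the evaluation report
#'
#' @param counts Counts from [classify_joins()].
#' @param potential_joins Number of potential joins in the truth layout
#'   (> 0).
#' @param lost_tags Number of lost tags from [locate_tags()].
#' @param cpu_seconds Externally supplied CPU time of the scaffolding run,
#'   including pre-processing and read mapping; NA when not benchmarked.
#' @param n50 Optional N50 in bp.
#' @param corrected_n50 Optional corrected N50 in bp.
#' @return An `evaluation_report` list with the five key metrics
#'   (correct_joins, incorrect_joins, skipped_tags, lost_tags, cpu_seconds)
#'   plus skipping_joins, joins_made, potential_joins, pct_correct (percent
#'   of potential joins), pct_incorrect (percent of joins made; NA when no
#'   joins were made), n50 and corrected_n50.
#' @export
summarize_metrics <- function(counts, potential_joins, lost_tags = 0L,
                              cpu_seconds = NA_real_, n50 = NA_real_,
                              corrected_n50 = NA_real_) {
  if (is.na(potential_joins) || potential_joins <= 0) {
    stop("potential_joins must be a positive count")
  }
  joins_made <- counts$joins_made
  stopifnot(joins_made == counts$correct_joins + counts$incorrect_joins +
              counts$skipping_joins)
  structure(list(
    correct_joins = counts$correct_joins,
    incorrect_joins = counts$incorrect_joins,
    skipping_joins = counts$skipping_joins,
    skipped_tags = counts$skipped_tags,
    lost_tags = lost_tags,
    joins_made = joins_made,
    potential_joins = potential_joins,
    pct_correct = 100 * counts$correct_joins / potential_joins,
    pct_incorrect = if (joins_made == 0L) NA_real_ else
      100 * counts$incorrect_joins / joins_made,
    n50 = n50,
    corrected_n50 = corrected_n50,
    cpu_seconds = cpu_seconds), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("scaffold evaluation: %d/%d potential joins correct (%.1f%%), ",
           "%d incorrect (%s%% of %d joins made), %d skipped tag(s), ",
           "%d lost tag(s)\n"),
    x$correct_joins, x$potential_joins, x$pct_correct, x$incorrect_joins,
    ifelse(is.na(x$pct_incorrect), "NA", sprintf("%.1f", x$pct_incorrect)),
    x$joins_made, x$skipped_tags, x$lost_tags))
  if (!is.na(x$n50)) {
    cat(sprintf("N50 %d bp, corrected N50 %d bp\n",
                as.integer(x$n50), as.integer(x$corrected_n50)))
  }
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(x[setdiff(names(x), character(0))], stringsAsFactors = FALSE)
}

#' Evaluate scaffolder output against a truth layout
#'
#' Full pipeline: [locate_tags()], [classify_joins()], [corrected_n50()],
#' [summarize_metrics()].
#'
#' @param scaffolds Scaffolder output sequences (FASTA path or sequences).
#' @param layout A `truth_layout`.
#' @param frag_tolerance Distance tolerance in bp; defaults to the largest
#'   `fragment_mean` among `libs`.
#' @param libs A [library_spec()] or list of them, used for the default
#'   tolerance.
#' @param cpu_seconds Externally supplied CPU time of the run.
#' @return An `evaluation_report`; the per-join verdicts and tag hits are
#'   attached as attributes `"verdicts"` and `"hits"`.
#' @export
evaluate_scaffolds <- function(scaffolds, layout, frag_tolerance = NULL,
                               libs = library_spec(),
                               cpu_seconds = NA_real_) {
  if (is.character(scaffolds) && length(scaffolds) == 1L &&
        file.exists(scaffolds)) {
    scaffolds <- read_fasta(scaffolds)
  }
  scaffolds <- as_seq_set(scaffolds)
  if (is.null(frag_tolerance)) {
    if (methods::is(libs, "library_spec")) libs <- list(libs)
    frag_tolerance <- max(vapply(libs, `[[`, numeric(1), "fragment_mean"))
  }
  located <- locate_tags(scaffolds, layout)
  cls <- classify_joins(located$hits, layout, frag_tolerance)
  nn <- corrected_n50(scaffolds, cls$verdicts)
  report <- summarize_metrics(cls$counts, layout$potential_joins,
                              lost_tags = length(located$lost),
                              cpu_seconds = cpu_seconds,
                              n50 = nn$n50, corrected_n50 = nn$corrected_n50)
  attr(report, "verdicts") <- cls$verdicts
  attr(report, "hits") <- located$hits
  report
}

#' Write per-join verdicts to TSV
#'
#' @param verdicts Verdicts from [classify_joins()] or the `"verdicts"`
#'   attribute of [evaluate_scaffolds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_join_verdicts <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
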