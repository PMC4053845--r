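# Independent brute-force oracles, deliberately written without the package's
# (or Biostrings') search/merge/classification machinery.

# reverse complement by character table
oracle_rc <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# position-by-position exact scan; subjects is a named character vector
oracle_occurrences <- function(pattern, subjects, both_strands = FALSE) {
  pats <- list(c(pattern, "+"))
  if (both_strands) pats <- c(pats, list(c(oracle_rc(pattern), "-")))
  m <- nchar(pattern)
  rows <- list()
  for (sid in names(subjects)) {
    s <- subjects[[sid]]
    n <- nchar(s)
    if (n < m) next
    for (p in pats) {
      for (i in 0:(n - m)) {
        if (substr(s, i + 1, i + m) == p[1]) {
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = sid, start = i, strand = p[2],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(subject_id = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$subject_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-base boolean coverage union; hits are 1-based inclusive reference
# intervals with qry_id/ref_id; returns 0-based half-open merged intervals
oracle_merge <- function(hits) {
  out <- NULL
  for (q in sort(unique(hits$qry_id))) {
    for (r in sort(unique(hits$ref_id[hits$qry_id == q]))) {
      h <- hits[hits$qry_id == q & hits$ref_id == r, , drop = FALSE]
      cov <- logical(max(h$ref_end))
      for (i in seq_len(nrow(h))) {
        cov[h$ref_start[i]:h$ref_end[i]] <- TRUE
      }
      rl <- rle(cov)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      keep <- rl$values
      out <- rbind(out, data.frame(
        qry_id = q, ref_id = r, ref_start = starts[keep] - 1L,
        ref_end = ends[keep], stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$qry_id, out$ref_id, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_n50 <- function(lengths) {
  lengths <- rev(sort(lengths))
  total <- sum(lengths)
  acc <- 0
  for (l in lengths) {
    acc <- acc + l
    if (acc >= total / 2) return(l)
  }
  0
}

# direct re-statement of the five classification rules on known tag
# placements within ONE scaffold. placed: data.frame(contig_id, tag_start,
# strand); truth: data.frame(contig_id, ref_id, layout_index, ref_tag_start,
# tag_length). Returns per-join categories/reasons in scaffold order.
oracle_classify <- function(placed, truth, tol) {
  placed <- placed[order(placed$tag_start), , drop = FALSE]
  k <- nrow(placed)
  cats <- character(0); reasons <- character(0); skipped <- integer(0)
  for (i in seq_len(k - 1)) {
    a <- truth[truth$contig_id == placed$contig_id[i], ]
    b <- truth[truth$contig_id == placed$contig_id[i + 1], ]
    sa <- placed$strand[i]; sb <- placed$strand[i + 1]
    mida <- placed$tag_start[i] + a$tag_length / 2
    midb <- placed$tag_start[i + 1] + b$tag_length / 2
    rmida <- a$ref_tag_start + a$tag_length / 2
    rmidb <- b$ref_tag_start + b$tag_length / 2
    step <- b$layout_index - a$layout_index
    if (a$ref_id != b$ref_id) {
      cat_i <- "incorrect"; rsn <- "different_sequence"
    } else if (sa != sb) {
      cat_i <- "incorrect"; rsn <- "orientation"
    } else if (!((sa == "+" && step > 0) || (sa == "-" && step < 0))) {
      cat_i <- "incorrect"; rsn <- "order"
    } else if (abs(abs(midb - mida) - abs(rmidb - rmida)) >= tol) {
      cat_i <- "incorrect"; rsn <- "distance"
    } else if (abs(step) == 1) {
      cat_i <- "correct"; rsn <- NA_character_
    } else {
      cat_i <- "skipping"; rsn <- NA_character_
    }
    cats <- c(cats, cat_i)
    reasons <- c(reasons, rsn)
    skipped <- c(skipped, if (cat_i == "skipping") abs(step) - 1L else 0L)
  }
  data.frame(category = cats, reason = reasons, skipped_count = skipped,
             stringsAsFactors = FALSE)
}

# random named sequence set for property tests
random_seq_set <- function(n, len, prefix = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- vapply(seq_len(n), function(i) scaftag::random_sequence(len),
              character(1))
  names(x) <- paste0(prefix, seq_len(n))
  scaftag::as_seq_set(x)
}

# assemble a scaffold string from oriented contig sequences and N gaps
join_with_gaps <- function(seqs, gaps) {
  stopifnot(length(gaps) == length(seqs) - 1 || length(gaps) == 1)
  if (length(gaps) == 1) gaps <- rep(gaps, length(seqs) - 1)
  out <- seqs[1]
  for (i in seq_along(gaps)) {
    out <- paste0(out, strrep("N", gaps[i]), seqs[i + 1])
  }
  out
}

# Figure-2c-style worked fixture: six tagged contigs, a scaffold that joins
# 1-2 correctly, skips tag 3 (whose contig is absent), carries contig 5
# reverse complemented and ends with a contig from a second sequence.
make_six_tag_fixture <- function(seed = 11) {
  set.seed(seed)
  r1 <- scaftag::random_sequence(2200)
  r2 <- scaftag::random_sequence(450)
  ref <- scaftag::as_seq_set(c(R1 = r1, R2 = r2))
  t1 <- scaftag::tile_reference(ref, contig_length = 400, gap_length = 50)
  stopifnot(nrow(t1$layout) == 6)  # five on R1, one on R2
  man <- scaftag::tag_contigs(t1$contigs, ref, t1$layout)
  layout <- scaftag::build_truth_layout(man)
  cs <- as.character(t1$contigs)
  scaffold <- join_with_gaps(
    c(cs["R1.1"], cs["R1.2"], cs["R1.4"], oracle_rc(cs[["R1.5"]]),
      cs["R2.1"]),
    gaps = c(50, 500, 50, 50))  # 500 = gap + missing contig 3 + gap
  list(layout = layout,
       scaffolds = scaftag::as_seq_set(c(scaf1 = scaffold)))
}
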