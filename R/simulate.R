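#' Describe a paired-end sequencing library
#'
#' Fragment lengths are drawn from Normal(`fragment_mean`, `fragment_sd`)
#' rounded to the nearest integer; the two `read_length`-base fragment ends
#' form an FR-oriented read pair and every base carries `base_quality`.
#' Defaults describe the short-fragment library used throughout the small
#' test cases: 500 +/- 30 bp fragments, 76 bp reads, quality 40, 30x
#' coverage. The long-fragment counterpart is
#' `library_spec(fragment_mean = 3000, fragment_sd = 200)`.
#'
#' @param fragment_mean Mean fragment (insert) length in bp; > 0.
#' @param fragment_sd Standard deviation of the fragment length in bp; >= 0.
#' @param read_length Read length in bp.
#' @param base_quality Phred base quality in \[0, 41\].
#' @param coverage Fold-coverage target used by [build_testcase()].
#' @return A `library_spec` list.
#' @export
library_spec <- function(fragment_mean = 500, fragment_sd = 30,
                         read_length = 76L, base_quality = 40L,
                         coverage = 30) {
  stopifnot(fragment_mean > 0, fragment_sd >= 0, read_length > 0,
            coverage > 0)
  if (base_quality < 0 || base_quality > 41) {
    stop("base_quality must be in [0, 41]")
  }
  structure(list(fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 read_length = as.integer(read_length),
                 base_quality = as.integer(base_quality),
                 coverage = coverage),
            class = "library_spec")
}

#' Generate a random DNA sequence
#'
#' Each base is drawn i.i.d. from A, C, G, T with equal probability.
#'
#' @param length Sequence length in bp; > 0.
#' @param seed Optional integer seed; identical seeds give identical output
#'   and the caller's RNG state is left untouched.
#' @return A base string of the requested length.
#' @export
random_sequence <- function(length, seed = NULL) {
  if (length(length) != 1L || is.na(length) || length <= 0) {
    stop("length must be a single positive number")
  }
  .with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                replace = TRUE), collapse = ""))
}

#' Simulate perfect paired-end reads from a template
#'
#' Fragments are sampled uniformly from the template: a start is drawn
#' uniformly over all template positions and a length from
#' Normal(mean, sd) rounded to the nearest integer; the draw is rejected
#' (both start and length redrawn) when the length falls below the read
#' length or the fragment would overrun the template. Read 1 is the first
#' `read_length` bases of the fragment and read 2 the reverse complement of
#' its last `read_length` bases (FR orientation). Reads are error-free.
#'
#' @param template A single sequence (character, `DNAString`, or a
#'   length-one `DNAStringSet`), at least `lib$fragment_mean` long.
#' @param lib A [library_spec()].
#' @param n_pairs Number of read pairs; > 0.
#' @param seed Optional integer seed.
#' @param name_prefix Prefix for read names; pair i is named
#'   `<prefix>:<i>/1` and `<prefix>:<i>/2`.
#' @return A list with `read1` and `read2` (`DNAStringSet`s, pair-matched
#'   names), `fragments` (data.frame of 0-based `start` and `length`), and
#'   the `lib` used.
#' @export
simulate_read_pairs <- function(template, lib = library_spec(), n_pairs,
                                seed = NULL, name_prefix = "frag") {
  template <- .as_single_sequence(template)
  L <- Biostrings::nchar(template)
  if (L < lib$fragment_mean) {
    stop("template (", L, " bp) is shorter than the mean fragment length")
  }
  if (length(n_pairs) != 1L || is.na(n_pairs) || n_pairs <= 0) {
    stop("n_pairs must be a single positive number")
  }
  n_pairs <- as.integer(n_pairs)
  frags <- .with_seed(seed, .draw_fragments(L, lib, n_pairs))
  fwd <- Biostrings::DNAStringSet(template,
                                  start = frags$start + 1L,
                                  width = lib$read_length)
  rev_views <- Biostrings::DNAStringSet(template,
                                        end = frags$start + frags$length,
                                        width = lib$read_length)
  rev <- Biostrings::reverseComplement(rev_views)
  names(fwd) <- sprintf("%s:%d/1", name_prefix, seq_len(n_pairs))
  names(rev) <- sprintf("%s:%d/2", name_prefix, seq_len(n_pairs))
  list(read1 = fwd, read2 = rev, fragments = frags, lib = lib)
}

# rejection sampling of (start, length); vectorised in batches
.draw_fragments <- function(L, lib, n_pairs) {
  starts <- integer(0)
  lens <- integer(0)
  while (length(starts) < n_pairs) {
    k <- max(2L * (n_pairs - length(starts)), 100L)
    s <- sample.int(L, k, replace = TRUE) - 1L
    l <- as.integer(round(stats::rnorm(k, lib$fragment_mean,
                                       lib$fragment_sd)))
    ok <- l >= lib$read_length & s + l <= L
    starts <- c(starts, s[ok])
    lens <- c(lens, l[ok])
  }
  data.frame(start = starts[seq_len(n_pairs)],
             length = lens[seq_len(n_pairs)])
}

.as_single_sequence <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1L) stop("expected a single template sequence")
    x <- x[[1L]]
  }
  if (is.character(x)) x <- Biostrings::DNAString(toupper(x))
  if (!methods::is(x, "DNAString")) stop("cannot interpret template sequence")
  x
}

#' Describe one scaffolding-graph path of a small test case
#'
#' @param contigs Ordered contig ids along the path.
#' @param strands Orientation of each contig in the path, `"+"` or `"-"`;
#'   defaults to all forward.
#' @param multiplier Coverage multiplier (> 0) controlling the read-pair
#'   evidence for this path relative to the library coverage.
#' @return A `path_spec` list.
#' @export
path_spec <- function(contigs, strands = NULL, multiplier = 1) {
  if (is.null(strands)) strands <- rep("+", length(contigs))
  stopifnot(length(strands) == length(contigs),
            all(strands %in% c("+", "-")), multiplier > 0,
            length(contigs) >= 1)
  structure(list(contigs = as.character(contigs), strands = strands,
                 multiplier = multiplier), class = "path_spec")
}

#' Describe a small truth-known test case
#'
#' A test case is a set of random contigs arranged into one or more paths
#' (the intended scaffolds); perfect read pairs are simulated from each
#' path's concatenated template and the contigs are then trimmed so that a
#' sequence gap separates every junction, which read pairs must bridge.
#'
#' @param paths A list of [path_spec()] objects (a bare character vector of
#'   contig ids is promoted to a single forward path).
#' @param contig_length Length of each random contig in bp.
#' @param trim_bp Bases trimmed from contig ends before output.
#' @param trim_ends Trim `"both"` ends (default) or only the `"right"` end.
#' @param replicates Number of independently generated replicates.
#' @param seed Base seed; replicate r uses seed + r.
#' @param lib A [library_spec()].
#' @return A `testcase_spec` list.
#' @export
test_case_spec <- function(paths, contig_length = 5000L, trim_bp = 40L,
                           trim_ends = c("both", "right"), replicates = 5L,
                           seed = 1L, lib = library_spec()) {
  if (is.character(paths)) paths <- list(path_spec(paths))
  if (methods::is(paths, "path_spec")) paths <- list(paths)
  stopifnot(is.list(paths), length(paths) >= 1)
  paths <- lapply(paths, function(p) {
    if (!methods::is(p, "path_spec")) p <- do.call(path_spec, p)
    p
  })
  trim_ends <- match.arg(trim_ends)
  stopifnot(contig_length > 0, trim_bp >= 0, replicates >= 1)
  ids <- sort(unique(unlist(lapply(paths, `[[`, "contigs"))))
  if (2 * trim_bp >= contig_length) stop("trim removes the whole contig")
  structure(list(paths = paths, contig_ids = ids,
                 contig_length = as.integer(contig_length),
                 trim_bp = as.integer(trim_bp), trim_ends = trim_ends,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), lib = lib),
            class = "testcase_spec")
}

#' Build a truth-known small test case
#'
#' For each replicate r (seeded with `spec$seed + r`), one random sequence
#' is generated per contig id; each path's contigs are concatenated in the
#' declared order and orientation into a template; read pairs are simulated
#' per template, with pair counts
#' `round(multiplier * coverage * template_length / (2 * read_length))`;
#' finally the contigs are trimmed by `trim_bp` at each end (or only the
#' right end) before being returned. The truth layout records the post-trim
#' true positions of each contig along each template.
#'
#' @param spec A [test_case_spec()].
#' @return A list of `spec$replicates` replicate lists, each holding
#'   `contigs` (trimmed, alphabetical id order), `templates`, `read1`,
#'   `read2`, `fragments` (with a `template_id` column), `layout`
#'   (data.frame: contig_id, ref_id, ref_start, ref_end, strand,
#'   layout_index) and `potential_joins`.
#' @export
build_testcase <- function(spec) {
  stopifnot(methods::is(spec, "testcase_spec"))
  lapply(seq_len(spec$replicates), function(r) {
    .with_seed(spec$seed + r, .build_one_replicate(spec))
  })
}

.build_one_replicate <- function(spec) {
  cl <- spec$contig_length
  full <- Biostrings::DNAStringSet(
    vapply(spec$contig_ids, function(id) random_sequence(cl), character(1)))
  names(full) <- spec$contig_ids

  templates <- Biostrings::DNAStringSet()
  layout <- NULL
  read1 <- Biostrings::DNAStringSet()
  read2 <- Biostrings::DNAStringSet()
  fragments <- NULL
  trim_left <- if (spec$trim_ends == "both") spec$trim_bp else 0L
  trim_right <- spec$trim_bp

  for (p in seq_along(spec$paths)) {
    path <- spec$paths[[p]]
    tid <- sprintf("path%d", p)
    parts <- lapply(seq_along(path$contigs), function(i) {
      s <- full[[path$contigs[i]]]
      if (path$strands[i] == "-") Biostrings::reverseComplement(s) else s
    })
    template <- do.call(Biostrings::xscat, parts)
    tset <- Biostrings::DNAStringSet(template)
    names(tset) <- tid
    templates <- c(templates, tset)

    tl <- Biostrings::nchar(template)
    n_pairs <- max(1L, as.integer(round(
      path$multiplier * spec$lib$coverage * tl /
        (2 * spec$lib$read_length))))
    pairs <- simulate_read_pairs(template, spec$lib, n_pairs,
                                 name_prefix = tid)
    read1 <- c(read1, pairs$read1)
    read2 <- c(read2, pairs$read2)
    fragments <- rbind(fragments,
                       cbind(template_id = tid, pairs$fragments))

    # post-trim true positions: contig i occupied [(i-1)*cl, i*cl) pre-trim
    idx <- seq_along(path$contigs) - 1L
    layout <- rbind(layout, data.frame(
      contig_id = path$contigs,
      ref_id = tid,
      ref_start = idx * cl + ifelse(path$strands == "-", trim_right,
                                    trim_left),
      ref_end = (idx + 1L) * cl - ifelse(path$strands == "-", trim_left,
                                         trim_right),
      strand = path$strands,
      layout_index = idx,
      stringsAsFactors = FALSE))
  }

  trimmed <- Biostrings::DNAStringSet(
    full, start = trim_left + 1L,
    end = Biostrings::width(full) - trim_right)
  names(trimmed) <- names(full)
  list(contigs = trimmed, templates = templates,
       read1 = read1, read2 = read2, fragments = fragments,
       layout = layout,
       potential_joins = sum(vapply(spec$paths,
                                    function(p) length(p$contigs) - 1L,
                                    integer(1))))
}

#' Tile a reference into perfect gap-separated contigs
#'
#' Per reference sequence, contigs of `contig_length` bp are cut at starts
#' 0, c+g, 2(c+g), ...; a trailing segment shorter than `contig_length` is
#' dropped. Sequences shorter than `contig_length` contribute no contigs.
#' The standard configurations are 3 kb contigs with 50 bp gaps and 10 kb
#' contigs with 300 bp gaps.
#'
#' @param reference Reference sequences, see [as_seq_set()].
#' @param contig_length Contig length c in bp; > 0.
#' @param gap_length Gap g between consecutive contigs in bp; >= 0.
#' @return A list with `contigs` (`DNAStringSet`, ids `<ref_id>.<k>`),
#'   `layout` (data.frame: contig_id, ref_id, ref_start, ref_end,
#'   layout_index; 0-based half-open) and `potential_joins`
#'   (sum over sequences of contig count minus one).
#' @export
tile_reference <- function(reference, contig_length = 3000L,
                           gap_length = 50L) {
  reference <- as_seq_set(reference)
  stopifnot(contig_length > 0, gap_length >= 0)
  c_ <- as.integer(contig_length)
  g <- as.integer(gap_length)
  layout <- NULL
  contigs <- Biostrings::DNAStringSet()
  for (rid in names(reference)) {
    L <- Biostrings::width(reference[rid])
    n <- (L + g) %/% (c_ + g)
    if (n == 0L) next
    starts <- (seq_len(n) - 1L) * (c_ + g)
    piece <- Biostrings::DNAStringSet(reference[[rid]], start = starts + 1L,
                                      width = c_)
    names(piece) <- sprintf("%s.%d", rid, seq_len(n))
    contigs <- c(contigs, piece)
    layout <- rbind(layout, data.frame(
      contig_id = names(piece), ref_id = rid, ref_start = starts,
      ref_end = starts + c_, layout_index = seq_len(n) - 1L,
      stringsAsFactors = FALSE))
  }
  if (is.null(layout)) {
    stop("no reference sequence is at least contig_length long; ",
         "tiling produced no contigs")
  }
  per_seq <- table(layout$ref_id)
  list(contigs = contigs, layout = layout,
       potential_joins = sum(per_seq - 1L))
}
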