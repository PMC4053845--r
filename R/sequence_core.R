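#' Sequence primitives and exact-occurrence search
#'
#' Sequences are held as named [Biostrings::DNAStringSet] objects over the
#' alphabet A, C, G, T, N. All internal coordinates are 0-based, half-open;
#' the only 1-based inclusive coordinates in the package are those read from
#' and written to nucmer show-coords tables (see [parse_coords()]).
#'
#' @name sequence_core
#' @keywords internal
NULL

.SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate and normalise a set of sequences
#'
#' Uppercases the bases and checks the alphabet, non-empty sequences and
#' unique non-empty identifiers.
#'
#' @param x A named character vector or a [Biostrings::DNAStringSet].
#' @return A named `DNAStringSet`, bases uppercase.
#' @export
as_seq_set <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (!methods::is(x, "DNAStringSet")) {
    stop("sequences must be a character vector or DNAStringSet")
  }
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence must have a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(x) == 0L)) stop("empty sequence not allowed")
  freq <- Biostrings::alphabetFrequency(x)
  bad <- rowSums(freq) - rowSums(freq[, .SEQ_ALPHABET, drop = FALSE])
  if (any(bad > 0L)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(ids[bad > 0L], collapse = ", "))
  }
  x
}

.check_bases <- function(seq, allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("expected a single non-empty base string")
  }
  alpha <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alpha), toupper(seq))) {
    stop("sequence contains characters outside {", alpha, "}")
  }
  toupper(seq)
}

#' Reverse complement of a base string
#'
#' @param seq A single string over A, C, G, T, N (case-insensitive).
#' @return The Watson-Crick reverse complement, uppercase; N maps to N.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- .check_bases(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find all exact occurrences of a pattern in a sequence collection
#'
#' Reports every full-length exact match of `pattern` (and, when
#' `both_strands`, of its reverse complement) in each subject. A match of the
#' reverse complement at forward position `start` is reported with strand
#' `"-"`. N in a subject never matches any pattern base, so tags are never
#' found inside scaffold gaps. Overlapping matches are all reported. A
#' reverse-complement-palindromic pattern is reported once per strand at the
#' same position.
#'
#' @param pattern A single base string over A, C, G, T (no N: tags are drawn
#'   from ungapped sequence).
#' @param subjects Sequences to search, see [as_seq_set()].
#' @param both_strands Also search the reverse complement of `pattern`.
#' @return A data.frame with columns `subject_id`, `start` (0-based) and
#'   `strand`, sorted ascending by (subject_id, start, strand).
#' @examples
#' subjects <- as_seq_set(c(s = "TACGACG"))
#' count_occurrences("ACG", subjects)
#' @export
count_occurrences <- function(pattern, subjects, both_strands = FALSE) {
  pattern <- .check_bases(pattern, allow_n = FALSE)
  subjects <- as_seq_set(subjects)
  hits <- .match_forward(pattern, subjects, "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
    hits <- rbind(hits, .match_forward(rc, subjects, "-"))
  }
  hits <- hits[order(hits$subject_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# forward-strand matches of pat, labelled with the given strand
.match_forward <- function(pat, subjects, strand) {
  m <- Biostrings::vmatchPattern(pat, subjects, fixed = TRUE)
  starts <- IRanges::start(m)  # IntegerList, 1-based
  n <- lengths(starts)
  data.frame(
    subject_id = rep(names(subjects), n),
    start = unlist(starts, use.names = FALSE) - 1L,
    strand = rep(strand, sum(n)),
    stringsAsFactors = FALSE
  )
}

#' Read a FASTA file into a sequence set
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return A validated `DNAStringSet`; ids are truncated at whitespace.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(x) <- sub("\\s.*$", "", names(x))
  as_seq_set(x)
}

#' Write a sequence set to FASTA
#'
#' @param x Sequences, see [as_seq_set()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(as_seq_set(x), path, format = "fasta",
                              width = width)
  invisible(path)
}

#' Write reads to FASTQ with a constant base quality
#'
#' All quality characters encode `base_quality` on the Sanger (+33) scale.
#'
#' @param reads Reads, see [as_seq_set()].
#' @param path Output path.
#' @param base_quality Phred quality in \[0, 41\] applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, base_quality = 40L) {
  reads <- as_seq_set(reads)
  if (base_quality < 0L || base_quality > 41L) {
    stop("base_quality must be in [0, 41]")
  }
  qchar <- rawToChar(as.raw(as.integer(base_quality) + 33L))
  quals <- Biostrings::BStringSet(
    vapply(Biostrings::width(reads),
           function(w) strrep(qchar, w), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

# run code under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so simulation helpers do not disturb the session RNG
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
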