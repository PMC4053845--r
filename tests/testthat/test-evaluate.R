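# shared fixture: a tiled, tagged 60 kb reference and its perfect scaffold
make_tiled_truth <- function(seed = 201, ref_len = 60000, gap = 50,
                             contig_len = 3000) {
  ref <- as_seq_set(stats::setNames(random_sequence(ref_len, seed = seed),
                                    "chr"))
  t1 <- tile_reference(ref, contig_len, gap)
  layout <- build_truth_layout(tag_contigs(t1$contigs, ref, t1$layout))
  perfect <- as_seq_set(c(scaf1 = join_with_gaps(
    as.character(t1$contigs), gap)))
  list(ref = ref, tiling = t1, layout = layout, perfect = perfect)
}

test_that("the six-tag worked example classifies every join type", {
  fx <- make_six_tag_fixture()
  report <- evaluate_scaffolds(fx$scaffolds, fx$layout,
                               frag_tolerance = 500)
  expect_equal(report$correct_joins, 1L)
  expect_equal(report$incorrect_joins, 2L)
  expect_equal(report$skipping_joins, 1L)
  expect_equal(report$skipped_tags, 1L)
  expect_equal(report$lost_tags, 1L)
  expect_equal(report$joins_made, 4L)
  v <- attr(report, "verdicts")
  expect_equal(v$category,
               c("correct", "skipping", "incorrect", "incorrect"))
  expect_equal(v$reason[3:4], c("orientation", "different_sequence"))
  expect_equal(v$skipped_count[2], 1L)
})

test_that("a perfect scaffold scores 100% correct with no errors", {
  fx <- make_tiled_truth()
  report <- evaluate_scaffolds(fx$perfect, fx$layout,
                               libs = library_spec())
  expect_equal(report$pct_correct, 100)
  expect_equal(report$incorrect_joins, 0L)
  expect_equal(report$skipped_tags, 0L)
  expect_equal(report$lost_tags, 0L)
  expect_equal(report$correct_joins, fx$layout$potential_joins)
  expect_equal(report$n50, report$corrected_n50)
})

test_that("reverse-complementing a scaffold changes no counts", {
  fx <- make_tiled_truth(seed = 202)
  # a deliberately imperfect scaffold: swap the first two contigs
  cs <- as.character(fx$tiling$contigs)
  ord <- c(2, 1, seq(3, length(cs)))
  scaf <- as_seq_set(c(s = join_with_gaps(cs[ord], 50)))
  fwd <- evaluate_scaffolds(scaf, fx$layout, frag_tolerance = 500)
  rc <- as_seq_set(stats::setNames(
    reverse_complement(as.character(scaf[[1]])), "s"))
  bwd <- evaluate_scaffolds(rc, fx$layout, frag_tolerance = 500)
  for (f in c("correct_joins", "incorrect_joins", "skipped_tags",
              "lost_tags", "joins_made", "pct_correct", "pct_incorrect")) {
    expect_equal(bwd[[f]], fwd[[f]], label = f)
  }
})

test_that("swapping the first two contigs plants two incorrect joins", {
  fx <- make_tiled_truth(seed = 203)
  cs <- as.character(fx$tiling$contigs)
  scaf <- as_seq_set(c(s = join_with_gaps(cs[c(2, 1, 3:length(cs))], 50)))
  report <- evaluate_scaffolds(scaf, fx$layout, frag_tolerance = 500)
  expect_equal(report$incorrect_joins, 2L)
  expect_equal(report$correct_joins, fx$layout$potential_joins - 2L)
  reasons <- attr(report, "verdicts")$reason
  expect_setequal(reasons[!is.na(reasons)], c("order", "distance"))
})

test_that("a tag absent from the output is lost, not misclassified", {
  fx <- make_tiled_truth(seed = 204, ref_len = 15000)
  cs <- as.character(fx$tiling$contigs)  # 4 contigs
  scaf <- as_seq_set(c(s = join_with_gaps(cs[c(1, 2, 4)],
                                          c(50, 3100))))
  report <- evaluate_scaffolds(scaf, fx$layout, frag_tolerance = 500)
  expect_equal(report$lost_tags, 1L)
  expect_equal(report$correct_joins, 1L)
  expect_equal(report$skipping_joins, 1L)
  expect_equal(report$skipped_tags, 1L)
  # conservation: located + lost tags account for every tag
  expect_equal(nrow(attr(report, "hits")) + report$lost_tags,
               fx$layout$n_tags)
})

test_that("multi-occurrence tags take the leftmost deterministic placement", {
  fx <- make_tiled_truth(seed = 205, ref_len = 15000)
  cs <- as.character(fx$tiling$contigs)
  scaf <- as_seq_set(c(
    b = join_with_gaps(cs, 50),
    a = paste0(cs[1], strrep("N", 50), cs[1])))  # duplicated contig 1
  expect_warning(located <- locate_tags(scaf, fx$layout), "multiple")
  h1 <- located$hits[located$hits$contig_id == fx$layout$tags$contig_id[1], ]
  expect_equal(h1$scaffold_id, "a")
  expect_equal(h1$start, unname(candidate_tag(cs[1], 50)$offset))
})

test_that("exhaustive 3-of-4 contig scaffolds match the rule oracle", {
  fx <- make_tiled_truth(seed = 206, ref_len = 14000)
  expect_equal(fx$layout$n_tags, 4L)
  cs <- as.character(fx$tiling$contigs)
  truth <- fx$layout$tags
  tol <- 200
  perms <- list()
  for (a in 1:4) for (b in 1:4) for (c in 1:4) {
    if (length(unique(c(a, b, c))) == 3) {
      perms[[length(perms) + 1]] <- c(a, b, c)
    }
  }
  expect_length(perms, 24)
  strands <- expand.grid(s1 = c("+", "-"), s2 = c("+", "-"),
                         s3 = c("+", "-"), stringsAsFactors = FALSE)
  n_checked <- 0
  for (p in perms) {
    for (r in seq_len(nrow(strands))) {
      st <- unlist(strands[r, ])
      seqs <- vapply(1:3, function(i) {
        s <- cs[p[i]]
        if (st[i] == "-") oracle_rc(s) else s
      }, character(1))
      scaf <- as_seq_set(c(s = join_with_gaps(seqs, 50)))
      located <- locate_tags(scaf, fx$layout)
      got <- classify_joins(located$hits, fx$layout, tol)

      # oracle placement computed arithmetically from the construction
      clen <- nchar(cs[1])
      placed <- do.call(rbind, lapply(1:3, function(i) {
        row <- truth[truth$contig_id == sprintf("chr.%d", p[i]), ]
        cstart <- (i - 1) * (clen + 50)
        tstart <- if (st[i] == "+") cstart + row$tag_offset else
          cstart + clen - row$tag_offset - row$tag_length
        data.frame(contig_id = row$contig_id, tag_start = tstart,
                   strand = st[i], stringsAsFactors = FALSE)
      }))
      want <- oracle_classify(placed, truth, tol)
      expect_equal(got$verdicts$category, want$category)
      expect_equal(got$verdicts$reason, want$reason)
      expect_equal(got$verdicts$skipped_count, want$skipped_count)
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 192)
})

test_that("raising the tolerance never loses correct joins", {
  fx <- make_tiled_truth(seed = 207, ref_len = 30000)
  cs <- as.character(fx$tiling$contigs)
  set.seed(208)
  scaf <- as_seq_set(c(s = join_with_gaps(
    sample(cs), sample(c(10, 50, 500, 2000), length(cs) - 1,
                       replace = TRUE))))
  located <- locate_tags(scaf, fx$layout)
  last <- -1L
  for (tol in c(50, 200, 1000, 5000, 50000)) {
    cnt <- classify_joins(located$hits, fx$layout, tol)$counts
    expect_gte(cnt$correct_joins, last)
    last <- cnt$correct_joins
  }
})

test_that("concatenating scaffolds keeps their internal correct joins", {
  fx <- make_tiled_truth(seed = 209, ref_len = 30000)
  cs <- as.character(fx$tiling$contigs)
  half <- length(cs) %/% 2
  s1 <- join_with_gaps(cs[1:half], 50)
  s2 <- join_with_gaps(cs[(half + 1):length(cs)], 50)
  separate <- evaluate_scaffolds(as_seq_set(c(a = s1, b = s2)), fx$layout,
                                 frag_tolerance = 500)
  joined <- evaluate_scaffolds(
    as_seq_set(c(a = paste0(s1, strrep("N", 5000), s2))), fx$layout,
    frag_tolerance = 500)
  expect_gte(joined$joins_made, separate$joins_made)
  expect_gte(joined$correct_joins, separate$correct_joins)
})

test_that("metric summaries follow the potential/made denominators", {
  counts <- list(correct_joins = 0L, incorrect_joins = 0L,
                 skipping_joins = 0L, skipped_tags = 0L, joins_made = 0L)
  rep0 <- summarize_metrics(counts, potential_joins = 10)
  expect_equal(rep0$pct_correct, 0)
  expect_true(is.na(rep0$pct_incorrect))  # no joins -> undefined error rate

  full <- list(correct_joins = 10L, incorrect_joins = 0L,
               skipping_joins = 0L, skipped_tags = 0L, joins_made = 10L)
  repf <- summarize_metrics(full, potential_joins = 10)
  expect_equal(repf$pct_correct, 100)
  expect_equal(repf$pct_incorrect, 0)

  expect_error(summarize_metrics(full, potential_joins = 0), "positive")

  set.seed(210)
  for (i in 1:10) {
    cj <- sample(0:50, 1); ij <- sample(0:20, 1); sj <- sample(0:10, 1)
    cnt <- list(correct_joins = cj, incorrect_joins = ij,
                skipping_joins = sj, skipped_tags = sj + sample(0:5, 1),
                joins_made = cj + ij + sj)
    r <- summarize_metrics(cnt, potential_joins = 100)
    expect_equal(r$pct_correct, 100 * cj / 100)
    if (r$joins_made > 0) {
      expect_equal(r$pct_incorrect, 100 * ij / (cj + ij + sj))
    }
  }
})

test_that("N50 follows the length-weighted median definition", {
  expect_equal(n50(c(8, 4, 4)), 8)
  expect_equal(n50(c(2, 2, 2, 3, 3, 4)), 3)
  expect_equal(n50(numeric(0)), 0L)
  set.seed(211)
  for (i in 1:20) {
    lens <- sample(1:1000, sample(1:30, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("corrected N50 splits scaffolds at incorrect joins only", {
  fx <- make_tiled_truth(seed = 212, ref_len = 30000)
  cs <- as.character(fx$tiling$contigs)
  # no incorrect joins: corrected equals plain
  rep_ok <- evaluate_scaffolds(fx$perfect, fx$layout, frag_tolerance = 500)
  expect_equal(rep_ok$corrected_n50, rep_ok$n50)

  # planted error: swap first two contigs, then recompute by hand
  scaf <- as_seq_set(c(s = join_with_gaps(cs[c(2, 1, 3:length(cs))], 50)))
  rep_bad <- evaluate_scaffolds(scaf, fx$layout, frag_tolerance = 500)
  v <- attr(rep_bad, "verdicts")
  bad <- v[v$category == "incorrect", ]
  cuts <- sort((bad$left_tag_end + bad$right_tag_start) %/% 2)
  slen <- nchar(as.character(scaf[[1]]))
  pieces <- diff(c(0, cuts, slen))
  expect_equal(rep_bad$corrected_n50, oracle_n50(pieces))
  expect_lt(rep_bad$corrected_n50, rep_bad$n50)
})
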