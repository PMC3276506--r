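test_that("aligning a hybrid equal to one parent yields no crossovers", {
  pp <- generate_parent_pair(synthetic_spec(2000, divergence = 0.06,
                                            seed = 12))
  hyb <- genome("hyb", pp$A$seq)
  aln <- three_way_align(hyb, pp$A, pp$B)
  expect_equal(nchar(aln$h), 2000L)          # collinear: one column per base
  pt <- paint(aln)
  expect_true(all(pt$class %in% c("A", "shared")))
  expect_length(call_crossovers(pt), 0L)
  # identical parents leave no diagnostic columns at all: warn
  pp0 <- generate_parent_pair(synthetic_spec(500, divergence = 0, seed = 12))
  pt0 <- paint(three_way_align(genome("h", pp0$A$seq), pp0$A, pp0$B))
  expect_warning(calls0 <- call_crossovers(pt0), "no crossover")
  expect_length(calls0, 0L)
})

test_that("degapped alignment rows reproduce the inputs and the anchored score equals a full DP oracle", {
  pp <- generate_parent_pair(synthetic_spec(2000, divergence = 0.03,
                                            seed = 5))
  # hybrid = parent A with one 12-bp deletion
  hyb <- genome("hyb", paste0(substr(pp$A$seq, 1, 899),
                              substr(pp$A$seq, 912, 2000)))
  aln <- three_way_align(hyb, pp$A, pp$B)
  expect_identical(gsub("-", "", aln$h), hyb$seq)
  expect_identical(gsub("-", "", aln$a), pp$A$seq)
  expect_identical(gsub("-", "", aln$b), pp$B$seq)
  # independent quadratic DP oracle on the full sequences
  mat <- phagerec:::aln_submat(1, -2)
  for (pn in c("a", "b")) {
    pr <- pairwise_rows(aln, pn)
    ref <- if (pn == "a") pp$A$seq else pp$B$seq
    full <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(hyb$seq), Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    expect_equal(score_pairwise(pr$x, pr$y), Biostrings::score(full),
                 info = pn)
  }
})

test_that("unrelated sequences are refused with advice", {
  g1 <- genome("u1", random_dna(500, seed = 1))
  g2 <- genome("u2", random_dna(500, seed = 2))
  g3 <- genome("u3", random_dna(500, seed = 3))
  expect_error(three_way_align(g1, g2, g3), "collinear")
})

test_that("painting classes follow the parsimony rules", {
  pp <- generate_parent_pair(synthetic_spec(1500, divergence = 0, seed = 2))
  hyb <- genome("h", pp$A$seq)
  pt <- paint(three_way_align(hyb, pp$A, pp$B))
  expect_true(all(pt$class == "shared"))
  # one private base: hybrid differs from both parents
  chars <- strsplit(pp$A$seq, "")[[1]]
  chars[700] <- setdiff(c("A", "C", "G", "T"), chars[700])[1]
  pt2 <- paint(three_way_align(genome("h", paste(chars, collapse = "")),
                               pp$A, pp$B))
  expect_equal(sum(pt2$class == "private"), 1L)
  expect_equal(which(pt2$class == "private"), 700L)
})

test_that("painting counts are invariant under swapping the parent labels", {
  trio <- make_trio(length = 1800, w = 8, seed = 33, divergence = 0.07)
  pt_ab <- paint(three_way_align(trio$hybrid, trio$A, trio$B))
  pt_ba <- paint(three_way_align(trio$hybrid, trio$B, trio$A))
  expect_equal(sum(pt_ab$class == "A"), sum(pt_ba$class == "B"))
  expect_equal(sum(pt_ab$class == "B"), sum(pt_ba$class == "A"))
  expect_equal(sum(pt_ab$class == "shared"), sum(pt_ba$class == "shared"))
  expect_equal(sum(pt_ab$class == "private"), sum(pt_ba$class == "private"))
})

test_that("a splice inside a planted identity window is recovered exactly", {
  for (seed in c(101, 102, 103)) {
    for (w in c(4L, 8L, 15L)) {
      trio <- make_trio(length = 2400, w = w, seed = seed,
                        divergence = 0.05)
      aln <- three_way_align(trio$hybrid, trio$A, trio$B)
      calls <- call_crossovers(paint(aln))
      expect_length(calls, 1L)
      cl <- calls[[1]]
      expect_equal(cl$direction, "A->B")
      expect_lte(cl$interval_start, trio$cut)
      expect_gte(cl$interval_end, trio$cut)
      mw <- microhomology_window(cl)
      expect_equal(mw$length, w)
      expect_equal(mw$a_start, trio$window_at)
      expect_equal(mw$a_end, trio$window_at + w - 1L)
      expect_false(mw$degenerate)
    }
  }
})

test_that("private columns inside the ambiguity region do not split a call", {
  trio <- make_trio(length = 1800, w = 9, at = 900, seed = 44,
                    divergence = 0.08, cut = 904)
  # inject a private mutation in the middle of the identity window
  chars <- strsplit(trio$hybrid$seq, "")[[1]]
  chars[903] <- "N"
  hyb <- genome("hybrid", paste(chars, collapse = ""))
  calls <- call_crossovers(paint(three_way_align(hyb, trio$A, trio$B)))
  expect_length(calls, 1L)
  expect_equal(calls[[1]]$private_inside, 903L)
})

test_that("a hand-built 8-base identical run bounds the crossover window", {
  # parents differ at the positions flanking an 8-base identical run;
  # the hybrid splices inside the run
  set.seed(71)
  left <- random_dna(400); run <- random_dna(8); right <- random_dna(400)
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1]]
    at <- sort(sample(length(ch), 60))
    ch[at] <- vapply(ch[at], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(ch, collapse = "")
  }
  force_diff <- function(s, at, ref) {
    ch <- strsplit(s, "")[[1]]
    ch[at] <- setdiff(c("A", "C", "G", "T"), substr(ref, at, at))[1]
    paste(ch, collapse = "")
  }
  bleft <- force_diff(mutate(left), 400, left)   # run flanks must differ
  bright <- force_diff(mutate(right), 1, right)
  A <- genome("A", paste0(left, run, right))
  B <- genome("B", paste0(bleft, run, bright))
  hyb <- genome("h", paste0(substr(A$seq, 1, 404), substr(B$seq, 405, 808)))
  calls <- call_crossovers(paint(three_way_align(hyb, A, B)))
  expect_length(calls, 1L)
  mw <- microhomology_window(calls[[1]])
  expect_equal(mw$length, 8L)
  expect_equal(c(mw$a_start, mw$a_end), c(401L, 408L))
})

test_that("a two-switch hybrid yields exactly two opposed crossovers", {
  sp <- synthetic_spec(6000, divergence = 0.08,
                       identity_windows = data.frame(position = c(2500, 4000),
                                                     length = c(8, 15)),
                       seed = 99)
  pp <- generate_parent_pair(sp)
  spl <- splice_hybrid(pp$A, pp$B,
                       data.frame(donor = c("A", "B", "A"),
                                  start = c(1, 2504, 4008),
                                  end = c(2503, 4007, 6000)))
  calls <- call_crossovers(paint(three_way_align(spl$hybrid, pp$A, pp$B)))
  expect_length(calls, 2L)
  expect_equal(vapply(calls, `[[`, "", "direction"), c("A->B", "B->A"))
  w <- vapply(lapply(calls, microhomology_window), `[[`, 0L, "length")
  expect_equal(w, c(8L, 15L))
})
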