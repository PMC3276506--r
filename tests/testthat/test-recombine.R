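test_that("cleavage produces pieces whose strands reconstruct the parent", {
  g <- genome("g", random_dna(200, seed = 1))
  # blunt cuts
  b <- cleave(g, cleavage_pair(100, 100))
  expect_equal(piece_end(b$left, "right")$polarity, "blunt")
  expect_equal(piece_end(b$right, "left")$polarity, "blunt")
  expect_identical(paste0(b$left$seq, b$right$seq), g$seq)
  # staggered cuts: top after 100, bottom after 108 -> 8-nt 5' overhangs
  s <- cleave(g, cleavage_pair(100, 108))
  eL <- piece_end(s$left, "right")
  expect_equal(eL$polarity, "5p")
  expect_equal(eL$strand, "bottom")
  expect_equal(eL$coords, c(101L, 108L))
  expect_equal(eL$tail_5to3, revcomp(substr(g$seq, 101, 108)))
  eR <- piece_end(s$right, "left")
  expect_equal(eR$polarity, "5p")
  expect_equal(eR$strand, "top")
  expect_equal(eR$tail_5to3, substr(g$seq, 101, 108))
  # 3' overhangs the other way round
  t3 <- cleave(g, cleavage_pair(108, 100))
  expect_equal(piece_end(t3$left, "right")$polarity, "3p")
  expect_equal(piece_end(t3$left, "right")$strand, "top")
  expect_error(cleave(g, cleavage_pair(0, 100)), "cross the genome ends")
  expect_error(cleave(g, cleavage_pair(100, 200)), "cross the genome ends")
})

test_that("resection removes the 5'-terminal strand and exposes a 3' tail", {
  g <- genome("g", random_dna(120, seed = 2))
  p <- cleave(g, cleavage_pair(60, 60))$left
  expect_identical(resect_5to3(p, "right", 0), p)
  r <- resect_5to3(p, "right", 7)
  e <- piece_end(r, "right")
  expect_equal(e$polarity, "3p")
  expect_equal(e$strand, "top")
  # string-slicing oracle: the exposed tail is the top strand 54..60
  expect_equal(e$tail_5to3, substr(g$seq, 54, 60))
  q <- cleave(g, cleavage_pair(60, 60))$right
  r2 <- resect_5to3(q, "left", 5)
  e2 <- piece_end(r2, "left")
  expect_equal(e2$polarity, "3p")
  expect_equal(e2$strand, "bottom")
  expect_equal(e2$tail_5to3, revcomp(substr(g$seq, 61, 65)))
  expect_error(resect_5to3(p, "right", 1000), "exceeds")
})

test_that("fully complementary overhangs anneal with no flap and rejoin", {
  g <- genome("g", random_dna(300, seed = 3))
  dsb <- cleave(g, cleavage_pair(150, 158))
  j <- anneal(piece_end(dsb$left, "right"), piece_end(dsb$right, "left"),
              min_match = 8)
  expect_s3_class(j, "joint")
  expect_equal(j$paired, 8L)
  expect_equal(j$px, c(151L, 158L))
  expect_equal(j$py, c(151L, 158L))
  merged <- trim_fill_ligate(j)
  expect_identical(merged$seq, g$seq)          # cleave-then-rejoin inverse
  expect_false(any(merged$prov == "fill"))
})

test_that("anneal refuses short or incompatible tails with a reason", {
  # overhangs sharing only 3 complementary bases out of 6
  mk <- function(tailA, tailB) {
    A <- genome("A", paste0(random_dna(60, seed = 4), tailA,
                            random_dna(20, seed = 14)))
    B <- genome("B", paste0(random_dna(20, seed = 15), tailB,
                            random_dna(60, seed = 5)))
    list(a = piece_end(cleave(A, cleavage_pair(60, 66))$left, "right"),
         b = piece_end(cleave(B, cleavage_pair(20, 26))$right, "left"))
  }
  # identical 3-base prefix, divergent remainder
  e <- mk("ACGTTT", "ACGAAA")
  f <- anneal(e$a, e$b, min_match = 6)
  expect_s3_class(f, "anneal_failure")
  expect_match(f$reason, ">= 6")
  # polarity mismatch
  g <- genome("g", random_dna(200, seed = 6))
  five <- piece_end(cleave(g, cleavage_pair(100, 108))$left, "right")
  three <- piece_end(cleave(g, cleavage_pair(108, 100))$right, "left")
  f2 <- anneal(five, three)
  expect_s3_class(f2, "anneal_failure")
  expect_match(f2$reason, "polarity")
  blunt <- piece_end(cleave(g, cleavage_pair(50, 50))$right, "left")
  expect_s3_class(anneal(five, blunt), "anneal_failure")
})

test_that("a 17-nt tail annealing 8 bases leaves a 9-nt flap that is excised and refilled", {
  # equivalent-site geometry: both tails are 17 nt; the first 8 bases are a
  # shared homology window, the trailing 9 diverge between the parents
  set.seed(7)
  H <- random_dna(8)
  DA <- "AAAAAAAAA"
  DB <- chartr("A", "C", DA)
  dupA <- random_dna(200); dupB <- random_dna(200)
  A <- genome("A", paste0(dupA, H, DA, random_dna(50)))
  B <- genome("B", paste0(random_dna(50), H, DB, dupB))
  # acceptor: left piece with bottom 5' overhang over H + DA
  accept <- cleave(A, cleavage_pair(200, 217))$left
  donor <- cleave(B, cleavage_pair(50, 67))$right
  j <- anneal(piece_end(accept, "right"), piece_end(donor, "left"),
              min_match = 6)
  expect_s3_class(j, "joint")
  expect_equal(j$paired, 8L)
  expect_equal(j$px, c(201L, 208L))            # the homology window in A
  merged <- trim_fill_ligate(j)
  # product: A duplex, homology window, then the donor's divergent 9 and
  # the donor duplex; the acceptor flap (DA) is gone
  expect_identical(merged$seq, paste0(dupA, H, DB, dupB))
  seg <- provenance_segments(merged)
  expect_equal(seg$donor[seg$start == 209], "fill")
  expect_equal(seg$end[seg$donor == "fill"] - seg$start[seg$donor == "fill"] + 1L,
               9L)
  ops <- vapply(merged$events, `[[`, "", "op")
  expect_true("trim" %in% ops && "fill" %in% ops && "ligate" %in% ops)
  trim <- merged$events[[which(ops == "trim")[1]]]
  expect_equal(diff(trim$coords) + 1L, 9L)     # the 9-nt displaced flap
})

test_that("CNSA-style joints excise non-homologous 3' nucleotides", {
  # 3' tails: acceptor tail ends with a 7-base homology; donor tail carries
  # 5 extra non-homologous 3' nucleotides that must be excised
  set.seed(8)
  H <- random_dna(7)
  dupA <- random_dna(150); dupB <- random_dna(150)
  A <- genome("A", paste0(dupA, H, random_dna(40)))
  B <- genome("B", paste0(random_dna(35), "GGGGG", H, dupB))
  accept <- resect_5to3(cleave(A, cleavage_pair(157, 150))$left, "right", 0)
  # bottom 3' tail of the donor spans its GGGGG + H region
  donor <- cleave(B, cleavage_pair(47, 35))$right
  eA <- piece_end(accept, "right"); eB <- piece_end(donor, "left")
  expect_equal(eA$polarity, "3p"); expect_equal(eB$polarity, "3p")
  j <- anneal(eA, eB, min_match = 7)
  expect_s3_class(j, "joint")
  expect_equal(j$paired, 7L)
  merged <- trim_fill_ligate(j)
  expect_identical(merged$seq, paste0(dupA, H, dupB))
  ops <- vapply(merged$events, `[[`, "", "op")
  trims <- merged$events[which(ops == "trim")]
  donor_trim <- Filter(function(e) e$piece == "donor", trims)
  expect_length(donor_trim, 1L)
  expect_equal(diff(donor_trim[[1]]$coords) + 1L, 5L)
})

test_that("CESA with identical parents returns the parent for any cuts", {
  g <- genome("A", random_dna(2000, seed = 9))
  g2 <- genome("B", g$seq)
  cuts <- list(cleavage_pair(500, 510), cleavage_pair(1500, 1512))
  prod <- cesa(g, g2, cutsA = cuts, cutsB = cuts, min_match = 6)
  expect_identical(prod$genome$seq, g$seq)
  # for the 3'-tail mechanism the donor cuts sit slightly off the acceptor
  # cuts so the resected tails share sequence
  cutsB <- list(cleavage_pair(470, 478), cleavage_pair(1530, 1540))
  prodn <- cnsa(g, g2, cutsA = cuts, cutsB = cutsB, resect = 30,
                min_match = 7)
  expect_identical(prodn$genome$seq, g$seq)
})

test_that("CESA on planted windows equals the splice oracle with switches inside them", {
  sp <- synthetic_spec(3000, divergence = 0.25,
                       identity_windows = data.frame(position = c(1000, 2000),
                                                     length = c(8, 15)),
                       seed = 11)
  pp <- generate_parent_pair(sp)
  c1 <- cleavage_pair(999, 1007)    # 5' overhang = the 8-bp window
  c2 <- cleavage_pair(1999, 2014)   # 5' overhang = the 15-bp window
  prod <- cesa(pp$A, pp$B, cutsA = list(c1, c2), cutsB = list(c1, c2))
  oracle <- splice_hybrid(pp$A, pp$B,
                          data.frame(donor = c("A", "B", "A"),
                                     start = c(1, 1008, 2015),
                                     end = c(1007, 2014, 3000)))$hybrid
  expect_identical(prod$genome$seq, oracle$seq)
  seg <- provenance_segments(prod)
  expect_equal(seg$donor, c("A", "B", "A"))
  # no silent edits: provenance maps back to the parents base by base
  chars <- strsplit(prod$genome$seq, "")[[1]]
  pa <- strsplit(pp$A$seq, "")[[1]]; pb <- strsplit(pp$B$seq, "")[[1]]
  isA <- prod$provenance == "A"; isB <- prod$provenance == "B"
  expect_true(all(chars[isA] == pa[prod$src[isA]]))
  expect_true(all(chars[isB] == pb[prod$src[isB]]))
})

test_that("CNSA anneals resected 3' tails at the microhomology", {
  sp <- synthetic_spec(3000, divergence = 0.25,
                       identity_windows = data.frame(position = c(1000, 2000),
                                                     length = c(8, 15)),
                       seed = 11)
  pp <- generate_parent_pair(sp)
  cutsA <- list(cleavage_pair(1006, 1014), cleavage_pair(1995, 2005))
  cutsB <- list(cleavage_pair(975, 991), cleavage_pair(2013, 2021))
  prod <- cnsa(pp$A, pp$B, cutsA = cutsA, cutsB = cutsB, resect = 40,
               min_match = 7)
  # the product must equal some splice with both switches inside the windows
  hits <- 0L
  for (s1 in 999:1007) for (s2 in 1999:2014) {
    o <- paste0(substr(pp$A$seq, 1, s1), substr(pp$B$seq, s1 + 1, s2),
                substr(pp$A$seq, s2 + 1, 3000))
    if (identical(o, prod$genome$seq)) hits <- hits + 1L
  }
  expect_gt(hits, 0L)
  # degenerate case: equivalent cuts and no resection reproduce CESA
  c1 <- cleavage_pair(999, 1007); c2 <- cleavage_pair(1999, 2014)
  expect_identical(
    cnsa(pp$A, pp$B, list(c1, c2), list(c1, c2), resect = 0,
         min_match = 6)$genome$seq,
    cesa(pp$A, pp$B, list(c1, c2), list(c1, c2), min_match = 6)$genome$seq)
})

test_that("recombinant products round-trip through the breakpoint caller", {
  sp <- synthetic_spec(3000, divergence = 0.15,
                       identity_windows = data.frame(position = c(1000, 2000),
                                                     length = c(8, 15)),
                       seed = 21)
  pp <- generate_parent_pair(sp)
  c1 <- cleavage_pair(999, 1007); c2 <- cleavage_pair(1999, 2014)
  prod <- cesa(pp$A, pp$B, list(c1, c2), list(c1, c2))
  calls <- call_crossovers(paint(three_way_align(prod$genome, pp$A, pp$B)))
  expect_length(calls, 2L)
  expect_lte(calls[[1]]$interval_start, 1008L)
  expect_gte(calls[[1]]$interval_end, 1000L)
  expect_lte(calls[[2]]$interval_start, 2015L)
  expect_gte(calls[[2]]$interval_end, 2000L)
  w <- vapply(lapply(calls, microhomology_window), `[[`, 0L, "length")
  expect_equal(w, c(8L, 15L))
})

test_that("event logs replay deterministically to the identical product", {
  sp <- synthetic_spec(2500, divergence = 0.2,
                       identity_windows = data.frame(position = c(800, 1700),
                                                     length = c(8, 12)),
                       seed = 31)
  pp <- generate_parent_pair(sp)
  c1 <- cleavage_pair(799, 807); c2 <- cleavage_pair(1699, 1711)
  prod <- cesa(pp$A, pp$B, list(c1, c2), list(c1, c2))
  expect_identical(replay_product(prod, pp$A, pp$B), prod)
  cutsA <- list(cleavage_pair(807, 814), cleavage_pair(1695, 1699))
  cutsB <- list(cleavage_pair(775, 790), cleavage_pair(1711, 1719))
  prodn <- cnsa(pp$A, pp$B, cutsA, cutsB, resect = 40)
  expect_identical(replay_product(prodn, pp$A, pp$B), prodn)
})

test_that("the stochastic wrapper is reproducible under a seed", {
  sp <- synthetic_spec(2500, divergence = 0.2,
                       identity_windows = data.frame(position = c(800, 1700),
                                                     length = c(8, 12)),
                       seed = 31)
  pp <- generate_parent_pair(sp)
  cand_left <- list(list(cutA = cleavage_pair(799, 807),
                         cutB = cleavage_pair(799, 807)),
                    list(cutA = cleavage_pair(800, 807),
                         cutB = cleavage_pair(800, 807)))
  cand_right <- list(list(cutA = cleavage_pair(1699, 1711),
                          cutB = cleavage_pair(1699, 1711)))
  d1 <- sample_recombinants(pp$A, pp$B, cand_left, cand_right, n = 8,
                            seed = 5, mechanism = "cesa")
  d2 <- sample_recombinants(pp$A, pp$B, cand_left, cand_right, n = 8,
                            seed = 5, mechanism = "cesa")
  expect_identical(d1, d2)
  expect_true(all(d1$ok))
  expect_true(all(d1$first_switch >= 800 & d1$first_switch <= 812))
})
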