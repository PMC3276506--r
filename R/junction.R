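#' @name junction
#' @title Pseudo-palindromes, hairpins and four-way junctions
#'
#' @description
#' A pseudo-palindrome is an imperfect inverted repeat: two arms that are
#' Watson-Crick complementary except for at most a few mismatched pairs,
#' separated by a short spacer (the loop once the arm folds back on itself).
#' In duplex DNA a pseudo-palindrome can extrude into a cruciform: two
#' opposed hairpins (one per strand) flanked by the two duplex arms, i.e. a
#' four-way junction of the kind cut by junction-resolving nucleases such as
#' phage T7 endonuclease I.
NULL

WC_PAIR <- c(A = "T", C = "G", G = "C", T = "A")

# is chars[i] Watson-Crick paired with chars[j]? N never pairs. An optional
# wobble flag additionally accepts G.T / T.G (RNA-style folding).
is_paired <- function(x, y, wobble = FALSE) {
  p <- !is.na(WC_PAIR[x]) & WC_PAIR[x] == y
  if (wobble) p <- p | (x == "G" & y == "T") | (x == "T" & y == "G")
  p & !is.na(p)
}

hairpin <- function(start, end, arm, loop, mismatches) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 arm = as.integer(arm), loop = as.integer(loop),
                 mismatches = as.integer(mismatches),
                 apex = as.integer(start + arm + (loop - 1L) %/% 2L)),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin> %d..%d: arm %d bp, loop %d nt, %d mismatch(es)\n",
              x$start, x$end, x$arm, x$loop, x$mismatches))
  invisible(x)
}

#' Scan a sequence for pseudo-palindromes (hairpins)
#'
#' Reports every maximal hairpin `X . loop . revcomp'(X)` with
#' `arm >= min_arm`, `3 <= loop <= max_loop` and at most `max_mismatch`
#' non-complementary arm pairs.  Maximal means extending the arms by one
#' more pair would exceed the mismatch budget or the sequence bounds.
#' Results are sorted by locus start, then loop length.
#'
#' @param seq A [genome] or DNA string.
#' @param min_arm Minimum arm length (>= 2).
#' @param max_loop Maximum loop length (minimum is the 3 nt steric floor).
#' @param max_mismatch Mismatch budget per hairpin.
#' @param wobble Also accept G.T pairs (RNA-mode folding).
#' @return `data.frame` with columns `start`, `end`, `arm`, `loop`,
#'   `mismatches`, `apex`.
#' @export
scan_inverted_repeats <- function(seq, min_arm = 4L, max_loop = 10L,
                                  max_mismatch = 0L, wobble = FALSE) {
  if (inherits(seq, "genome")) seq <- seq$seq
  seq <- normalize_dna(seq)
  if (min_arm < 2L) stop("min_arm must be >= 2")
  if (max_loop < 3L) stop("max_loop must be >= 3 (steric floor)")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  rows <- list()
  for (l in 3L:max_loop) {
    for (i in seq_len(n)) {            # i = loop start
      if (i + l + min_arm - 1L > n || i - min_arm < 1L) next
      mism <- 0L
      arm <- 0L; arm_mism <- 0L
      k <- 1L
      while (i - k >= 1L && i + l + k - 1L <= n) {
        ok <- is_paired(chars[i - k], chars[i + l + k - 1L], wobble)
        if (!ok) mism <- mism + 1L
        if (mism > max_mismatch) break
        arm <- k; arm_mism <- mism
        k <- k + 1L
      }
      if (arm >= min_arm)
        rows[[length(rows) + 1L]] <-
          c(start = i - arm, end = i + l + arm - 1L, arm = arm, loop = l,
            mismatches = arm_mism)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(), arm = integer(),
                      loop = integer(), mismatches = integer(),
                      apex = integer()))
  out <- as.data.frame(do.call(rbind, rows))
  out$apex <- out$start + out$arm + (out$loop - 1L) %/% 2L
  out <- out[order(out$start, out$loop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold an interval into its maximal-arm hairpin
#'
#' Folds exactly the given interval: the stem is contiguous and pairs the
#' interval's outermost bases inward; the arm is the longest one whose
#' mismatch count stays within `max_mismatch` and whose loop is at least
#' 3 nt (tie-break: longest arm, hence shortest loop).
#'
#' @param seq A [genome] or DNA string.
#' @param iv An [interval] of length >= 7 (or NULL to fold the whole
#'   string).
#' @param max_mismatch Mismatch budget (default 0).
#' @param wobble Accept G.T pairs.
#' @return A `hairpin` (coordinates on the input), or an object of class
#'   `unfoldable` if no stem with a >= 2 bp arm and >= 3 nt loop exists.
#' @export
fold_hairpin <- function(seq, iv = NULL, max_mismatch = 0L, wobble = FALSE) {
  if (inherits(seq, "genome")) seq <- seq$seq
  seq <- normalize_dna(seq)
  if (is.null(iv)) iv <- interval(1L, nchar(seq))
  n <- iv$end - iv$start + 1L
  if (n < 7L) stop("interval must span at least 7 nt")
  chars <- strsplit(substr(seq, iv$start, iv$end), "", fixed = TRUE)[[1]]
  amax <- (n - 3L) %/% 2L
  mism <- cumsum(!is_paired(chars[seq_len(amax)],
                            chars[n - seq_len(amax) + 1L], wobble))
  ok <- which(mism <= max_mismatch)
  ok <- ok[ok >= 2L]
  if (length(ok) == 0L)
    return(structure(list(start = iv$start, end = iv$end),
                     class = "unfoldable"))
  a <- max(ok)
  hairpin(iv$start, iv$end, a, n - 2L * a, mism[a])
}

#' @export
print.unfoldable <- function(x, ...) {
  cat(sprintf("<unfoldable> %d..%d: no stem with loop >= 3\n",
              x$start, x$end))
  invisible(x)
}

#' Build the cruciform four-way junction extruded by a hairpin
#'
#' The pseudo-palindrome extrudes into two opposed hairpins, one per strand,
#' occupying the same locus; the branch points are the two
#' duplex-to-hairpin transition bonds, and the four arms of the junction are
#' the two duplex flanks and the two hairpin stems.
#'
#' @param g A [genome].
#' @param h A hairpin on `g` (one row of [scan_inverted_repeats()] output,
#'   or a `hairpin`).
#' @param min_arm Minimum acceptable arm length; junction-resolving
#'   endonuclease I cleaves duplex arms as short as 2--4 bp, so the default
#'   is 2.
#' @return Object of class `four_way_junction`.
#' @export
build_four_way_junction <- function(g, h, min_arm = 2L) {
  if (is.data.frame(h)) {
    stopifnot(nrow(h) == 1L)
    h <- hairpin(h$start, h$end, h$arm, h$loop, h$mismatches)
  }
  L <- genome_length(g)
  if (h$start < 1L || h$end > L) stop("hairpin lies outside the genome")
  flank_left <- h$start - 1L
  flank_right <- L - h$end
  arms <- c(duplex_left = flank_left, stem_top = h$arm, stem_bottom = h$arm,
            duplex_right = flank_right)
  if (any(arms < min_arm))
    stop(sprintf("junction rejected: arm(s) below minimum %d bp (%s)",
                 min_arm,
                 paste(names(arms)[arms < min_arm], collapse = ", ")))
  bottom <- h
  # the bottom-strand hairpin occupies the same locus with the same
  # geometry: complementing both arms preserves pairing and mismatches
  structure(list(locus = interval(h$start, h$end),
                 top_hairpin = h, bottom_hairpin = bottom,
                 branch_points = c(h$start - 1L, h$end),
                 arm_lengths = arms, genome_id = g$id,
                 genome_length = L),
            class = "four_way_junction")
}

#' @export
print.four_way_junction <- function(x, ...) {
  cat(sprintf("<four_way_junction> %s %d..%d: stems %d bp (%d mismatch(es)), loop %d nt, branch bonds after %d and %d\n",
              x$genome_id, x$locus$start, x$locus$end, x$top_hairpin$arm,
              x$top_hairpin$mismatches, x$top_hairpin$loop,
              x$branch_points[1], x$branch_points[2]))
  invisible(x)
}

#' Assign endonuclease I cleavage bonds to a four-way junction
#'
#' Endo I cuts the two continuous (non-crossover) strands near the branch
#' points.  With `offset = 0` the cuts sit at the branch bonds: the top
#' strand is cut after position `locus start - 1` and the bottom strand
#' after position `locus end`, leaving complementary 5' overhangs spanning
#' the extruded region.  A nonzero `offset` translates both cut bonds
#' `offset` positions towards the 5' side of the top strand; the overhang
#' length (the bond separation) is unchanged.
#'
#' @param j A `four_way_junction`.
#' @param offset Cut offset in bonds (default 0 = at the branch points).
#' @return Object of class `cleavage_pair` with `top_cut` and `bottom_cut`
#'   ("cut after position i" bonds), overhang polarity and length.
#' @export
assign_endoI_cuts <- function(j, offset = 0L) {
  stopifnot(inherits(j, "four_way_junction"))
  top_cut <- j$branch_points[1] - offset
  bottom_cut <- j$branch_points[2] - offset
  if (top_cut < 1L || bottom_cut > j$genome_length - 1L)
    stop("cut bonds fall outside the genome")
  cleavage_pair(top_cut, bottom_cut)
}

#' Construct a cleavage pair
#'
#' @param top_cut,bottom_cut Bonds ("cut after position i") for the top and
#'   bottom strand, in top-strand coordinates.
#' @return Object of class `cleavage_pair` with the overhang polarity
#'   (5' if the bottom cut lies downstream of the top cut, 3' if upstream,
#'   blunt if equal) and overhang length `|bottom_cut - top_cut|`.
#' @export
cleavage_pair <- function(top_cut, bottom_cut) {
  top_cut <- as.integer(top_cut); bottom_cut <- as.integer(bottom_cut)
  polarity <- if (bottom_cut > top_cut) "5p"
              else if (bottom_cut < top_cut) "3p" else "blunt"
  structure(list(top_cut = top_cut, bottom_cut = bottom_cut,
                 polarity = polarity,
                 overhang_length = abs(bottom_cut - top_cut)),
            class = "cleavage_pair")
}

#' @export
print.cleavage_pair <- function(x, ...) {
  cat(sprintf("<cleavage_pair> top after %d, bottom after %d (%s%s)\n",
              x$top_cut, x$bottom_cut,
              switch(x$polarity, "5p" = "5' overhang, ",
                     "3p" = "3' overhang, ", blunt = "blunt"),
              if (x$polarity == "blunt") ""
              else sprintf("%d nt", x$overhang_length)))
  invisible(x)
}

#' Revalidate a reported hairpin by direct pair counting
#'
#' Counts complementary pairs over the arms of a reported hairpin; a valid
#' report satisfies `paired = arm - mismatches`.
#'
#' @param seq A [genome] or DNA string.
#' @param h One hairpin (row or `hairpin`).
#' @param wobble Accept G.T pairs.
#' @return Number of complementary arm pairs.
#' @export
count_arm_pairs <- function(seq, h, wobble = FALSE) {
  if (inherits(seq, "genome")) seq <- seq$seq
  if (is.data.frame(h)) h <- hairpin(h$start, h$end, h$arm, h$loop,
                                     h$mismatches)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- seq_len(h$arm)
  sum(is_paired(chars[h$start + k - 1L], chars[h$end - k + 1L], wobble))
}
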