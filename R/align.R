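#' @name three_way_alignment
#' @title Anchored three-way alignment of a hybrid and its two parents
#'
#' @description
#' The hybrid is aligned against both parents with an anchor-and-fill
#' strategy: k-mers (default k = 16) that occur exactly once in each of the
#' three sequences are chained monotonically (ties broken by leftmost start),
#' anchor blocks are clipped to be non-overlapping and trimmed at their edges,
#' and the regions between anchors are filled by affine-gap global alignment
#' (Needleman-Wunsch) of the corresponding subsequences.  The two pairwise
#' alignments (hybrid~A, hybrid~B) are merged on the hybrid row into
#' three-row columns.  The procedure is deterministic.
NULL

# substitution matrix over A,C,G,T,N where N mismatches everything
aln_submat <- function(match = 1, mismatch = -2) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

default_aln_params <- function() {
  list(k = 16L, anchor_trim = 5L, match = 1, mismatch = -2,
       gap_open = 5, gap_ext = 2)
}

# positions of k-mers occurring exactly once in the sequence
unique_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list(kmer = character(), pos = integer()))
  km <- substring(seq, 1:(n - k + 1L), k:n)
  keep <- !(duplicated(km) | duplicated(km, fromLast = TRUE))
  list(kmer = km[keep], pos = which(keep))
}

# longest chain of anchors strictly increasing in all three coordinates.
# Anchors are pre-sorted by hybrid position; an O(n log n) longest
# increasing subsequence on the A coordinate, then a greedy pass enforcing
# the B coordinate.  Ties broken leftmost.
chain_anchors <- function(anc) {
  if (nrow(anc) == 0L) return(anc)
  o <- order(anc$h, anc$a, anc$b)
  anc <- anc[o, , drop = FALSE]
  n <- nrow(anc)
  # patience LIS on a
  tails <- integer(0)        # index into anc of smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    v <- anc$a[i]
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (anc$a[tails[mid]] < v) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  idx <- integer(0)
  cur <- tails[length(tails)]
  while (cur > 0L) { idx <- c(cur, idx); cur <- prev[cur] }
  chain <- anc[idx, , drop = FALSE]
  # greedy filter for strictly increasing b
  keep <- logical(nrow(chain))
  last_b <- -Inf
  for (i in seq_len(nrow(chain))) {
    if (chain$b[i] > last_b) { keep[i] <- TRUE; last_b <- chain$b[i] }
  }
  chain[keep, , drop = FALSE]
}

# clip chained anchors so blocks are strictly non-overlapping in all three
# coordinate systems, then trim `trim` bases off both ends of each block
clip_anchors <- function(chain, k, trim) {
  if (nrow(chain) == 0L) return(chain)
  chain$len <- k
  out <- chain[0, , drop = FALSE]
  eh <- ea <- eb <- 0L   # last used position per sequence
  for (i in seq_len(nrow(chain))) {
    adv <- max(eh - chain$h[i] + 1L, ea - chain$a[i] + 1L,
               eb - chain$b[i] + 1L, 0L)
    len <- chain$len[i] - adv
    if (len < 1L) next
    row <- data.frame(h = chain$h[i] + adv, a = chain$a[i] + adv,
                      b = chain$b[i] + adv, len = len)
    out <- rbind(out, row)
    eh <- row$h + len - 1L; ea <- row$a + len - 1L; eb <- row$b + len - 1L
  }
  # edge trim leaves slack for the gap aligner near anchor boundaries
  if (trim > 0L && nrow(out) > 0L) {
    wide <- out$len - 2L * trim >= 4L
    out$h[wide] <- out$h[wide] + trim
    out$a[wide] <- out$a[wide] + trim
    out$b[wide] <- out$b[wide] + trim
    out$len[wide] <- out$len[wide] - 2L * trim
  }
  out
}

# affine global alignment of two strings; returns list(x=, y=) aligned with
# "-" gaps.  Empty inputs handled explicitly.
pair_align <- function(x, y, par) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx == 0L && ny == 0L) return(list(x = "", y = ""))
  if (nx == 0L) return(list(x = strrep("-", ny), y = y))
  if (ny == 0L) return(list(x = x, y = strrep("-", nx)))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y),
    type = "global", substitutionMatrix = aln_submat(par$match, par$mismatch),
    gapOpening = par$gap_open, gapExtension = par$gap_ext)
  list(x = as.character(Biostrings::alignedPattern(pa)),
       y = as.character(Biostrings::alignedSubject(pa)))
}

# anchored pairwise alignment of `ref` vs `other` given anchor table with
# columns r (ref pos), o (other pos), len.  All non-trivial inter-anchor
# gaps are aligned in one vectorised pairwiseAlignment call.
anchored_pair_align <- function(ref, other, anchors, par) {
  n_anc <- nrow(anchors)
  # gap regions before each anchor plus the tail gap
  pr <- c(1L, anchors$r + anchors$len)
  po <- c(1L, anchors$o + anchors$len)
  r_to <- c(anchors$r - 1L, nchar(ref))
  o_to <- c(anchors$o - 1L, nchar(other))
  gx <- substr(rep(ref, n_anc + 1L), pr, r_to)
  gy <- substr(rep(other, n_anc + 1L), po, o_to)
  gx[r_to < pr] <- ""
  gy[o_to < po] <- ""
  ax <- gx; ay <- gy
  # identical gap content needs no DP; empty-vs-nonempty is all-gap
  triv <- gx == gy
  one_sided <- xor(nzchar(gx), nzchar(gy)) & !triv
  ax[one_sided & !nzchar(gx)] <- strrep("-", nchar(gy[one_sided & !nzchar(gx)]))
  ay[one_sided & !nzchar(gy)] <- strrep("-", nchar(gx[one_sided & !nzchar(gy)]))
  # equal-length gaps with few mismatches: the diagonal (gapless) alignment
  # is provably optimal, since any gapped global alignment of equal-length
  # strings carries at least two gap runs (penalty 2*(open+ext)) and can
  # recoup at most (match - mismatch) per converted mismatch plus one
  # unmatched column of `match`
  eqlen <- !triv & !one_sided & nzchar(gx) & nchar(gx) == nchar(gy)
  if (any(eqlen)) {
    mism <- mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)),
                   gx[eqlen], gy[eqlen], USE.NAMES = FALSE)
    diag_ok <- mism * (par$match - par$mismatch) <=
      par$match + 2 * (par$gap_open + par$gap_ext)
    keep <- which(eqlen)[diag_ok]
    triv[keep] <- TRUE      # ax/ay already hold the ungapped strings
  }
  todo <- which(!triv & !one_sided)
  if (length(todo)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(gx[todo]), Biostrings::DNAStringSet(gy[todo]),
      type = "global",
      substitutionMatrix = aln_submat(par$match, par$mismatch),
      gapOpening = par$gap_open, gapExtension = par$gap_ext)
    ax[todo] <- as.character(Biostrings::alignedPattern(pa))
    ay[todo] <- as.character(Biostrings::alignedSubject(pa))
  }
  blocks <- if (n_anc > 0L)
    substr(rep(ref, n_anc), anchors$r, anchors$r + anchors$len - 1L)
  else character(0)
  xs <- character(2L * n_anc + 1L); ys <- xs
  xs[seq_len(n_anc + 1L) * 2L - 1L] <- ax
  ys[seq_len(n_anc + 1L) * 2L - 1L] <- ay
  if (n_anc > 0L) {
    xs[seq_len(n_anc) * 2L] <- blocks
    ys[seq_len(n_anc) * 2L] <- blocks
  }
  list(x = paste(xs, collapse = ""), y = paste(ys, collapse = ""))
}

# merge two pairwise alignments sharing the same ungapped reference row into
# three rows (ref, a, b); insertions relative to the reference are emitted
# a-first, then b (deterministic)
merge_on_reference <- function(al_a, al_b) {
  # fast path: neither pairwise alignment has gaps (collinear trio)
  if (!grepl("-", al_a$x, fixed = TRUE) && !grepl("-", al_b$x, fixed = TRUE))
    return(list(h = al_a$x, a = al_a$y, b = al_b$y))
  h1 <- strsplit(al_a$x, "", fixed = TRUE)[[1]]
  a1 <- strsplit(al_a$y, "", fixed = TRUE)[[1]]
  h2 <- strsplit(al_b$x, "", fixed = TRUE)[[1]]
  b2 <- strsplit(al_b$y, "", fixed = TRUE)[[1]]
  i <- 1L; j <- 1L
  n1 <- length(h1); n2 <- length(h2)
  H <- character(0); A <- character(0); B <- character(0)
  # process in chunks for speed: here a simple loop is fine for the sizes used
  res_h <- vector("list", n1 + n2); res_a <- res_h; res_b <- res_h; k <- 0L
  push <- function(h, a, b) {
    k <<- k + 1L; res_h[[k]] <<- h; res_a[[k]] <<- a; res_b[[k]] <<- b
  }
  while (i <= n1 || j <= n2) {
    ins_a <- i <= n1 && h1[i] == "-"
    ins_b <- j <= n2 && h2[j] == "-"
    if (ins_a) { push("-", a1[i], "-"); i <- i + 1L }
    else if (ins_b) { push("-", "-", b2[j]); j <- j + 1L }
    else {
      if (i > n1 || j > n2 || h1[i] != h2[j])
        stop("internal error: reference rows disagree during merge")
      push(h1[i], a1[i], b2[j]); i <- i + 1L; j <- j + 1L
    }
  }
  list(h = paste(unlist(res_h[seq_len(k)]), collapse = ""),
       a = paste(unlist(res_a[seq_len(k)]), collapse = ""),
       b = paste(unlist(res_b[seq_len(k)]), collapse = ""))
}

#' Three-way alignment of a hybrid genome and its two parents
#'
#' @param hybrid,A,B [genome]s; the three sequences must be near-collinear
#'   (share a chain of unique anchor k-mers).
#' @param params Optional list overriding `k` (anchor k-mer size, default
#'   16), `anchor_trim`, `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @return Object of class `three_way_alignment`: gapped rows `h`, `a`, `b`
#'   (equal length; degapping reproduces the inputs exactly), per-column
#'   source coordinates `h_pos`, `a_pos`, `b_pos` (NA at gaps), and the
#'   parameters used.
#' @export
three_way_align <- function(hybrid, A, B, params = list()) {
  par <- utils::modifyList(default_aln_params(), params)
  kh <- unique_kmers(hybrid$seq, par$k)
  ka <- unique_kmers(A$seq, par$k)
  kb <- unique_kmers(B$seq, par$k)
  common <- intersect(intersect(kh$kmer, ka$kmer), kb$kmer)
  if (length(common) == 0L)
    stop(paste0("no shared unique ", par$k, "-mers between the three ",
                "sequences; the genomes are not near-collinear -- supply a ",
                "precomputed alignment instead"))
  anc <- data.frame(h = kh$pos[match(common, kh$kmer)],
                    a = ka$pos[match(common, ka$kmer)],
                    b = kb$pos[match(common, kb$kmer)])
  anc <- chain_anchors(anc)
  anc <- clip_anchors(anc, par$k, par$anchor_trim)
  if (nrow(anc) == 0L)
    stop("anchor chaining failed; the genomes are not near-collinear")
  al_a <- anchored_pair_align(hybrid$seq, A$seq,
                              data.frame(r = anc$h, o = anc$a, len = anc$len),
                              par)
  al_b <- anchored_pair_align(hybrid$seq, B$seq,
                              data.frame(r = anc$h, o = anc$b, len = anc$len),
                              par)
  m <- merge_on_reference(al_a, al_b)
  stopifnot(identical(gsub("-", "", m$h, fixed = TRUE), hybrid$seq),
            identical(gsub("-", "", m$a, fixed = TRUE), A$seq),
            identical(gsub("-", "", m$b, fixed = TRUE), B$seq))
  hc <- strsplit(m$h, "", fixed = TRUE)[[1]]
  ac <- strsplit(m$a, "", fixed = TRUE)[[1]]
  bc <- strsplit(m$b, "", fixed = TRUE)[[1]]
  posify <- function(ch) { p <- cumsum(ch != "-"); p[ch == "-"] <- NA_integer_; p }
  structure(list(ids = c(hybrid = hybrid$id, A = A$id, B = B$id),
                 h = m$h, a = m$a, b = m$b,
                 h_chars = hc, a_chars = ac, b_chars = bc,
                 h_pos = posify(hc), a_pos = posify(ac), b_pos = posify(bc),
                 params = par, n_anchors = nrow(anc)),
            class = "three_way_alignment")
}

#' @export
print.three_way_alignment <- function(x, ...) {
  cat(sprintf("<three_way_alignment> %d columns (%s / %s / %s), %d anchor block(s)\n",
              nchar(x$h), x$ids[1], x$ids[2], x$ids[3], x$n_anchors))
  invisible(x)
}

#' Score a gapped pairwise alignment with affine gap penalties
#'
#' Companion to [three_way_align()]: scores two equal-length gapped rows
#' with the same scheme the gap-filling aligner uses (match/mismatch from
#' the substitution matrix, a gap run of length L costing
#' `gap_open + L * gap_ext`), so an anchored alignment can be compared
#' against a full dynamic-programming run.
#'
#' @param x,y Equal-length gapped sequences (`-` gaps).
#' @param params As in [three_way_align()].
#' @return Numeric score.
#' @export
score_pairwise <- function(x, y, params = list()) {
  par <- utils::modifyList(default_aln_params(), params)
  xc <- strsplit(x, "", fixed = TRUE)[[1]]
  yc <- strsplit(y, "", fixed = TRUE)[[1]]
  stopifnot(length(xc) == length(yc))
  gx <- xc == "-"; gy <- yc == "-"
  if (any(gx & gy)) stop("column with gaps in both rows")
  sub <- aln_submat(par$match, par$mismatch)
  score <- sum(sub[cbind(xc[!gx & !gy], yc[!gx & !gy])])
  runs <- function(g) { r <- rle(g); r$lengths[r$values] }
  gap_runs <- c(runs(gx), runs(gy))
  score - sum(vapply(gap_runs, function(L) par$gap_open + L * par$gap_ext, 0))
}

#' Extract the aligned hybrid~parent rows from a three-way alignment
#'
#' Drops columns that are gapped in both requested rows, yielding a proper
#' pairwise alignment.
#'
#' @param aln A `three_way_alignment`.
#' @param parent `"a"` or `"b"`.
#' @return List with gapped strings `x` (hybrid) and `y` (parent).
#' @export
pairwise_rows <- function(aln, parent = c("a", "b")) {
  parent <- match.arg(parent)
  yc <- if (parent == "a") aln$a_chars else aln$b_chars
  keep <- !(aln$h_chars == "-" & yc == "-")
  list(x = paste(aln$h_chars[keep], collapse = ""),
       y = paste(yc[keep], collapse = ""))
}
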