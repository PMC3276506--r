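#' @name recombine
#' @title Strand-annealing recombination simulators (CESA and CNSA)
#'
#' @description
#' Sequence-level models of two double-strand-break repair mechanisms that
#' can join two phage genomes across a short homology:
#' \describe{
#'   \item{CESA}{cleavage at *equivalent* sites in both parents (four-way
#'     junction resolution leaves complementary 5' overhangs) followed by
#'     strand annealing; the acceptor's non-homologous 5' flap is displaced
#'     and removed, the gap is filled from the donor tail, and the nicks are
#'     ligated.}
#'   \item{CNSA}{cleavage at *nonequivalent* sites, 5' resection of the
#'     break ends to expose 3' single-stranded tails, annealing of the tails
#'     at a microhomology, excision of the non-homologous 3' nucleotides,
#'     gap filling and ligation.}
#' }
#' A duplex piece tracks both strand extents in top-strand coordinates, so
#' end chemistry (blunt, 5' overhang, 3' overhang) is derived, not stored.
#' Enzymatic actors (Endo I, gp2.5, gp6, gp5/Trx, ligase) appear only in
#' event logs; the model is purely sequence-level and deterministic given
#' explicit cut sites.
NULL

# a duplex piece: seq is the top-strand-sense string covering
# [start .. start + nchar(seq) - 1] in the piece's own frame; top/bot are
# the absolute extents c(s, e) of the two strands; prov labels each covered
# position with its parent ("A"/"B"/"fill"); src is the parent coordinate
# (NA for fill)
dsb_piece <- function(parent, top, bot, label, events = list()) {
  region <- c(min(top[1], bot[1]), max(top[2], bot[2]))
  seq <- substr(parent$seq, region[1], region[2])
  structure(list(seq = seq, start = region[1],
                 top = as.integer(top), bot = as.integer(bot),
                 prov = rep(label, nchar(seq)),
                 src = region[1]:region[2],
                 label = label, events = events),
            class = "dsb_piece")
}

piece_char <- function(p, pos) substr(p$seq, pos - p$start + 1L, pos - p$start + 1L)
piece_sub <- function(p, s, e) substr(p$seq, s - p$start + 1L, e - p$start + 1L)

#' @export
print.dsb_piece <- function(x, ...) {
  cat(sprintf("<dsb_piece> top %d..%d, bottom %d..%d (%d event(s))\n",
              x$top[1], x$top[2], x$bot[1], x$bot[2], length(x$events)))
  cat(sprintf("  left end: %s; right end: %s\n",
              format_end(piece_end(x, "left")),
              format_end(piece_end(x, "right"))))
  invisible(x)
}

#' End chemistry of a duplex piece
#'
#' @param p A `dsb_piece`.
#' @param side `"left"` or `"right"`.
#' @return List with `polarity` (`"5p"`, `"3p"` or `"blunt"`), the
#'   protruding `strand`, the absolute tail extent `coords`, the tail in
#'   top-strand sense (`tail_topsense`) and as the actual single strand read
#'   5' to 3' (`tail_5to3`).
#' @export
piece_end <- function(p, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") {
    d <- p$bot[1] - p$top[1]
    if (d > 0) {          # top protrudes left: its 5' terminus
      coords <- c(p$top[1], p$bot[1] - 1L); strand <- "top"; pol <- "5p"
    } else if (d < 0) {   # bottom protrudes left: its 3' terminus
      coords <- c(p$bot[1], p$top[1] - 1L); strand <- "bottom"; pol <- "3p"
    } else { coords <- NULL; strand <- NA; pol <- "blunt" }
  } else {
    d <- p$top[2] - p$bot[2]
    if (d > 0) {          # top protrudes right: its 3' terminus
      coords <- c(p$bot[2] + 1L, p$top[2]); strand <- "top"; pol <- "3p"
    } else if (d < 0) {   # bottom protrudes right: its 5' terminus
      coords <- c(p$top[2] + 1L, p$bot[2]); strand <- "bottom"; pol <- "5p"
    } else { coords <- NULL; strand <- NA; pol <- "blunt" }
  }
  ts <- if (is.null(coords)) "" else piece_sub(p, coords[1], coords[2])
  t53 <- if (ts == "") "" else if (strand == "top") ts else revcomp(ts)
  structure(list(piece = p, side = side, polarity = pol, strand = strand,
                 coords = coords, tail_topsense = ts, tail_5to3 = t53),
            class = "piece_end")
}

format_end <- function(e) {
  if (e$polarity == "blunt") "blunt"
  else sprintf("%s' overhang %d nt (%s strand)",
               substr(e$polarity, 1, 1), nchar(e$tail_topsense), e$strand)
}

#' Cleave a genome into two duplex pieces
#'
#' @param g A [genome].
#' @param cuts A [cleavage_pair]: top-strand cut after `top_cut`,
#'   bottom-strand cut after `bottom_cut` (both 1..length-1).
#' @param label Provenance label for the pieces (default the genome id).
#' @return List with `left` and `right` `dsb_piece`s whose strands
#'   reconstruct the parent exactly.
#' @export
cleave <- function(g, cuts, label = g$id) {
  L <- genome_length(g)
  i <- cuts$top_cut; j <- cuts$bottom_cut
  if (i < 1L || i > L - 1L || j < 1L || j > L - 1L)
    stop(sprintf("cut bonds (%d, %d) cross the genome ends (1..%d)",
                 i, j, L - 1L))
  ev <- function(piece) list(list(op = "cleave", genome = g$id,
                                  top_cut = i, bottom_cut = j,
                                  piece = piece))
  list(left = dsb_piece(g, top = c(1L, i), bot = c(1L, j), label,
                        events = ev("left")),
       right = dsb_piece(g, top = c(i + 1L, L), bot = c(j + 1L, L), label,
                         events = ev("right")))
}

#' Excise the middle duplex piece between two cleavages
#'
#' @param g A [genome].
#' @param cuts_left,cuts_right [cleavage_pair]s with the left cuts strictly
#'   upstream of the right cuts.
#' @param label Provenance label.
#' @return The middle `dsb_piece`.
#' @export
middle_piece <- function(g, cuts_left, cuts_right, label = g$id) {
  if (cuts_left$top_cut >= cuts_right$top_cut ||
      cuts_left$bottom_cut >= cuts_right$bottom_cut)
    stop("left cuts must lie strictly upstream of right cuts")
  dsb_piece(g, top = c(cuts_left$top_cut + 1L, cuts_right$top_cut),
            bot = c(cuts_left$bottom_cut + 1L, cuts_right$bottom_cut),
            label,
            events = list(list(op = "cleave", genome = g$id,
                               top_cut = cuts_left$top_cut,
                               bottom_cut = cuts_left$bottom_cut,
                               piece = "middle-left"),
                          list(op = "cleave", genome = g$id,
                               top_cut = cuts_right$top_cut,
                               bottom_cut = cuts_right$bottom_cut,
                               piece = "middle-right")))
}

#' 5' to 3' resection of a piece end
#'
#' Removes `n` nucleotides from the 5'-terminal strand at the given end
#' (the top strand at a left end, the bottom strand at a right end),
#' lengthening the 3' overhang by `n`.
#'
#' @param p A `dsb_piece`.
#' @param side `"left"` or `"right"`.
#' @param n Number of nucleotides to remove (>= 0).
#' @return The resected piece.
#' @export
resect_5to3 <- function(p, side = c("left", "right"), n) {
  side <- match.arg(side)
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  if (n == 0L) return(p)
  if (side == "left") {
    if (p$top[1] + n > p$top[2])
      stop("resection exceeds the top strand length")
    p$top[1] <- p$top[1] + n
  } else {
    if (p$bot[2] - n < p$bot[1])
      stop("resection exceeds the bottom strand length")
    p$bot[2] <- p$bot[2] - n
  }
  p$events <- c(p$events, list(list(op = "resect", side = side, n = n)))
  p
}

#' Anneal two single-stranded break ends
#'
#' Finds the best complementary register between the single-stranded tails
#' of a right-side end and a left-side end of equal overhang polarity.  At
#' each register the paired region is the longest contiguous complementary
#' run (allowing up to `max_mismatch` internal violations, but always
#' starting and ending on a complementary pair); the best register maximises
#' that run, ties broken towards the smaller register shift.  Tail portions
#' outside the paired run are retained as flaps for [trim_fill_ligate()].
#'
#' @param endX A right-side [piece_end()].
#' @param endY A left-side [piece_end()].
#' @param min_match Minimum paired bases for a qualifying joint.
#' @param max_mismatch Mismatch budget inside the paired run (default 0).
#' @return A `joint`, or an `anneal_failure` (with a `reason`) if no
#'   register qualifies or the end chemistries are incompatible.
#' @export
anneal <- function(endX, endY, min_match = 6L, max_mismatch = 0L) {
  fail <- function(reason)
    structure(list(ok = FALSE, reason = reason), class = "anneal_failure")
  if (endX$side != "right" || endY$side != "left")
    return(fail("anneal expects a right-side end and a left-side end"))
  if (endX$polarity == "blunt" || endY$polarity == "blunt")
    return(fail("blunt end has no single-stranded tail to anneal"))
  if (endX$polarity != endY$polarity)
    return(fail(sprintf("polarity mismatch: %s vs %s overhangs",
                        endX$polarity, endY$polarity)))
  tx <- strsplit(endX$tail_topsense, "", fixed = TRUE)[[1]]
  ty <- strsplit(endY$tail_topsense, "", fixed = TRUE)[[1]]
  nx <- length(tx); ny <- length(ty)
  # complementarity of the antiparallel tails is equality in top-strand
  # sense; N never pairs
  best <- NULL
  for (d in (-(ny - 1L)):(nx - 1L)) {
    qs <- max(1L, 1L - d); qe <- min(ny, nx - d)
    if (qe - qs + 1L < 1L) next
    q <- qs:qe
    m <- tx[q + d] == ty[q] & tx[q + d] != "N"
    run <- best_run(m, max_mismatch)
    if (is.null(run)) next
    cand <- list(d = d, len = run$len, mism = run$mism,
                 q1 = q[run$from], q2 = q[run$to],
                 matches = sum(m))
    if (is.null(best) ||
        cand$len > best$len ||
        (cand$len == best$len && cand$matches > best$matches) ||
        (cand$len == best$len && cand$matches == best$matches &&
         abs(cand$d) < abs(best$d)) ||
        (cand$len == best$len && cand$matches == best$matches &&
         abs(cand$d) == abs(best$d) && cand$d < best$d))
      best <- cand
  }
  if (is.null(best) || best$len < min_match)
    return(fail(sprintf(
      "no register with >= %d paired bases (best %d)", min_match,
      if (is.null(best)) 0L else best$len)))
  # absolute coordinates of the paired run in each piece's frame
  px <- endX$coords[1] + (best$q1 + best$d) - 1L
  py <- endY$coords[1] + best$q1 - 1L
  len <- best$len
  structure(list(X = endX$piece, Y = endY$piece,
                 polarity = endX$polarity,
                 px = c(px, px + len - 1L), py = c(py, py + len - 1L),
                 shift = px - py, paired = len, mismatches = best$mism,
                 x_tail = endX$coords, y_tail = endY$coords),
            class = "joint")
}

# longest window in logical vector m with at most `budget` FALSEs, starting
# and ending on TRUE; returns from/to/len/mism or NULL
best_run <- function(m, budget) {
  n <- length(m)
  best <- NULL
  lo <- 1L; bad <- 0L
  for (hi in seq_len(n)) {
    if (!m[hi]) bad <- bad + 1L
    while (bad > budget) { if (!m[lo]) bad <- bad - 1L; lo <- lo + 1L }
    from <- lo; to <- hi
    while (from <= to && !m[from]) from <- from + 1L
    while (to >= from && !m[to]) to <- to - 1L
    if (from > to) next
    len <- to - from + 1L
    if (is.null(best) || len > best$len)
      best <- list(from = from, to = to, len = len,
                   mism = sum(!m[from:to]))
  }
  best
}

#' @export
print.joint <- function(x, ...) {
  cat(sprintf("<joint> %s-overhang anneal: %d paired (%d mismatch(es)); acceptor %d..%d ~ donor %d..%d\n",
              substr(x$polarity, 1, 1), x$paired, x$mismatches,
              x$px[1], x$px[2], x$py[1], x$py[2]))
  invisible(x)
}

#' @export
print.anneal_failure <- function(x, ...) {
  cat(sprintf("<anneal_failure> %s\n", x$reason))
  invisible(x)
}

#' Resolve an annealed joint: trim flaps, fill gaps, ligate
#'
#' Each tail's unpaired *terminal* portion (the part beyond the paired run
#' towards the strand's free terminus) is excised: for 5'-overhang joints
#' this is the displaced 5' flap, for 3'-overhang joints the non-homologous
#' 3' nucleotides.  Unpaired tail portions on the duplex side are retained;
#' any strand gap opposite such a retained template (or opposite intact
#' duplex) is filled by copying the template, with provenance `"fill"`.
#' Remaining nicks are ligated.
#'
#' @param joint An [anneal()] joint.
#' @return A merged `dsb_piece` in the acceptor's coordinate frame, with
#'   per-position provenance and the combined event log.
#' @export
trim_fill_ligate <- function(joint) {
  if (inherits(joint, "anneal_failure"))
    stop(sprintf("cannot resolve a failed joint: %s", joint$reason))
  stopifnot(inherits(joint, "joint"))
  X <- joint$X; Y <- joint$Y
  events <- c(X$events, Y$events,
              list(list(op = "anneal", polarity = joint$polarity,
                        paired = joint$paired,
                        acceptor = joint$px, donor = joint$py)))
  # trim unpaired terminal tail portions
  if (joint$polarity == "5p") {
    # X right end: 5' tail on the bottom strand, free terminus at the
    # highest coordinate; Y left end: 5' tail on top, terminus lowest
    if (X$bot[2] > joint$px[2]) {
      events <- c(events, list(list(op = "trim", piece = "acceptor",
                                    strand = "bottom",
                                    coords = c(joint$px[2] + 1L, X$bot[2]))))
      X$bot[2] <- joint$px[2]
    }
    if (Y$top[1] < joint$py[1]) {
      events <- c(events, list(list(op = "trim", piece = "donor",
                                    strand = "top",
                                    coords = c(Y$top[1], joint$py[1] - 1L))))
      Y$top[1] <- joint$py[1]
    }
  } else {
    # 3' joints: X tail on top (terminus highest), Y tail on bottom
    # (terminus lowest)
    if (X$top[2] > joint$px[2]) {
      events <- c(events, list(list(op = "trim", piece = "acceptor",
                                    strand = "top",
                                    coords = c(joint$px[2] + 1L, X$top[2]))))
      X$top[2] <- joint$px[2]
    }
    if (Y$bot[1] < joint$py[1]) {
      events <- c(events, list(list(op = "trim", piece = "donor",
                                    strand = "bottom",
                                    coords = c(Y$bot[1], joint$py[1] - 1L))))
      Y$bot[1] <- joint$py[1]
    }
  }
  S <- joint$shift
  topY <- Y$top + S; botY <- Y$bot + S
  gap_top <- c(X$top[2] + 1L, topY[1] - 1L)
  gap_bot <- c(X$bot[2] + 1L, botY[1] - 1L)
  if (gap_top[2] < gap_top[1] - 1L || gap_bot[2] < gap_bot[1] - 1L)
    stop("joint resolution would overlap strands; incompatible cut geometry")
  region <- c(min(X$top[1], X$bot[1]), max(topY[2], botY[2]))
  n <- region[2] - region[1] + 1L
  chars <- character(n); prov <- character(n); src <- rep(NA_integer_, n)
  at <- function(pos) pos - region[1] + 1L
  # acceptor contribution
  xe <- max(X$top[2], X$bot[2])
  idx <- at(region[1]:xe)
  chars[idx] <- strsplit(piece_sub(X, region[1], xe), "", fixed = TRUE)[[1]]
  prov[idx] <- X$prov[(region[1]:xe) - X$start + 1L]
  src[idx] <- X$src[(region[1]:xe) - X$start + 1L]
  # donor contribution (shifted frame)
  ys <- min(topY[1], botY[1])
  idx <- at(ys:region[2])
  chars[idx] <- strsplit(piece_sub(Y, ys - S, region[2] - S), "",
                         fixed = TRUE)[[1]]
  prov[idx] <- Y$prov[(ys:region[2]) - S - Y$start + 1L]
  src[idx] <- Y$src[(ys:region[2]) - S - Y$start + 1L]
  # paired region: both strands are authentic; where the heteroduplex
  # mismatches, the top-strand base (and its provenance) wins
  if (joint$paired > 0L) {
    pcoords <- joint$px[1]:joint$px[2]
    ppos <- at(pcoords)
    xs_chars <- strsplit(piece_sub(X, joint$px[1], joint$px[2]), "",
                         fixed = TRUE)[[1]]
    ys_chars <- strsplit(piece_sub(Y, joint$py[1], joint$py[2]), "",
                         fixed = TRUE)[[1]]
    # in a 5' joint the top strand of the heteroduplex comes from the donor,
    # in a 3' joint from the acceptor; the top-strand base wins where the
    # (budgeted) heteroduplex mismatches
    top_from_y <- joint$polarity == "5p"
    chars[ppos] <- if (top_from_y) ys_chars else xs_chars
    p_prov <- X$prov[pcoords - X$start + 1L]
    p_src <- X$src[pcoords - X$start + 1L]
    sel <- xs_chars != ys_chars
    if (top_from_y && any(sel)) {
      yi <- (joint$py[1]:joint$py[2])[sel] - Y$start + 1L
      p_prov[sel] <- Y$prov[yi]
      p_src[sel] <- Y$src[yi]
    }
    prov[ppos] <- p_prov
    src[ppos] <- p_src
  }
  # fill strand gaps from the opposite-strand template
  fills <- integer()
  for (gap in list(gap_top, gap_bot)) {
    if (gap[2] < gap[1]) next
    gpos <- gap[1]:gap[2]
    covered <- (gpos >= X$top[1] & gpos <= X$top[2]) |
      (gpos >= X$bot[1] & gpos <= X$bot[2]) |
      (gpos >= topY[1] & gpos <= topY[2]) |
      (gpos >= botY[1] & gpos <= botY[2])
    if (!all(covered))
      stop(sprintf("no template strand covers gap %d..%d", gap[1], gap[2]))
    fills <- c(fills, gpos)
  }
  if (length(fills)) {
    fills <- sort(unique(fills))
    prov[at(fills)] <- "fill"
    src[at(fills)] <- NA_integer_
    events <- c(events, list(list(op = "fill", coords = range(fills),
                                  n = length(fills))))
  }
  events <- c(events, list(list(op = "ligate",
                                top_nick = X$top[2],
                                bottom_nick = X$bot[2])))
  merged <- structure(list(
    seq = paste(chars, collapse = ""), start = region[1],
    top = c(min(X$top[1], X$bot[1]), region[2]),
    bot = c(min(X$top[1], X$bot[1]), region[2]),
    prov = prov, src = src, label = "recombinant", events = events),
    class = "dsb_piece")
  # the merged piece is duplex across its interior, but its outer ends keep
  # the untouched chemistry of the two input pieces
  merged$top <- c(X$top[1], topY[2])
  merged$bot <- c(X$bot[1], botY[2])
  merged
}
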