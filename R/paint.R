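#' Paint a hybrid genome by parental origin
#'
#' Classifies every alignment column of a hybrid/parent-A/parent-B
#' three-way alignment by deterministic parsimony:
#' \describe{
#'   \item{`A`}{A-diagnostic: hybrid = A, hybrid != B.}
#'   \item{`B`}{B-diagnostic: hybrid = B, hybrid != A.}
#'   \item{`shared`}{hybrid = A = B.}
#'   \item{`private`}{hybrid differs from both parents (a mutation private
#'     to the hybrid, not a switch).}
#'   \item{`gap`}{any of the three rows is gapped.}
#' }
#' `N` mismatches every base, including itself.
#'
#' @param aln A [three_way_align()] result.
#' @return Object of class `painting`: per-column `class`, source
#'   coordinates, and run-length `segments` (a `data.frame` with the class,
#'   column range and hybrid coordinate range of each contiguous run).
#' @export
paint <- function(aln) {
  stopifnot(inherits(aln, "three_way_alignment"))
  h <- aln$h_chars; a <- aln$a_chars; b <- aln$b_chars
  eq <- function(x, y) x == y & x != "N" & x != "-"
  ha <- eq(h, a); hb <- eq(h, b)
  cls <- rep("private", length(h))
  cls[ha & hb] <- "shared"
  cls[ha & !hb] <- "A"
  cls[!ha & hb] <- "B"
  cls[h == "-" | a == "-" | b == "-"] <- "gap"
  r <- rle(cls)
  to <- cumsum(r$lengths)
  from <- to - r$lengths + 1L
  hs <- aln$h_pos[from]; he <- aln$h_pos[to]
  segments <- data.frame(class = r$values, col_start = from, col_end = to,
                         h_start = hs, h_end = he,
                         stringsAsFactors = FALSE)
  structure(list(class = cls, h_pos = aln$h_pos, a_pos = aln$a_pos,
                 b_pos = aln$b_pos, segments = segments, aln = aln),
            class = "painting")
}

#' @export
print.painting <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("A", "B", "shared", "private", "gap")))
  cat("<painting> column classes:\n")
  print(tab)
  invisible(x)
}

#' Painting as a per-position table
#'
#' @param p A [paint()] result.
#' @return `data.frame` with one row per alignment column: `class` and the
#'   hybrid/parent coordinates (NA at gaps).
#' @export
painting_table <- function(p) {
  data.frame(column = seq_along(p$class), class = p$class,
             hybrid_pos = p$h_pos, parentA_pos = p$a_pos,
             parentB_pos = p$b_pos, stringsAsFactors = FALSE)
}

#' Call crossover intervals from a painting
#'
#' A crossover is emitted between every adjacent pair of opposite-parent
#' diagnostic columns.  The ambiguity interval is the open run between them
#' in hybrid coordinates: the switch cannot be localised further because the
#' intervening sequence is identical between the parents.  Private columns
#' are mutations, not switches; they never split a call but are listed in
#' its report.
#'
#' @param p A [paint()] result.
#' @return List of `crossover_call` objects (empty, with a warning, if the
#'   painting has no diagnostic columns).  Each call carries the flanking
#'   diagnostic columns, the direction (`"A->B"` or `"B->A"`), the ambiguity
#'   interval in hybrid coordinates (`length` may be 0), and the hybrid
#'   positions of any private columns inside it.
#' @export
call_crossovers <- function(p) {
  stopifnot(inherits(p, "painting"))
  dcols <- which(p$class %in% c("A", "B"))
  if (length(dcols) == 0L) {
    warning("painting has no diagnostic columns; no crossovers can be called")
    return(list())
  }
  lab <- p$class[dcols]
  out <- list()
  for (i in seq_len(length(dcols) - 1L)) {
    if (lab[i] == lab[i + 1L]) next
    lc <- dcols[i]; rc <- dcols[i + 1L]
    open_cols <- if (rc > lc + 1L) (lc + 1L):(rc - 1L) else integer()
    priv <- open_cols[p$class[open_cols] == "private"]
    hs <- p$h_pos[lc] + 1L
    he <- p$h_pos[rc] - 1L
    out[[length(out) + 1L]] <- structure(list(
      direction = paste0(lab[i], "->", lab[i + 1L]),
      left_col = lc, right_col = rc,
      left_diag_hpos = p$h_pos[lc], right_diag_hpos = p$h_pos[rc],
      interval_start = hs, interval_end = he,
      interval_length = max(0L, he - hs + 1L),
      private_inside = p$h_pos[priv],
      painting = p), class = "crossover_call")
  }
  out
}

#' @export
print.crossover_call <- function(x, ...) {
  cat(sprintf("<crossover_call> %s; ambiguity interval %s (length %d)%s\n",
              x$direction,
              if (x$interval_length > 0L)
                sprintf("hybrid %d..%d", x$interval_start, x$interval_end)
              else sprintf("between hybrid %d and %d",
                           x$left_diag_hpos, x$right_diag_hpos),
              x$interval_length,
              if (length(x$private_inside))
                sprintf("; %d private column(s) inside",
                        length(x$private_inside)) else ""))
  invisible(x)
}

#' Microhomology window of a crossover
#'
#' The maximal run of alignment columns where the two parents agree (no
#' gaps, `N` never matches) containing the crossover's ambiguity interval,
#' reported as an interval in parent-A coordinates with its length in bp.
#' This is the window within which a strand-annealing crossover cannot be
#' localised; parents identical over the whole alignment give a degenerate
#' whole-genome window, which is flagged.
#'
#' @param call A [call_crossovers()] call.
#' @return Object of class `microhomology_window`: `a_start`, `a_end`,
#'   `length` (bp), `degenerate` flag, and whether the window fully
#'   contains the ambiguity interval.
#' @export
microhomology_window <- function(call) {
  stopifnot(inherits(call, "crossover_call"))
  p <- call$painting
  aln <- p$aln
  eq <- aln$a_chars == aln$b_chars & aln$a_chars != "-" & aln$a_chars != "N"
  ncol <- length(eq)
  # expand outward from the open interval between the flanking diagnostics
  lo <- call$left_col + 1L
  hi <- call$right_col - 1L
  if (lo > hi) {
    # zero-length ambiguity interval: the window is the empty bond between
    # the two diagnostic columns
    return(structure(list(a_start = NA_integer_, a_end = NA_integer_,
                          length = 0L, degenerate = FALSE, contains = TRUE),
                     class = "microhomology_window"))
  }
  if (!all(eq[lo:hi])) {
    # broken identity inside the interval: fall back to the longest
    # identical run within it (leftmost on ties)
    r <- rle(eq[lo:hi])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    lo2 <- lo + starts[best] - 1L
    hi2 <- lo + ends[best] - 1L
    contains <- FALSE
    lo <- lo2; hi <- hi2
  } else contains <- TRUE
  while (lo > 1L && eq[lo - 1L]) lo <- lo - 1L
  while (hi < ncol && eq[hi + 1L]) hi <- hi + 1L
  acols <- which(!is.na(aln$a_pos[lo:hi])) + lo - 1L
  structure(list(a_start = aln$a_pos[min(acols)],
                 a_end = aln$a_pos[max(acols)],
                 length = sum(eq[lo:hi]),
                 degenerate = lo == 1L && hi == ncol,
                 contains = contains),
            class = "microhomology_window")
}

#' @export
print.microhomology_window <- function(x, ...) {
  cat(sprintf("<microhomology_window> parent-A %s, length %d bp%s\n",
              if (is.na(x$a_start)) "(empty)"
              else sprintf("%d..%d", x$a_start, x$a_end),
              x$length,
              if (x$degenerate) " [degenerate: parents identical]" else ""))
  invisible(x)
}
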