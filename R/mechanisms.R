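#' @rdname recombine
#' @details
#' `cesa()` runs the full equivalent-site mechanism: parent A is cleaved at
#' two junctions (its left and right arms are the acceptor ends), parent B
#' at the two equivalent junctions (the middle piece is the donor), and the
#' two joints are annealed and resolved.  The product's provenance shows an
#' A prefix, a B patch and an A suffix, with `"fill"` marking re-synthesised
#' positions.
#'
#' @param A,B Parent [genome]s (acceptor and donor, respectively).
#' @param cutsA,cutsB Lists of two [cleavage_pair]s each (left and right
#'   cut, in genome order).
#' @param min_match Minimum annealed bases per joint (default 6 for the
#'   5'-overhang CESA joints, 7 for the 3'-tail CNSA joints).
#' @param max_mismatch Mismatch budget inside an annealed run (default 0).
#' @return An object of class `recombination_product`: the recombinant
#'   [genome], per-position `provenance` (`"A"`, `"B"` or `"fill"`), source
#'   coordinates `src`, and the ordered `event_log`.
#' @export
cesa <- function(A, B, cutsA, cutsB, min_match = 6L, max_mismatch = 0L) {
  run_mechanism(A, B, cutsA, cutsB, resect = 0L, min_match = min_match,
                max_mismatch = max_mismatch, mechanism = "CESA")
}

#' @rdname recombine
#' @details
#' `cnsa()` differs from `cesa()` by 5'-resecting all four break ends by
#' `resect` nucleotides before annealing, so the joints anneal 3'
#' single-stranded tails at a microhomology; the non-homologous 3'
#' nucleotides of a tail are excised during resolution.
#'
#' @param resect 5' resection length in nt applied to each break end before
#'   annealing (CNSA only).  Must be long enough to expose the
#'   microhomology as a 3' tail.
#' @export
cnsa <- function(A, B, cutsA, cutsB, resect = 40L, min_match = 7L,
                 max_mismatch = 0L) {
  run_mechanism(A, B, cutsA, cutsB, resect = as.integer(resect),
                min_match = min_match, max_mismatch = max_mismatch,
                mechanism = "CNSA")
}

run_mechanism <- function(A, B, cutsA, cutsB, resect, min_match,
                          max_mismatch, mechanism) {
  stopifnot(length(cutsA) == 2L, length(cutsB) == 2L)
  a_left <- cleave(A, cutsA[[1]], label = "A")$left
  a_right <- cleave(A, cutsA[[2]], label = "A")$right
  donor <- middle_piece(B, cutsB[[1]], cutsB[[2]], label = "B")
  if (resect > 0L) {
    a_left <- resect_5to3(a_left, "right", resect)
    a_right <- resect_5to3(a_right, "left", resect)
    donor <- resect_5to3(donor, "left", resect)
    donor <- resect_5to3(donor, "right", resect)
  }
  j1 <- anneal(piece_end(a_left, "right"), piece_end(donor, "left"),
               min_match = min_match, max_mismatch = max_mismatch)
  if (inherits(j1, "anneal_failure"))
    stop(sprintf("%s left joint failed: %s", mechanism, j1$reason))
  p1 <- trim_fill_ligate(j1)
  j2 <- anneal(piece_end(p1, "right"), piece_end(a_right, "left"),
               min_match = min_match, max_mismatch = max_mismatch)
  if (inherits(j2, "anneal_failure"))
    stop(sprintf("%s right joint failed: %s", mechanism, j2$reason))
  prod <- trim_fill_ligate(j2)
  stopifnot(prod$top[1] == 1L, prod$bot[1] == 1L,
            prod$top[2] == prod$bot[2])
  params <- list(mechanism = mechanism,
                 cutsA = cutsA, cutsB = cutsB, resect = resect,
                 min_match = min_match, max_mismatch = max_mismatch)
  structure(list(
    genome = genome(sprintf("%s_%s_x_%s", tolower(mechanism), A$id, B$id),
                    prod$seq),
    provenance = prod$prov, src = prod$src,
    event_log = c(list(list(op = "start", mechanism = mechanism,
                            params = params)), prod$events),
    parents = c(A = A$id, B = B$id), params = params),
    class = "recombination_product")
}

#' @export
print.recombination_product <- function(x, ...) {
  r <- rle(x$provenance)
  cat(sprintf("<recombination_product> %s: %d bp; provenance %s; %d logged event(s)\n",
              x$genome$id, genome_length(x$genome),
              paste(sprintf("%s(%d)", r$values, r$lengths), collapse = " "),
              length(x$event_log)))
  invisible(x)
}

#' Provenance segments of a recombination product
#'
#' @param x A `recombination_product` (or an intermediate `dsb_piece`).
#' @return `data.frame` with one row per contiguous provenance run
#'   (`donor`, `start`, `end` in product coordinates).
#' @export
provenance_segments <- function(x) {
  r <- rle(if (inherits(x, "dsb_piece")) x$prov else x$provenance)
  to <- cumsum(r$lengths)
  data.frame(donor = r$values, start = to - r$lengths + 1L, end = to,
             stringsAsFactors = FALSE)
}

#' Replay a recombination product's event log
#'
#' The event log records the mechanism and every parameter of the run;
#' replaying re-executes the mechanism from the logged parameters and
#' returns the reconstructed product, which must be identical to the
#' original -- the determinism check for the simulators.
#'
#' @param x A `recombination_product`.
#' @param A,B The parent genomes.
#' @return The replayed `recombination_product`.
#' @export
replay_product <- function(x, A, B) {
  p <- x$params
  if (p$mechanism == "CESA")
    cesa(A, B, p$cutsA, p$cutsB, min_match = p$min_match,
         max_mismatch = p$max_mismatch)
  else
    cnsa(A, B, p$cutsA, p$cutsB, resect = p$resect,
         min_match = p$min_match, max_mismatch = p$max_mismatch)
}

#' Sample recombinants over candidate cleavage sites
#'
#' The deterministic simulators take explicit cut sites; this stochastic
#' wrapper samples cut-site pairings from candidate lists (e.g. the
#' junction module's Endo I assignments near each crossover region) and
#' reports the distribution of realised crossover positions -- multiple
#' cleavable junctions per region is what raises recombination frequency.
#'
#' @param A,B Parent [genome]s.
#' @param candidates_left,candidates_right Lists of candidate
#'   `list(cutA = cleavage_pair, cutB = cleavage_pair)` pairings for the
#'   left and right joint regions.
#' @param n Number of draws.
#' @param seed Mandatory integer seed.
#' @param mechanism `"cesa"` or `"cnsa"`.
#' @param ... Passed to the mechanism.
#' @return `data.frame` with one row per draw: the candidate indices, a
#'   success flag, and the product's first/last switch positions.
#' @export
sample_recombinants <- function(A, B, candidates_left, candidates_right,
                                n = 20L, seed, mechanism = c("cesa", "cnsa"),
                                ...) {
  mechanism <- match.arg(mechanism)
  fun <- if (mechanism == "cesa") cesa else cnsa
  with_seed(seed, {
    il <- sample.int(length(candidates_left), n, replace = TRUE)
    ir <- sample.int(length(candidates_right), n, replace = TRUE)
    rows <- lapply(seq_len(n), function(k) {
      cl <- candidates_left[[il[k]]]; cr <- candidates_right[[ir[k]]]
      res <- tryCatch(
        fun(A, B, cutsA = list(cl$cutA, cr$cutA),
            cutsB = list(cl$cutB, cr$cutB), ...),
        error = function(e) e)
      if (inherits(res, "error"))
        return(data.frame(draw = k, left_candidate = il[k],
                          right_candidate = ir[k], ok = FALSE,
                          first_switch = NA_integer_,
                          last_switch = NA_integer_))
      seg <- provenance_segments(res)
      sw <- seg$start[-1L]
      data.frame(draw = k, left_candidate = il[k], right_candidate = ir[k],
                 ok = TRUE,
                 first_switch = if (length(sw)) min(sw) else NA_integer_,
                 last_switch = if (length(sw)) max(sw) else NA_integer_)
    })
    do.call(rbind, rows)
  })
}
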