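#' @name synthetic
#' @title Synthetic parent/hybrid genomes with known truth
#'
#' @description
#' The generator emulates the situation of two near-collinear phage genomes
#' (such as T3 and T7): a parent pair diverged by i.i.d. substitutions at a
#' chosen per-site rate, with forced-identical windows planted inside the
#' divergent context (the microhomology windows crossovers resolve into),
#' planted pseudo-palindromes near prospective crossover sites, and hybrids
#' spliced from the parents with sporadic private point substitutions.  Every
#' construction records its exact truth so downstream inference can be scored.
NULL

DNA4 <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification for a synthetic parent pair
#'
#' @param length Genome length in bp.
#' @param divergence Per-site substitution probability between the parents,
#'   in `[0, 0.5]`.
#' @param identity_windows Optional `data.frame` with columns `position`,
#'   `length`: runs forced identical between the parents.
#' @param palindromes Optional `data.frame` with columns `position`, `arm`,
#'   `loop`, `mismatches`: pseudo-palindromes planted (identically) in both
#'   parents.
#' @param indel_rate Per-site probability of a 1--20 bp indel in parent B
#'   (default 0 so the trio stays collinear).
#' @param seed Mandatory integer seed; there is no implicit global RNG.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(length, divergence = 0.05, identity_windows = NULL,
                           palindromes = NULL, indel_rate = 0, seed) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1")
  if (divergence < 0 || divergence > 0.5)
    stop("divergence must be in [0, 0.5]")
  if (indel_rate < 0 || indel_rate > 0.01)
    stop("indel_rate must be in [0, 0.01]")
  if (missing(seed)) stop("seed is mandatory")
  feats <- list()
  if (!is.null(identity_windows)) {
    identity_windows <- as.data.frame(identity_windows)
    stopifnot(all(c("position", "length") %in% names(identity_windows)))
    feats <- c(feats, lapply(seq_len(nrow(identity_windows)), function(i)
      c(identity_windows$position[i],
        identity_windows$position[i] + identity_windows$length[i] - 1L)))
  }
  if (!is.null(palindromes)) {
    palindromes <- as.data.frame(palindromes)
    stopifnot(all(c("position", "arm", "loop") %in% names(palindromes)))
    if (is.null(palindromes$mismatches)) palindromes$mismatches <- 0L
    feats <- c(feats, lapply(seq_len(nrow(palindromes)), function(i)
      c(palindromes$position[i],
        palindromes$position[i] + 2L * palindromes$arm[i] +
          palindromes$loop[i] - 1L)))
  }
  if (length(feats)) {
    bounds <- do.call(rbind, feats)
    if (any(bounds[, 1] < 1L) || any(bounds[, 2] > length))
      stop("identity windows / palindromes must lie within the genome")
    o <- order(bounds[, 1])
    bounds <- bounds[o, , drop = FALSE]
    if (nrow(bounds) > 1L &&
        any(bounds[-1L, 1] <= bounds[-nrow(bounds), 2]))
      stop("identity windows / palindromes must not overlap")
  }
  structure(list(length = length, divergence = divergence,
                 identity_windows = identity_windows,
                 palindromes = palindromes, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# vector of positions protected from divergence (windows + palindromes)
protected_positions <- function(spec) {
  prot <- logical(spec$length)
  w <- spec$identity_windows
  if (!is.null(w))
    for (i in seq_len(nrow(w)))
      prot[w$position[i]:(w$position[i] + w$length[i] - 1L)] <- TRUE
  p <- spec$palindromes
  if (!is.null(p))
    for (i in seq_len(nrow(p)))
      prot[p$position[i]:(p$position[i] + 2L * p$arm[i] + p$loop[i] - 1L)] <- TRUE
  prot
}

#' Generate a diverged parent genome pair
#'
#' Parent B is derived from parent A by i.i.d. substitutions at rate
#' `spec$divergence` (uniform over the three alternative bases) and, if
#' `indel_rate > 0`, sporadic 1--20 bp indels; forced-identity windows and
#' planted palindromes are never mutated.  Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec].
#' @return List with elements `A`, `B` (genomes), `truth` (integer vector of
#'   every substituted position, in A coordinates) and `indels` (a
#'   `data.frame` of indel events, empty when `indel_rate = 0`).
#' @export
generate_parent_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    a <- sample(DNA4, L, replace = TRUE)
    p <- spec$palindromes
    if (!is.null(p))
      for (i in seq_len(nrow(p)))
        a <- plant_palindrome_chars(a, p$position[i], p$arm[i], p$loop[i],
                                    p$mismatches[i])
    prot <- protected_positions(spec)
    b <- a
    sub_at <- which(stats::runif(L) < spec$divergence & !prot)
    if (length(sub_at)) {
      shift <- sample(1:3, length(sub_at), replace = TRUE)
      idx <- (match(a[sub_at], DNA4) - 1L + shift) %% 4L + 1L
      b[sub_at] <- DNA4[idx]
    }
    # identity windows must sit in divergent context: force the positions
    # immediately flanking each window to differ so the window is the exact
    # microhomology truth
    w <- spec$identity_windows
    if (!is.null(w)) {
      flanks <- c(w$position - 1L, w$position + w$length)
      flanks <- flanks[flanks >= 1L & flanks <= L]
      flanks <- flanks[!prot[flanks]]
      if (length(flanks)) {
        shift <- sample(1:3, length(flanks), replace = TRUE)
        idx <- (match(a[flanks], DNA4) - 1L + shift) %% 4L + 1L
        b[flanks] <- DNA4[idx]
      }
    }
    truth <- which(a != b)   # indels are applied below, after truth is taken
    indels <- data.frame(position = integer(), type = character(),
                         length = integer(), stringsAsFactors = FALSE)
    if (spec$indel_rate > 0) {
      at <- which(stats::runif(L) < spec$indel_rate & !prot)
      if (length(at)) {
        type <- sample(c("ins", "del"), length(at), replace = TRUE)
        len <- sample(1:20, length(at), replace = TRUE)
        # apply right-to-left so earlier coordinates stay valid
        for (i in rev(seq_along(at))) {
          pos <- at[i]
          if (type[i] == "del") {
            to <- min(pos + len[i] - 1L, length(b))
            if (any(prot[pos:min(to, L)])) next
            b <- b[-(pos:to)]
          } else {
            b <- append(b, sample(DNA4, len[i], replace = TRUE), after = pos)
          }
          indels <- rbind(data.frame(position = pos, type = type[i],
                                     length = len[i],
                                     stringsAsFactors = FALSE), indels)
        }
      }
    }
    list(A = genome("parentA", paste(a, collapse = "")),
         B = genome("parentB", paste(b, collapse = "")),
         truth = truth, indels = indels)
  })
}

# plant on a character vector: left arm kept as-is, spacer kept, right arm
# rewritten as the reverse complement of the left arm with exactly
# `mismatches` violations (a violated pair gets the left base itself, which
# is never Watson-Crick self-complementary)
plant_palindrome_chars <- function(chars, position, arm, loop, mismatches = 0L) {
  if (arm < 2L) stop("arm must be >= 2")
  if (loop < 3L) stop("loop must be >= 3")
  if (mismatches > arm) stop("mismatches cannot exceed arm length")
  to <- position + 2L * arm + loop - 1L
  if (position < 1L || to > length(chars))
    stop(sprintf("palindrome %d..%d is out of bounds (1..%d)",
                 position, to, length(chars)))
  left <- chars[position:(position + arm - 1L)]
  right <- unname(COMP[rev(left)])
  if (mismatches > 0L) {
    # deterministic placement: evenly spaced arm positions
    at <- unique(round(seq(1L, arm, length.out = mismatches)))
    stopifnot(length(at) == mismatches)
    right[at] <- rev(left)[at]
  }
  chars[(position + arm + loop):(position + 2L * arm + loop - 1L)] <- right
  chars
}

#' Plant a pseudo-palindrome into a genome
#'
#' Rewrites the region starting at `position` to read
#' `X . spacer . revcomp(X)` where `X` is the existing left arm, with exactly
#' `mismatches` non-complementary arm pairs; the rest of the genome is
#' unchanged.  Mismatch placement is deterministic (evenly spaced).
#'
#' @param g A [genome].
#' @param position 1-based start of the left arm.
#' @param arm Arm length in bp (>= 2).
#' @param loop Spacer (loop) length in nt (>= 3).
#' @param mismatches Number of violated arm pairs (default 0).
#' @return The modified genome.
#' @export
plant_pseudo_palindrome <- function(g, position, arm, loop, mismatches = 0L) {
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  chars <- plant_palindrome_chars(chars, as.integer(position),
                                  as.integer(arm), as.integer(loop),
                                  as.integer(mismatches))
  genome(g$id, paste(chars, collapse = ""))
}

#' Splice a hybrid genome from two parents
#'
#' Concatenates donor subsequences in order and then applies private point
#' substitutions, recording the exact construction as a `hybrid_truth`.
#'
#' @param A,B Parent [genome]s.
#' @param segments `data.frame` with columns `donor` (`"A"`/`"B"`), `start`,
#'   `end` (1-based inclusive, in donor coordinates).  Successive segments
#'   must alternate donors; within each donor, segments must be in increasing,
#'   non-overlapping order.
#' @param private_mutations Optional `data.frame` with columns `position`
#'   (hybrid coordinates) and `base`, applied after splicing.
#' @return List with `hybrid` (a genome) and `truth` (class `hybrid_truth`:
#'   `segments` augmented with hybrid coordinates, `switch_points` in hybrid
#'   coordinates, and `private_mutations`).
#' @export
splice_hybrid <- function(A, B, segments, private_mutations = NULL) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("donor", "start", "end") %in% names(segments)))
  n <- nrow(segments)
  if (n < 1L) stop("at least one segment is required")
  if (!all(segments$donor %in% c("A", "B")))
    stop("segment donors must be 'A' or 'B'")
  if (n > 1L && any(segments$donor[-1L] == segments$donor[-n]))
    stop("successive segments must alternate donors")
  for (d in c("A", "B")) {
    seg <- segments[segments$donor == d, , drop = FALSE]
    if (nrow(seg) > 1L &&
        any(seg$start[-1L] <= seg$end[-nrow(seg)]))
      stop(sprintf("segments from parent %s overlap or are out of order", d))
  }
  parents <- list(A = A, B = B)
  pieces <- character(n)
  for (i in seq_len(n)) {
    g <- parents[[segments$donor[i]]]
    if (segments$start[i] < 1L || segments$end[i] > genome_length(g) ||
        segments$start[i] > segments$end[i])
      stop(sprintf("segment %d (%d..%d) is invalid for parent %s",
                   i, segments$start[i], segments$end[i], segments$donor[i]))
    pieces[i] <- substr(g$seq, segments$start[i], segments$end[i])
  }
  widths <- nchar(pieces)
  hyb_end <- cumsum(widths)
  hyb_start <- hyb_end - widths + 1L
  seq <- paste(pieces, collapse = "")
  if (!is.null(private_mutations)) {
    private_mutations <- as.data.frame(private_mutations)
    stopifnot(all(c("position", "base") %in% names(private_mutations)))
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    if (any(private_mutations$position < 1L |
            private_mutations$position > length(chars)))
      stop("private mutation position out of bounds")
    chars[private_mutations$position] <- toupper(private_mutations$base)
    seq <- paste(chars, collapse = "")
  } else {
    private_mutations <- data.frame(position = integer(), base = character(),
                                    stringsAsFactors = FALSE)
  }
  truth <- structure(list(
    segments = cbind(segments,
                     hybrid_start = hyb_start, hybrid_end = hyb_end),
    switch_points = if (n > 1L) hyb_end[-n] else integer(),
    private_mutations = private_mutations), class = "hybrid_truth")
  list(hybrid = genome("hybrid", seq), truth = truth)
}

#' @export
print.hybrid_truth <- function(x, ...) {
  cat(sprintf("<hybrid_truth> %d segment(s), %d switch point(s), %d private mutation(s)\n",
              nrow(x$segments), length(x$switch_points),
              nrow(x$private_mutations)))
  invisible(x)
}

#' Write a synthetic trio and its truth to disk
#'
#' Convenience used by the command-line interface: writes `parents.fasta`,
#' `hybrid.fasta` and a JSON truth file into `dir`.
#'
#' @param pair Result of [generate_parent_pair()].
#' @param spl Result of [splice_hybrid()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_set <- function(pair, spl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(list(pair$A, pair$B), file.path(dir, "parents.fasta"))
  write_fasta(spl$hybrid, file.path(dir, "hybrid.fasta"))
  truth <- list(segments = spl$truth$segments,
                switch_points = spl$truth$switch_points,
                private_mutations = spl$truth$private_mutations,
                diagnostic_positions = pair$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
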