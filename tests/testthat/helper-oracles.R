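# Fixture builders and independent brute-force oracles used across the suite.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a seeded trio: diverged parents with one planted identity window of width w
# at `at`, spliced at `cut` (inside the window)
make_trio <- function(length = 2400L, w = 8L, at = length %/% 2L,
                      divergence = 0.05, seed = 1L, cut = at + w %/% 2L) {
  sp <- synthetic_spec(length, divergence = divergence,
                       identity_windows = data.frame(position = at,
                                                     length = w),
                       seed = seed)
  pair <- generate_parent_pair(sp)
  spl <- splice_hybrid(pair$A, pair$B,
                       data.frame(donor = c("A", "B"),
                                  start = c(1L, cut + 1L),
                                  end = c(cut, length)))
  list(A = pair$A, B = pair$B, hybrid = spl$hybrid, truth = spl$truth,
       window_at = at, w = w, cut = cut)
}

# --- restriction-site oracle: naive sliding window with IUPAC expansion ----

IUPAC_SET <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

oracle_find_sites <- function(seq, recognition) {
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc <- strsplit(recognition, "", fixed = TRUE)[[1]]
  k <- length(rc)
  hits <- integer()
  for (i in seq_len(length(sc) - k + 1L)) {
    win <- sc[i:(i + k - 1L)]
    # N in the subject never matches
    ok <- all(vapply(seq_len(k), function(j)
      win[j] != "N" && win[j] %in% IUPAC_SET[[rc[j]]], logical(1)))
    if (ok) hits <- c(hits, i)
  }
  hits
}

# --- hairpin oracle: exhaustive enumeration over (loop start, loop, arm) ---

oracle_scan_hairpins <- function(seq, min_arm, max_loop, max_mismatch,
                                 wobble = FALSE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(sc)
  paired <- function(x, y) {
    p <- !is.na(comp[x]) && comp[[x]] == y
    if (wobble) p <- p || (x == "G" && y == "T") || (x == "T" && y == "G")
    p
  }
  mism_count <- function(i, l, a) {
    sum(vapply(seq_len(a), function(k)
      !paired(sc[i - k], sc[i + l + k - 1L]), logical(1)))
  }
  rows <- list()
  for (l in 3L:max_loop) for (i in seq_len(n)) {
    amax <- min(i - 1L, n - i - l + 1L)
    if (amax < min_arm) next
    best <- 0L; best_m <- 0L
    for (a in seq_len(amax)) {
      m <- mism_count(i, l, a)
      if (m <= max_mismatch) { best <- a; best_m <- m } else break
    }
    if (best >= min_arm)
      rows[[length(rows) + 1L]] <- c(start = i - best,
                                     end = i + l + best - 1L,
                                     arm = best, loop = l,
                                     mismatches = best_m)
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), arm = integer(),
                      loop = integer(), mismatches = integer()))
  out <- as.data.frame(do.call(rbind, rows))
  out <- out[order(out$start, out$loop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- minimal GenBank flat-file builder -------------------------------------

write_minimal_genbank <- function(path, seq, cds) {
  lines <- c(
    sprintf("LOCUS       SYNREC%06d %d bp    DNA     linear   PHG 01-JAN-2026",
            1L, nchar(seq)),
    "DEFINITION  synthetic record for parser tests.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)))
  for (i in seq_len(nrow(cds))) {
    loc <- sprintf("%d..%d", cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     CDS             %s", loc),
               sprintf("                     /gene=\"%s\"", cds$gene[i]))
  }
  lines <- c(lines, "ORIGIN")
  chunks <- substring(seq, seq(1, nchar(seq), 60),
                      pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))
  for (j in seq_along(chunks)) {
    row <- chunks[j]
    grp <- substring(row, seq(1, nchar(row), 10),
                     pmin(seq(10, nchar(row) + 9, 10), nchar(row)))
    lines <- c(lines, sprintf("%9d %s", (j - 1L) * 60L + 1L,
                              paste(tolower(grp), collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}
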