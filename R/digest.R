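#' Bundled restriction enzyme table
#'
#' Loads the enzyme table shipped with the package (or a user-supplied TSV
#' with the same columns).  Cut offsets count bonds from the recognition-site
#' start: `cut_top = k` means the top strand is cut after the k-th base of
#' the site (0 = immediately 5' of the site).  Geometry follows REBASE:
#' MboI `^GATC`, NdeI `CA^TATG`, HpaI `GTT^AAC`, AvrII `C^CTAGG`,
#' StuI `AGG^CCT`.
#'
#' @param path TSV with columns `name`, `recognition`, `cut_top`,
#'   `cut_bottom`.
#' @return `data.frame` of enzymes.
#' @export
restriction_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                                   package = "phagerec")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_top", "cut_bottom") %in%
                  names(tab)))
  tab$recognition <- toupper(tab$recognition)
  len <- nchar(tab$recognition)
  if (any(len < 4L)) stop("recognition sites must be >= 4 bp")
  if (any(tab$cut_top < 0L | tab$cut_top > len |
          tab$cut_bottom < 0L | tab$cut_bottom > len))
    stop("cut offsets must lie within [0, site length]")
  tab
}

#' Look up (or construct) a restriction enzyme
#'
#' @param name Enzyme name present in `table`, or a new name if
#'   `recognition` is supplied.
#' @param recognition,cut_top,cut_bottom Definition of a custom enzyme
#'   (IUPAC recognition string; bond offsets from site start).
#' @param table Enzyme table, by default the bundled one.
#' @return A one-row `data.frame` of class `enzyme`.
#' @export
enzyme <- function(name, recognition = NULL, cut_top = NULL,
                   cut_bottom = NULL, table = restriction_enzymes()) {
  if (is.null(recognition)) {
    hit <- table[table$name == name, , drop = FALSE]
    if (nrow(hit) != 1L) stop(sprintf("unknown enzyme '%s'", name))
  } else {
    if (is.null(cut_bottom)) cut_bottom <- nchar(recognition) - cut_top
    hit <- data.frame(name = name, recognition = toupper(recognition),
                      cut_top = as.integer(cut_top),
                      cut_bottom = as.integer(cut_bottom),
                      stringsAsFactors = FALSE)
    if (nchar(hit$recognition) < 4L) stop("recognition site must be >= 4 bp")
  }
  class(hit) <- c("enzyme", "data.frame")
  hit
}

is_palindromic_site <- function(recognition) {
  identical(revcomp(recognition), recognition)
}

#' Find recognition sites of an enzyme on a genome
#'
#' Reports the 1-based start position of every match of the (IUPAC-expanded)
#' recognition sequence on the top strand, including overlapping tandem
#' matches.  Windows containing `N` never match.  For non-palindromic sites,
#' bottom-strand matches are reported too, with a `strand` attribute; all
#' bundled enzymes are palindromic.
#'
#' @param g A [genome].
#' @param e An [enzyme].
#' @return Sorted integer vector of site starts with a `strand` attribute.
#' @export
find_sites <- function(g, e) {
  subj <- Biostrings::DNAString(g$seq)
  scan1 <- function(pat) {
    # IUPAC expansion only needed when the site has ambiguity codes
    iupac <- grepl("[^ACGT]", pat)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  fixed = !iupac)
    pos <- BiocGenerics::start(m)
    if (length(pos)) {
      w <- nchar(pat)
      hasN <- vapply(pos, function(p)
        grepl("N", substr(g$seq, p, p + w - 1L), fixed = TRUE), logical(1))
      pos <- pos[!hasN]
    }
    pos
  }
  top <- scan1(e$recognition)
  strand <- rep("+", length(top))
  if (!is_palindromic_site(e$recognition)) {
    bot <- scan1(revcomp(e$recognition))
    top <- c(top, bot)
    strand <- c(strand, rep("-", length(bot)))
  }
  o <- order(top)
  structure(as.integer(top[o]), strand = strand[o])
}

#' In-silico digestion of a linear genome
#'
#' Cut bonds are `site start + cut_top - 1` ("cut after position i");
#' fragments are the inter-cut distances including both genome ends.  A
#' genome with no sites yields a single fragment of the genome length.
#'
#' @param g A [genome].
#' @param e An [enzyme].
#' @return Object of class `digest` with fields `genome_id`, `enzyme`,
#'   `cut_positions` (sorted bonds), `fragments` (ordered bp sizes) and
#'   `genome_length`.
#' @export
digest_linear <- function(g, e) {
  sites <- find_sites(g, e)
  L <- genome_length(g)
  cuts <- as.integer(sites) + e$cut_top - 1L
  cuts <- sort(unique(cuts[cuts >= 1L & cuts <= L - 1L]))
  fragments <- diff(c(0L, cuts, L))
  structure(list(genome_id = g$id, enzyme = e$name, cut_positions = cuts,
                 fragments = fragments, genome_length = L),
            class = "digest")
}

#' @export
print.digest <- function(x, ...) {
  cat(sprintf("<digest> %s / %s: %d cut(s), fragments (bp): %s\n",
              x$genome_id, x$enzyme, length(x$cut_positions),
              paste(sort(x$fragments, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

# relative size agreement: |x - y| <= tolerance * mean(x, y)
same_band <- function(x, y, tolerance) {
  abs(x - y) <= tolerance * (x + y) / 2
}

#' Localise the differences between two digests
#'
#' Fragment sizes are compared as multisets, where two fragments are "the
#' same band" if their sizes agree within the relative `tolerance`
#' (`tolerance = 0` is exact mode).  Site gain/loss is computed by walking
#' the two cut-position lists with a running offset learned from shared
#' flanking cuts, so collinear genomes of slightly different length (e.g. a
#' hybrid carrying a shorter exchanged segment) still pair their shared
#' sites.
#'
#' @param a,b [digest_linear()] results for the same enzyme; `a` is the
#'   reference ("lost" means present in `a`, absent from `b`).
#' @param tolerance Relative band-size tolerance (default 0.05, emulating
#'   agarose resolution).
#' @param site_slack Maximum residual offset (bp) for two cut positions to
#'   be considered the same site after offset alignment.
#' @return Object of class `digest_diff`.
#' @export
diff_digests <- function(a, b, tolerance = 0.05, site_slack = 32L) {
  if (!identical(a$enzyme, b$enzyme))
    stop(sprintf("digests are from different enzymes (%s vs %s)",
                 a$enzyme, b$enzyme))
  fa <- sort(a$fragments)
  fb <- sort(b$fragments)
  lost <- integer(); gained <- integer()
  i <- 1L; j <- 1L
  while (i <= length(fa) || j <= length(fb)) {
    if (i > length(fa)) { gained <- c(gained, fb[j]); j <- j + 1L }
    else if (j > length(fb)) { lost <- c(lost, fa[i]); i <- i + 1L }
    else if (same_band(fa[i], fb[j], tolerance)) { i <- i + 1L; j <- j + 1L }
    else if (fa[i] < fb[j]) { lost <- c(lost, fa[i]); i <- i + 1L }
    else { gained <- c(gained, fb[j]); j <- j + 1L }
  }
  ca <- a$cut_positions; cb <- b$cut_positions
  lost_sites <- integer(); gained_sites <- integer()
  i <- 1L; j <- 1L; offset <- 0L
  while (i <= length(ca) || j <= length(cb)) {
    if (i > length(ca)) { gained_sites <- c(gained_sites, cb[j]); j <- j + 1L }
    else if (j > length(cb)) { lost_sites <- c(lost_sites, ca[i]); i <- i + 1L }
    else if (abs(ca[i] - (cb[j] + offset)) <= site_slack) {
      offset <- ca[i] - cb[j]
      i <- i + 1L; j <- j + 1L
    } else if (ca[i] < cb[j] + offset) {
      lost_sites <- c(lost_sites, ca[i]); i <- i + 1L
    } else {
      gained_sites <- c(gained_sites, cb[j]); j <- j + 1L
    }
  }
  structure(list(enzyme = a$enzyme,
                 lost_fragments = lost, gained_fragments = gained,
                 lost_sites = lost_sites, gained_sites = gained_sites,
                 band_tolerance = tolerance),
            class = "digest_diff")
}

#' @export
print.digest_diff <- function(x, ...) {
  cat(sprintf("<digest_diff> %s (tolerance %.3g)\n", x$enzyme,
              x$band_tolerance))
  cat(sprintf("  lost bands:   %s\n",
              if (length(x$lost_fragments))
                paste(x$lost_fragments, collapse = ", ") else "none"))
  cat(sprintf("  gained bands: %s\n",
              if (length(x$gained_fragments))
                paste(x$gained_fragments, collapse = ", ") else "none"))
  cat(sprintf("  lost sites:   %s\n",
              if (length(x$lost_sites))
                paste(x$lost_sites, collapse = ", ") else "none"))
  cat(sprintf("  gained sites: %s\n",
              if (length(x$gained_sites))
                paste(x$gained_sites, collapse = ", ") else "none"))
  invisible(x)
}

#' Is a digest diff empty?
#' @param d A `digest_diff`.
#' @return `TRUE` if no bands and no sites differ.
#' @export
is_empty_diff <- function(d) {
  length(d$lost_fragments) == 0L && length(d$gained_fragments) == 0L &&
    length(d$lost_sites) == 0L && length(d$gained_sites) == 0L
}

#' Merge digest fragments into gel bands
#'
#' Fragments whose sizes agree within the relative `resolution` co-migrate
#' as one band; a band reports its mean size and multiplicity.
#'
#' @param d A `digest`.
#' @param resolution Relative size resolution (> 0), e.g. 0.05 for a 1\%
#'   agarose gel read by eye.
#' @return `data.frame` with columns `size` (mean bp) and `n`.
#' @export
gel_bands <- function(d, resolution = 0.05) {
  if (resolution <= 0) stop("resolution must be > 0")
  sizes <- sort(d$fragments)
  if (length(sizes) == 0L)
    return(data.frame(size = numeric(), n = integer()))
  means <- sizes[1]; counts <- 1L
  for (s in sizes[-1]) {
    k <- length(means)
    if (abs(s - means[k]) <= resolution * (s + means[k]) / 2) {
      means[k] <- (means[k] * counts[k] + s) / (counts[k] + 1L)
      counts[k] <- counts[k] + 1L
    } else {
      means <- c(means, s); counts <- c(counts, 1L)
    }
  }
  data.frame(size = means, n = counts)
}
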