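#' Read a multi-record FASTA file into a list of genomes
#'
#' Records are uppercased and `U` is normalised to `T`; any character outside
#' `A`, `C`, `G`, `T`, `N` is rejected.  Record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to an existing FASTA file.
#' @return List of [genome] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(x))
  lapply(seq_along(x), function(i) genome(ids[i], as.character(x[[i]])))
}

#' Write genomes to a FASTA file
#'
#' @param genomes A [genome] or list of genomes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read CDS coordinates from a GenBank flat file
#'
#' A minimal parser for GenBank flat files restricted to what the package
#' needs: simple `CDS` feature locations of the form `start..end` or
#' `complement(start..end)`.  `join(...)` spans are rejected.  Feature names
#' are taken from the `/gene` qualifier, falling back to `/locus_tag` then
#' `/product`.
#'
#' @param path Path to a GenBank flat file.
#' @return `data.frame` with columns `gene`, `start`, `end`, `strand`
#'   (1-based inclusive).  Empty, with a warning, if the record has no CDS
#'   features.
#' @export
read_genbank_cds <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  feat_from <- grep("^FEATURES", lines)
  feat_to <- grep("^(ORIGIN|CONTIG|//)", lines)
  if (length(feat_from) == 0L) stop(sprintf("no FEATURES block in %s", path))
  feat_to <- if (length(feat_to)) min(feat_to[feat_to > feat_from[1]]) else length(lines) + 1L
  block <- lines[(feat_from[1] + 1L):(feat_to - 1L)]

  # a feature header has its key at column 6; qualifier/continuation lines
  # are indented further
  is_key <- grepl("^ {5}\\S", block)
  starts <- which(is_key)
  out <- list()
  for (si in seq_along(starts)) {
    from <- starts[si]
    to <- if (si < length(starts)) starts[si + 1L] - 1L else length(block)
    key <- sub("^ +(\\S+).*$", "\\1", block[from])
    if (key != "CDS") next
    body <- block[from:to]
    # location may continue over lines until the first qualifier
    qual_at <- grep("^ +/", body)
    loc_lines <- body[seq_len(if (length(qual_at)) qual_at[1] - 1L else length(body))]
    loc <- gsub("\\s", "", paste(sub("^ +CDS", "", loc_lines), collapse = ""))
    if (grepl("join|order", loc))
      stop(sprintf("join/order CDS locations are not supported (%s)", loc))
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    loc <- gsub("^complement\\(|\\)$", "", loc)
    loc <- gsub("[<>]", "", loc)
    m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
    if (length(m) != 3L)
      stop(sprintf("cannot parse CDS location '%s'", loc))
    quals <- paste(body, collapse = " ")
    pick <- function(q) {
      mm <- regmatches(quals, regexec(sprintf('/%s="([^"]*)"', q), quals))[[1]]
      if (length(mm) == 2L) mm[2] else NA_character_
    }
    nm <- pick("gene")
    if (is.na(nm)) nm <- pick("locus_tag")
    if (is.na(nm)) nm <- pick("product")
    if (is.na(nm)) nm <- sprintf("CDS_%d", length(out) + 1L)
    out[[length(out) + 1L]] <- data.frame(
      gene = nm, start = as.integer(m[2]), end = as.integer(m[3]),
      strand = strand, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    warning(sprintf("no CDS features in %s", path))
    return(data.frame(gene = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
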