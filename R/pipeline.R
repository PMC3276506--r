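#' Run the full hybrid-characterisation pipeline
#'
#' Orchestrates the analysis stages end to end for a hybrid genome and its
#' two parents: in-silico digestion and digest-diff for every configured
#' enzyme, three-way alignment and parentage painting, crossover-interval
#' and microhomology-window inference, and a pseudo-palindrome/four-way
#' junction scan in a window around each crossover.  Progress is logged to
#' stderr; results are returned (and optionally written as JSON/TSV/FASTA
#' into a report directory).
#'
#' @param config A YAML file path or a list with elements:
#'   \describe{
#'     \item{`hybrid`, `parentA`, `parentB`}{FASTA paths (single record
#'       each), or [genome] objects; alternatively}
#'     \item{`synthetic`}{a list with `spec` arguments for
#'       [synthetic_spec()] plus `segments` (and optional
#'       `private_mutations`) for [splice_hybrid()].}
#'     \item{`enzymes`}{character vector of enzyme names (default the five
#'       bundled mapping enzymes).}
#'     \item{`tolerance`}{digest-diff band tolerance (default 0.05).}
#'     \item{`junction`}{list of [scan_inverted_repeats()] arguments
#'       (`min_arm`, `max_loop`, `max_mismatch`) plus `window`, the
#'       half-width in bp scanned around each crossover (default 150).}
#'     \item{`out_dir`}{optional report directory.}
#'   }
#' @return Object of class `pipeline_report` (invisibly if `out_dir` is
#'   set): the config, digests and diffs, painting, crossover calls with
#'   microhomology windows, and junction scan results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[phagerec %s] ", fmt),
                    format(Sys.time(), "%H:%M:%S"), ...))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    log_stage("%s done in %.2fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  truth <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    trio <- stage("synth", {
      spec <- do.call(synthetic_spec, syn$spec)
      pair <- generate_parent_pair(spec)
      spl <- splice_hybrid(pair$A, pair$B, as.data.frame(syn$segments),
                           if (!is.null(syn$private_mutations))
                             as.data.frame(syn$private_mutations))
      list(hybrid = spl$hybrid, A = pair$A, B = pair$B, truth = spl$truth)
    })
    hybrid <- trio$hybrid; A <- trio$A; B <- trio$B; truth <- trio$truth
  } else {
    get_genome <- function(x, what) {
      if (inherits(x, "genome")) return(x)
      if (is.null(x)) stop(sprintf("config must name '%s'", what))
      gs <- read_fasta(x)
      if (length(gs) != 1L)
        stop(sprintf("%s: expected a single FASTA record", what))
      gs[[1]]
    }
    loaded <- stage("load", list(h = get_genome(config$hybrid, "hybrid"),
                                 a = get_genome(config$parentA, "parentA"),
                                 b = get_genome(config$parentB, "parentB")))
    hybrid <- loaded$h; A <- loaded$a; B <- loaded$b
  }

  enzymes <- config$enzymes
  if (is.null(enzymes)) enzymes <- c("AvrII", "HpaI", "MboI", "NdeI", "StuI")
  tolerance <- if (is.null(config$tolerance)) 0.05 else config$tolerance
  digests <- stage("digest", {
    lapply(stats::setNames(enzymes, enzymes), function(en) {
      e <- enzyme(en)
      list(hybrid = digest_linear(hybrid, e),
           parentA = digest_linear(A, e),
           parentB = digest_linear(B, e))
    })
  })
  diffs <- stage("digest-diff", {
    lapply(digests, function(d)
      diff_digests(d$parentA, d$hybrid, tolerance = tolerance))
  })

  aln <- stage("align", three_way_align(hybrid, A, B,
                                        params = config$alignment %||% list()))
  pt <- stage("paint", paint(aln))
  calls <- stage("crossover", {
    if (any(pt$class %in% c("A", "B"))) call_crossovers(pt) else list()
  })
  windows <- lapply(calls, microhomology_window)

  jcfg <- config$junction %||% list()
  jwin <- jcfg$window %||% 150L
  junctions <- stage("junctions", {
    lapply(calls, function(cl) {
      lo <- max(1L, (cl$left_diag_hpos %||% 1L) - jwin)
      hi <- min(genome_length(hybrid), (cl$right_diag_hpos) + jwin)
      hp <- scan_inverted_repeats(substr(hybrid$seq, lo, hi),
                                  min_arm = jcfg$min_arm %||% 4L,
                                  max_loop = jcfg$max_loop %||% 10L,
                                  max_mismatch = jcfg$max_mismatch %||% 1L)
      if (nrow(hp)) {
        hp$start <- hp$start + lo - 1L
        hp$end <- hp$end + lo - 1L
        hp$apex <- hp$apex + lo - 1L
      }
      hp
    })
  })

  report <- structure(list(
    config = config,
    genomes = list(hybrid = hybrid$id, parentA = A$id, parentB = B$id,
                   lengths = c(hybrid = genome_length(hybrid),
                               parentA = genome_length(A),
                               parentB = genome_length(B))),
    digests = digests, diffs = diffs, alignment = aln, painting = pt,
    crossovers = calls, microhomology = windows, junctions = junctions,
    truth = truth), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    log_stage("report written to %s", config$out_dir)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> hybrid %s vs parents %s / %s\n",
              x$genomes$hybrid, x$genomes$parentA, x$genomes$parentB))
  ndiff <- sum(vapply(x$diffs, Negate(is_empty_diff), logical(1)))
  cat(sprintf("  digest diffs: %d/%d enzymes differ\n", ndiff,
              length(x$diffs)))
  cat(sprintf("  crossovers: %d\n", length(x$crossovers)))
  for (i in seq_along(x$crossovers)) {
    cl <- x$crossovers[[i]]; w <- x$microhomology[[i]]
    cat(sprintf("   %d. %s, ambiguity hybrid %s, microhomology %d bp\n",
                i, cl$direction,
                if (cl$interval_length > 0)
                  sprintf("%d..%d", cl$interval_start, cl$interval_end)
                else "(zero-length)", w$length))
  }
  invisible(x)
}

# serialise the report as JSON + TSV + FASTA into a directory
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(painting_table(report$painting),
                     file.path(dir, "painting.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- lapply(seq_along(report$crossovers), function(i) {
    cl <- report$crossovers[[i]]; w <- report$microhomology[[i]]
    list(direction = cl$direction,
         interval_start = cl$interval_start,
         interval_end = cl$interval_end,
         interval_length = cl$interval_length,
         private_inside = cl$private_inside,
         microhomology = list(a_start = w$a_start, a_end = w$a_end,
                              length = w$length, degenerate = w$degenerate))
  })
  diffs <- lapply(report$diffs, function(d)
    list(lost_fragments = d$lost_fragments,
         gained_fragments = d$gained_fragments,
         lost_sites = d$lost_sites, gained_sites = d$gained_sites,
         band_tolerance = d$band_tolerance))
  jsonlite::write_json(
    list(config = report$config, genomes = report$genomes,
         digest_diffs = diffs, crossovers = calls),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  junc <- do.call(rbind, c(report$junctions,
                           list(data.frame(start = integer(), end = integer(),
                                           arm = integer(), loop = integer(),
                                           mismatches = integer(),
                                           apex = integer()))))
  utils::write.table(junc, file.path(dir, "junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
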