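#' Efficiency of plating (EOP)
#'
#' EOP of a phage on a strain is its titer on that strain divided by its
#' titer on the reference strain, computed per replicate and aggregated as
#' mean +/- sd.  The standard deviation is reported as `NA` for a single
#' replicate.
#'
#' @param counts `data.frame` with columns `strain`, `phage`, `titer`
#'   (PFU/ml, >= 0) and `replicate`.
#' @param reference_strain Reference strain name (each phage must have a
#'   nonzero titer on it in every replicate used).
#' @return `data.frame` with one row per (phage, strain != reference):
#'   `mean`, `sd`, `n`, and `below_detection` (TRUE when every replicate
#'   titer was zero).
#' @export
eop <- function(counts, reference_strain = "BL21") {
  counts <- as.data.frame(counts)
  stopifnot(all(c("strain", "phage", "titer", "replicate") %in% names(counts)))
  if (any(counts$titer < 0)) stop("titers must be >= 0")
  out <- list()
  for (ph in unique(counts$phage)) {
    cp <- counts[counts$phage == ph, , drop = FALSE]
    ref <- cp[cp$strain == reference_strain, , drop = FALSE]
    if (nrow(ref) == 0L)
      stop(sprintf("no reference strain '%s' counts for phage %s",
                   reference_strain, ph))
    for (st in setdiff(unique(cp$strain), reference_strain)) {
      cs <- cp[cp$strain == st, , drop = FALSE]
      m <- merge(cs, ref[, c("replicate", "titer")], by = "replicate",
                 suffixes = c("", "_ref"))
      if (nrow(m) == 0L) next
      if (any(m$titer_ref == 0))
        stop(sprintf("zero reference titer for phage %s (replicate %s)",
                     ph, paste(m$replicate[m$titer_ref == 0], collapse = ",")))
      e <- m$titer / m$titer_ref
      out[[length(out) + 1L]] <- data.frame(
        phage = ph, strain = st, mean = mean(e),
        sd = if (length(e) > 1L) stats::sd(e) else NA_real_,
        n = length(e), below_detection = all(m$titer == 0),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Phage adsorption efficiency
#'
#' The fraction of phage particles bound to cells after the adsorption
#' period, `[1 - free/original] x 100` percent.  A free titer exceeding the
#' original (negative efficiency) is clamped to 0 and flagged with a
#' warning.
#'
#' @param original_pfu Original PFU in the bacteria-phage mixture (> 0).
#' @param free_pfu PFU of free phage after adsorption (>= 0).
#' @return Adsorption efficiency in percent (vectorised).
#' @export
adsorption_efficiency <- function(original_pfu, free_pfu) {
  if (any(original_pfu <= 0)) stop("original_pfu must be > 0")
  if (any(free_pfu < 0)) stop("free_pfu must be >= 0")
  eff <- (1 - free_pfu / original_pfu) * 100
  if (any(eff < 0)) {
    warning("free PFU exceeds original PFU; negative efficiency clamped to 0")
    eff[eff < 0] <- 0
  }
  eff
}

#' Read a plate-count TSV
#'
#' @param path TSV with columns `strain`, `phage`, `titer`, `replicate`.
#' @return `data.frame` of counts.
#' @export
read_plate_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "phage", "titer", "replicate") %in% names(tab)))
  tab
}
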