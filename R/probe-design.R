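# Probe tiling: enumerate antisense candidate windows, filter on GC and Tm,
# and pick a maximum-cardinality non-overlapping set with a minimum
# inter-probe gap (interval scheduling by earliest compatible end).

probe_columns <- c("target_id", "start", "end", "length", "sequence",
                   "gc_fraction", "tm_celsius", "ddU_pairing")

empty_probe_frame <- function() {
  data.frame(target_id = character(0), start = integer(0), end = integer(0),
             length = integer(0), sequence = character(0),
             gc_fraction = numeric(0), tm_celsius = numeric(0),
             ddU_pairing = logical(0), stringsAsFactors = FALSE)
}

#' Enumerate candidate antisense probes along a target
#'
#' Slides windows of every allowed length over the target (sense strand,
#' 0-based half-open coordinates) and keeps those whose GC fraction lies in
#' `gc_range` (inclusive). Each candidate is reported as the reverse
#' complement of its target window (the probe, 5'->3') together with its
#' nearest-neighbor Tm and whether the target base immediately 5' of the
#' window is an A — in which case the ddU appended to the probe's 3' end
#' during enzymatic labeling also base-pairs with the target.
#'
#' @param target Target sequence (sense strand, ACGT).
#' @param length_range Allowed probe lengths, `c(min, max)`; default 18-22.
#' @param gc_range Allowed GC fraction, `c(min, max)`; default 0.45-0.60.
#' @param target_id Identifier recorded with each candidate.
#' @param na_molar,oligo_molar Salt and strand concentrations for the Tm
#'   model (see [melting_temperature()]).
#' @return A `data.frame` sorted by `(start, length)` with columns
#'   `target_id`, `start`, `end`, `length`, `sequence`, `gc_fraction`,
#'   `tm_celsius`, `ddU_pairing`.
#' @export
enumerate_candidates <- function(target, length_range = c(18, 22),
                                 gc_range = c(0.45, 0.60),
                                 target_id = "target",
                                 na_molar = 0.05, oligo_molar = 250e-9) {
  stopifnot(length(length_range) == 2L, length_range[1] >= 2,
            length_range[1] <= length_range[2],
            length(gc_range) == 2L, gc_range[1] <= gc_range[2])
  chars <- check_acgt(target, "target")
  n <- length(chars)
  if (n < length_range[1]) return(empty_probe_frame())
  is_gc <- cumsum(c(0, chars %in% c("G", "C")))
  rows <- list()
  for (start in 0:(n - length_range[1])) {
    for (len in length_range[1]:length_range[2]) {
      end <- start + len
      if (end > n) break
      gc <- (is_gc[end + 1] - is_gc[start + 1]) / len
      if (gc < gc_range[1] || gc > gc_range[2]) next
      window <- substr(target, start + 1, end)
      rows[[length(rows) + 1L]] <- list(
        target_id = target_id, start = start, end = end, length = len,
        sequence = revcomp(window), gc_fraction = gc,
        tm_celsius = melting_temperature(window, na_molar, oligo_molar),
        ddU_pairing = start > 0 && chars[start] == "A"
      )
    }
  }
  if (length(rows) == 0) return(empty_probe_frame())
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# assert the ProbeSet invariants; called on every design result
validate_probe_set <- function(probes, target, params) {
  if (nrow(probes) == 0) return(invisible(TRUE))
  stopifnot(all(probes$end - probes$start == probes$length),
            all(probes$length >= params$length_range[1]),
            all(probes$length <= params$length_range[2]),
            all(probes$gc_fraction >= params$gc_range[1] - 1e-12),
            all(probes$gc_fraction <= params$gc_range[2] + 1e-12))
  for (i in seq_len(nrow(probes))) {
    window <- substr(target, probes$start[i] + 1, probes$end[i])
    stopifnot(identical(probes$sequence[i], revcomp(window)))
  }
  if (nrow(probes) > 1) {
    gaps <- probes$start[-1] - probes$end[-nrow(probes)]
    stopifnot(all(gaps >= params$min_gap))
  }
  invisible(TRUE)
}

#' Design a non-overlapping probe set for a target
#'
#' Candidate windows ([enumerate_candidates()]) are first filtered to a Tm
#' window of `+/- tm_halfwidth` around the candidate median Tm ("similar
#' melting temperature"), then a maximum-cardinality set of
#' non-overlapping candidates with inter-probe gap of at least `min_gap`
#' nucleotides is selected by the earliest-compatible-end greedy sweep,
#' which is optimal for interval scheduling. Ties among candidates sharing
#' an end are resolved (when `prefer_ddU_pairing`) in favor of candidates
#' whose appended 3' ddU pairs with the target, then in favor of longer
#' probes — a reproducible stand-in for the manual curation such sets
#' traditionally receive.
#'
#' @inheritParams enumerate_candidates
#' @param tm_halfwidth Half-width of the Tm acceptance window around the
#'   candidate median, in degrees C (default 2.5).
#' @param min_gap Minimum nucleotides between adjacent probes (default 2).
#' @param prefer_ddU_pairing Prefer candidates whose 3' ddU pairs with the
#'   target when breaking ties (default `TRUE`); a soft preference, never a
#'   filter.
#' @return A `data.frame` of class `probe_set`, ordered by `start`, with
#'   the same columns as [enumerate_candidates()] plus design parameters in
#'   `attr(, "params")`. If no candidate survives filtering, an empty set
#'   is returned with a `"warnings"` attribute describing why.
#' @examples
#' target <- gen_target_sequence(300, 0.5, seed = 1)
#' ps <- design_set(target)
#' nrow(ps)
#' @export
design_set <- function(target, length_range = c(18, 22),
                       gc_range = c(0.45, 0.60), tm_halfwidth = 2.5,
                       min_gap = 2, prefer_ddU_pairing = TRUE,
                       target_id = "target",
                       na_molar = 0.05, oligo_molar = 250e-9) {
  stopifnot(tm_halfwidth >= 0, min_gap >= 0)
  params <- list(length_range = length_range, gc_range = gc_range,
                 tm_halfwidth = tm_halfwidth, min_gap = min_gap,
                 prefer_ddU_pairing = prefer_ddU_pairing,
                 tm_model = "nearest-neighbor, unified DNA/DNA parameters",
                 na_molar = na_molar, oligo_molar = oligo_molar)
  cand <- enumerate_candidates(target, length_range, gc_range, target_id,
                               na_molar, oligo_molar)
  warnings <- character(0)
  if (nrow(cand) > 0) {
    med <- median(cand$tm_celsius)
    keep <- abs(cand$tm_celsius - med) <= tm_halfwidth
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    warnings <- c(warnings, "no candidates survived GC/Tm filtering")
    out <- empty_probe_frame()
  } else {
    pref <- if (prefer_ddU_pairing) !cand$ddU_pairing else rep(FALSE, nrow(cand))
    ord <- order(cand$end, pref, -cand$length, cand$start)
    cand <- cand[ord, , drop = FALSE]
    selected <- logical(nrow(cand))
    last_end <- -Inf
    for (i in seq_len(nrow(cand))) {
      if (cand$start[i] >= last_end + min_gap || last_end == -Inf) {
        selected[i] <- TRUE
        last_end <- cand$end[i]
      }
    }
    out <- cand[selected, , drop = FALSE]
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "params") <- params
  if (length(warnings) > 0) attr(out, "warnings") <- warnings
  class(out) <- c("probe_set", "data.frame")
  validate_probe_set(out, target, params)
  out
}

#' Split a probe set into two interleaved (alternating) subsets
#'
#' Probes ordered by start position are dealt alternately into two
#' subsets, so the two resulting probe sets tile the target in an
#' alternating arrangement — the layout used when labeling the two halves
#' with spectrally distinct dyes for two-color codetection controls. The
#' subset sizes differ by at most one (e.g. 35 probes split 18 + 17).
#'
#' @param probes A `probe_set` (or compatible `data.frame` with a `start`
#'   column).
#' @return A list with elements `a` (probes at even positional index,
#'   0-based) and `b` (odd), both inheriting the design parameters.
#' @export
interleave <- function(probes) {
  stopifnot(is.data.frame(probes))
  ord <- order(probes$start)
  probes <- probes[ord, , drop = FALSE]
  idx <- seq_len(nrow(probes))
  split_one <- function(rows) {
    out <- probes[rows, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "params") <- attr(probes, "params")
    class(out) <- c("probe_set", "data.frame")
    out
  }
  list(a = split_one(idx[idx %% 2 == 1L]),
       b = split_one(idx[idx %% 2 == 0L]))
}

#' Design probe sets for every record of a FASTA file
#'
#' @param path Path to a FASTA file of target sequences.
#' @param ... Passed to [design_set()]; `target_id` is taken from the
#'   FASTA record names.
#' @return A named list of `probe_set` objects, one per record.
#' @export
design_from_fasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    design_set(as.character(seqs[[i]]), target_id = names(seqs)[i], ...)
  })
  names(out) <- names(seqs)
  out
}

#' Write a probe set as TSV
#'
#' Columns: `target_id`, `start`, `end`, `length`, `strand` (always `-`),
#' `sequence`, `gc_fraction`, `tm_celsius`, `ddU_pairing`.
#'
#' @param probes A `probe_set`.
#' @param path Output path.
#' @export
write_probe_tsv <- function(probes, path) {
  out <- as.data.frame(probes)
  out$strand <- rep("-", nrow(out))
  out <- out[, c("target_id", "start", "end", "length", "strand",
                 "sequence", "gc_fraction", "tm_celsius", "ddU_pairing")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write probe sequences as FASTA
#'
#' Record names are `<target_id>_<start>_<end>`.
#'
#' @param probes A `probe_set`.
#' @param path Output path.
#' @export
write_probe_fasta <- function(probes, path) {
  seqs <- Biostrings::DNAStringSet(probes$sequence)
  names(seqs) <- sprintf("%s_%d_%d", probes$target_id, probes$start,
                         probes$end)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
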