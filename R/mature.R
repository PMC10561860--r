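#' Mature-miRNA arm candidates from a precursor hairpin
#'
#' Derives a candidate mature sequence from a predicted precursor by
#' cleaving flush with a hairpin loop: the 5p candidate is the `length`
#' nucleotides ending immediately before the chosen loop's first unpaired
#' base; the 3p candidate is the `length` nucleotides starting immediately
#' after the loop's last unpaired base. If the arm is shorter than
#' `length` the candidate is truncated with a warning. Coordinates are
#' 1-based and inclusive.
#'
#' @param record The precursor [rna_record].
#' @param structure Its [secondary_structure]; must contain at least
#'   `loop_index` hairpin loops.
#' @param arm `"5p"` or `"3p"`.
#' @param length Candidate length in nucleotides (typical mature miRNAs
#'   are ~22 nt; allowed 18-26, plus shorter truncations near the ends).
#' @param loop_index Which hairpin loop (1-based, 5' to 3') anchors the
#'   cleavage.
#' @return An object of class `mature_candidate`: `parent_id`, `arm`,
#'   `start`, `end`, `sequence`, `loop_index`.
#' @export
mature_candidates <- function(record, structure, arm = c("5p", "3p"),
                              length = 22L, loop_index = 1L) {
  arm <- match.arg(arm)
  if (nchar(structure$dotbracket) != nchar(record$sequence))
    stop(sprintf("record '%s': structure not aligned to sequence", record$id))
  loops <- hairpin_loops(structure$dotbracket)
  if (!nrow(loops))
    stop(sprintf("record '%s': not a hairpin (no hairpin loop in structure)", record$id))
  if (loop_index < 1L || loop_index > nrow(loops))
    stop(sprintf("record '%s': loop_index %d out of range (structure has %d hairpin loop(s))",
                 record$id, loop_index, nrow(loops)))
  L <- nchar(record$sequence)
  loop <- loops[loop_index, ]
  if (arm == "5p") {
    end <- loop$start - 1L
    start <- max(1L, end - length + 1L)
  } else {
    start <- loop$end + 1L
    end <- min(L, start + length - 1L)
  }
  if (end < start)
    stop(sprintf("record '%s': no %s arm next to loop %d", record$id, arm, loop_index))
  if (end - start + 1L < length)
    warning(sprintf("record '%s': %s arm shorter than %d nt; candidate truncated to %d nt",
                    record$id, arm, length, end - start + 1L), call. = FALSE)
  structure(list(parent_id = record$id, arm = arm,
                 start = start, end = end,
                 sequence = substr(record$sequence, start, end),
                 loop_index = loop_index),
            class = "mature_candidate")
}

#' @export
print.mature_candidate <- function(x, ...) {
  cat(sprintf("<mature_candidate> %s %s %d-%d (loop %d)\n  %s\n",
              x$parent_id, x$arm, x$start, x$end, x$loop_index, x$sequence))
  invisible(x)
}

#' Write mature candidates to FASTA
#'
#' Headers carry the parent id, arm, 1-based inclusive coordinates and
#' anchoring loop, e.g. `>mir-1|5p|5-26|loop1`.
#'
#' @param candidates List of `mature_candidate`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mature_fasta <- function(candidates, path) {
  lines <- unlist(lapply(candidates, function(cc)
    c(sprintf(">%s|%s|%d-%d|loop%d", cc$parent_id, cc$arm, cc$start, cc$end,
              cc$loop_index),
      cc$sequence)))
  writeLines(lines, path)
  invisible(path)
}
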