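NUCS <- c("A", "C", "G", "U")
# the 8 paired/unpaired patterns of a 3-nt window after ')' -> '(' collapsing
TRIPLET_PATTERNS <- c("(((", "((.", "(.(", "(..", ".((", ".(.", "..(", "...")
DINUCS <- as.vector(outer(NUCS, NUCS, paste0))   # AA AC ... by first letter

#' The canonical 93-feature manifest
#'
#' The fixed, versioned ordering of the descriptor computed by
#' [featurize()]. Groups:
#'
#' * `triplet` (32): frequencies of (middle nucleotide, 3-position
#'   paired/unpaired pattern) windows, e.g. `"A((("`.
#' * `composition` (45): mono- and dinucleotide counts and percentages,
#'   G+C and A+U counts and percentages, and sequence length.
#' * `structural` (4): stem count, hairpin-loop count, total hairpin-loop
#'   length, base-pair count.
#' * `thermodynamic` (12): MFE and its normalized forms (`dG`, `MFE1`-`MFE4`),
#'   base-pairing propensity `dP`, average base pairs per stem `avg_bp`,
#'   and the ensemble features `Q` (Shannon entropy of the base-pair
#'   probability distribution), `dQ` (length-normalized entropy), `dD`
#'   (length-normalized ensemble base-pair distance) and `zD` (z-score of
#'   `dD` against dinucleotide-shuffled nulls).
#'
#' @return A data frame with columns `name` and `group`, exactly 93 rows,
#'   in descriptor order.
#' @export
feature_manifest <- function() {
  triplet <- as.vector(t(outer(NUCS, TRIPLET_PATTERNS, paste0)))
  comp <- c(paste0("cnt_", NUCS), paste0("pct_", NUCS),
            paste0("cnt_", DINUCS), paste0("pct_", DINUCS),
            "cnt_G_plus_C", "cnt_A_plus_U", "pct_G_plus_C", "pct_A_plus_U",
            "length")
  structural <- c("n_stems", "n_loops", "loop_length", "tot_bp")
  thermo <- c("mfe", "dG", "dP", "MFE1", "MFE2", "MFE3", "MFE4", "avg_bp",
              "Q", "dQ", "dD", "zD")
  df <- data.frame(
    name = c(triplet, comp, structural, thermo),
    group = c(rep("triplet", length(triplet)),
              rep("composition", length(comp)),
              rep("structural", length(structural)),
              rep("thermodynamic", length(thermo))),
    stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 93L, !anyDuplicated(df$name))
  df
}

#' @rdname feature_manifest
#' @export
manifest_version <- function() "hairpinclass-93-v1"
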