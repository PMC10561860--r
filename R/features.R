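#' Triplet sequence-structure element frequencies
#'
#' Every window of three adjacent positions is binned by its middle
#' nucleotide and its 3-character paired/unpaired pattern, after rewriting
#' `)` to `(` so that both partners of a pair read as paired. With four
#' middle nucleotides and eight patterns there are 32 bins; each window
#' contributes 1/(L-2), so the 32 values are frequencies summing to 1.
#'
#' @param sequence RNA sequence (length L >= 3).
#' @param dotbracket Dot-bracket string aligned to `sequence`.
#' @return Named numeric vector of the 32 triplet frequencies, in manifest
#'   order.
#' @export
triplet_elements <- function(sequence, dotbracket) {
  sequence <- normalize_rna(sequence)
  L <- nchar(sequence)
  if (nchar(dotbracket) != L) stop("dotbracket must be aligned to sequence")
  if (L < 3L) stop("triplet elements need a sequence of length >= 3")
  collapsed <- chartr(")", "(", dotbracket)
  nt <- strsplit(sequence, "")[[1]]
  st <- strsplit(collapsed, "")[[1]]
  bins <- as.vector(t(outer(NUCS, TRIPLET_PATTERNS, paste0)))
  counts <- setNames(numeric(32L), bins)
  for (i in seq_len(L - 2L)) {
    key <- paste0(nt[i + 1L], st[i], st[i + 1L], st[i + 2L])
    counts[key] <- counts[key] + 1
  }
  counts / (L - 2L)
}

#' Base-composition features
#'
#' Mononucleotide counts and percentages (`count/L * 100`), overlapping
#' dinucleotide counts and percentages (`count/(L-1) * 100`), and the
#' combined G+C and A+U counts and percentages.
#'
#' @param sequence RNA sequence (length L >= 2).
#' @return Named numeric vector of the 45 composition features (including
#'   `length`), in manifest order.
#' @export
composition_features <- function(sequence) {
  sequence <- normalize_rna(sequence)
  L <- nchar(sequence)
  if (L < 2L) stop("composition features need a sequence of length >= 2")
  nt <- strsplit(sequence, "")[[1]]
  mono <- vapply(NUCS, function(x) sum(nt == x), 0)
  di_str <- paste0(nt[-L], nt[-1])
  di <- vapply(DINUCS, function(xy) sum(di_str == xy), 0)
  gc <- mono[["G"]] + mono[["C"]]
  au <- mono[["A"]] + mono[["U"]]
  c(setNames(mono, paste0("cnt_", NUCS)),
    setNames(mono / L * 100, paste0("pct_", NUCS)),
    setNames(di, paste0("cnt_", DINUCS)),
    setNames(di / (L - 1) * 100, paste0("pct_", DINUCS)),
    cnt_G_plus_C = gc, cnt_A_plus_U = au,
    pct_G_plus_C = gc / L * 100, pct_A_plus_U = au / L * 100,
    length = L)
}

#' GC content of a sequence, in percent
#'
#' @param sequence RNA sequence string.
#' @return `(|G| + |C|) / L * 100`.
#' @export
gc_content <- function(sequence) {
  sequence <- normalize_rna(sequence)
  nt <- strsplit(sequence, "")[[1]]
  sum(nt %in% c("G", "C")) / length(nt) * 100
}

# divide-with-convention: zero denominators yield 0 so every descriptor
# stays finite and degenerate hairpins remain classifiable
div0 <- function(num, den) if (is.na(den) || den == 0) 0 else num / den

#' Structural and thermodynamic features
#'
#' Minimum-free-energy indices normalized by length, GC content and motif
#' counts: `dG = MFE/L`, `dP = tot_bp/L`, `MFE1 = dG/%(G+C)`,
#' `MFE2 = dG/n_stems`, `MFE3 = dG/n_loops`, `MFE4 = dG/tot_bp`,
#' `avg_bp = tot_bp/n_stems`. Any zero denominator yields 0.
#'
#' @param structure An annotated [secondary_structure] with `mfe` set.
#' @param sequence The corresponding RNA sequence.
#' @return Named numeric vector: `mfe`, `dG`, `dP`, `MFE1`, `MFE2`,
#'   `MFE3`, `MFE4`, `avg_bp`.
#' @export
thermo_features <- function(structure, sequence) {
  sequence <- normalize_rna(sequence)
  L <- nchar(sequence)
  if (nchar(structure$dotbracket) != L)
    stop("structure must be aligned to sequence")
  if (is.na(structure$n_stems)) structure <- annotate_motifs(structure)
  mfe <- structure$mfe
  if (is.na(mfe)) stop("structure has no MFE; fold it or set mfe")
  dG <- mfe / L
  c(mfe = mfe,
    dG = dG,
    dP = structure$tot_bp / L,
    MFE1 = div0(dG, gc_content(sequence)),
    MFE2 = div0(dG, structure$n_stems),
    MFE3 = div0(dG, structure$n_loops),
    MFE4 = div0(dG, structure$tot_bp),
    avg_bp = div0(structure$tot_bp, structure$n_stems))
}

#' Ensemble (base-pair probability) features
#'
#' From the base-pair probability matrix of the thermodynamic ensemble:
#' `Q = -sum(p_ij * log2(p_ij))` over i < j (zero-probability terms
#' contribute 0), `dQ = Q/L` (length-normalized Shannon entropy),
#' `dD = sum(p_ij * (1 - p_ij))/L` (ensemble base-pair distance per
#' nucleotide). `zD` standardizes `dD` against `n_shuffles`
#' dinucleotide-preserving shuffles refolded by `backend`:
#' `zD = (dD - mean)/sd` over the shuffled values (0 when no backend or no
#' shuffles are given, or when the null spread is zero).
#'
#' @param structure A [secondary_structure] carrying `pair_probs`.
#' @param sequence The corresponding RNA sequence (needed for `zD`).
#' @param backend Optional [folding_backend] used to refold shuffles.
#' @param n_shuffles Number of shuffles for the `zD` null (default 100
#'   when a backend is supplied, else 0).
#' @param seed Integer seed for the shuffle set.
#' @return Named numeric vector: `Q`, `dQ`, `dD`, `zD`.
#' @export
entropy_features <- function(structure, sequence = NULL, backend = NULL,
                             n_shuffles = if (is.null(backend)) 0L else 100L,
                             seed = 1L) {
  if (is.null(structure$pair_probs))
    stop("structure has no pair_probs; use a partition-function-capable backend ",
         "(e.g. vienna_backend()) or a fixture probability matrix")
  L <- nchar(structure$dotbracket)
  p <- structure$pair_probs[upper.tri(structure$pair_probs)]
  p <- p[p > 0]
  Q <- -sum(p * log2(p))
  dD <- sum(p * (1 - p)) / L
  zD <- 0
  if (n_shuffles > 0L) {
    if (is.null(backend) || is.null(sequence))
      stop("zD needs both a sequence and a folding backend to refold shuffles")
    shuf <- dinucleotide_shuffle(sequence, n_shuffles, seed = seed)
    null_dD <- vapply(shuf, function(s) {
      pp <- pair_probabilities(backend, s)
      q <- pp[upper.tri(pp)]
      sum(q * (1 - q)) / L
    }, 0, USE.NAMES = FALSE)
    s <- sd(null_dD)
    zD <- if (is.na(s) || s == 0) 0 else (dD - mean(null_dD)) / s
  }
  c(Q = Q, dQ = Q / L, dD = dD, zD = zD)
}

#' Compute the full 93-feature descriptor
#'
#' Concatenates the triplet, composition, structural and thermodynamic
#' blocks in [feature_manifest()] order for one (record, structure) pair.
#' Deterministic given the inputs, the backend and `seed`.
#'
#' @param record An [rna_record].
#' @param structure The matching [secondary_structure]; must carry
#'   `pair_probs` (fold with a partition-function backend or attach a
#'   fixture matrix).
#' @param backend Optional [folding_backend], used only for the `zD`
#'   shuffle null.
#' @param n_shuffles Shuffles for `zD` (0 disables the null; `zD` is then 0).
#' @param seed Seed for the shuffle null.
#' @return Numeric vector of length 93, named by the manifest, with
#'   attribute `manifest_version`.
#' @export
featurize <- function(record, structure, backend = NULL,
                      n_shuffles = if (is.null(backend)) 0L else 100L,
                      seed = 1L) {
  if (nchar(structure$dotbracket) != nchar(record$sequence))
    stop(sprintf("record '%s': structure not aligned to sequence", record$id))
  if (is.na(structure$n_stems)) structure <- annotate_motifs(structure)
  v <- c(triplet_elements(record$sequence, structure$dotbracket),
         composition_features(record$sequence),
         n_stems = structure$n_stems, n_loops = structure$n_loops,
         loop_length = structure$loop_length, tot_bp = structure$tot_bp,
         thermo_features(structure, record$sequence),
         entropy_features(structure, record$sequence, backend = backend,
                          n_shuffles = n_shuffles, seed = seed))
  manifest <- feature_manifest()
  if (!identical(names(v), manifest$name))
    stop("internal error: feature vector does not match the manifest")
  if (!all(is.finite(v)))
    stop(sprintf("record '%s': non-finite feature value", record$id))
  attr(v, "manifest_version") <- manifest_version()
  v
}

#' Featurize a set of records into a feature matrix
#'
#' @param records List of [rna_record]s.
#' @param structures List of matching [secondary_structure]s.
#' @inheritParams featurize
#' @return Numeric matrix (records x 93) with record ids as row names and
#'   manifest names as column names.
#' @export
featurize_set <- function(records, structures, backend = NULL,
                          n_shuffles = 0L, seed = 1L) {
  stopifnot(length(records) == length(structures))
  m <- t(vapply(seq_along(records), function(i)
    featurize(records[[i]], structures[[i]], backend = backend,
              n_shuffles = n_shuffles, seed = seed),
    numeric(93L)))
  rownames(m) <- vapply(records, `[[`, "", "id")
  m
}

#' Standard (z-score) feature scaling
#'
#' `fit_scaler()` learns per-feature means and standard deviations on
#' training vectors; `apply_scaler()` centres and scales new vectors with
#' them. Constant features scale to 0 (their sd is treated as 1). The
#' fitted scaler is stored inside trained models so that prediction-time
#' inputs are scaled identically to the training data.
#'
#' @param x Numeric matrix of training feature vectors (>= 2 rows).
#' @return `fit_scaler()`: an object of class `feature_scaler`;
#'   `apply_scaler()`: the scaled matrix.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("fit_scaler needs at least 2 rows")
  center <- colMeans(x)
  # population sd, so a two-point column {0, 2} scales to exactly {-1, +1}
  scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
  scale[scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$center))
    stop("column count does not match the fitted scaler")
  sweep(sweep(x, 2L, scaler$center), 2L, scaler$scale, "/")
}
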