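#' Filtering policy for candidate precursors
#'
#' The retention windows applied to candidate hairpins before training:
#' sequence length strictly below `max_length`, minimum free energy inside
#' `[mfe_min, mfe_max]` (inclusive) and GC content inside
#' `[gc_min, gc_max]` percent (inclusive). The defaults bound the range
#' observed across known insect precursors: the longest is 222 nt, MFE
#' spans roughly -174.9 to -5.4 kcal/mol, and GC content reaches down to
#' 12.28%.
#'
#' @param max_length Length bound in nucleotides (kept iff length < this).
#' @param mfe_min,mfe_max MFE window in kcal/mol.
#' @param gc_min,gc_max GC-content window in percent.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(max_length = 250, mfe_min = -180, mfe_max = -5,
                          gc_min = 10, gc_max = 85) {
  stopifnot(mfe_min <= mfe_max, gc_min <= gc_max, max_length > 0)
  structure(list(max_length = max_length, mfe_min = mfe_min,
                 mfe_max = mfe_max, gc_min = gc_min, gc_max = gc_max),
            class = "filter_policy")
}

#' Apply the length/MFE/GC retention filters
#'
#' A record is kept iff `length < max_length`, `mfe_min <= MFE <= mfe_max`
#' and `gc_min <= GC% <= gc_max`. Rejections carry the first failing rule
#' (checked in that order).
#'
#' @param records List of [rna_record]s.
#' @param structures List of matching [secondary_structure]s (for MFE).
#' @param policy A [filter_policy].
#' @return A list with `kept` (integer indices into `records`) and
#'   `rejected` (data frame with columns `id`, `reason`).
#' @export
apply_filters <- function(records, structures, policy = filter_policy()) {
  stopifnot(length(records) == length(structures))
  reasons <- vapply(seq_along(records), function(i) {
    L <- nchar(records[[i]]$sequence)
    mfe <- structures[[i]]$mfe
    gc <- gc_content(records[[i]]$sequence)
    if (L >= policy$max_length) "length"
    else if (is.na(mfe) || mfe < policy$mfe_min || mfe > policy$mfe_max) "mfe_window"
    else if (gc < policy$gc_min || gc > policy$gc_max) "gc_window"
    else ""
  }, "")
  kept <- which(reasons == "")
  rejected <- data.frame(
    id = vapply(records[which(reasons != "")], `[[`, "", "id"),
    reason = reasons[reasons != ""],
    stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected)
}

#' Stratified train/test split
#'
#' Assigns each row of a labelled table to the training or test partition,
#' stratified by label so that both classes are split in the same
#' proportion (within one row). Deterministic under `seed`.
#'
#' @param table Data frame with a binary `label` column (0/1).
#' @param train_fraction Fraction assigned to training (default 0.75).
#' @param seed Integer seed.
#' @return `table` with a `split` column (`"train"`/`"test"`).
#' @export
split_dataset <- function(table, train_fraction = 0.75, seed = 1L) {
  if (nrow(table) < 4L) stop("need at least 4 rows to split")
  if (length(unique(table$label)) < 2L)
    stop("both labels must be present to split")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  split <- rep("test", nrow(table))
  # largest-remainder allocation: per-class floor, then round the total up
  # to round(n * fraction) so overall proportions are exact when possible
  labs <- sort(unique(table$label))
  target <- vapply(labs, function(l) sum(table$label == l) * train_fraction, 0)
  n_train <- floor(target)
  short <- round(sum(target)) - sum(n_train)
  if (short > 0) {
    bump <- order(target - n_train, decreasing = TRUE)[seq_len(short)]
    n_train[bump] <- n_train[bump] + 1L
  }
  for (k in seq_along(labs)) {
    idx <- which(table$label == labs[k])
    split[sample(idx, n_train[k])] <- "train"
  }
  table$split <- split
  table
}

#' Generate synthetic hairpin fixtures
#'
#' Builds a labelled set of synthetic precursors and non-precursors for
#' testing and small-scale experiments, with no folding engine required.
#'
#' Positives are constructed stem-loops: a stem of `stem_range` pairs
#' (Watson-Crick, with a G-U wobble substituted at rate `wobble_rate`), a
#' hairpin loop of `loop_range` nucleotides, and short unpaired flanking
#' tails. Their dot-bracket follows the construction and their free energy
#' is the [stacking_backend()] score (-2 kcal/mol per stacked pair, +3 per
#' loop), so every positive passes the default [filter_policy()].
#' Negatives are dinucleotide-preserving shuffles of positives
#' (composition-matched) and uniform-random weakly structured sequences,
#' folded and scored with [stacking_backend()]. All structures carry the
#' backend's fixture base-pair probability matrices.
#'
#' @param n_pos,n_neg Number of positive / negative fixtures.
#' @param stem_range Integer range of stem lengths in pairs.
#' @param loop_range Integer range of hairpin-loop sizes in nucleotides.
#' @param tail_range Integer range of each flanking tail length.
#' @param wobble_rate Per-pair probability of substituting a G-U wobble.
#' @param seed Integer seed; output is fully reproducible.
#' @return A list with `records`, `structures`, `labels` (1 = hairpin
#'   positive, 0 = negative) and `seed`.
#' @export
generate_fixtures <- function(n_pos, n_neg, stem_range = c(15L, 40L),
                              loop_range = c(3L, 10L), tail_range = c(0L, 12L),
                              wobble_rate = 0.1, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  be <- stacking_backend()
  records <- list(); structures <- list(); labels <- integer(0)

  make_positive <- function(id) {
    n_stem <- sample(stem_range[1]:stem_range[2], 1L)
    n_loop <- sample(loop_range[1]:loop_range[2], 1L)
    tails <- sample(tail_range[1]:tail_range[2], 2L, replace = TRUE)
    left <- sample(NUCS, n_stem, replace = TRUE)
    right <- chartr("ACGU", "UGCA", left)            # complement
    wob <- runif(n_stem) < wobble_rate
    right[wob & left == "G"] <- "U"                  # G-U wobble
    left[wob & left == "A"] <- "G"                   # G-U (right stays U)
    loop <- sample(NUCS, n_loop, replace = TRUE)
    t5 <- sample(NUCS, tails[1], replace = TRUE)
    t3 <- sample(NUCS, tails[2], replace = TRUE)
    seq <- paste(c(t5, left, loop, rev(right), t3), collapse = "")
    db <- paste(c(rep(".", tails[1]), rep("(", n_stem), rep(".", n_loop),
                  rep(")", n_stem), rep(".", tails[2])), collapse = "")
    st <- secondary_structure(db, 0)
    st$mfe <- stacking_score(st)
    st$pair_probs <- fixture_probs(st, be$p_pair)
    list(record = rna_record(id, seq, source = sprintf("synthetic stem-loop (seed %d)", seed)),
         structure = st)
  }

  for (i in seq_len(n_pos)) {
    p <- make_positive(sprintf("pos_%04d", i))
    records[[length(records) + 1L]] <- p$record
    structures[[length(structures) + 1L]] <- p$structure
    labels <- c(labels, 1L)
  }
  for (i in seq_len(n_neg)) {
    id <- sprintf("neg_%04d", i)
    if (i %% 2L == 1L && n_pos > 0L) {
      # composition-matched shuffle of a positive
      donor <- records[[sample.int(n_pos, 1L)]]$sequence
      seq <- dinucleotide_shuffle(donor, 1L, seed = sample.int(2^30, 1L))
      src <- sprintf("dinucleotide shuffle of a synthetic positive (seed %d)", seed)
    } else {
      seq <- paste(sample(NUCS, sample(60:150, 1L), replace = TRUE), collapse = "")
      src <- sprintf("uniform random sequence (seed %d)", seed)
    }
    st <- fold(be, seq)
    st$pair_probs <- fixture_probs(st, be$p_pair)
    records[[length(records) + 1L]] <- rna_record(id, seq, source = src)
    structures[[length(structures) + 1L]] <- st
    labels <- c(labels, 0L)
  }
  list(records = records, structures = structures, labels = labels, seed = seed)
}

# degenerate fixture ensemble: probability p on each predicted pair
fixture_probs <- function(structure, p = 0.95) {
  L <- length(structure$pair_table)
  probs <- matrix(0, L, L)
  open <- which(structure$pair_table > seq_len(L))
  for (i in open) probs[i, structure$pair_table[i]] <- p
  probs
}

#' Assemble a labelled feature table
#'
#' Featurizes records and binds ids, labels and (optionally) split
#' membership into one data frame -- the tabular dataset format used by
#' the balancing and classification steps.
#'
#' @param records,structures,labels As returned by [generate_fixtures()]
#'   or assembled from files.
#' @inheritParams featurize_set
#' @return Data frame: `id`, 93 manifest-ordered feature columns, `label`.
#' @export
build_dataset <- function(records, structures, labels, backend = NULL,
                          n_shuffles = 0L, seed = 1L) {
  stopifnot(length(records) == length(labels))
  if (anyDuplicated(vapply(records, `[[`, "", "id")))
    stop("record ids must be unique within a dataset")
  m <- featurize_set(records, structures, backend = backend,
                     n_shuffles = n_shuffles, seed = seed)
  df <- data.frame(id = rownames(m), m, label = as.integer(labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Read / write dataset tables
#'
#' Datasets are stored as CSV (first column `id`, then the 93
#' manifest-ordered feature columns, then `label` and optional `split`
#' and `synthetic` columns) with a JSON sidecar recording the manifest
#' version, seed and class counts.
#'
#' @param dataset Data frame as built by [build_dataset()].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, meta = list()) {
  write.csv(dataset, path, row.names = FALSE)
  sidecar <- c(list(manifest_version = manifest_version(),
                    n_rows = nrow(dataset),
                    class_counts = as.list(table(dataset$label))),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  manifest <- feature_manifest()
  missing <- setdiff(manifest$name, colnames(df))
  if (length(missing))
    stop(sprintf("dataset is missing %d manifest feature column(s)", length(missing)))
  df
}

# feature matrix / label helpers shared by balancing and classification
dataset_matrix <- function(dataset) {
  as.matrix(dataset[, feature_manifest()$name, drop = FALSE])
}
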