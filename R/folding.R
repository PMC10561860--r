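#' Folding backends
#'
#' Secondary structures and base-pair probabilities are obtained through a
#' pluggable backend contract: any object with [fold()] and
#' [pair_probabilities()] methods. Two backends ship with the package:
#'
#' * [vienna_backend()] shells out to the `RNAfold` executable for
#'   thermodynamic minimum-free-energy structures and partition-function
#'   base-pair probabilities.
#' * [stacking_backend()] is a self-contained deterministic greedy folder:
#'   it searches for the single best complementary stem-loop (Watson-Crick
#'   plus G-U wobble pairs, hairpin loop of at least 3 nt) and assigns a
#'   free energy from a fixed stacking score. It exists so that every
#'   feature and model in the package can be exercised, reproducibly, with
#'   no external folding engine; its energies are a coarse surrogate, not
#'   nearest-neighbour thermodynamics.
#'
#' Backends are deterministic: two calls on the same sequence return
#' identical structures.
#'
#' @param backend A folding backend.
#' @param sequence RNA sequence string (A/C/G/U).
#' @return `fold()` returns a [secondary_structure] with `mfe` populated;
#'   `pair_probabilities()` returns an L x L numeric matrix with base-pair
#'   probabilities in the upper triangle.
#' @name folding_backend
NULL

#' @rdname folding_backend
#' @export
fold <- function(backend, sequence) UseMethod("fold")

#' @rdname folding_backend
#' @export
pair_probabilities <- function(backend, sequence) UseMethod("pair_probabilities")

#' RNAfold-based folding backend
#'
#' Wraps the `RNAfold` command-line program (ViennaRNA). [fold()] runs
#' `RNAfold --noPS`; [pair_probabilities()] runs the partition function
#' (`-p`) and reads the base-pair probabilities from the dot-plot file.
#'
#' @param rnafold Path to the `RNAfold` executable.
#' @return An object of class `c("vienna_backend", "folding_backend")`.
#' @export
vienna_backend <- function(rnafold = "RNAfold") {
  if (!nzchar(Sys.which(rnafold)))
    stop(sprintf("'%s' not found on PATH; use stacking_backend() or supply structures directly",
                 rnafold))
  structure(list(rnafold = rnafold),
            class = c("vienna_backend", "folding_backend"))
}

#' @export
fold.vienna_backend <- function(backend, sequence) {
  out <- run_rnafold(backend, sequence, partfunc = FALSE)
  m <- regmatches(out$struct_line,
                  regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)", out$struct_line))[[1]]
  if (length(m) != 3L) stop("could not parse RNAfold output")
  secondary_structure(m[2], as.numeric(m[3]))
}

#' @export
pair_probabilities.vienna_backend <- function(backend, sequence) {
  out <- run_rnafold(backend, sequence, partfunc = TRUE)
  L <- nchar(sequence)
  probs <- matrix(0, L, L)
  # dot-plot 'ubox' lines carry i j sqrt(p(i,j))
  ub <- grep("^\\s*[0-9]+\\s+[0-9]+\\s+[0-9.eE+-]+\\s+ubox\\s*$", out$dp_lines,
             value = TRUE)
  for (line in ub) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    i <- as.integer(f[1]); j <- as.integer(f[2])
    probs[i, j] <- as.numeric(f[3])^2
  }
  probs
}

run_rnafold <- function(backend, sequence, partfunc = FALSE) {
  dir <- tempfile("rnafold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fa <- file.path(dir, "in.fa")
  writeLines(c(">q", sequence), fa)
  args <- c("--noPS", if (partfunc) "-p", "--infile", fa)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  res <- suppressWarnings(system2(backend$rnafold, args, stdout = TRUE, stderr = FALSE))
  struct_line <- grep("^[().]+\\s+[({[]", res, value = TRUE)[1]
  if (is.na(struct_line)) stop("RNAfold produced no structure line")
  dp_lines <- character(0)
  if (partfunc) {
    dp <- list.files(dir, pattern = "_dp\\.ps$", full.names = TRUE)
    if (!length(dp)) stop("RNAfold -p produced no dot-plot file")
    dp_lines <- readLines(dp[1])
  }
  list(struct_line = struct_line, dp_lines = dp_lines)
}

#' Deterministic greedy stacking folder
#'
#' A minimal folding backend that pairs the longest complementary stem it
#' can find around each candidate hairpin loop (loop size >= `min_loop`),
#' admitting A-U, G-C and G-U pairs, and keeps the stem with the most
#' pairs (first such stem on ties). The assigned energy is a fixed
#' stacking score: -2 kcal/mol per stacked pair plus a +3 kcal/mol penalty
#' per hairpin loop; an unpaired sequence scores 0.
#'
#' [pair_probabilities()] returns a degenerate ensemble concentrated on
#' the greedy structure: probability `p_pair` on each of its base pairs.
#'
#' @param min_loop Minimum hairpin-loop size in nucleotides.
#' @param p_pair Probability mass put on each predicted pair.
#' @return An object of class `c("stacking_backend", "folding_backend")`.
#' @export
stacking_backend <- function(min_loop = 3L, p_pair = 0.95) {
  structure(list(min_loop = as.integer(min_loop), p_pair = p_pair),
            class = c("stacking_backend", "folding_backend"))
}

can_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G") |
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' @export
fold.stacking_backend <- function(backend, sequence) {
  chars <- strsplit(normalize_rna(sequence), "")[[1]]
  L <- length(chars)
  best_n <- 0L; best_i <- 0L; best_j <- 0L
  if (L >= backend$min_loop + 2L) {
    for (i in seq_len(L - backend$min_loop - 1L)) {
      j_min <- i + backend$min_loop + 1L
      for (j in j_min:L) {
        if (!can_pair(chars[i], chars[j])) next
        n <- 1L
        while (i - n >= 1L && j + n <= L && can_pair(chars[i - n], chars[j + n]))
          n <- n + 1L
        if (n > best_n) { best_n <- n; best_i <- i; best_j <- j }
      }
    }
  }
  db <- rep(".", L)
  if (best_n >= 2L) {   # single pairs give no stacking energy; leave unpaired
    idx <- seq_len(best_n) - 1L
    db[best_i - idx] <- "("
    db[best_j + idx] <- ")"
  }
  db <- paste(db, collapse = "")
  st <- secondary_structure(db, 0)
  st$mfe <- stacking_score(st)
  st
}

# -2 per stacked adjacent pair, +3 per hairpin loop; 0 when unpaired.
stacking_score <- function(structure) {
  pt <- structure$pair_table
  open <- which(pt > seq_along(pt))
  if (!length(open)) return(0)
  stacked <- sum(vapply(open, function(i)
    i + 1L <= length(pt) && pt[i + 1L] == pt[i] - 1L && pt[i + 1L] > 0L, TRUE))
  -2 * stacked + 3 * nrow(hairpin_loops(structure$dotbracket))
}

#' @export
pair_probabilities.stacking_backend <- function(backend, sequence) {
  st <- fold(backend, sequence)
  L <- nchar(sequence)
  probs <- matrix(0, L, L)
  pt <- st$pair_table
  open <- which(pt > seq_along(pt))
  for (i in open) probs[i, pt[i]] <- backend$p_pair
  probs
}

#' Dinucleotide-preserving sequence shuffles
#'
#' Generates random shuffles of a sequence that preserve its exact
#' dinucleotide (and hence mononucleotide) composition, using the
#' Altschul-Erickson Euler-path algorithm. Used to build the null
#' distribution behind the `zD` feature.
#'
#' @param sequence RNA sequence string.
#' @param n Number of shuffles.
#' @param seed Integer seed; the shuffle set is reproducible given
#'   (`sequence`, `n`, `seed`).
#' @return Character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequence, n, seed = 1L) {
  chars <- strsplit(normalize_rna(sequence), "")[[1]]
  L <- length(chars)
  if (L < 3L) return(rep(sequence, n))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  vapply(seq_len(n), function(dummy) shuffle_once(chars), "")
}

shuffle_once <- function(chars) {
  L <- length(chars)
  verts <- unique(chars)
  edges <- lapply(setNames(verts, verts),
                  function(v) chars[which(chars[-L] == v) + 1L])
  last <- chars[L]
  inner <- setdiff(verts, last)
  # choose one outgoing edge per non-terminal vertex such that the chosen
  # edges form a tree directed toward the terminal vertex
  repeat {
    pick <- vapply(inner, function(v) sample(edges[[v]], 1L), "")
    ok <- all(vapply(inner, function(v) {
      seen <- character(0)
      while (v %in% inner && !(v %in% seen)) { seen <- c(seen, v); v <- pick[[v]] }
      v == last
    }, TRUE))
    if (ok || length(inner) == 0L) break
  }
  walk_edges <- lapply(setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (v %in% inner) {
      e <- e[-match(pick[[v]], e)]
      c(if (length(e) > 1L) sample(e) else e, pick[[v]])
    } else {
      if (length(e) > 1L) sample(e) else e
    }
  })
  used <- setNames(integer(length(verts)), verts)
  out <- character(L)
  out[1] <- chars[1]
  for (i in 2:L) {
    v <- out[i - 1L]
    used[v] <- used[v] + 1L
    out[i] <- walk_edges[[v]][used[v]]
  }
  paste(out, collapse = "")
}
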