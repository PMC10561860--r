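#' An identified RNA sequence
#'
#' Constructs an `rna_record`, the basic sequence container of the package:
#' an identifier, an RNA sequence over the strict alphabet \{A, C, G, U\},
#' and a free-text provenance tag. DNA input is accepted and normalized
#' (T is rewritten to U, case is folded to upper).
#'
#' @param id Character identifier (non-empty).
#' @param sequence RNA or DNA sequence string.
#' @param source Free-text provenance tag.
#' @return An object of class `rna_record` with fields `id`, `sequence`
#'   (normalized) and `source`.
#' @examples
#' rna_record("mir-1", "ugcaTT")$sequence  # "UGCAUU"
#' @export
rna_record <- function(id, sequence, source = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  sequence <- normalize_rna(sequence, id = id)
  structure(list(id = id, sequence = sequence, source = source),
            class = "rna_record")
}

#' @export
print.rna_record <- function(x, ...) {
  cat(sprintf("<rna_record> %s (%d nt)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

# T->U and uppercase normalization; strict ACGU alphabet afterwards.
normalize_rna <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop(sprintf("record '%s': sequence must be a non-empty string", id))
  s <- chartr("tT", "uU", sequence)
  s <- toupper(s)
  bad <- setdiff(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
  if (length(bad))
    stop(sprintf("record '%s': disallowed character(s) %s (ambiguity codes are rejected)",
                 id, paste(sQuote(unique(bad)), collapse = ", ")))
  s
}

#' Read sequences from a FASTA file
#'
#' Reads a FASTA file into a list of [rna_record]s, applying T->U and
#' uppercase normalization. Records containing ambiguity codes (N, R, ...)
#' are rejected with an error naming the offending entry; with
#' `permissive = TRUE` they are skipped with a warning instead.
#'
#' @param path Path to a FASTA file.
#' @param source Provenance tag stored on every record (defaults to the
#'   file name).
#' @param permissive If `TRUE`, skip (rather than fail on) records with
#'   ambiguity codes.
#' @return A list of [rna_record]s, in file order.
#' @export
read_fasta <- function(path, source = basename(path), permissive = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids)))
    stop(sprintf("malformed FASTA header in %s", path))
  # header up to first whitespace is the id, as in most tools
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  out <- vector("list", length(set))
  keep <- logical(length(set))
  for (i in seq_along(set)) {
    rec <- tryCatch(rna_record(ids[i], as.character(set[[i]]), source = source),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (permissive) {
        warning(sprintf("skipping record '%s': %s", ids[i], conditionMessage(rec)),
                call. = FALSE)
        next
      }
      stop(rec)
    }
    out[[i]] <- rec
    keep[i] <- TRUE
  }
  out[keep]
}

#' Write records to a FASTA file
#'
#' @param records A list of [rna_record]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, `[[`, "", "sequence")
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Build the pair table of a dot-bracket string
#'
#' Matches every `(` to its `)` by stack-based nesting. The result is an
#' integer vector of length `nchar(dotbracket)`: position `i` holds the
#' 1-based index of its partner, or 0 if unpaired.
#'
#' @param dotbracket String over `(`, `)` and `.`.
#' @return Integer pair table (0 = unpaired); symmetric and involutive.
#' @examples
#' build_pair_table("((..))")  # 6 5 0 0 2 1
#' @export
build_pair_table <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad))
    stop(sprintf("invalid dot-bracket character(s): %s (pseudoknot alphabets are not supported)",
                 paste(sQuote(bad), collapse = ", ")))
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack))
        stop(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced dot-bracket: unmatched '(' at position %d", stack[1]))
  pt
}

#' A secondary structure with derived motifs
#'
#' Bundles a dot-bracket string, its minimum free energy (kcal/mol), the
#' pair table, and optionally a base-pair probability matrix. Motif counts
#' (stems, hairpin loops, loop length) are filled in by [annotate_motifs()],
#' which is called on construction by default.
#'
#' Positions are 1-based and intervals closed throughout.
#'
#' @param dotbracket String over `(`, `)`, `.`.
#' @param mfe Minimum free energy in kcal/mol.
#' @param pair_probs Optional L x L matrix of base-pair probabilities; only
#'   the upper triangle (i < j) is used. Entries must lie in \[0, 1\] and
#'   each row/column total pairing probability must not exceed 1 (up to a
#'   small numerical tolerance).
#' @param annotate If `TRUE` (default), run [annotate_motifs()].
#' @return An object of class `secondary_structure` with fields
#'   `dotbracket`, `mfe`, `pair_table`, `tot_bp`, `n_stems`, `n_loops`,
#'   `loop_length`, `pair_probs`.
#' @export
secondary_structure <- function(dotbracket, mfe = NA_real_, pair_probs = NULL,
                                annotate = TRUE) {
  pt <- build_pair_table(dotbracket)
  L <- length(pt)
  if (!is.null(pair_probs)) {
    pair_probs <- as.matrix(pair_probs)
    if (!all(dim(pair_probs) == c(L, L)))
      stop("pair_probs must be an L x L matrix")
    up <- pair_probs[upper.tri(pair_probs)]
    if (any(up < -1e-9 | up > 1 + 1e-9))
      stop("pair probabilities must lie in [0, 1]")
    m <- pair_probs
    m[lower.tri(m, diag = TRUE)] <- 0
    tot <- rowSums(m) + colSums(m)
    if (any(tot > 1 + 1e-6))
      stop("total pairing probability of a position exceeds 1")
  }
  s <- structure(list(dotbracket = dotbracket, mfe = as.numeric(mfe),
                      pair_table = pt, tot_bp = sum(pt > seq_along(pt)),
                      n_stems = NA_integer_, n_loops = NA_integer_,
                      loop_length = NA_integer_, pair_probs = pair_probs),
                 class = "secondary_structure")
  if (annotate) s <- annotate_motifs(s) else s
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d bp, MFE %.2f kcal/mol\n",
              nchar(x$dotbracket), x$tot_bp, x$mfe))
  cat(sprintf("  stems: %s  hairpin loops: %s  loop length: %s\n",
              x$n_stems, x$n_loops, x$loop_length))
  invisible(x)
}

#' Annotate stems and hairpin loops on a secondary structure
#'
#' A stem is a maximal run of stacked base pairs -- pairs (i, j) and
#' (i+1, j-1) in direct contact -- whose run length reaches `min_stack`
#' (default 4, i.e. more than three contiguous pairs). A hairpin loop is a
#' maximal unpaired run immediately enclosed by a single pair, i.e. a
#' dot-bracket substring `(\\.+)`; internal loops and bulges are not
#' counted. `loop_length` is the total (or, with `loop_length_mode =
#' "longest"`, the maximal) number of unpaired bases across hairpin loops.
#'
#' @param structure A [secondary_structure].
#' @param min_stack Minimum stacked-pair run length for a stem (default 4;
#'   set to 3 to compare against tools that admit 3-pair helices).
#' @param loop_length_mode `"sum"` (default) or `"longest"`.
#' @return The structure with `n_stems`, `n_loops`, `loop_length` filled in.
#' @export
annotate_motifs <- function(structure, min_stack = 4,
                            loop_length_mode = c("sum", "longest")) {
  loop_length_mode <- match.arg(loop_length_mode)
  pt <- structure$pair_table
  open <- which(pt > seq_along(pt))       # i of every pair (i, j), i < j
  # stacked runs: pair at i and pair at i+1 with partners j, j-1
  runs <- integer(0)
  if (length(open)) {
    len <- 1L
    for (k in seq_along(open)[-1]) {
      stacked <- open[k] == open[k - 1] + 1L && pt[open[k]] == pt[open[k - 1]] - 1L
      if (stacked) len <- len + 1L
      else { runs <- c(runs, len); len <- 1L }
    }
    runs <- c(runs, len)
  }
  structure$n_stems <- sum(runs >= min_stack)
  loops <- hairpin_loops(structure$dotbracket)
  structure$n_loops <- nrow(loops)
  sizes <- if (nrow(loops)) loops$end - loops$start + 1L else integer(0)
  structure$loop_length <-
    if (!length(sizes)) 0L
    else if (loop_length_mode == "sum") sum(sizes)
    else max(sizes)
  structure
}

# Hairpin loops as closed 1-based [start, end] intervals of unpaired bases.
hairpin_loops <- function(dotbracket) {
  m <- gregexpr("\\(\\.+\\)", dotbracket)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0)))
  start <- as.integer(m) + 1L
  end <- as.integer(m) + attr(m, "match.length") - 2L
  data.frame(start = start, end = end)
}

#' Parse a Vienna-format structure file
#'
#' Reads entries of the form produced by thermodynamic folding tools:
#' a `>` header line, a sequence line, and a dot-bracket line ending with
#' the minimum free energy in parentheses, e.g. `"(((...))) (-1.20)"`.
#'
#' @param path Path to the file.
#' @return A list of entries, each a list with elements `record` (an
#'   [rna_record]) and `structure` (a [secondary_structure]).
#' @export
parse_vienna <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) stop(sprintf("no '>' headers found in %s", path))
  out <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[headers[k]]))
    body <- lines[seq(headers[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(body) < 2L)
      stop(sprintf("entry '%s': expected a sequence line and a structure line", id))
    seq_line <- gsub("\\s", "", body[1])
    struct_line <- trimws(body[2])
    m <- regmatches(struct_line,
                    regexec("^([().]+)\\s+\\(\\s*(-?[0-9]+(?:\\.[0-9]+)?)\\s*\\)$",
                            struct_line))[[1]]
    if (length(m) != 3L)
      stop(sprintf("entry '%s': structure line must end with '(<mfe>)'", id))
    db <- m[2]
    mfe <- as.numeric(m[3])
    if (nchar(db) != nchar(seq_line))
      stop(sprintf("entry '%s': structure length %d does not match sequence length %d",
                   id, nchar(db), nchar(seq_line)))
    rec <- rna_record(id, seq_line, source = basename(path))
    out[[k]] <- list(record = rec, structure = secondary_structure(db, mfe))
  }
  out
}

#' Write (record, structure) entries in Vienna format
#'
#' @param entries A list of `list(record =, structure =)` pairs as returned
#'   by [parse_vienna()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    writeLines(c(paste0(">", e$record$id), e$record$sequence,
                 sprintf("%s (%.2f)", e$structure$dotbracket, e$structure$mfe)),
               con)
  }
  invisible(path)
}
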