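# Independent brute-force oracles used to cross-check the implementation.
# These are written in a deliberately naive style (plain loops, direct
# formula transcription) and share no code with the package internals.

# random balanced dot-bracket string of length <= max_len
random_dotbracket <- function(max_len = 60L) {
  len <- sample(4:max_len, 1L)
  out <- character(0)
  depth <- 0L
  for (i in seq_len(len)) {
    remaining <- len - i + 1L
    choices <- c(".", if (remaining > depth + 1L) "(", if (depth > 0L) ")")
    ch <- sample(choices, 1L)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    out <- c(out, ch)
  }
  while (depth > 0L) { out <- c(out, ")"); depth <- depth - 1L }
  paste(out, collapse = "")
}

# naive pair table: scan for innermost "(...)" pairs repeatedly
oracle_pair_table <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pt <- integer(length(chars))
  work <- chars
  repeat {
    done <- TRUE
    for (i in seq_along(work)) {
      if (work[i] != "(") next
      j <- i + 1L
      while (j <= length(work) && work[j] %in% c(".", "*")) j <- j + 1L
      if (j <= length(work) && work[j] == ")") {
        pt[i] <- j; pt[j] <- i
        work[i] <- "*"; work[j] <- "*"
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  # dots also become unpaired zeros; '*' marks consumed brackets
  pt
}

# brute-force stems: enumerate all maximal stacked-pair runs from the pair set
oracle_motifs <- function(db, min_stack = 4L) {
  pt <- oracle_pair_table(db)
  pairs <- list()
  for (i in seq_along(pt)) if (pt[i] > i) pairs[[length(pairs) + 1L]] <- c(i, pt[i])
  has_pair <- function(i, j) i >= 1 && j >= 1 && i <= length(pt) && pt[i] == j
  n_stems <- 0L
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    if (has_pair(i - 1L, j + 1L)) next        # not a run start
    len <- 0L
    while (i + len < j - len && has_pair(i + len, j - len)) len <- len + 1L
    if (len >= min_stack) n_stems <- n_stems + 1L
  }
  # hairpin loops: maximal dot runs whose immediate neighbours pair with
  # each other
  chars <- strsplit(db, "")[[1]]
  n_loops <- 0L; loop_len <- 0L
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == ".") {
      j <- i
      while (j < length(chars) && chars[j + 1L] == ".") j <- j + 1L
      if (i > 1L && j < length(chars) && pt[i - 1L] == j + 1L) {
        n_loops <- n_loops + 1L
        loop_len <- loop_len + (j - i + 1L)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  list(n_stems = n_stems, n_loops = n_loops, loop_length = loop_len,
       tot_bp = length(pairs))
}

# naive transcription of every feature formula; returns the 93 values in
# manifest order
oracle_featurize <- function(sequence, db, mfe, pair_probs,
                             null_dD = NULL) {
  nt <- strsplit(sequence, "")[[1]]
  L <- length(nt)
  nucs <- c("A", "C", "G", "U")
  pats <- c("(((", "((.", "(.(", "(..", ".((", ".(.", "..(", "...")
  coll <- gsub(")", "(", db, fixed = TRUE)
  st <- strsplit(coll, "")[[1]]
  trip <- numeric(0)
  for (n in nucs) for (p in pats) {
    cnt <- 0L
    for (i in 1:(L - 2L)) {
      if (nt[i + 1L] == n && paste0(st[i], st[i + 1L], st[i + 2L]) == p)
        cnt <- cnt + 1L
    }
    trip <- c(trip, cnt / (L - 2L))
  }
  mono_cnt <- sapply(nucs, function(x) sum(nt == x))
  dinucs <- as.vector(outer(nucs, nucs, paste0))
  di_cnt <- sapply(dinucs, function(xy) {
    cnt <- 0L
    for (i in 1:(L - 1L)) if (paste0(nt[i], nt[i + 1L]) == xy) cnt <- cnt + 1L
    cnt
  })
  gc_cnt <- mono_cnt["G"] + mono_cnt["C"]
  au_cnt <- mono_cnt["A"] + mono_cnt["U"]
  mot <- oracle_motifs(db)
  gc_pct <- gc_cnt / L * 100
  dG <- mfe / L
  safe <- function(a, b) if (b == 0) 0 else a / b
  Q <- 0; dD <- 0
  for (i in 1:(L - 1L)) for (j in (i + 1L):L) {
    p <- pair_probs[i, j]
    if (p > 0) {
      Q <- Q - p * log2(p)
      dD <- dD + p * (1 - p)
    }
  }
  dD <- dD / L
  zD <- if (is.null(null_dD) || sd(null_dD) == 0) 0
        else (dD - mean(null_dD)) / sd(null_dD)
  unname(c(trip,
           mono_cnt, mono_cnt / L * 100,
           di_cnt, di_cnt / (L - 1L) * 100,
           gc_cnt, au_cnt, gc_cnt / L * 100, au_cnt / L * 100, L,
           mot$n_stems, mot$n_loops, mot$loop_length, mot$tot_bp,
           mfe, dG, mot$tot_bp / L,
           safe(dG, gc_pct), safe(dG, mot$n_stems), safe(dG, mot$n_loops),
           safe(dG, mot$tot_bp), safe(mot$tot_bp, mot$n_stems),
           Q, Q / L, dD, zD))
}

# is point s on the segment between some pair of rows of xm?
on_some_segment <- function(s, xm, tol = 1e-8) {
  for (i in seq_len(nrow(xm))) for (j in seq_len(nrow(xm))) {
    if (i == j) next
    a <- xm[i, ]; b <- xm[j, ]
    ab <- b - a
    denom <- sum(ab^2)
    t <- if (denom == 0) 0 else sum((s - a) * ab) / denom
    if (t >= -tol && t <= 1 + tol && sqrt(sum((s - (a + t * ab))^2)) < tol)
      return(TRUE)
  }
  FALSE
}

# random-sequence fixture helpers
random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                                  collapse = "")
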