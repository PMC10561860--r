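test_that("triplet elements bin windows by middle nucleotide and collapsed pattern", {
  v <- triplet_elements("AAA", "...")
  expect_length(v, 32L)
  expect_equal(unname(v["A..."]), 1)
  expect_equal(sum(v), 1)
  expect_equal(sum(v != 0), 1L)

  # ')' collapses to '(' before pattern lookup
  v <- triplet_elements("GGGGAAAACCCC", "((((....))))")
  expect_equal(sum(v), 1)
  oracle <- oracle_featurize("GGGGAAAACCCC", "((((....))))", -3.1,
                             matrix(0, 12, 12))[1:32]
  expect_equal(unname(v), oracle, tolerance = 1e-12)

  expect_error(triplet_elements("AU", ".."), ">= 3")
})

test_that("triplet frequencies form a probability vector on random inputs", {
  set.seed(11)
  for (rep in 1:100) {
    db <- random_dotbracket(50L)
    s <- random_rna(nchar(db))
    v <- triplet_elements(s, db)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("composition features use overlapping windows and sum to 100", {
  v <- composition_features("GCGC")
  expect_equal(unname(v["pct_G_plus_C"]), 100)
  expect_equal(unname(v["pct_A"]), 0)

  v <- composition_features("AUAU")
  expect_equal(unname(v["pct_AU"]), 2 / 3 * 100)   # windows AU, UA, AU
  expect_equal(unname(v["pct_UA"]), 1 / 3 * 100)

  set.seed(3)
  for (rep in 1:50) {
    v <- composition_features(random_rna(sample(5:120, 1L)))
    expect_equal(sum(v[paste0("pct_", c("A", "C", "G", "U"))]), 100, tolerance = 1e-9)
    di <- as.vector(outer(c("A","C","G","U"), c("A","C","G","U"), paste0))
    expect_equal(sum(v[paste0("pct_", di)]), 100, tolerance = 1e-9)
    expect_equal(unname(v["pct_G_plus_C"] + v["pct_A_plus_U"]), 100, tolerance = 1e-9)
  }
})

test_that("thermodynamic features follow the ratio definitions with zero-denominator convention", {
  # dG is MFE over length
  s <- secondary_structure(paste(rep(".", 100), collapse = ""), -25)
  rec <- rna_record("r", random_rna(100))
  expect_equal(unname(thermo_features(s, rec$sequence)["dG"]), -0.25)

  # fully unpaired: every motif-normalized index degenerates to 0
  s <- secondary_structure("....", 0)
  tf <- thermo_features(s, "ACGU")
  expect_equal(unname(tf[c("dP", "MFE2", "MFE3", "MFE4", "avg_bp")]),
               rep(0, 5))

  s <- secondary_structure("((((....))))", -3.10)
  tf <- thermo_features(s, "GGGGAAAACCCC")
  expect_equal(unname(tf["dG"]), -3.10 / 12)
  expect_equal(unname(tf["dP"]), 4 / 12)
  expect_equal(unname(tf["MFE3"]), -3.10 / 12 / 1)   # one hairpin loop
  expect_equal(unname(tf["MFE2"]), -3.10 / 12 / 1)   # one stem
  expect_equal(unname(tf["MFE4"]), -3.10 / 12 / 4)
  expect_equal(unname(tf["avg_bp"]), 4)
})

test_that("entropy features evaluate the ensemble sums", {
  L <- 10L
  db <- paste(rep(".", L), collapse = "")
  p0 <- matrix(0, L, L)
  s <- secondary_structure(db, 0, pair_probs = p0)
  e <- entropy_features(s)
  expect_equal(unname(e[c("dQ", "dD")]), c(0, 0))

  p1 <- p0; p1[2, 9] <- 1
  e <- entropy_features(secondary_structure(db, 0, pair_probs = p1))
  expect_equal(unname(e[c("dQ", "dD")]), c(0, 0))   # log2(1) = 0

  p5 <- p0; p5[2, 9] <- 0.5
  e <- entropy_features(secondary_structure(db, 0, pair_probs = p5))
  expect_equal(unname(e["dQ"]), 0.05)
  expect_equal(unname(e["dD"]), 0.025)

  expect_error(entropy_features(secondary_structure(db, 0)), "pair_probs")
})

test_that("featurize emits 93 manifest-ordered finite values, deterministically", {
  manifest <- feature_manifest()
  expect_equal(nrow(manifest), 93L)
  expect_equal(sum(manifest$group == "triplet"), 32L)

  fx <- generate_fixtures(3, 3, seed = 21)
  v1 <- featurize(fx$records[[1]], fx$structures[[1]])
  v2 <- featurize(fx$records[[1]], fx$structures[[1]])
  expect_length(v1, 93L)
  expect_identical(names(v1), manifest$name)
  expect_true(all(is.finite(v1)))
  expect_identical(v1, v2)
})

test_that("featurize matches the naive brute-force oracle on 200 random fixtures", {
  fx <- generate_fixtures(100, 100, seed = 99)
  for (i in seq_along(fx$records)) {
    rec <- fx$records[[i]]
    st <- fx$structures[[i]]
    got <- featurize(rec, st)
    want <- oracle_featurize(rec$sequence, st$dotbracket, st$mfe, st$pair_probs)
    expect_equal(unname(got), want, tolerance = 1e-9, info = rec$id, ignore_attr = TRUE)
  }
})

test_that("zD standardizes against the shuffle null and is seed-reproducible", {
  be <- stacking_backend()
  fx <- generate_fixtures(1, 0, seed = 5)
  rec <- fx$records[[1]]; st <- fx$structures[[1]]
  v1 <- featurize(rec, st, backend = be, n_shuffles = 20, seed = 7)
  v2 <- featurize(rec, st, backend = be, n_shuffles = 20, seed = 7)
  expect_identical(v1["zD"], v2["zD"])

  # naive recomputation from the same shuffle set
  shuf <- dinucleotide_shuffle(rec$sequence, 20, seed = 7)
  null_dD <- sapply(shuf, function(s) {
    pp <- pair_probabilities(be, s)
    tot <- 0
    L <- nchar(s)
    for (i in 1:(L - 1)) for (j in (i + 1):L)
      tot <- tot + pp[i, j] * (1 - pp[i, j])
    tot / L
  })
  want <- oracle_featurize(rec$sequence, st$dotbracket, st$mfe, st$pair_probs,
                           null_dD = null_dD)
  expect_equal(unname(v1["zD"]), want[93], tolerance = 1e-9)
})

test_that("dinucleotide shuffles preserve dinucleotide composition", {
  set.seed(2)
  dimer_table <- function(s) {
    nt <- strsplit(s, "")[[1]]
    sort(table(paste0(nt[-length(nt)], nt[-1])))
  }
  for (rep in 1:20) {
    s <- random_rna(sample(20:80, 1L))
    shuf <- dinucleotide_shuffle(s, 5, seed = rep)
    for (x in shuf) expect_identical(dimer_table(x), dimer_table(s))
  }
})

test_that("scaler standardizes training data and tolerates constant columns", {
  x <- cbind(a = c(0, 2), b = c(5, 5))
  sc <- fit_scaler(x)
  scaled <- apply_scaler(sc, x)
  expect_equal(scaled[, "a"], c(-1, 1))
  expect_equal(scaled[, "b"], c(0, 0))

  set.seed(8)
  x <- matrix(rnorm(200), 20, 10)
  sc <- fit_scaler(x)
  z <- apply_scaler(sc, x)
  expect_true(all(abs(colMeans(z)) < 1e-9))

  expect_error(fit_scaler(x[1, , drop = FALSE]), "at least 2")
})
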