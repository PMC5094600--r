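test_that("swinger enumeration is the 23 non-identity permutations, with group structure", {
  rules <- swingerRules()
  expect_length(rules, 23L)
  expect_false(any(duplicated(names(rules))))
  sym <- vapply(rules, isSymmetricRule, TRUE)
  expect_equal(sum(sym), 9L)
  expect_equal(sum(!sym), 14L)
  # cycle-type census: 6 transpositions, 3 double transpositions,
  # 8 three-cycles, 6 four-cycles
  n_fixed <- vapply(rules, function(r)
    sum(r@mapping[c("A", "C", "G", "T")] == c("A", "C", "G", "T")), 0L)
  expect_equal(sum(n_fixed == 2L), 6L)   # single transpositions
  expect_equal(sum(n_fixed == 0L & sym), 3L)
  expect_equal(sum(n_fixed == 1L), 8L)   # 3-cycles
  expect_equal(sum(n_fixed == 0L & !sym), 6L)  # 4-cycles
  # every rule composed with its inverse is the identity
  for (r in rules)
    expect_equal(unname(composeRules(r, inverseRule(r))),
                 c("A", "C", "G", "T"))
  # closure: composites always land inside the 24-element symmetric group
  all_perms <- c(lapply(rules, function(r) unname(r@mapping)),
                 list(c("A", "C", "G", "T")))
  for (a in rules[1:5])
    for (b in rules)
      expect_true(any(vapply(all_perms, identical,
                             TRUE, unname(composeRules(a, b)))))
})

test_that("applySwinger substitutes letters, preserves length and inverts", {
  expect_equal(applySwinger("ACGT", "A<->C"), "CAGT")
  r3 <- swingerRule("A>C>G>A")
  s <- "ACGTTGCA"
  expect_equal(applySwinger(applySwinger(applySwinger(s, r3), r3), r3), s)
  set.seed(11)
  for (r in swingerRules()) {
    s <- rand_dna(50)
    t <- applySwinger(s, r)
    expect_equal(nchar(t), 50L)
    expect_equal(applySwinger(t, inverseRule(r)), s)
    if (isSymmetricRule(r)) expect_equal(applySwinger(t, r), s)
  }
  expect_error(applySwinger("", "A<->C"), "empty")
  expect_warning(out <- applySwinger("ACNGT", "A<->C"), "ambiguity")
  expect_equal(out, "CANGT")
})

test_that("applyDel keeps three, skips one or two, and records the posmap", {
  ts <- applyDel("ACGTACGT", delRule(1, 0))
  expect_equal(transformedResidues(ts), "ACGACG")
  expect_equal(posmap(ts), c(0L, 1L, 2L, 4L, 5L, 6L))
  ts2 <- applyDel("ACGTACGTAC", delRule(2, 0))
  expect_equal(transformedResidues(ts2), "ACGCGT")
  expect_equal(posmap(ts2), c(0L, 1L, 2L, 5L, 6L, 7L))
  # residues before the phase offset are retained verbatim
  ts3 <- applyDel("ACGTACGT", delRule(1, 2))
  expect_equal(posmap(ts3), c(0L, 1L, 2L, 3L, 4L, 6L, 7L))
  expect_error(applyDel("ACG", delRule(1, 0)), "period")
  rules <- delRules()
  expect_length(rules, 9L)
  expect_equal(sum(vapply(rules, function(r) r@skip, 0L) == 1L), 4L)
  expect_equal(sum(vapply(rules, function(r) r@skip, 0L) == 2L), 5L)
})

test_that("across all phases every interior position is kept exactly 3 times", {
  s <- rand_dna(37)
  for (skip in 1:2) {
    period <- 3L + skip
    kept <- integer(nchar(s))
    for (phase in 0:(period - 1L)) {
      pm <- posmap(applyDel(s, delRule(skip, phase)))
      kept[pm + 1L] <- kept[pm + 1L] + 1L
    }
    # positions at or beyond one full period are shared by exactly 3 phases
    expect_true(all(kept[(period + 1L):nchar(s)] == 3L))
  }
})

test_that("revComp is the Watson-Crick involution", {
  expect_equal(revComp("ACGT"), "ACGT")
  expect_equal(revComp("AAAC"), "GTTT")
  set.seed(5)
  for (i in 1:10) {
    s <- rand_dna(sample(10:60, 1))
    expect_equal(revComp(revComp(s)), s)
  }
})

test_that("projectToSource gives minimal source intervals and round-trips", {
  g <- genomeSequence("ACGTACGT")
  sw <- transformGenome(g, "A<->C")
  expect_equal(unname(projectToSource(sw, 2, 5)),
               matrix(c(2L, 5L), 1, dimnames = NULL))
  del <- applyDel("ACGTACGT", delRule(1, 0))
  expect_equal(unname(projectToSource(del, 0, 6)),
               matrix(c(0L, 4L, 3L, 7L), 2))
  expect_error(projectToSource(del, 0, 7), "out of range")
  # round trip: source letters at projected positions, re-deleted,
  # equal the transformed slice (posmap oracle)
  set.seed(21)
  for (i in 1:20) {
    s <- rand_dna(sample(12:60, 1))
    rule <- delRule(sample(1:2, 1), sample(0:3, 1))
    ts <- applyDel(s, rule)
    n <- nchar(transformedResidues(ts))
    a <- sample.int(n, 1) - 1L
    b <- a + sample.int(n - a, 1)
    iv <- projectToSource(ts, a, b)
    pos <- unlist(apply(iv, 1, function(r) r[1]:(r[2] - 1L)))
    expect_equal(sort(pos), sort(posmap(ts)[(a + 1L):b]))
    src <- strsplit(s, "")[[1]]
    expect_equal(paste(src[posmap(ts)[(a + 1L):b] + 1L], collapse = ""),
                 substr(transformedResidues(ts), a + 1L, b))
  }
})

test_that("transformGenome dispatches on rule type and keeps coordinates", {
  g <- genomeSequence("ACGTACGTACGT", id = "g1")
  id <- transformGenome(g, "identity")
  expect_equal(transformedResidues(id), genomeResidues(g))
  expect_equal(posmap(id), 0:11)
  sw <- transformGenome(g, "A>C>G>A")
  expect_equal(nchar(transformedResidues(sw)), 12L)
  expect_equal(posmap(sw), 0:11)
  del <- transformGenome(g, "del3-2.1")
  expect_equal(ruleLabel(del), "del3-2.1")
  expect_equal(posmap(del), c(0L, 1L, 2L, 3L, 6L, 7L, 8L, 11L))
  expect_error(transformGenome(g, "A<->Z"), "unknown swinger rule")
})
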