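test_that("p-distances follow the gap-excluding mismatch fraction", {
  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "MNPQRSTVWY",
           d = "MNPQRGHIKL")
  d <- pdistance_matrix(aln)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["a", "d"], 0.5)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  # gapped columns are excluded pairwise
  g <- c(a = "AC-EF", b = "ACDEF", c = "AC-EF")
  expect_equal(pdistance_matrix(g)["a", "b"], 0)

  expect_error(pdistance_matrix(c(a = "AC", b = "ACD", c = "AC")),
               "equal gapped length")
  expect_error(pdistance_matrix(c(a = "A-", b = "-A", c = "AA")),
               "no comparable columns")
  expect_error(pdistance_matrix(c(a = "AC", b = "AC")), "at least 3")
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length,
                        c(tr$tip.label, rep(NA, tr$Nnode))[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 1)
  expect_equal(unname(bl["B"]), 1)
  expect_equal(unname(bl["C"]), 3)
})

test_that("NJ recovers additive quartets exactly (topology and lengths)", {
  set.seed(17)
  for (k in 1:15) {
    # random positive branch lengths on a random quartet topology
    taxa <- c("t1", "t2", "t3", "t4")
    pair <- sample(taxa, 2)
    rest <- setdiff(taxa, pair)
    bl <- stats::runif(5, 0.05, 1)
    nwk <- sprintf("((%s:%f,%s:%f):%f,%s:%f,%s:%f);",
                   pair[1], bl[1], pair[2], bl[2], bl[5],
                   rest[1], bl[3], rest[2], bl[4])
    gen <- ape::read.tree(text = nwk)
    d <- ape::cophenetic.phylo(gen)[taxa, taxa]
    tr <- nj_tree(d)
    expect_setequal(tr$tip.label, taxa)
    # topology must match the least-squares oracle over all 3 topologies
    oracle <- brute_quartet(d)
    expect_setequal(quartet_pair(tr, first = "t1"),
                    sort(taxa[if (1 %in% oracle$pair) oracle$pair
                              else setdiff(1:4, oracle$pair)]))
    # and the oracle's fit must be exact for additive input
    expect_lt(oracle$rss, 1e-20)
    # total tree length is preserved for additive matrices
    expect_equal(sum(tr$edge.length), sum(gen$edge.length),
                 tolerance = 1e-10)
  }
})

test_that("NJ is consistent on additive matrices from larger trees", {
  set.seed(23)
  for (k in 1:8) {
    gen <- ape::rtree(sample(5:8, 1), rooted = FALSE,
                      br = function(n) stats::runif(n, 0.1, 1))
    d <- ape::cophenetic.phylo(gen)
    tr <- nj_tree(d[gen$tip.label, gen$tip.label])
    expect_equal(topo_signature(tr), topo_signature(gen))
  }
})

test_that("negative NJ branch lengths are clamped without changing taxa", {
  # a non-additive matrix known to produce a negative NJ edge
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0),
              4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 0.1; d["b", "a"] <- 0.1
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_setequal(tr$tip.label, letters[1:4])
})

test_that("bootstrap supports are seed-deterministic and signal-driven", {
  expect_error(bootstrap_supports(c(a = "AC", b = "AC", c = "AC"), 0),
               "n_reps")
  # 20 columns perfectly supporting ab|cd
  aln <- c(a = strrep("A", 20), b = strrep("A", 20),
           c = strrep("C", 20), d = strrep("C", 20))
  tr <- bootstrap_supports(aln, 25, seed = 3)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_equal(unname(sup), 1)

  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.08,(C:0.1,D:0.1):0.08);")
  tips <- evolve_on_tree(ape::unroot(tree), strrep("ACDEFGHIKLMNPQRSTVWY", 10),
                         rate = 1, seed = 5)
  t1 <- bootstrap_supports(tips, 40, seed = 11)
  t2 <- bootstrap_supports(tips, 40, seed = 11)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("outgroup rooting preserves the bipartition set", {
  expect_error(root_with_outgroup(ape::rtree(4), letters[1:10]),
               "missing")
  tr <- ape::unroot(ape::rtree(8, br = function(n) stats::runif(n, 0.1, 1)))
  expect_error(root_with_outgroup(tr, tr$tip.label), "every taxon")
  set.seed(31)
  for (k in 1:8) {
    tr <- ape::unroot(ape::rtree(8, br = function(n) stats::runif(n, 0.1, 1)))
    rooted <- root_with_outgroup(tr, tr$tip.label[1])
    expect_true(ape::is.rooted(rooted))
    expect_setequal(bipartitions(rooted), bipartitions(tr))
  }
})

test_that("rooting on a non-monophyletic outgroup is refused", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(root_with_outgroup(ape::unroot(tr), c("A", "C")),
               "not monophyletic")
})

test_that("monophyly checks match the edge-bipartition definition", {
  tr <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  expect_equal(check_monophyly(tr, c(A = "x", B = "x", C = "y", D = "y")),
               c(x = TRUE, y = TRUE))
  expect_equal(check_monophyly(tr, c(A = "x", B = "y", C = "x", D = "y")),
               c(x = FALSE, y = FALSE))
  expect_equal(unname(check_monophyly(
    tr, c(A = "s", B = "t", C = "t", D = "t"))["s"]), TRUE)
  expect_error(check_monophyly(tr, c(A = "x", B = "x", C = "y")),
               "unlabeled")
})

test_that("trees evolved at low divergence are recovered by NJ bootstrap", {
  gen <- ape::unroot(ape::read.tree(text = paste0(
    "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.05,",
    "((E:0.05,F:0.05):0.05,(G:0.05,H:0.05):0.05):0.05);")))
  root_seq <- paste(rep(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                        50), collapse = "")
  sig_gen <- topo_signature(gen)
  hits <- 0
  runs <- 30
  for (s in seq_len(runs)) {
    tips <- evolve_on_tree(gen, root_seq, rate = 1, seed = 1000 + s)
    # modal topology over bootstrap replicates
    reps <- 20
    sigs <- character(reps)
    for (r in seq_len(reps)) {
      set.seed(5000 + s * 100 + r)
      idx <- sample.int(nchar(root_seq), nchar(root_seq), replace = TRUE)
      mat <- do.call(rbind, strsplit(tips, ""))
      rep_aln <- apply(mat[, idx, drop = FALSE], 1, paste, collapse = "")
      names(rep_aln) <- names(tips)
      sigs[r] <- topo_signature(nj_tree(pdistance_matrix(rep_aln)))
    }
    modal <- names(sort(table(sigs), decreasing = TRUE))[1]
    if (modal == sig_gen) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.9)
})
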