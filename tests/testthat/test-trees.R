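test_that("parse_newick reads topology and lengths as written", {
  t <- parse_newick("((A:1,B:2):3);")
  expect_s3_class(t, "clone_tree")
  expect_equal(length(t$parent), 4)
  root <- which(is.na(t$parent))
  founder <- which(t$parent == root)
  expect_equal(t$edge_length[founder], 3)
  leaves <- setdiff(which(!is.na(t$parent)), founder)
  expect_setequal(t$name[leaves], c("A", "B"))
  expect_setequal(t$edge_length[leaves], c(1, 2))

  minimal <- parse_newick("(A:1);")
  expect_equal(length(minimal$parent), 2)
  expect_equal(sum(minimal$edge_length, na.rm = TRUE), 1)
})

test_that("malformed Newick reports a character offset", {
  expect_error(parse_newick("((A:1,B:2):3));"), "character 14")
  expect_error(parse_newick("(((A:1,B:2):3);"), "unclosed")
  expect_error(parse_newick("(A:1,B:2)"), "';'")
})

test_that("negative branch lengths and root edges are handled", {
  expect_error(parse_newick("((A:-1,B:2):3);"), "negative")
  expect_warning(t <- parse_newick("((A:1,B:2):3):9;"), "root")
  expect_equal(sum(t$edge_length, na.rm = TRUE), 6)
})

test_that("missing branch lengths default to zero", {
  t <- parse_newick("((A,B:2):3);")
  expect_equal(sort(t$edge_length[!is.na(t$parent)]), c(0, 2, 3))
})

test_that("write_newick round-trips random trees, including zero lengths", {
  skip_if_not_installed("withr")
  withr::with_seed(101, {
    for (i in 1:100) {
      t <- rand_tree(extra = sample(1:12, 1))
      # sprinkle exact zero-length edges
      nz <- which(!is.na(t$parent))
      t$edge_length[sample(nz, 1)] <- 0
      if (sum(t$edge_length, na.rm = TRUE) == 0)
        t$edge_length[nz[1]] <- 1
      back <- parse_newick(write_newick(t))
      expect_identical(iso_canon(back), iso_canon(t))
    }
  })
  # explicit zero-length serialization
  t0 <- parse_newick("((A:0,B:2):3);")
  expect_match(write_newick(t0), "A:0")
})

test_that("clone_tree invariants are enforced", {
  expect_error(clone_tree(c(NA, 1, 1), c(NA, 1, 2)), "exactly one child")
  expect_error(clone_tree(c(NA, 1), c(NA, -2)), "negative|positive")
  expect_error(clone_tree(c(NA, 1), c(NA, 0)), "positive")
  expect_error(clone_tree(NA_integer_, NA_real_), "at least")
  expect_error(clone_tree(c(NA, 1L, 4L, 3L), c(NA, 1, 1, 1)),
               "cycle|disconnected")
})

test_that("binarize_multifurcations follows the zero-length spine rule", {
  # founder with subtree depths (2,1,1): the deep child keeps its edge, the
  # two shallow children move one level down behind a zero-length spine
  t <- parse_newick("(((X:1)A:5,B:1,C:2)F:4);")
  b <- binarize_multifurcations(t)
  expect_true(all(vapply(seq_along(b$parent),
                         function(v) sum(b$parent == v, na.rm = TRUE),
                         integer(1)) <= 2))
  expect_equal(sum(b$edge_length, na.rm = TRUE),
               sum(t$edge_length, na.rm = TRUE))
  expect_equal(sum(b$inserted), 1)
  d <- tip_depths(b)
  expect_equal(unname(d[names(d) == "X"]), 3)     # A kept its level
  expect_equal(unname(d[names(d) %in% c("B", "C")]), c(3, 3)) # pushed down
})

test_that("binarization is the identity on binary trees", {
  t <- parse_newick("(((X:1,Y:2)A:5,B:1)F:4);")
  b <- binarize_multifurcations(t)
  expect_equal(sum(b$inserted), 0)
  expect_identical(iso_canon(b), iso_canon(t))
})

test_that("star multifurcation gets children - 2 spine edges, length kept", {
  t <- parse_newick("((A:1,B:1,C:1,D:1)F:0.5);")
  b <- binarize_multifurcations(t)
  expect_equal(sum(b$inserted), 2)
  expect_equal(sum(b$edge_length, na.rm = TRUE), 4.5)
})

test_that("binarization conserves length and never lowers tip depth", {
  skip_if_not_installed("withr")
  withr::with_seed(77, {
    for (i in 1:40) {
      t <- rand_tree(extra = sample(2:15, 1))
      b <- binarize_multifurcations(t)
      expect_equal(sum(b$edge_length, na.rm = TRUE),
                   sum(t$edge_length, na.rm = TRUE))
      d_t <- sort(tip_depths(t))
      d_b <- sort(tip_depths(b))
      expect_gte(min(as.integer(d_b)), min(as.integer(d_t)))
      expect_gte(max(as.integer(d_b)), max(as.integer(d_t)))
    }
  })
})

test_that("depth_profile reports per-tree depths and the cohort maximum", {
  t1 <- parse_newick("(F:3);")                 # depth 1
  t2 <- parse_newick("((a:1,b:1)F:1);")        # depth 2
  t3 <- parse_newick("(((((x:1)a:1)b:1)c:1)F:1);") # depth 5
  expect_equal(attr(depth_profile(t1), "d_max"), 1)
  expect_equal(unname(tip_depths(t2)), c(2, 2))
  dp <- depth_profile(list(t1, t2, t3))
  expect_equal(dp$max_depth, c(1, 2, 5))
  expect_equal(attr(dp, "d_max"), 5)
  expect_error(depth_profile(list()), "at least one")
})

test_that("binarize_vaf thresholds at VAF >= 0.05 inclusively", {
  m <- matrix(c(0.049, 0.05, 0.51), nrow = 1)
  expect_equal(as.vector(binarize_vaf(m)), c(0, 1, 1))
  z <- matrix(0, 3, 4)
  expect_true(all(binarize_vaf(z) == 0))
  expect_true(all(binarize_vaf(z, threshold = 0) == 1))
  expect_error(binarize_vaf(matrix(c(0.2, 1.4), 1)), "\\[0, 1\\]")
  # data frame with an identifier column survives
  df <- data.frame(variant = c("v1", "v2"), r1 = c(0.2, 0.01),
                   r2 = c(0.04, 0.8))
  b <- binarize_vaf(df)
  expect_equal(b$variant, c("v1", "v2"))
  expect_equal(b$r1, c(1, 0))
  expect_equal(b$r2, c(0, 1))
})
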