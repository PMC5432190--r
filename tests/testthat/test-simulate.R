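test_that("archetype topologies are frozen and ordered by complexity", {
  mc <- base_topology("MC")
  expect_equal(length(mc$parent), 2)
  sizes <- vapply(c("PL", "PM", "PH"),
                  function(cl) length(base_topology(cl)$parent), integer(1))
  expect_true(sizes[["PH"]] > sizes[["PM"]])
  expect_true(sizes[["PM"]] > sizes[["PL"]])
  depths <- vapply(c("PL", "PM", "PH", "MT"),
                   function(cl) max(tip_depths(base_topology(cl))),
                   integer(1))
  expect_true(all(diff(depths[c("PL", "PM", "PH", "MT")]) > 0))
  expect_equal(max(tip_depths(base_topology("MT"))), 5)
  expect_identical(write_newick(base_topology("PH")),
                   write_newick(base_topology("PH")))
  expect_error(base_topology("XX"), "unknown topology class")
})

test_that("perturbation keeps trees valid and scales with the index", {
  skip_if_not_installed("withr")
  # a fixed seed gives a deterministic perturbation
  a <- perturb_topology(base_topology("PM"), 3, seed = 11)
  b <- perturb_topology(base_topology("PM"), 3, seed = 11)
  expect_identical(write_newick(a), write_newick(b))
  withr::with_seed(79, {
    dev <- sapply(c(1, 5), function(idx) {
      mean(sapply(1:200, function(i) {
        t <- perturb_topology(base_topology("PL"), idx)
        expect_gte(length(t$parent), 2)
        abs(length(t$parent) - length(base_topology("PL")$parent))
      }))
    })
    expect_gt(dev[2], dev[1])  # node-count deviation grows with the index
  })
})

test_that("edge-length assignment conserves the total exactly", {
  skip_if_not_installed("withr")
  withr::with_seed(83, {
    for (i in 1:25) {
      t <- perturb_topology(base_topology("PM"), 3)
      tot <- sample(50:800, 1)
      tot <- max(tot, length(t$parent) - 1)
      out <- assign_edge_lengths(t, sample(c("TR", "BL", "BR"), 1),
                                 variance_index = sample(1:4, 1),
                                 total_ssnvs = tot)
      expect_equal(sum(out$edge_length, na.rm = TRUE), tot)
      expect_true(all(out$edge_length[!is.na(out$parent)] ==
                        round(out$edge_length[!is.na(out$parent)])))
    }
  })
  expect_error(assign_edge_lengths(base_topology("PH"), "TR", 1,
                                   total_ssnvs = 3), "smaller than")
})

test_that("mean trunk fraction orders TR > BL > BR", {
  skip_if_not_installed("withr")
  withr::with_seed(89, {
    frac <- sapply(c("TR", "BL", "BR"), function(p) {
      mean(sapply(1:200, function(i) {
        t <- assign_edge_lengths(base_topology("PM"), p,
                                 variance_index = 2, total_ssnvs = 500)
        root <- which(is.na(t$parent))
        t$edge_length[which(t$parent == root)] /
          sum(t$edge_length, na.rm = TRUE)
      }))
    })
    expect_gt(frac[["TR"]], frac[["BL"]])
    expect_gt(frac[["BL"]], frac[["BR"]])
    expect_equal(frac[["TR"]], 0.8, tolerance = 0.05)
    expect_equal(frac[["BL"]], 0.5, tolerance = 0.05)
    expect_equal(frac[["BR"]], 0.2, tolerance = 0.05)
  })
})

test_that("generate_design produces the documented cohorts", {
  co1 <- generate_design("I", seed = 91)
  expect_equal(length(co1$trees), 40)
  expect_equal(length(unique(co1$truth)), 4)
  # design I: unit edge lengths (topology is the only signal)
  expect_true(all(vapply(co1$trees, function(t)
    all(t$edge_length[!is.na(t$parent)] == 1), logical(1))))

  co3 <- generate_design("III", seed = 91)
  expect_equal(length(co3$trees), 90)
  expect_equal(length(unique(co3$truth)), 9)
  expect_setequal(unique(co3$truth),
                  as.vector(outer(c("PL", "PM", "PH"), c("TR", "BL", "BR"),
                                  paste, sep = "-")))
  expect_error(generate_design("I", classes = "PL-TR"), "invalid class")
})

test_that("the same seed reproduces a byte-identical cohort", {
  a <- generate_design("III", trees_per_class = 3, seed = 97)
  b <- generate_design("III", trees_per_class = 3, seed = 97)
  expect_identical(vapply(a$trees, write_newick, character(1)),
                   vapply(b$trees, write_newick, character(1)))
  expect_identical(a$truth, b$truth)
})

test_that("within-class spread grows with the variance index", {
  skip_if_not_installed("withr")
  withr::with_seed(101, {
    within_var <- sapply(c(1, 3, 5), function(v) {
      mean(sapply(1:30, function(s) {
        co <- generate_design("II", trees_per_class = 5, variance_index = v)
        rs <- register_set(co$trees)
        mean(sapply(unique(co$truth), function(cl)
          tree_variance(rs$Z[co$truth == cl, , drop = FALSE])))
      }))
    })
    expect_true(all(diff(within_var) > 0))
  })
})

test_that("classes are well separated at the lowest indices", {
  co <- generate_design("III", seed = 103)
  rs <- register_set(co$trees)
  D <- distance_matrix(rs)
  same <- outer(co$truth, co$truth, "==") & upper.tri(D)
  diff_cl <- outer(co$truth, co$truth, "!=") & upper.tri(D)
  expect_gt(mean(D[diff_cl]), 3 * mean(D[same]))
})

test_that("cohorts round-trip through the on-disk format", {
  co <- generate_design("II", trees_per_class = 3, seed = 107)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  trees <- read_clone_trees(file.path(dir, "cohort.nwk"))
  expect_equal(length(trees), 9)
  truth <- read.delim(file.path(dir, "cohort_truth.tsv"))
  expect_equal(truth$class, co$truth)
  td <- tidy(co)
  expect_equal(nrow(td), 9)
  expect_true(all(td$total_ssnvs >= td$n_nodes - 1))
})
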