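test_that("Ward dendrogram matches a brute-force linkage oracle", {
  # two points merge once at their Euclidean distance
  two <- ward_dendrogram(rbind(c(0, 0), c(3, 4)), c("a", "b"))
  expect_equal(nrow(two$hc$merge), 1L)
  expect_equal(two$hc$height, 5)
  # the nearest pair merges first
  coll <- ward_dendrogram(matrix(c(0, 1, 10), 3), c("a", "a", "b"))
  expect_equal(sort(coll$hc$merge[1, ]), c(-2L, -1L))
  # randomized instances against the O(n^3) Lance-Williams oracle
  set.seed(51)
  for (rep in 1:3) {
    X <- matrix(rnorm(24), 12)
    d <- ward_dendrogram(X, rep(c("a", "b"), 6))
    orc <- ward_oracle(X)
    expect_equal(d$hc$height, orc$height, tolerance = 1e-8)
    expect_equal(apply(d$hc$merge, 1, sort), apply(orc$merge, 1, sort))
  }
  # planted 4-cluster fixture is recovered exactly when cutting at 4
  set.seed(52)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  X4 <- centers[rep(1:4, each = 10), ] + matrix(rnorm(80, sd = 0.5), 40)
  d4 <- ward_dendrogram(X4, rep(letters[1:4], each = 10))
  expect_true(same_partition(stats::cutree(d4$hc, 4), rep(1:4, each = 10)))
  expect_error(ward_dendrogram(matrix(1, 1, 2), "a"), "size")
})

test_that("class merge order reads the topology from pure subtrees", {
  set.seed(53)
  # two classes: a single split
  Z <- rbind(matrix(rnorm(20, sd = 0.1), 10),
             matrix(rnorm(20, sd = 0.1) + 5, 10))
  lab <- rep(c("urine", "sweat"), each = 10)
  d <- ward_dendrogram(Z, lab); d$scores <- Z
  topo <- class_merge_order(d, c("urine", "sweat"))
  expect_equal(format_topology(topo), "(urine,sweat)")
  expect_equal(attr(topo, "method"), "samples")
  # permuting the sample order leaves the topology unchanged
  i <- sample(nrow(Z))
  d2 <- ward_dendrogram(Z[i, ], lab[i]); d2$scores <- Z[i, ]
  expect_equal(format_topology(class_merge_order(d2, c("urine", "sweat"))),
               "(urine,sweat)")
  # impure subtrees fall back to centroid clustering
  overlap <- rbind(matrix(rnorm(30), 15), matrix(rnorm(30), 15))
  lab2 <- rep(c("urine", "sweat"), each = 15)
  dov <- ward_dendrogram(overlap, lab2); dov$scores <- overlap
  expect_message(topo2 <- class_merge_order(dov, c("urine", "sweat")),
                 "centroid")
  expect_equal(attr(topo2, "method"), "centroid_fallback")
  expect_equal(format_topology(topo2), "(urine,sweat)")
})

test_that("reference spectra cluster into the expected class topology", {
  train <- fresh_reference()
  m <- fit_plsda_cv(train$X, train$meta$fluid, train$meta$donor_id,
                    K_max = 10, seed = 11)
  sc <- pls_project(m, train$X)$scores
  d <- ward_dendrogram(sc, train$meta$fluid)
  d$scores <- sc
  topo <- class_merge_order(d)
  expect_equal(format_topology(topo),
               "((blood,(saliva,semen)),(urine,sweat))")
  expect_equal(attr(topo, "method"), "samples")
})

test_that("tree construction yields two-class node models and leaf Q-tests", {
  train <- fresh_reference()
  tree <- fit_tree_scheme(train, alpha = 5e-5, seed = 11)
  # a five-leaf binary tree has four internal nodes
  count <- function(nd) {
    if (nd$type == "leaf") return(c(nodes = 0L, leaves = 1L))
    count(nd$children$L) + count(nd$children$R) + c(nodes = 1L, leaves = 0L)
  }
  expect_equal(count(tree$root), c(nodes = 4L, leaves = 5L))
  walk <- function(nd) {
    if (nd$type == "leaf") {
      expect_s3_class(nd$q_model, "q_model")
      expect_equal(nd$q_model$alpha, 5e-5)
    } else {
      expect_equal(length(nd$model$class_labels), 2L)
      expect_length(intersect(nd$left_labels, nd$right_labels), 0L)
      walk(nd$children$L); walk(nd$children$R)
    }
  }
  walk(tree$root)
  # every training spectrum routes to its own leaf
  pred <- classify_tree(tree, train$X)
  expect_equal(pred$candidate, train$meta$fluid)
  expect_gt(mean(pred$predicted == train$meta$fluid), 1 - 10 * 5e-5)
  # topology errors are rejected
  expect_error(build_tree(train, list("blood", list())), "topology")
})

test_that("tree classification records paths and rejects interferents", {
  train <- fresh_reference()
  tree <- fit_tree_scheme(train, alpha = 5e-5, seed = 11)
  tpl <- default_fluid_templates()
  set.seed(54)
  Xu <- area_normalize_matrix(simulate_fluid_matrix(tpl$urine, 10, 5))
  pu <- classify_tree(tree, Xu)
  expect_true(all(pu$predicted == "urine"))
  expect_true(all(pu$path == "root>urine+sweat>urine"))
  # aged semen with strongly decayed protein bands (~40 percent) still
  # routes to the semen leaf; at moderate aging the Q-test accepts it too
  set.seed(55)
  Xs <- simulate_fluid_matrix(tpl$semen, 10, 5)
  aging <- default_aging_models()$semen
  ps_strong <- classify_tree(tree, area_normalize_matrix(
    apply_aging(Xs, aging, 129)))
  expect_true(all(ps_strong$candidate == "semen"))
  ps_month <- classify_tree(tree, area_normalize_matrix(
    apply_aging(Xs, aging, 31)))
  expect_gt(mean(ps_month$predicted == "semen"), 0.9)
  # off-template interferents are flagged at every leaf they reach
  nb <- preprocess_spectra(simulate_non_bf(seed = 56))
  pn <- classify_tree(tree, nb$X)
  expect_true(all(pn$predicted == "OUTLIER"))
  # returned labels are always leaves of the tree
  expect_true(all(pu$candidate %in% tree$class_labels))
})

test_that("flat and tree schemes agree on fresh in-distribution spectra", {
  train <- fresh_reference()
  flat <- fit_flat_scheme(train, alpha = 0.005, seed = 11)
  tree <- fit_tree_scheme(train, alpha = 5e-5, seed = 11)
  set.seed(57)
  tpl <- default_fluid_templates()
  for (f in c("blood", "urine")) {
    X <- area_normalize_matrix(simulate_fluid_matrix(tpl[[f]], 12, 5))
    expect_equal(classify_flat(flat, X)$candidate,
                 classify_tree(tree, X)$candidate)
  }
})

test_that("the tree scheme is more robust to aging than the flat scheme", {
  data <- preprocess_spectra(simulate_dataset(
    dataset_design(n_donors = 8, replicates = 4, ages = c(1L, 150L),
                   seed = 58)))
  flat_cv <- cross_validate(data, "flat", k_folds = 4, seed = 58)
  tree_cv <- cross_validate(data, "tree", k_folds = 4, seed = 58)
  sf <- summarize_confusion(flat_cv)
  st <- summarize_confusion(tree_cv)
  aged_f <- sf$accuracy[sf$stratum == "5 months"]
  aged_t <- st$accuracy[st$stratum == "5 months"]
  expect_lt(aged_f, 1)          # the flat scheme demonstrably degrades
  expect_gte(aged_t, aged_f)    # the tree is at least as accurate
})
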