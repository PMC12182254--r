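test_that("top-node selection follows the 10+10 rule with availability limits", {
  set.seed(3)
  covs <- rnorm(268, 0, 0.2)
  sel <- select_top_nodes(covs)
  expect_equal(nrow(sel$nodes), 20)
  expect_equal(sum(sel$nodes$sign == "positive"), 10)
  expect_equal(sum(sel$nodes$sign == "negative"), 10)
  pos <- sel$nodes$covariance[sel$nodes$sign == "positive"]
  neg <- sel$nodes$covariance[sel$nodes$sign == "negative"]
  expect_true(all(diff(pos) <= 0))       # descending
  expect_true(all(diff(neg) >= 0))       # ascending
  expect_equal(pos, sort(covs[covs > 0], decreasing = TRUE)[1:10])
  expect_equal(neg, sort(covs[covs < 0])[1:10])

  # fewer strictly-signed entries than requested: returns the available 14
  covs2 <- c(runif(4, 0.1, 1), -runif(30, 0.1, 1), rep(0, 10))
  sel2 <- select_top_nodes(covs2)
  expect_equal(nrow(sel2$nodes), 14)
  expect_equal(sum(sel2$nodes$sign == "positive"), 4)

  # zero covariance belongs to neither list
  expect_equal(nrow(select_top_nodes(rep(0, 50))$nodes), 0)

  # ties broken by lower node index
  sel3 <- select_top_nodes(c(0.5, 0.5, 0.5, -0.2), k_pos = 2)
  expect_equal(sel3$nodes$node_id[sel3$nodes$sign == "positive"], c("1", "2"))
})

test_that("selection is permutation-equivariant and antisymmetric under negation", {
  set.seed(5)
  covs <- rnorm(40); names(covs) <- sprintf("n%02d", 1:40)
  perm <- sample(40)
  sel <- select_top_nodes(covs)
  sel_p <- select_top_nodes(covs[perm])
  expect_setequal(sel$nodes$node_id, sel_p$nodes$node_id)

  sel_neg <- select_top_nodes(-covs)
  expect_setequal(sel$nodes$node_id[sel$nodes$sign == "positive"],
                  sel_neg$nodes$node_id[sel_neg$nodes$sign == "negative"])
})

test_that("per-system counts conserve the selection and include zero systems", {
  atlas <- synthetic_atlas(50, n_systems = 10, seed = 2)
  expect_equal(sort(unique(atlas$system)), sort(functional_systems))
  set.seed(6)
  covs <- rnorm(50); names(covs) <- 1:50
  sel <- select_top_nodes(covs)
  counts <- count_by_system(sel, atlas)
  expect_equal(nrow(counts), 10)          # fixed spider axes
  expect_equal(sum(counts$count), nrow(sel$nodes))

  # all selected nodes in one system
  atlas_one <- tibble::tibble(node_id = 1:50, system = "OnlyOne")
  counts_one <- count_by_system(sel, atlas_one)
  expect_equal(counts_one$count, nrow(sel$nodes))

  # planted: 2 selected per system
  atlas_bal <- tibble::tibble(node_id = 1:50,
                              system = rep(sprintf("S%02d", 1:10), 5))
  covs_bal <- rep(0, 50)
  covs_bal[1:20] <- rep(c(0.5, -0.5), 10)  # nodes 1-20 cover each system twice
  names(covs_bal) <- 1:50
  counts_bal <- count_by_system(select_top_nodes(covs_bal), atlas_bal)
  expect_true(all(counts_bal$count == 2))

  expect_error(count_by_system(sel, atlas[1:10, ]), "missing from atlas")
})

test_that("fold-averaged covariances are the entrywise mean", {
  v1 <- c(a = 1, b = -2, c = 3)
  expect_equal(average_covariances(list(v1)), v1)
  expect_equal(unname(average_covariances(list(v1, -v1))), c(0, 0, 0))
  set.seed(7)
  folds <- replicate(5, rnorm(8), simplify = FALSE)
  expect_equal(average_covariances(folds),
               colMeans(do.call(rbind, folds)))
  # tibble interface used by crossval output
  tab <- tibble::tibble(repeat_index = rep(1:2, each = 3),
                        node_id = rep(1:3, 2),
                        covariance = c(1, 2, 3, 3, 4, 5))
  expect_equal(unname(average_covariances(tab)), c(2, 3, 4))
  expect_error(average_covariances(list()), "non-empty")
})

test_that("edge highlights select 5+5 nodes and their within-group edges", {
  set.seed(9)
  v <- 30
  covs <- rnorm(v); names(covs) <- 1:v
  mean_conn <- matrix(rnorm(v * v), v, v); mean_conn <- (mean_conn + t(mean_conn)) / 2
  eh <- top_edges(covs, mean_conn, k = 5)
  expect_equal(sum(eh$nodes$sign == "positive"), 5)
  expect_equal(sum(eh$nodes$sign == "negative"), 5)
  expect_false(eh$flag)
  expect_equal(nrow(eh$edges), 2 * choose(5, 2))
  # edges lie within the complete graph on each signed group
  for (sg in c("positive", "negative")) {
    grp <- eh$nodes$node_id[eh$nodes$sign == sg]
    sub <- eh$edges[eh$edges$sign == sg, ]
    expect_true(all(sub$node_x %in% grp) && all(sub$node_y %in% grp))
  }
  # edge weights come from the group-mean connectome
  e1 <- eh$edges[1, ]
  expect_equal(e1$weight,
               mean_conn[as.integer(e1$node_x), as.integer(e1$node_y)])

  # k = 1: single node per sign, no edges
  eh1 <- top_edges(covs, mean_conn, k = 1)
  expect_equal(nrow(eh1$nodes), 2)
  expect_equal(nrow(eh1$edges), 0)

  # fewer than k of one sign: available nodes returned and flagged
  covs_pos <- abs(covs); names(covs_pos) <- 1:v
  covs_pos[1:2] <- -covs_pos[1:2]
  eh2 <- top_edges(covs_pos, mean_conn, k = 5)
  expect_true(eh2$flag)
  expect_equal(sum(eh2$nodes$sign == "negative"), 2)

  # atlas coordinates attached when supplied
  eh3 <- top_edges(covs, mean_conn, k = 3, atlas = synthetic_atlas(v, seed = 1))
  expect_true(all(c("system", "x", "y", "z") %in% names(eh3$nodes)))
})
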