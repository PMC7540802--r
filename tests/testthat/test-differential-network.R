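# Top-k extraction, subnetwork decomposition, colour mapping, GraphML export.

test_that("colour_map hits the green/white/red anchors and clamps", {
  expect_equal(unname(colour_map(0)), c(255L, 255L, 255L))
  expect_equal(unname(colour_map(-0.5)), c(0L, 255L, 0L))
  expect_equal(unname(colour_map(0.5)), c(255L, 0L, 0L))
  expect_equal(unname(colour_map(0.25)), c(255L, 128L, 128L))
  expect_equal(unname(colour_map(-0.25)), c(128L, 255L, 128L))
  # clamping beyond the anchors
  expect_equal(unname(colour_map(3)), c(255L, 0L, 0L))
  expect_equal(unname(colour_map(-99)), c(0L, 255L, 0L))
  expect_error(colour_map(NaN), "finite")
  expect_error(colour_map(0, halfwidth = 0), "positive")
})

test_that("colour_map is symmetric and channel-monotone on each half-range", {
  d <- seq(0, 0.5, by = 0.05)
  up <- colour_map(d)
  down <- colour_map(-d)
  # red side mirrors green side with r and g channels exchanged
  expect_equal(up[, "r"], rep(255L, length(d)))
  expect_equal(down[, "g"], rep(255L, length(d)))
  expect_equal(up[, "g"], down[, "r"])
  expect_equal(up[, "b"], down[, "b"])
  # monotone: increasing |value| drains the non-saturated channels
  expect_true(all(diff(up[, "g"]) <= 0))
  expect_true(all(diff(up[, "b"]) <= 0))
})

test_that("node colours centre at the mean and saturate at the extremes", {
  one <- node_colour_map(c(g = 1.68))
  expect_equal(unname(one["g", ]), c(255L, 255L, 255L))
  m <- node_colour_map(c(lo = 0, mid = 2, hi = 4))
  expect_equal(unname(m["mid", ]), c(255L, 255L, 255L))
  expect_equal(unname(m["hi", ]), c(255L, 0L, 0L))
  expect_equal(unname(m["lo", ]), c(0L, 255L, 0L))
  flat <- node_colour_map(c(a = 1, b = 1, c = 1))
  expect_true(all(flat == 255L))
})

test_that("top_k_links orders by absolute score and nests across k", {
  scored <- data.frame(
    gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
    interaction_type = "activation",
    link_id = c("A|activation|B", "B|activation|C", "C|activation|D"),
    link_score = c(5, -6, 1),
    stringsAsFactors = FALSE
  )
  top2 <- top_k_links(scored, 2)
  expect_equal(top2$link_score, c(-6, 5))
  expect_equal(top_k_links(scored, 3)$link_score, c(-6, 5, 1))
  expect_error(top_k_links(scored, 4), "exceeds the 3")

  case <- random_case(20, 80, seed = 61, with_expression = FALSE)
  sc <- score_links(case$net, case$profile)
  for (k in 2:10) {
    expect_true(all(
      top_k_links(sc, k - 1)$link_id %in% top_k_links(sc, k)$link_id
    ))
  }
})

test_that("components_by_size matches union-find and orders largest first", {
  links <- data.frame(
    gene_a = c("A", "B", "D"), gene_b = c("B", "C", "E"),
    interaction_type = "activation",
    link_id = c("A|activation|B", "B|activation|C", "D|activation|E"),
    link_score = c(1, 2, 3), stringsAsFactors = FALSE
  )
  comps <- components_by_size(links)
  expect_equal(lapply(comps, `[[`, "genes"), list(c("A", "B", "C"), c("D", "E")))
  expect_equal(components_by_size(links[1, ])[[1]]$genes, c("A", "B"))
  expect_equal(components_by_size(links[0, ]), list())

  # random case: component gene partition equals an independent union-find
  case <- random_case(25, 40, seed = 71, with_expression = FALSE)
  sc <- score_links(case$net, case$profile)
  comps2 <- components_by_size(sc)
  got <- lapply(comps2, `[[`, "genes")
  want <- oracle_components(sc)
  expect_setequal(
    vapply(got, paste, character(1), collapse = ","),
    vapply(want, paste, character(1), collapse = ",")
  )
  # partition covers exactly the incident genes, sizes non-increasing
  expect_setequal(unlist(got), unique(c(sc$gene_a, sc$gene_b)))
  sizes <- vapply(comps2, `[[`, numeric(1), "n_links")
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted modules come out as the leading subnetworks", {
  # three chains of 10, 7 and 5 links plus 25 scattered singleton links
  chain <- function(prefix, n_links) {
    genes <- sprintf("%s%02d", prefix, seq_len(n_links + 1))
    data.frame(
      gene_a = genes[-length(genes)], gene_b = genes[-1],
      interaction_type = "activation", stringsAsFactors = FALSE
    )
  }
  scatter <- data.frame(
    gene_a = sprintf("x%02d", 1:25), gene_b = sprintf("y%02d", 1:25),
    interaction_type = "activation", stringsAsFactors = FALSE
  )
  df <- rbind(chain("a", 10), chain("b", 7), chain("c", 5), scatter)
  df$link_id <- link_identity(df$gene_a, df$gene_b, df$interaction_type)
  df$link_score <- seq_len(nrow(df))
  comps <- components_by_size(df)
  expect_equal(
    vapply(comps[1:3], `[[`, numeric(1), "n_links"),
    c(10, 7, 5)
  )
})

test_that("views export to GraphML and round-trip links and attributes", {
  case <- random_case(30, 120, seed = 81, with_expression = TRUE)
  sc <- score_links(case$net, case$profile)
  view <- build_view(sc, node_values = case$profile$expr2, k = 47)
  expect_equal(nrow(view$links), 47)
  expect_equal(
    unname(view$edge_colours),
    colour_hex(colour_map(view$links$link_score, 0, 0.5))
  )

  prefix <- file.path(withr::local_tempdir(), "view")
  export_view(view, prefix)
  back <- read_view_graph(paste0(prefix, ".graphml"))
  expect_equal(nrow(back$edges), 47)
  expect_setequal(back$edges$link_id, view$links$link_id)
  expect_setequal(back$nodes$name, names(view$node_values))
  ord <- match(view$links$link_id, back$edges$link_id)
  expect_equal(back$edges$link_score[ord], view$links$link_score)
  expect_identical(back$edges$colour[ord], unname(view$edge_colours))
  nord <- match(names(view$node_values), back$nodes$name)
  expect_equal(back$nodes$value[nord], unname(view$node_values))
})

test_that("head-to-head views share the link set and differ only in scores", {
  case <- random_case(30, 120, seed = 91, with_expression = FALSE)
  sc <- score_links(case$net, case$profile)
  view <- build_view(sc, k = 20)
  other <- experiment_profile(
    "drug",
    logfc = stats::setNames(
      -0.5 * case$profile$logfc, names(case$profile$logfc)
    )
  )
  h2h <- head_to_head_view(view, other)
  expect_identical(h2h$links$link_id, view$links$link_id)
  expect_equal(h2h$links$link_score, -0.5 * view$links$link_score)
  expect_false(identical(h2h$edge_colours, view$edge_colours))

  sparse <- experiment_profile("sparse", logfc = c(nope = 1))
  expect_error(head_to_head_view(view, sparse), "lacks log-fold changes")
})
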