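# Jaccard overlap, union-set Pearson correlation, drug ranking.

test_that("jaccard_index handles the standard set-theory cases", {
  expect_equal(jaccard_index(c("x", "y"), c("y", "x")), 1)
  expect_equal(jaccard_index(c("x", "y"), c("u", "v")), 0)
  expect_equal(jaccard_index(character(0), character(0)), 0)
  expect_equal(jaccard_index(c("a", "a", "b"), c("b", "c")), 1 / 3)
  # symmetry and ordering invariance
  set.seed(4)
  for (i in 1:10) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    j <- jaccard_index(a, b)
    expect_equal(j, jaccard_index(b, a))
    expect_equal(j, jaccard_index(rev(a), sample(b)))
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

# Two selections over a shared toy network, built from explicit logfc maps.
make_pair <- function(disease_lfc, drug_lfc, q = 0.25) {
  net <- toy_network(list(
    c("A", "activation", "B"), c("B", "activation", "C"),
    c("C", "activation", "D"), c("D", "activation", "E"),
    c("E", "activation", "F"), c("A", "inhibition", "F")
  ))
  dz <- select_links(
    net, experiment_profile("disease", logfc = disease_lfc), q
  )
  drug <- select_links(
    net, experiment_profile("drug", logfc = drug_lfc), q
  )
  list(net = net, disease = dz, drug = drug)
}

test_that("a perfect reverser correlates -1 before inversion and +1 after", {
  lfc <- c(A = 2, B = -1, C = 3, D = -2, E = 1, F = -3)
  p <- make_pair(lfc, -lfc)
  r_raw <- pearson_on_union(p$disease, p$drug)
  expect_equal(as.numeric(r_raw), -1)
  r_inv <- pearson_on_union(invert_selection(p$disease), p$drug)
  expect_equal(as.numeric(r_inv), 1)
  # and an identical drug correlates +1 with the uninverted disease
  p2 <- make_pair(lfc, lfc)
  expect_equal(as.numeric(pearson_on_union(p2$disease, p2$drug)), 1)
})

test_that("pearson_on_union reproduces hand-computed correlations", {
  # perfectly linear pairs -> 1; perfectly anti-linear -> -1
  expect_equal(oracle_pearson(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(oracle_pearson(c(1, 2, 3), c(1, 0, -1)), -1)

  case <- random_case(10, 30, seed = 41, with_expression = FALSE)
  case2 <- random_case(10, 30, seed = 41, with_expression = FALSE)
  set.seed(42)
  case2$profile <- experiment_profile(
    "other",
    logfc = stats::setNames(rnorm(10), names(case$profile$logfc))
  )
  s1 <- select_links(case$net, case$profile, 0.15)
  s2 <- select_links(case2$net, case2$profile, 0.15)
  ids <- union(s1$selected$link_id, s2$selected$link_id)
  expect_equal(
    as.numeric(pearson_on_union(s1, s2)),
    oracle_pearson(unname(s1$full_scores[ids]), unname(s2$full_scores[ids]))
  )
})

test_that("degenerate unions give an explicit NA, not a number", {
  lfc <- c(A = 2, B = -1, C = 3, D = -2, E = 1, F = -3)
  p <- make_pair(lfc, -lfc)
  tiny <- p$drug
  tiny$selected <- tiny$selected[1, , drop = FALSE]
  dz <- p$disease
  dz$selected <- dz$selected[1, , drop = FALSE]
  # union of 1 or 2 links: fewer than 3 pairs
  if (nrow(unique(rbind(tiny$selected, dz$selected))) < 3) {
    expect_true(is.na(pearson_on_union(dz, tiny)))
  }
  # zero variance on one side
  flat <- p$drug
  flat$full_scores[] <- 1
  expect_true(is.na(pearson_on_union(p$disease, flat)))
})

test_that("pearson is invariant to positive rescaling of drug logfc", {
  case <- random_case(12, 30, seed = 51, with_expression = FALSE)
  drug_lfc <- case$profile$logfc
  net <- case$net
  dz_lfc <- stats::setNames(
    rnorm(length(drug_lfc)), names(drug_lfc)
  )
  dz <- invert_selection(
    select_links(net, experiment_profile("dz", logfc = dz_lfc), 0.15)
  )
  s1 <- select_links(net, experiment_profile("d", logfc = drug_lfc), 0.15)
  s2 <- select_links(net, experiment_profile("d", logfc = 7 * drug_lfc), 0.15)
  expect_equal(
    as.numeric(pearson_on_union(dz, s1)),
    as.numeric(pearson_on_union(dz, s2))
  )
})

test_that("rank_drugs orders by score with id tie-breaks and NA last", {
  lfc <- c(A = 2, B = -1, C = 3, D = -2, E = 1, F = -3)
  p <- make_pair(lfc, -lfc)
  dz_inv <- invert_selection(p$disease)

  reverser <- p$drug
  reverser$experiment_id <- "b_reverser"
  same <- p$drug
  same$experiment_id <- "a_same"
  flat <- p$drug
  flat$full_scores[] <- 1 # undefined correlation
  flat$experiment_id <- "z_flat"

  rk <- rank_drugs(dz_inv, list(reverser, same, flat))
  # identical scores tie, broken by experiment_id ascending
  expect_identical(
    rk$pearson$experiment_id,
    c("a_same", "b_reverser", "z_flat")
  )
  expect_true(is.na(rk$pearson$pearson_r[3]))
  expect_equal(rk$pearson$rank, 1:3)
  expect_identical(attr(rk$jaccard, "ranked_by"), "jaccard")
  expect_error(rank_drugs(dz_inv, list()), "empty")

  single <- rank_drugs(dz_inv, list(reverser))
  expect_equal(nrow(single$pearson), 1)
  expect_equal(single$pearson$rank, 1)
})

test_that("sign-aware Jaccard only counts direction-concordant overlaps", {
  lfc <- c(A = 2, B = -1, C = 3, D = -2, E = 1, F = -3)
  p <- make_pair(lfc, -lfc) # drug reverses: after inversion signs agree
  dz_inv <- invert_selection(p$disease)
  plain <- compare_drug(dz_inv, p$drug)
  aware <- compare_drug(dz_inv, p$drug, sign_aware_jaccard = TRUE)
  expect_equal(aware$jaccard, plain$jaccard) # all concordant here

  p2 <- make_pair(lfc, lfc) # drug mimics disease: all discordant after inversion
  dz_inv2 <- invert_selection(p2$disease)
  aware2 <- compare_drug(dz_inv2, p2$drug, sign_aware_jaccard = TRUE)
  expect_equal(aware2$n_intersection, 0)
  expect_equal(aware2$jaccard, 0)
})

test_that("ranking tables write with the published column layout", {
  lfc <- c(A = 2, B = -1, C = 3, D = -2, E = 1, F = -3)
  p <- make_pair(lfc, -lfc)
  rk <- rank_drugs(invert_selection(p$disease), list(p$drug))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(rk$pearson, f)
  lines <- readLines(f)
  expect_identical(lines[1], "# ranked_by=pearson")
  expect_match(lines[2], "rank\texperiment_id\tpearson_r\tr_squared")
  tab <- utils::read.delim(f, comment.char = "#")
  expect_equal(tab$r_squared, tab$pearson_r^2)
})
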