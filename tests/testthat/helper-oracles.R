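# Fixtures and independent oracles used across the suite. The oracles are
# deliberately naive (explicit loops, full sorts, union-find) and share no
# code with the package implementation they check.

# Small deterministic network builder.
toy_network <- function(edges) {
  # edges: list of c(gene_a, type, gene_b)
  df <- do.call(rbind, lapply(edges, function(e) {
    data.frame(
      gene_a = e[1], interaction_type = e[2], gene_b = e[3],
      stringsAsFactors = FALSE
    )
  }))
  interaction_network(df)
}

# Random scoreable test case: network + profile over the same genes.
random_case <- function(n_genes, n_links, seed, with_expression = TRUE) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  pairs <- t(utils::combn(genes, 2))
  take <- sample(nrow(pairs), min(n_links, nrow(pairs)))
  df <- data.frame(
    gene_a = pairs[take, 1],
    interaction_type = sample(
      c("activation", "inhibition", "unknown"), length(take), replace = TRUE
    ),
    gene_b = pairs[take, 2],
    stringsAsFactors = FALSE
  )
  net <- interaction_network(df)
  if (with_expression) {
    e1 <- stats::setNames(round(stats::runif(n_genes, 0, 5), 2), genes)
    e2 <- stats::setNames(round(stats::runif(n_genes, 0, 5), 2), genes)
    prof <- experiment_profile("case", expr1 = e1, expr2 = e2)
  } else {
    prof <- experiment_profile(
      "case",
      logfc = stats::setNames(round(stats::rnorm(n_genes), 2), genes)
    )
  }
  list(net = net, profile = prof)
}

# Brute-force reference for select_links: materializes every score list with
# explicit per-link loops, sorts, and takes ceiling(q * n) per tail.
oracle_select <- function(net, profile, q, mode = "union") {
  links <- net$links
  lfc <- profile$logfc
  ids <- character(0)
  scores_ls <- numeric(0)
  is_vals <- numeric(0)
  ids_is <- character(0)
  for (i in seq_len(nrow(links))) {
    a <- links$gene_a[i]; b <- links$gene_b[i]
    if (!(a %in% names(lfc)) || !(b %in% names(lfc))) next
    s <- if (links$interaction_type[i] == "inhibition") {
      lfc[[a]] - lfc[[b]]
    } else {
      lfc[[a]] + lfc[[b]]
    }
    ids <- c(ids, links$link_id[i])
    scores_ls <- c(scores_ls, s)
    if (length(profile$expr1) > 0 &&
      all(c(a, b) %in% names(profile$expr1)) &&
      all(c(a, b) %in% names(profile$expr2))) {
      ids_is <- c(ids_is, links$link_id[i])
      is_vals <- c(
        is_vals,
        min(
          profile$expr1[[a]] + profile$expr1[[b]],
          profile$expr2[[a]] + profile$expr2[[b]]
        )
      )
    }
  }
  tails <- function(score, id, m) {
    if (length(score) == 0) return(character(0))
    m <- min(m, length(score))
    top <- id[order(-score, id)][seq_len(m)]
    bot <- id[order(score, id)][seq_len(m)]
    union(top, bot)
  }
  crit <- list()
  crit$link_score <- tails(scores_ls, ids, ceiling(q * length(ids)))
  if (length(is_vals) > 0) {
    crit$interaction_score <- tails(is_vals, ids_is, ceiling(q * length(ids_is)))
  }
  genes <- intersect(net$genes, names(lfc))
  gv <- unname(lfc[genes])
  m <- ceiling(q * length(genes))
  tail_genes <- union(
    genes[order(-gv, genes)][seq_len(m)],
    genes[order(gv, genes)][seq_len(m)]
  )
  hit <- character(0)
  for (i in seq_len(nrow(links))) {
    if (!(links$link_id[i] %in% ids)) next
    if (links$gene_a[i] %in% tail_genes || links$gene_b[i] %in% tail_genes) {
      hit <- c(hit, links$link_id[i])
    }
  }
  crit$gene_logfc <- hit
  selected <- if (mode == "union") Reduce(union, crit) else Reduce(intersect, crit)
  sort(selected)
}

# Plain union-find over gene ids, for checking connected components.
oracle_components <- function(links) {
  parent <- stats::setNames(
    unique(c(links$gene_a, links$gene_b)),
    unique(c(links$gene_a, links$gene_b))
  )
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(links))) {
    ra <- find(links$gene_a[i]); rb <- find(links$gene_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(names(parent), find, character(1))
  unname(lapply(split(names(parent), roots), sort))
}

# Closed-form Pearson r, written out from the definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
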