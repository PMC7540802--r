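# Relevance scoring of interactions by differential expression, and
# extreme-quantile filtering of each experiment's links to its relevant set.

#' LinkScore of one or more links
#'
#' The LinkScore of an activating (or unknown-type) interaction is the sum of
#' the log-fold changes of its two genes; for an inhibition it is their
#' difference. For a directed inhibition the difference is source minus
#' target; for an undirected one, the lexicographically smaller gene id minus
#' the larger (a fixed convention - the two symmetric quantile tails used for
#' filtering make selection independent of this orientation).
#'
#' @param gene_a,gene_b gene ids (vectors).
#' @param interaction_type `"activation"`, `"inhibition"` or `"unknown"`.
#' @param logfc named numeric vector, gene -> log-fold change.
#' @param directed logical; when `FALSE` the pair is canonicalized first.
#' @return numeric vector of LinkScores; `NA` where a gene has no log-fold
#'   change (the caller logs and excludes such links).
#' @export
link_score <- function(gene_a, gene_b, interaction_type, logfc,
                       directed = FALSE) {
  directed <- rep_len(directed, length(gene_a))
  swap <- !directed & gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  fa <- unname(logfc[a])
  fb <- unname(logfc[b])
  ifelse(interaction_type == "inhibition", fa - fb, fa + fb)
}

#' InteractionScore of one or more links
#'
#' The joint-expression score: within each condition the expression levels of
#' the two interacting genes are summed, and the smaller of the two condition
#' sums is returned. High values flag pairs that are strongly expressed under
#' both conditions.
#'
#' @param gene_a,gene_b gene ids (vectors).
#' @param expr1,expr2 named numeric vectors, gene -> expression per condition.
#' @return numeric vector; `NA` where either gene lacks expression in either
#'   condition (the link is then ineligible for this criterion).
#' @export
interaction_score <- function(gene_a, gene_b, expr1, expr2) {
  s1 <- unname(expr1[gene_a]) + unname(expr1[gene_b])
  s2 <- unname(expr2[gene_a]) + unname(expr2[gene_b])
  pmin(s1, s2)
}

#' Score every network link against one experiment
#'
#' @param net an [interaction_network()].
#' @param profile an [experiment_profile()].
#' @return data.frame of scoreable links (both genes carry a log-fold change)
#'   with columns `gene_a`, `interaction_type`, `gene_b`, `directed`,
#'   `link_id`, `logfc_a`, `logfc_b`, `link_score`, `interaction_score`
#'   (`NA` throughout when the profile has no raw expression). The number of
#'   links excluded for missing log-fold changes is attached as attribute
#'   `n_excluded` and reported with a message.
#' @export
score_links <- function(net, profile) {
  stopifnot(inherits(net, "interaction_network"))
  stopifnot(inherits(profile, "experiment_profile"))
  df <- net$links
  lfc <- profile$logfc
  keep <- df$gene_a %in% names(lfc) & df$gene_b %in% names(lfc)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(
      "score_links[", profile$experiment_id, "]: excluded ", n_excluded,
      " link(s) with missing log-fold changes"
    )
  }
  df <- df[keep, , drop = FALSE]
  df$logfc_a <- unname(lfc[df$gene_a])
  df$logfc_b <- unname(lfc[df$gene_b])
  df$link_score <- ifelse(
    df$interaction_type == "inhibition",
    df$logfc_a - df$logfc_b,
    df$logfc_a + df$logfc_b
  )
  df$interaction_score <- if (has_expression(profile)) {
    interaction_score(df$gene_a, df$gene_b, profile$expr1, profile$expr2)
  } else {
    rep(NA_real_, nrow(df))
  }
  rownames(df) <- NULL
  attr(df, "n_excluded") <- n_excluded
  df
}

# Indices of the top/bottom `m` entries of `score`, ties at either boundary
# broken by ascending `id` so selection is reproducible and order-invariant.
.tail_idx <- function(score, id, m) {
  if (m <= 0 || length(score) == 0) return(integer(0))
  m <- min(m, length(score))
  top <- order(-score, id)[seq_len(m)]
  bottom <- order(score, id)[seq_len(m)]
  union(top, bottom)
}

#' Filter an experiment's links to the extreme-quantile relevant set
#'
#' Applies up to three relevance criteria, each retaining the top and bottom
#' `ceiling(quantile_fraction * n)` of its own eligible population:
#' \describe{
#'   \item{link_score}{the most up- and most down-regulated links by
#'     LinkScore (population: scoreable links).}
#'   \item{interaction_score}{the links with extreme joint-expression scores
#'     (population: links with expression in both conditions); skipped
#'     silently when the profile carries log-fold changes only.}
#'   \item{gene_logfc}{links incident to a gene whose own log-fold change is
#'     in an extreme tail (population: network genes with a log-fold change).}
#' }
#' In `"union"` mode (default) a link is selected if any applied criterion
#' fires; in `"sequential"` mode it must pass every applied criterion.
#' Boundary ties are broken by lexicographic link (or gene) identity.
#'
#' @param net an [interaction_network()].
#' @param profile an [experiment_profile()].
#' @param quantile_fraction tail fraction per criterion, in (0, 0.5).
#'   Default `1e-4` (the 0.01\% threshold used on genome-scale networks);
#'   small simulated networks need a larger fraction such as `1e-2`.
#' @param mode `"union"` or `"sequential"`.
#' @param criteria criteria to attempt, subset of
#'   `c("link_score", "interaction_score", "gene_logfc")`.
#' @return a `link_selection`: list with `experiment_id`, `selected` (scored
#'   link data.frame plus a `criteria_passed` column, ordered by `link_id`),
#'   `quantile_fraction`, `criteria_used` (the criteria that actually ran),
#'   `selection_mode`, and `full_scores` (named vector link_id -> LinkScore
#'   over all scoreable links, kept for union-set correlations).
#' @export
select_links <- function(net, profile, quantile_fraction = 1e-4,
                         mode = c("union", "sequential"),
                         criteria = c(
                           "link_score", "interaction_score", "gene_logfc"
                         )) {
  mode <- match.arg(mode)
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (!(quantile_fraction > 0 && quantile_fraction < 0.5)) {
    stop("quantile_fraction must lie in (0, 0.5), got ", quantile_fraction)
  }
  scored <- score_links(net, profile)
  if (nrow(scored) < 2) {
    stop(
      "profile ", profile$experiment_id, " covers ", nrow(scored),
      " scoreable link(s); need at least 2"
    )
  }

  pass <- list()
  if ("link_score" %in% criteria) {
    m <- ceiling(quantile_fraction * nrow(scored))
    idx <- .tail_idx(scored$link_score, scored$link_id, m)
    pass$link_score <- scored$link_id[idx]
  }
  if ("interaction_score" %in% criteria && has_expression(profile)) {
    elig <- which(!is.na(scored$interaction_score))
    m <- ceiling(quantile_fraction * length(elig))
    idx <- elig[.tail_idx(
      scored$interaction_score[elig], scored$link_id[elig], m
    )]
    pass$interaction_score <- scored$link_id[idx]
  }
  if ("gene_logfc" %in% criteria) {
    genes <- intersect(net$genes, names(profile$logfc))
    g_lfc <- profile$logfc[genes]
    m <- ceiling(quantile_fraction * length(genes))
    tail_genes <- genes[.tail_idx(unname(g_lfc), genes, m)]
    hit <- scored$gene_a %in% tail_genes | scored$gene_b %in% tail_genes
    pass$gene_logfc <- scored$link_id[hit]
  }
  criteria_used <- names(pass)
  if (length(pass) == 0) stop("no applicable selection criteria")

  ids <- if (mode == "union") {
    Reduce(union, pass)
  } else {
    Reduce(intersect, pass)
  }
  selected <- scored[scored$link_id %in% ids, , drop = FALSE]
  selected$criteria_passed <- vapply(
    selected$link_id,
    function(id) {
      paste(criteria_used[vapply(pass, function(p) id %in% p, logical(1))],
        collapse = ","
      )
    },
    character(1)
  )
  selected <- selected[order(selected$link_id), , drop = FALSE]
  rownames(selected) <- NULL

  structure(
    list(
      experiment_id = profile$experiment_id,
      selected = selected,
      quantile_fraction = quantile_fraction,
      criteria_used = criteria_used,
      selection_mode = mode,
      full_scores = stats::setNames(scored$link_score, scored$link_id)
    ),
    class = "link_selection"
  )
}

#' @export
print.link_selection <- function(x, ...) {
  cat(
    "link_selection", x$experiment_id, "-", nrow(x$selected),
    "link(s) selected of", length(x$full_scores), "scoreable",
    sprintf(
      "(q = %g, mode = %s, criteria: %s)\n",
      x$quantile_fraction, x$selection_mode,
      paste(x$criteria_used, collapse = ", ")
    )
  )
  invisible(x)
}

#' Invert a selection's regulation signs
#'
#' Negates every LinkScore (and the member-gene log-fold changes, for
#' consistency) while keeping the selected link set identical. Inverting the
#' disease selection makes a signature-reversing drug correlate positively
#' with it. The experiment id gains an `"_inverted"` suffix; inverting twice
#' restores the original object exactly.
#'
#' @param sel a `link_selection`.
#' @return a `link_selection` with negated scores.
#' @export
invert_selection <- function(sel) {
  stopifnot(inherits(sel, "link_selection"))
  out <- sel
  out$experiment_id <- if (endsWith(sel$experiment_id, "_inverted")) {
    sub("_inverted$", "", sel$experiment_id)
  } else {
    paste0(sel$experiment_id, "_inverted")
  }
  for (col in c("link_score", "logfc_a", "logfc_b")) {
    out$selected[[col]] <- -out$selected[[col]]
  }
  out$full_scores <- -out$full_scores
  out
}

#' Write a link selection as annotated TSV
#'
#' Comment lines prefixed `#` record the experiment id, quantile fraction,
#' mode and criteria; then one row per selected link.
#'
#' @param sel a `link_selection`.
#' @param path output file.
#' @export
write_selection <- function(sel, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# experiment_id=", sel$experiment_id),
    paste0("# quantile_fraction=", format(sel$quantile_fraction)),
    paste0("# mode=", sel$selection_mode),
    paste0("# criteria_used=", paste(sel$criteria_used, collapse = ","))
  ), con)
  df <- sel$selected[, c(
    "gene_a", "interaction_type", "gene_b", "link_score",
    "interaction_score", "logfc_a", "logfc_b", "criteria_passed"
  )]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a link selection written by [write_selection()]
#'
#' @param path file path.
#' @return a `link_selection` (without `full_scores`, which the TSV does not
#'   carry).
#' @export
read_selection <- function(path) {
  header <- readLines(path, n = 10)
  header <- header[startsWith(header, "# ")]
  meta <- strsplit(sub("^# ", "", header), "=", fixed = TRUE)
  meta <- stats::setNames(
    vapply(meta, `[`, character(1), 2),
    vapply(meta, `[`, character(1), 1)
  )
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$directed <- FALSE
  df$link_id <- link_identity(df$gene_a, df$gene_b, df$interaction_type)
  structure(
    list(
      experiment_id = unname(meta[["experiment_id"]]),
      selected = df[order(df$link_id), , drop = FALSE],
      quantile_fraction = as.numeric(meta[["quantile_fraction"]]),
      criteria_used = strsplit(meta[["criteria_used"]], ",")[[1]],
      selection_mode = unname(meta[["mode"]]),
      full_scores = NULL
    ),
    class = "link_selection"
  )
}
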