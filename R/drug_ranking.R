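# Compare the inverted disease link selection against a drug library and
# rank drugs by link-set overlap (Jaccard) and LinkScore correlation
# (Pearson on the union of selected links).

#' Jaccard index of two link-identity sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty
#' (no evidence of overlap).
#'
#' @param set_a,set_b character vectors of link identities (duplicates
#'   ignored).
#' @return a number in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  n_union <- length(union(set_a, set_b))
  if (n_union == 0) return(0)
  length(intersect(set_a, set_b)) / n_union
}

#' Pearson correlation of LinkScores on the union of selected links
#'
#' The correlation is computed over the union of the two selections' link
#' sets - every link for which at least one of the two experiments put a
#' LinkScore past its threshold - with scores looked up in the full
#' (unfiltered) score maps so that union members selected by only one side
#' still contribute a pair. Links missing a score on either side are dropped
#' (count reported via attribute `n_dropped`).
#'
#' @param disease_sel the (inverted) disease `link_selection`.
#' @param drug_sel a drug `link_selection`.
#' @param disease_scores,drug_scores named vectors link_id -> LinkScore over
#'   all scoreable links; default to the `full_scores` stored in each
#'   selection.
#' @return Pearson r, with attributes `n_correlated` (paired links used) and
#'   `n_dropped`. `NA` when fewer than 3 pairs exist or either side has zero
#'   variance.
#' @export
pearson_on_union <- function(disease_sel, drug_sel,
                             disease_scores = disease_sel$full_scores,
                             drug_scores = drug_sel$full_scores) {
  if (is.null(disease_scores) || is.null(drug_scores)) {
    stop("full LinkScore maps are required for union-set correlation")
  }
  ids <- union(disease_sel$selected$link_id, drug_sel$selected$link_id)
  x <- disease_scores[ids]
  y <- drug_scores[ids]
  ok <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!ok)
  x <- x[ok]
  y <- y[ok]
  r <- if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    NA_real_
  } else {
    stats::cor(x, y, method = "pearson")
  }
  structure(r, n_correlated = length(x), n_dropped = n_dropped)
}

#' Compare one drug selection against the inverted disease selection
#'
#' @inheritParams pearson_on_union
#' @param sign_aware_jaccard when `TRUE`, the intersection counts only links
#'   whose drug LinkScore agrees in sign with the inverted disease LinkScore
#'   (direction-aware overlap); the union is unchanged. Off by default: the
#'   plain set-theoretic Jaccard.
#' @return one-row data.frame: `experiment_id`, `jaccard`, `pearson_r`,
#'   `r_squared`, `n_intersection`, `n_union`, `n_correlated`.
#' @export
compare_drug <- function(disease_sel, drug_sel,
                         disease_scores = disease_sel$full_scores,
                         drug_scores = drug_sel$full_scores,
                         sign_aware_jaccard = FALSE) {
  a <- disease_sel$selected$link_id
  b <- drug_sel$selected$link_id
  inter <- intersect(a, b)
  if (sign_aware_jaccard && length(inter) > 0) {
    sa <- disease_scores[inter]
    sb <- drug_scores[inter]
    inter <- inter[!is.na(sa) & !is.na(sb) & sign(sa) == sign(sb) & sa != 0]
  }
  n_union <- length(union(a, b))
  jac <- if (n_union == 0) 0 else length(inter) / n_union
  r <- pearson_on_union(disease_sel, drug_sel, disease_scores, drug_scores)
  data.frame(
    experiment_id = drug_sel$experiment_id,
    jaccard = jac,
    pearson_r = as.numeric(r),
    r_squared = as.numeric(r)^2,
    n_intersection = length(inter),
    n_union = n_union,
    n_correlated = attr(r, "n_correlated"),
    stringsAsFactors = FALSE
  )
}

#' Rank a drug library against an inverted disease signature
#'
#' For every drug experiment the link-set Jaccard index and the union-set
#' Pearson correlation against the inverted disease selection are computed,
#' and two ranking tables are returned: one sorted by Pearson r (drugs whose
#' correlation is undefined sort last, marked `NA`), one by Jaccard. Ties are
#' broken by experiment id, ascending.
#'
#' @param disease_sel the disease `link_selection`, already passed through
#'   [invert_selection()].
#' @param drug_selections list of drug `link_selection` objects.
#' @param sign_aware_jaccard see [compare_drug()].
#' @return list with elements `pearson` and `jaccard`, each a `drug_ranking`
#'   data.frame with a leading `rank` column.
#' @export
rank_drugs <- function(disease_sel, drug_selections,
                       sign_aware_jaccard = FALSE) {
  if (length(drug_selections) == 0) stop("empty drug library")
  rows <- do.call(rbind, lapply(
    drug_selections, compare_drug,
    disease_sel = disease_sel, sign_aware_jaccard = sign_aware_jaccard
  ))

  rank_by <- function(score) {
    ord <- order(-score, rows$experiment_id, na.last = TRUE)
    out <- rows[ord, , drop = FALSE]
    out <- cbind(rank = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    class(out) <- c("drug_ranking", "data.frame")
    out
  }
  pearson <- rank_by(rows$pearson_r)
  attr(pearson, "ranked_by") <- "pearson"
  jaccard <- rank_by(rows$jaccard)
  attr(jaccard, "ranked_by") <- "jaccard"
  list(pearson = pearson, jaccard = jaccard)
}

#' Write a drug ranking table as annotated TSV
#'
#' Mirrors the published ranking-table layout: rank, experiment id, score
#' (both signed r and r^2 for the Pearson table), with the ranking
#' parameters as `#` comment lines.
#'
#' @param ranking a `drug_ranking` from [rank_drugs()].
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  by <- attr(ranking, "ranked_by")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ranked_by=", by), con)
  cols <- if (identical(by, "pearson")) {
    c("rank", "experiment_id", "pearson_r", "r_squared", "n_correlated")
  } else {
    c("rank", "experiment_id", "jaccard", "n_intersection", "n_union")
  }
  utils::write.table(
    ranking[, cols],
    con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
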