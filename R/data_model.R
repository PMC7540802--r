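# ---- link identity ---------------------------------------------------------

#' Canonical identity string for a set of links
#'
#' Undirected links are identified by their unordered gene pair plus the
#' interaction type; directed links keep their source/target order. Two links
#' are the same link if and only if their identity strings are equal.
#'
#' @param gene_a,gene_b character vectors of gene identifiers.
#' @param interaction_type character vector in
#'   `c("activation", "inhibition", "unknown")`.
#' @param directed logical vector (recycled); `FALSE` canonicalizes the pair.
#' @return character vector of identity strings.
#' @export
link_identity <- function(gene_a, gene_b, interaction_type, directed = FALSE) {
  directed <- rep_len(directed, length(gene_a))
  swap <- !directed & gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  paste(a, interaction_type, b, sep = "|")
}

.valid_types <- c("activation", "inhibition", "unknown")

# Canonicalize a raw link data.frame: map type tokens, order undirected pairs,
# drop self-loops and duplicates (with counts reported via attributes).
.canonicalize_links <- function(links, strict = FALSE) {
  stopifnot(all(c("gene_a", "interaction_type", "gene_b") %in% names(links)))
  if (is.null(links$directed)) links$directed <- FALSE

  tok <- tolower(trimws(links$interaction_type))
  type <- rep("unknown", length(tok))
  type[tok %in% c("activation", "stimulation", "+")] <- "activation"
  type[tok %in% c("inhibition", "repression", "-")] <- "inhibition"
  unrecognized <- !(tok %in% c(
    "activation", "stimulation", "+",
    "inhibition", "repression", "-", "unknown"
  ))
  if (strict && any(unrecognized)) {
    stop(
      "unrecognized interaction type token(s): ",
      paste(unique(links$interaction_type[unrecognized]), collapse = ", ")
    )
  }
  links$interaction_type <- type

  swap <- !links$directed & links$gene_a > links$gene_b
  tmp <- links$gene_a[swap]
  links$gene_a[swap] <- links$gene_b[swap]
  links$gene_b[swap] <- tmp

  self <- links$gene_a == links$gene_b
  n_self <- sum(self)
  if (n_self > 0) {
    warning(n_self, " self-loop link(s) dropped")
    links <- links[!self, , drop = FALSE]
  }
  id <- link_identity(
    links$gene_a, links$gene_b,
    links$interaction_type, links$directed
  )
  dup <- duplicated(id)
  n_dup <- sum(dup)
  links <- links[!dup, , drop = FALSE]
  links$link_id <- id[!dup]
  links <- links[order(links$link_id), , drop = FALSE]
  rownames(links) <- NULL
  attr(links, "n_self_loops") <- n_self
  attr(links, "n_duplicates") <- n_dup
  links
}

# ---- InteractionNetwork ----------------------------------------------------

#' Construct a typed interaction network
#'
#' @param links data.frame with columns `gene_a`, `interaction_type`,
#'   `gene_b` and optionally `directed` (default `FALSE`). Self-loops are
#'   dropped with a warning; duplicate links (under [link_identity()]) are
#'   collapsed.
#' @param strict error on unrecognized interaction-type tokens instead of
#'   mapping them to `"unknown"`.
#' @return an `interaction_network`: list with `genes` (sorted character
#'   vector) and `links` (canonical data.frame with a `link_id` column).
#' @export
interaction_network <- function(links, strict = FALSE) {
  links <- .canonicalize_links(as.data.frame(links), strict = strict)
  net <- structure(
    list(
      genes = sort(unique(c(links$gene_a, links$gene_b))),
      links = links
    ),
    class = "interaction_network"
  )
  net
}

#' @export
print.interaction_network <- function(x, ...) {
  tab <- table(factor(x$links$interaction_type, levels = .valid_types))
  cat(
    "interaction_network:", length(x$genes), "genes,",
    nrow(x$links), "links",
    sprintf(
      "(%d activation, %d inhibition, %d unknown)\n",
      tab[["activation"]], tab[["inhibition"]], tab[["unknown"]]
    )
  )
  invisible(x)
}

#' Read a typed edge list
#'
#' Expects tab-separated lines `source <tab> interaction_type <tab> target`
#' (SIF-compatible ordering), with or without a header line. Type tokens
#' `activation`/`stimulation`/`+` map to activation,
#' `inhibition`/`repression`/`-` to inhibition, anything else to unknown
#' (or an error when `strict = TRUE`).
#'
#' @param path file path.
#' @param strict error on unrecognized type tokens.
#' @param directed treat links as directed source -> target.
#' @return an [interaction_network()].
#' @export
read_network <- function(path, strict = FALSE, directed = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty network file: ", path)
  if (grepl("^source\t", lines[1], ignore.case = TRUE)) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad) > 0) {
    stop(
      "network format error: expected 3 tab-separated columns at line ",
      bad[1], " of ", path
    )
  }
  links <- data.frame(
    gene_a = vapply(parts, `[[`, character(1), 1L),
    interaction_type = vapply(parts, `[[`, character(1), 2L),
    gene_b = vapply(parts, `[[`, character(1), 3L),
    directed = directed,
    stringsAsFactors = FALSE
  )
  net <- interaction_network(links, strict = strict)
  n_dropped <- attr(net$links, "n_self_loops") + attr(net$links, "n_duplicates")
  if (n_dropped > 0) {
    message(
      "read_network: dropped ", attr(net$links, "n_self_loops"),
      " self-loop(s) and ", attr(net$links, "n_duplicates"),
      " duplicate link(s)"
    )
  }
  net
}

#' Write a network as a tab-separated edge list
#'
#' @param net an [interaction_network()].
#' @param path output file.
#' @export
write_network <- function(net, path) {
  df <- net$links[, c("gene_a", "interaction_type", "gene_b")]
  names(df) <- c("source", "interaction_type", "target")
  utils::write.table(
    df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

# ---- ExperimentProfile -----------------------------------------------------

#' Construct an experiment's expression profile
#'
#' Holds per-gene expression for two conditions on a log-like scale and the
#' derived log-fold changes (condition 2 minus condition 1). When only
#' log-fold changes are available (the usual shape of a drug-perturbation
#' library entry), the expression maps stay empty and downstream filtering
#' silently skips the joint-expression (InteractionScore) criterion.
#'
#' @param experiment_id identifier, conventionally
#'   `drug_concentration_cellline` (e.g. `"josamycin_4.8e-06_MCF7"`).
#' @param expr1,expr2 named numeric vectors (gene -> expression) or `NULL`.
#' @param logfc named numeric vector; computed as `expr2 - expr1` over the
#'   genes present in both conditions when omitted.
#' @return an `experiment_profile` object.
#' @export
experiment_profile <- function(experiment_id, expr1 = NULL, expr2 = NULL,
                               logfc = NULL) {
  expr1 <- if (is.null(expr1)) stats::setNames(numeric(0), character(0)) else expr1
  expr2 <- if (is.null(expr2)) stats::setNames(numeric(0), character(0)) else expr2
  if (is.null(logfc)) {
    shared <- intersect(names(expr1), names(expr2))
    logfc <- stats::setNames(expr2[shared] - expr1[shared], shared)
  }
  if (anyDuplicated(names(logfc))) stop("duplicate gene in logfc map")
  structure(
    list(
      experiment_id = experiment_id,
      expr1 = expr1, expr2 = expr2, logfc = logfc
    ),
    class = "experiment_profile"
  )
}

#' @export
print.experiment_profile <- function(x, ...) {
  cat(
    "experiment_profile", x$experiment_id, "-", length(x$logfc),
    "genes with logfc;", length(x$expr1), "with raw expression\n"
  )
  invisible(x)
}

#' Whether a profile carries raw two-condition expression
#'
#' @param profile an [experiment_profile()].
#' @return logical.
#' @export
has_expression <- function(profile) {
  length(profile$expr1) > 0 && length(profile$expr2) > 0
}

#' Read an expression profile table
#'
#' Tab-separated with a header: either `gene`, `expr_cond1`, `expr_cond2`
#' (log-fold changes computed as cond2 - cond1) or `gene`, `logfc`.
#'
#' @param path file path.
#' @param experiment_id id for the profile; defaults to the file's base name.
#' @return an [experiment_profile()].
#' @export
read_profile <- function(path, experiment_id = NULL) {
  if (is.null(experiment_id)) {
    experiment_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"gene" %in% names(df)) stop("profile file lacks a 'gene' column: ", path)
  if (anyDuplicated(df$gene)) {
    stop(
      "duplicate gene row(s) in ", path, ": ",
      paste(unique(df$gene[duplicated(df$gene)]), collapse = ", ")
    )
  }
  num_cols <- setdiff(names(df), "gene")
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
      stop(
        "non-numeric value in column '", cc, "' at data line ", bad,
        " of ", path
      )
    }
  }
  if (all(c("expr_cond1", "expr_cond2") %in% names(df))) {
    experiment_profile(
      experiment_id,
      expr1 = stats::setNames(df$expr_cond1, df$gene),
      expr2 = stats::setNames(df$expr_cond2, df$gene)
    )
  } else if ("logfc" %in% names(df)) {
    experiment_profile(
      experiment_id,
      logfc = stats::setNames(df$logfc, df$gene)
    )
  } else {
    stop(
      "profile file needs columns gene + expr_cond1 + expr_cond2, ",
      "or gene + logfc: ", path
    )
  }
}

#' Write an expression profile table
#'
#' @param profile an [experiment_profile()].
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  if (has_expression(profile)) {
    genes <- sort(intersect(names(profile$expr1), names(profile$expr2)))
    df <- data.frame(
      gene = genes,
      expr_cond1 = unname(profile$expr1[genes]),
      expr_cond2 = unname(profile$expr2[genes])
    )
  } else {
    genes <- sort(names(profile$logfc))
    df <- data.frame(gene = genes, logfc = unname(profile$logfc[genes]))
  }
  utils::write.table(
    df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

# ---- CountTable and RPKM ---------------------------------------------------

#' Construct a read-count table
#'
#' @param counts numeric matrix, genes x samples, non-negative integers.
#' @param gene_length_bp named numeric vector of positive transcript lengths
#'   in base pairs; must cover the count matrix rows.
#' @param library_size named numeric vector of total mapped reads per sample;
#'   defaults to the column sums of `counts`. Must be positive.
#' @return a `count_table` object.
#' @export
count_table <- function(counts, gene_length_bp, library_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  missing_len <- setdiff(rownames(counts), names(gene_length_bp))
  if (length(missing_len) > 0) {
    stop("no gene length for: ", paste(missing_len, collapse = ", "))
  }
  structure(
    list(
      counts = counts,
      gene_length_bp = gene_length_bp,
      library_size = library_size
    ),
    class = "count_table"
  )
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `count * 1e9 / (gene_length_bp * library_size)`: linear in the count,
#' inversely proportional to transcript length and to sequencing depth.
#'
#' @param tab a [count_table()].
#' @param gene gene id(s); default all genes.
#' @param sample sample id(s); default all samples.
#' @return numeric matrix (or vector/scalar when dropped) of RPKM values.
#' @export
rpkm <- function(tab, gene = rownames(tab$counts),
                 sample = colnames(tab$counts)) {
  stopifnot(inherits(tab, "count_table"))
  if (!all(gene %in% rownames(tab$counts))) {
    stop("unknown gene: ", paste(setdiff(gene, rownames(tab$counts)), collapse = ", "))
  }
  if (!all(sample %in% colnames(tab$counts))) {
    stop("unknown sample: ", paste(setdiff(sample, colnames(tab$counts)), collapse = ", "))
  }
  cts <- tab$counts[gene, sample, drop = FALSE]
  out <- cts * 1e9 /
    outer(tab$gene_length_bp[gene], tab$library_size[sample])
  drop(out)
}

#' Read a count matrix plus gene-length file
#'
#' @param counts_path TSV gene x sample matrix (header = sample ids, first
#'   column = gene ids).
#' @param lengths_path 2-column TSV `gene`, `length_bp`.
#' @param library_size optional named vector; defaults to column sums.
#' @return a [count_table()].
#' @export
read_counts <- function(counts_path, lengths_path, library_size = NULL) {
  cts <- as.matrix(utils::read.delim(counts_path, row.names = 1))
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  count_table(cts, stats::setNames(len[[2]], len[[1]]), library_size)
}

#' Shifted log2 transform
#'
#' @param x non-negative numeric vector (e.g. RPKM values).
#' @param pseudocount positive shift added before the log, default 1.
#' @return `log2(x + pseudocount)`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  if (any(x < 0, na.rm = TRUE)) stop("log_transform requires non-negative input")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2(x + pseudocount)
}
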