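# End-to-end orchestration: disease selection, inversion, per-drug selection,
# ranking, differential-network views, and a run manifest sufficient to
# reproduce the analysis.

#' In-memory repositioning screen
#'
#' The computational core of [run_repositioning()]: filters the disease
#' experiment's links to its relevant set, inverts it, filters every drug
#' experiment's links, and ranks the drugs by union-set Pearson correlation
#' and by link-set Jaccard overlap against the inverted disease signature.
#'
#' @param net an [interaction_network()].
#' @param disease_profile the disease [experiment_profile()].
#' @param drug_profiles named list of drug [experiment_profile()]s.
#' @param quantile_fraction tail fraction for [select_links()].
#' @param mode `"union"` or `"sequential"` criterion combination.
#' @param sign_aware_jaccard see [compare_drug()].
#' @return list with `disease_selection` (as selected), `inverted` (the
#'   inverted disease selection), `drug_selections` (named list) and
#'   `rankings` (list of `pearson` and `jaccard` tables from [rank_drugs()]).
#' @export
screen_drugs <- function(net, disease_profile, drug_profiles,
                         quantile_fraction = 1e-4,
                         mode = c("union", "sequential"),
                         sign_aware_jaccard = FALSE) {
  mode <- match.arg(mode)
  disease_sel <- select_links(
    net, disease_profile,
    quantile_fraction = quantile_fraction, mode = mode
  )
  inverted <- invert_selection(disease_sel)
  drug_sels <- lapply(
    drug_profiles, select_links,
    net = net, quantile_fraction = quantile_fraction, mode = mode
  )
  rankings <- rank_drugs(
    inverted, drug_sels,
    sign_aware_jaccard = sign_aware_jaccard
  )
  list(
    disease_selection = disease_sel,
    inverted = inverted,
    drug_selections = drug_sels,
    rankings = rankings
  )
}

#' Pipeline configuration
#'
#' @param network path to the edge-list TSV ([read_network()]).
#' @param disease path to the disease profile TSV ([read_profile()]).
#' @param drugs_dir directory of drug profile TSVs (one per experiment).
#' @param out_dir output directory (created if needed).
#' @param quantile_fraction tail fraction for [select_links()].
#' @param mode criterion combination, `"union"` or `"sequential"`.
#' @param top_k links in the differential-network views (default 47).
#' @param sign_aware_jaccard direction-aware overlap, see [compare_drug()].
#' @param strict error on unrecognized interaction-type tokens.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(network, disease, drugs_dir, out_dir,
                            quantile_fraction = 1e-4,
                            mode = "union", top_k = 47,
                            sign_aware_jaccard = FALSE, strict = FALSE) {
  structure(
    list(
      network = network, disease = disease, drugs_dir = drugs_dir,
      out_dir = out_dir, quantile_fraction = quantile_fraction,
      mode = mode, top_k = top_k,
      sign_aware_jaccard = sign_aware_jaccard, strict = strict
    ),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full repositioning pipeline on files
#'
#' Reads the network, disease profile and drug library, runs
#' [screen_drugs()], writes both ranking tables, the disease and
#' head-to-head drug differential-network views (GraphML + attribute TSVs)
#' and a JSON manifest recording every parameter, input checksum and output
#' file. A failing stage aborts with the stage name and removes partial
#' outputs. Fully deterministic: identical inputs and config give
#' byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_repositioning <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  out <- function(name) {
    path <- file.path(cfg$out_dir, name)
    outputs <<- c(outputs, path)
    path
  }
  on_error_cleanup <- function(e) {
    unlink(outputs)
    stop(e)
  }

  tryCatch({
    net <- .stage("read_network", read_network(cfg$network, strict = cfg$strict))
    disease <- .stage("read_disease_profile", read_profile(cfg$disease, "disease"))
    drug_files <- sort(list.files(cfg$drugs_dir, "\\.tsv$", full.names = TRUE))
    if (length(drug_files) == 0) {
      stop("stage 'read_drug_library' failed: no .tsv profiles in ", cfg$drugs_dir)
    }
    drugs <- .stage(
      "read_drug_library",
      stats::setNames(
        lapply(drug_files, read_profile),
        sub("\\.tsv$", "", basename(drug_files))
      )
    )

    res <- .stage("screen_drugs", screen_drugs(
      net, disease, drugs,
      quantile_fraction = cfg$quantile_fraction, mode = cfg$mode,
      sign_aware_jaccard = cfg$sign_aware_jaccard
    ))

    .stage("write_rankings", {
      write_ranking(res$rankings$pearson, out("ranking_pearson.tsv"))
      write_ranking(res$rankings$jaccard, out("ranking_jaccard.tsv"))
      write_selection(res$disease_selection, out("disease_selection.tsv"))
    })

    top_drug <- res$rankings$pearson$experiment_id[1]
    views <- .stage("differential_network", {
      scored <- score_links(net, disease)
      node_vals <- if (has_expression(disease)) {
        disease$expr2[sort(unique(c(scored$gene_a, scored$gene_b)))]
      } else {
        NULL
      }
      k <- min(cfg$top_k, nrow(scored))
      disease_view <- build_view(scored, node_values = node_vals, k = k)
      export_view(disease_view, out("disease_view"))
      outputs <<- c(
        outputs,
        file.path(cfg$out_dir, c("disease_view_nodes.tsv", "disease_view_edges.tsv"))
      )
      drug_view <- head_to_head_view(disease_view, drugs[[top_drug]])
      export_view(drug_view, out("drug_view"))
      outputs <<- c(
        outputs,
        file.path(cfg$out_dir, c("drug_view_nodes.tsv", "drug_view_edges.tsv"))
      )
      list(k = k, top_drug = top_drug)
    })

    manifest <- list(
      tool = "linkscreen",
      version = as.character(utils::packageVersion("linkscreen")),
      parameters = list(
        quantile_fraction = cfg$quantile_fraction,
        mode = cfg$mode,
        top_k = views$k,
        sign_aware_jaccard = cfg$sign_aware_jaccard,
        strict = cfg$strict
      ),
      inputs = list(
        network = list(
          path = cfg$network,
          md5 = unname(tools::md5sum(cfg$network))
        ),
        disease = list(
          path = cfg$disease,
          md5 = unname(tools::md5sum(cfg$disease))
        ),
        drugs = lapply(drug_files, function(f) {
          list(path = f, md5 = unname(tools::md5sum(f)))
        })
      ),
      stages = list(
        links_in_network = nrow(net$links),
        links_scoreable = length(res$disease_selection$full_scores),
        links_selected_disease = nrow(res$disease_selection$selected),
        criteria_used = res$disease_selection$criteria_used,
        n_drugs = length(drugs),
        head_to_head_drug = views$top_drug
      ),
      outputs = basename(outputs)
    )
    manifest_path <- out("manifest.json")
    jsonlite::write_json(
      manifest, manifest_path,
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    invisible(manifest)
  }, error = on_error_cleanup)
}
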