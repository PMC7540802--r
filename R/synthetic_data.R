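# Synthetic inputs with the statistical structure the pipeline assumes: a
# sparse typed interaction network with gene modules, a disease perturbation
# that up-regulates some modules and down-regulates another, and a drug
# library containing one planted signature reverser among noise drugs.
# Stands in for the protein-interaction / drug-perturbation compendia the
# method is normally run on, and supplies ground truth for recovery tests.

# Independent, reproducible RNG stream per generation stage.
.stage_seed <- function(seed, tag) {
  (as.integer(seed) %% 1000000L) * 1009L + sum(utf8ToInt(tag)) %% 1009L
}

#' Simulation configuration
#'
#' Defaults describe a small but structured study: 500 genes carrying three
#' 30-gene modules (two up-regulated by disease, one down-regulated,
#' mirroring an actin-like and cytokine-like induction plus a CD34-like
#' loss), a 2000-link network in which module genes are preferentially
#' interconnected, a 2 log2-unit disease effect over 0.3 log2 units of
#' noise, and a 50-experiment drug library whose planted reverser undoes
#' 90\% of the disease signature. Baseline expression 1.68 matches the
#' normalized-expression scale the method is typically visualized on.
#'
#' @param n_genes,n_links network size.
#' @param inhibition_fraction probability a link is inhibitory.
#' @param n_modules,module_size gene-module structure; with two or more
#'   modules the second is the down-regulated one, the rest are up-regulated.
#' @param disease_effect mean absolute log2 fold change of perturbed genes.
#' @param noise_sd log2-scale expression noise (s.d.).
#' @param n_drugs library size including the planted reverser.
#' @param reverser_fidelity fraction of the disease log-fold changes the
#'   planted drug reverses, in `[0, 1]`.
#' @param baseline_expression mean control expression (log-like scale).
#' @param seed integer master seed; every generator derives its own stream
#'   from it, so stages are independently reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, n_links = 2000,
                       inhibition_fraction = 0.2,
                       n_modules = 3, module_size = 30,
                       disease_effect = 2, noise_sd = 0.3,
                       n_drugs = 50, reverser_fidelity = 0.9,
                       baseline_expression = 1.68, seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_links = n_links,
    inhibition_fraction = inhibition_fraction,
    n_modules = n_modules, module_size = module_size,
    disease_effect = disease_effect, noise_sd = noise_sd,
    n_drugs = n_drugs, reverser_fidelity = reverser_fidelity,
    baseline_expression = baseline_expression, seed = seed
  )
  stopifnot(
    n_genes > 0, n_links > 0, n_modules > 0, module_size > 0, n_drugs > 0,
    noise_sd > 0, disease_effect >= 0,
    inhibition_fraction >= 0, inhibition_fraction <= 1,
    reverser_fidelity >= 0, reverser_fidelity <= 1
  )
  if (n_modules * module_size > n_genes) {
    stop("n_modules * module_size exceeds n_genes")
  }
  structure(cfg, class = "sim_config")
}

# Gene names and module assignment are a pure function of the config.
.sim_genes <- function(cfg) {
  sprintf("G%05d", seq_len(cfg$n_genes))
}

.sim_modules <- function(cfg) {
  mod <- rep(0L, cfg$n_genes)
  mod[seq_len(cfg$n_modules * cfg$module_size)] <-
    rep(seq_len(cfg$n_modules), each = cfg$module_size)
  stats::setNames(mod, .sim_genes(cfg))
}

#' Simulate a typed interaction network with module structure
#'
#' Draws exactly `n_links` distinct gene pairs, with pairs inside the same
#' module weighted 20x more likely than background pairs, then labels each
#' link inhibition with probability `inhibition_fraction` (activation
#' otherwise). Bit-reproducible given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return an [interaction_network()] with a `modules` attribute
#'   (gene -> module index, 0 = background).
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  if (cfg$n_links > n * (n - 1) / 2) {
    stop(
      "n_links = ", cfg$n_links, " exceeds the ", n * (n - 1) / 2,
      " possible pairs of ", n, " genes"
    )
  }
  genes <- .sim_genes(cfg)
  modules <- .sim_modules(cfg)

  set.seed(.stage_seed(cfg$seed, "network"))
  pair_idx <- which(upper.tri(matrix(0, n, n)))
  i <- ((pair_idx - 1) %% n) + 1 # row (smaller index)
  j <- ((pair_idx - 1) %/% n) + 1 # column
  w <- ifelse(modules[i] > 0 & modules[i] == modules[j], 20, 1)
  take <- sample(length(pair_idx), cfg$n_links, prob = w)
  type <- ifelse(
    stats::runif(cfg$n_links) < cfg$inhibition_fraction,
    "inhibition", "activation"
  )
  net <- interaction_network(data.frame(
    gene_a = genes[i[take]],
    interaction_type = type,
    gene_b = genes[j[take]],
    stringsAsFactors = FALSE
  ))
  attr(net, "modules") <- modules
  net
}

#' Simulate the disease perturbation
#'
#' Control expression is Normal(`baseline_expression`, `noise_sd`) per gene
#' on the log scale, floored at 0. The perturbed condition adds
#' `+disease_effect` to genes of the up-modules and `-disease_effect` to the
#' down-module (module 2 when there are at least two modules), plus fresh
#' Normal(0, `noise_sd`) noise, again floored at 0.
#'
#' @param cfg a [sim_config()].
#' @param net the network from [simulate_network()] (supplies the module
#'   assignment; falls back to the config's deterministic assignment).
#' @return list with `profile` (an [experiment_profile()] with id
#'   `"disease"`) and `truth` (list: `perturbed_up`, `perturbed_down`
#'   gene sets, `reverser_id` still `NA`).
#' @export
simulate_disease <- function(cfg, net = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  modules <- if (!is.null(net)) attr(net, "modules") else .sim_modules(cfg)
  genes <- names(modules)
  down_module <- if (cfg$n_modules >= 2) 2L else 0L
  up <- genes[modules > 0 & modules != down_module]
  down <- if (down_module > 0) genes[modules == down_module] else character(0)

  set.seed(.stage_seed(cfg$seed, "disease"))
  expr1 <- pmax(
    stats::rnorm(length(genes), cfg$baseline_expression, cfg$noise_sd), 0
  )
  effect <- numeric(length(genes))
  effect[genes %in% up] <- cfg$disease_effect
  effect[genes %in% down] <- -cfg$disease_effect
  expr2 <- pmax(expr1 + effect + stats::rnorm(length(genes), 0, cfg$noise_sd), 0)

  profile <- experiment_profile(
    "disease",
    expr1 = stats::setNames(expr1, genes),
    expr2 = stats::setNames(expr2, genes)
  )
  list(
    profile = profile,
    truth = list(
      perturbed_up = up, perturbed_down = down, reverser_id = NA_character_
    )
  )
}

#' Simulate a drug-perturbation library with one planted reverser
#'
#' Generates `n_drugs - 1` noise drugs whose log-fold changes are pure
#' Normal(0, `noise_sd`) noise, plus one planted reverser whose log-fold
#' changes equal `-reverser_fidelity` times the disease log-fold changes
#' plus the same noise. The reverser's position in the library is
#' randomized. Experiment ids follow the drug_concentration_cellline
#' convention of perturbation compendia.
#'
#' @param cfg a [sim_config()].
#' @param disease_profile the disease [experiment_profile()].
#' @param truth ground-truth list from [simulate_disease()].
#' @return list with `profiles` (named list of [experiment_profile()],
#'   log-fold changes only) and `truth` with `reverser_id` filled in.
#' @export
simulate_drug_library <- function(cfg, disease_profile, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_drugs < 2) stop("n_drugs must be at least 2")
  genes <- names(disease_profile$logfc)
  dz <- unname(disease_profile$logfc)

  set.seed(.stage_seed(cfg$seed, "drugs"))
  reverser_pos <- sample.int(cfg$n_drugs, 1)
  cells <- c("MCF7", "HL60", "PC3")
  profiles <- vector("list", cfg$n_drugs)
  ids <- character(cfg$n_drugs)
  for (i in seq_len(cfg$n_drugs)) {
    conc <- sprintf("%.2e", stats::runif(1, 1e-7, 2e-5))
    ids[i] <- sprintf("drug%03d_%s_%s", i, conc, cells[(i - 1) %% 3 + 1])
    noise <- stats::rnorm(length(genes), 0, cfg$noise_sd)
    lfc <- if (i == reverser_pos) {
      -cfg$reverser_fidelity * dz + noise
    } else {
      noise
    }
    profiles[[i]] <- experiment_profile(
      ids[i],
      logfc = stats::setNames(lfc, genes)
    )
  }
  names(profiles) <- ids
  truth$reverser_id <- ids[reverser_pos]
  list(profiles = profiles, truth = truth)
}

#' Simulate a full study and write it to disk
#'
#' Writes `network.tsv`, `disease.tsv`, one `drugs/<experiment_id>.tsv`
#' per drug, and `ground_truth.tsv` into `dir` - a complete file-based
#' input set for [run_repositioning()].
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the ground-truth list.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(file.path(dir, "drugs"), recursive = TRUE, showWarnings = FALSE)
  net <- simulate_network(cfg)
  dz <- simulate_disease(cfg, net)
  lib <- simulate_drug_library(cfg, dz$profile, dz$truth)

  write_network(net, file.path(dir, "network.tsv"))
  write_profile(dz$profile, file.path(dir, "disease.tsv"))
  for (p in lib$profiles) {
    write_profile(p, file.path(dir, "drugs", paste0(p$experiment_id, ".tsv")))
  }
  truth <- lib$truth
  gt <- data.frame(
    gene = c(truth$perturbed_up, truth$perturbed_down, truth$reverser_id),
    role = c(
      rep("perturbed_up", length(truth$perturbed_up)),
      rep("perturbed_down", length(truth$perturbed_down)),
      "reverser_experiment"
    )
  )
  utils::write.table(
    gt, file.path(dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(truth)
}
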