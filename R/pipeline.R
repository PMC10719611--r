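## End-to-end orchestration: simulate -> tiger -> sensitivity -> infer ->
## survival -> asr, driven by one config with seeded reproducibility and
## a JSON manifest of parameters, outputs and checksums.

.default_run_config <- function() {
  list(seed = 1L,
       out_dir = NULL,
       stages = c("simulate", "tiger", "sensitivity", "infer",
                  "survival", "asr"),
       sim = list(),       # sim_config() overrides
       inputs = NULL,      # alternatively: loci_dir, tree, traits, survival
       n_bootstrap = 100L,
       tolerance_cutoff = 0.10,
       label_style = "ending_bin",
       write_cumulative = FALSE,
       mcmc = NULL)        # mcmc_settings() overrides; NULL = marginal only
}

#' Validate and normalize a pipeline run configuration
#'
#' @param config list (or path to a YAML file) overriding the defaults;
#'   exactly one of a `sim` block or an `inputs` block (paths `loci_dir`,
#'   `tree`, `traits`, `survival`) drives the run.
#' @return normalized config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_run_config(), config)
  if (!is.null(cfg$inputs) && length(cfg$sim))
    stop("provide either an 'inputs' block or a 'sim' block, not both")
  if (!is.null(cfg$inputs)) {
    for (p in unlist(cfg$inputs))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  bad <- setdiff(cfg$stages, .default_run_config()$stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  cfg
}

.stage_dir <- function(out_dir, stage) {
  d <- file.path(out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the analysis pipeline
#'
#' Executes the toggled stages in order, writing per-stage outputs under
#' `out_dir` and a `manifest.json` recording the seed, stage parameters
#' and md5 checksums of every written file. Reruns with the same config
#' are byte-identical for the deterministic stages and identical given
#' `(seed, settings)` for the MCMC stage.
#'
#' @param config see [run_config()].
#' @param out_dir output directory (defaults to `config$out_dir` or a
#'   temporary directory).
#' @return (invisibly) a list with the per-stage in-memory results and
#'   the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- run_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("phylotox_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "phylotox",
                   version = as.character(utils::packageVersion("phylotox")),
                   seed = cfg$seed, stages = list())
  res <- list()

  ## ---- inputs: simulate or load -------------------------------------
  if ("simulate" %in% cfg$stages) {
    sc <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                cfg$sim))
    d <- .stage_dir(out_dir, "simulate")
    species_tree <- sim_yule_tree(sc$n_taxa, sc$birth_rate, seed = sc$seed)
    loci <- sim_locus_collection(species_tree, sc)
    trait <- sim_binary_trait(species_tree, sc$r01, sc$r10, sc$root_dist,
                              seed = sc$seed + 1L)
    surv <- do.call(rbind, lapply(species_tree$tip.label, function(sp) {
      tol <- trait$tip_states[sp] == "tolerant"
      sim_survival(sp, sc$p0, if (tol) 0 else sc$beta, sc$n_vials,
                   sc$larvae_per_vial, sc$dose,
                   seed = sc$seed + 100L + match(sp, species_tree$tip.label))
    }))
    write_newick(species_tree, file.path(d, "species_tree.nwk"))
    for (id in names(loci)) {
      write_fasta(loci[[id]]$alignment, file.path(d, paste0(id, ".fasta")))
      write_newick(loci[[id]]$tree, file.path(d, paste0(id, ".nwk")))
    }
    tdf <- data.frame(species = names(trait$tip_states),
                      state = unname(trait$tip_states))
    write.table(tdf, file.path(d, "traits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(surv, file.path(d, "survival.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$simulate <- list(species_tree = species_tree, loci = loci,
                         trait = trait, survival = surv)
    manifest$stages$simulate <- list(n_taxa = sc$n_taxa, n_loci = sc$n_loci,
                                     sites_per_locus = sc$sites_per_locus,
                                     discordance_prob = sc$discordance_prob)
    .log_stage("simulate", sc$n_loci, " loci on ", sc$n_taxa, " taxa")
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    loci <- NULL
    if (!is.null(inp$loci_dir)) {
      ff <- sort(list.files(inp$loci_dir, "\\.(fa|fasta)$", full.names = TRUE))
      loci <- lapply(ff, function(f) list(alignment = read_fasta(f)))
      names(loci) <- sub("\\.(fa|fasta)$", "", basename(ff))
    }
    res$simulate <- list(
      species_tree = if (!is.null(inp$tree)) read_newick(inp$tree),
      loci = loci,
      trait = if (!is.null(inp$traits))
        list(tip_states = read_trait_table(inp$traits)),
      survival = if (!is.null(inp$survival))
        read_survival_table(inp$survival))
  }
  loci <- res$simulate$loci

  ## ---- tiger: per-locus rate scoring and binning --------------------
  if ("tiger" %in% cfg$stages) {
    if (is.null(loci)) stop("tiger stage needs loci from simulate/inputs")
    d <- .stage_dir(out_dir, "tiger")
    for (id in names(loci)) {
      tab <- tiger_table(loci[[id]]$alignment)
      loci[[id]]$rates <- tab$score
      loci[[id]]$bins <- tab$bin
      write.table(tab, file.path(d, paste0(id, "_rates.tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (isTRUE(cfg$write_cumulative)) {
        cum <- cumulative_alignments(loci[[id]]$alignment, tab$bin)
        for (k in seq_along(cum))
          write_fasta(cum[[k]],
                      file.path(d, sprintf("%s_bins2-%d.fasta", id, k + 2L)))
      }
    }
    res$tiger <- loci
    manifest$stages$tiger <- list(n_loci = length(loci), n_bins = 10L)
    .log_stage("tiger", "scored ", length(loci), " loci")
  }

  ## ---- sensitivity: ranking, inclusion sets, 64 jobs, grids ---------
  if ("sensitivity" %in% cfg$stages) {
    if (is.null(res$tiger)) stop("sensitivity stage needs tiger output")
    loci <- res$tiger
    d <- .stage_dir(out_dir, "sensitivity")
    retained <- filter_loci_all_bins(lapply(loci, `[[`, "bins"))
    if (length(retained) < 8L)
      stop("fewer than 8 loci have sites in every bin; cannot build ",
           "8 inclusion sets")
    ## one tree per locus from its all-variant-sites alignment
    locus_trees <- lapply(loci[retained], function(l) {
      va <- cumulative_alignments(l$alignment, l$bins)[[8L]]
      neighbor_joining(jc_distance(va))
    })
    D <- rf_matrix(locus_trees)
    emb <- classical_mds(D, k = 2L)
    cd <- centroid_distances(emb)
    ranking <- retained[order(cd, retained)]
    write.table(D, file.path(d, "tree_distances.tsv"), sep = "\t",
                quote = FALSE)
    write.table(data.frame(locus = rownames(emb), emb,
                           centroid_distance = cd),
                file.path(d, "embedding.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(ranking, file.path(d, "locus_ranking.tsv"))
    jobs <- build_sensitivity_sets(loci, ranking,
                                   label_style = cfg$label_style)
    job_trees <- lapply(jobs, function(j)
      bootstrap_support(j$alignment, cfg$n_bootstrap,
                        seed = cfg$seed + 1000L))
    reference <- job_trees[[length(job_trees)]] # maximal job
    grids <- support_grid(reference, job_trees,
                          vapply(jobs, `[[`, 1L, "bin_subset"),
                          vapply(jobs, `[[`, 1L, "inclusion_set"))
    for (i in seq_along(grids))
      write.table(grids[[i]],
                  file.path(d, sprintf("support_grid_clade%02d.tsv", i)),
                  sep = "\t", quote = FALSE)
    jm <- data.frame(job = names(jobs),
                     bin_subset = vapply(jobs, `[[`, 1L, "bin_subset"),
                     inclusion_set = vapply(jobs, `[[`, 1L, "inclusion_set"),
                     label = vapply(jobs, `[[`, "", "label"),
                     n_loci = lengths(lapply(jobs, `[[`, "loci")),
                     n_sites = vapply(jobs, function(j) ncol(j$alignment), 0L))
    write.table(jm, file.path(d, "jobs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$sensitivity <- list(retained = retained, ranking = ranking,
                            distances = D, embedding = emb, jobs = jobs,
                            job_trees = job_trees, grids = grids)
    manifest$stages$sensitivity <-
      list(n_retained = length(retained), n_jobs = length(jobs),
           jobs = names(jobs), n_bootstrap = cfg$n_bootstrap)
    .log_stage("sensitivity", length(retained), " retained loci, ",
               length(jobs), " jobs")
  }

  ## ---- infer: gene trees and quartet species tree -------------------
  if ("infer" %in% cfg$stages) {
    if (is.null(loci)) stop("infer stage needs loci")
    d <- .stage_dir(out_dir, "infer")
    gene_trees <- lapply(loci, function(l)
      bootstrap_support(l$alignment, cfg$n_bootstrap,
                        seed = cfg$seed + 2000L))
    for (id in names(gene_trees))
      write_newick(gene_trees[[id]], file.path(d, paste0(id, "_nj.nwk")))
    ntax <- length(gene_trees[[1L]]$tip.label)
    sp_tree <- if (ntax <= 9L) exact_quartet_species_tree(gene_trees)
               else greedy_quartet_species_tree(gene_trees)
    write_newick(sp_tree, file.path(d, "species_tree_quartet.nwk"))
    res$infer <- list(gene_trees = gene_trees, species_tree = sp_tree)
    manifest$stages$infer <-
      list(n_gene_trees = length(gene_trees),
           quartet_score = attr(sp_tree, "quartet_score"))
    .log_stage("infer", "species tree from ", length(gene_trees),
               " gene trees (quartet score ",
               attr(sp_tree, "quartet_score"), ")")
  }

  ## ---- survival: per-species assay summary --------------------------
  if ("survival" %in% cfg$stages) {
    surv <- res$simulate$survival
    if (is.null(surv)) stop("survival stage needs a survival table")
    d <- .stage_dir(out_dir, "survival")
    summ <- summarize_assay(surv, cutoff = cfg$tolerance_cutoff)
    write.table(summ, file.path(d, "assay_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$survival <- summ
    manifest$stages$survival <-
      list(n_species = nrow(summ),
           n_tolerant = sum(summ$call == "A"))
    .log_stage("survival", nrow(summ), " species, ",
               sum(summ$call == "A"), " tolerant")
  }

  ## ---- asr: reconstruction on the pruned tree -----------------------
  if ("asr" %in% cfg$stages) {
    traits <- res$simulate$trait$tip_states
    tree <- if (!is.null(res$infer)) res$infer$species_tree
            else res$simulate$species_tree
    if (is.null(traits) || is.null(tree))
      stop("asr stage needs a tree and a trait table")
    d <- .stage_dir(out_dir, "asr")
    if (is.null(tree$edge.length) || !ape::is.rooted(tree))
      tree <- res$simulate$species_tree # quartet tree has no usable lengths
    pruned <- prune_to_scored(tree, traits)
    r_hat <- mle_rate(pruned, traits)
    marg <- marginal_asr(pruned, traits, as.numeric(r_hat))
    fit <- if (!is.null(cfg$mcmc)) {
      st <- do.call(mcmc_settings,
                    utils::modifyList(list(seed = cfg$seed), cfg$mcmc))
      bbm_mcmc(pruned, traits, st)
    } else marg
    loss <- count_losses(pruned, traits)
    write.table(summary(fit), file.path(d, "node_probabilities.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    annotated <- fit$tree
    annotated$node.label <- sprintf("%.3f", fit$probs[, 1L])
    write_newick(annotated, file.path(d, "annotated_tree.nwk"))
    writeLines(utils::capture.output(print(loss)),
               file.path(d, "loss_report.txt"))
    res$asr <- list(rate_mle = r_hat, fit = fit, losses = loss,
                    pruned_tree = pruned)
    manifest$stages$asr <-
      list(n_tips = ape::Ntip(pruned), rate_mle = as.numeric(r_hat),
           transitions = loss$transitions, losses = loss$losses,
           method = fit$method)
    .log_stage("asr", ape::Ntip(pruned), " scored tips; ",
               loss$losses, " parsimony losses")
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest$files <- data.frame(path = sub(paste0("^", out_dir, "/?"), "",
                                          files),
                               md5 = unname(tools::md5sum(files)),
                               stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
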