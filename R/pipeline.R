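#' Run the full synthetic end-to-end pipeline
#'
#' Generates the synthetic input bundle (proteome, expression atlas,
#' stress screen, genotype panel, locus alignment) under one seed, runs
#' every enabled stage — finger scan/classification, finger-domain NJ
#' tree, expression CV/clustering/stress screen, BLUP + PCA + GLM
#' association, locus variant extraction and LD — and writes each
#' stage's tables plus the resolved configuration to `out_dir`.
#'
#' @param config Named list. Recognized keys: `seed`, `out_dir`,
#'   `stages` (subset of `fingers`, `tree`, `expression`, `association`,
#'   `ld`), `n_proteins`, `bootstrap_replicates`, `k_clusters`,
#'   `n_lines`, `n_markers`, `alpha`, `maf_threshold`, `ld_bin_width`.
#'   Unknown keys are rejected.
#' @return Invisibly, a named list of the per-stage result objects.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- list(seed = 1L, out_dir = tempfile("zfatlas_run_"),
                   stages = c("fingers", "tree", "expression",
                              "association", "ld"),
                   n_proteins = 30L, bootstrap_replicates = 100L,
                   k_clusters = 3L, n_lines = 150L, n_markers = 200L,
                   alpha = 1e-2, maf_threshold = 0.05,
                   ld_bin_width = 500L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (length(cfg$stages) == 0)
    stop("no stages enabled")
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  taxonomy <- zf_taxonomy()
  out <- list(config = cfg)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(cfg$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (any(c("fingers", "tree") %in% cfg$stages)) {
    prot <- make_proteome(cfg$n_proteins, taxonomy = taxonomy,
                          seed = cfg$seed)
    profile <- profile_proteome(prot$records, taxonomy)
    out$profile <- profile
    write_finger_table(profile, file.path(cfg$out_dir, "fingers.tsv"))
    tsv(taxonomy_summary_table(profile, taxonomy),
        "taxonomy_summary.tsv")
    message("fingers: ", profile$summary$total_fingers, " fingers in ",
            profile$summary$total_proteins, " proteins")
    if ("tree" %in% cfg$stages) {
      domains <- extract_finger_domains(profile, prot$records)
      aln <- anchor_align(domains)
      tree <- bootstrap_support(aln, cfg$bootstrap_replicates,
                                seed = cfg$seed)
      write_newick(tree, file.path(cfg$out_dir, "domains.nwk"))
      tsv(leaf_metadata(domains, profile, taxonomy),
          "leaf_metadata.tsv")
      out$tree <- tree
      message("tree: ", length(tree$tip.label), " finger domains")
    }
  }
  if ("expression" %in% cfg$stages) {
    atlas <- make_expression(seed = cfg$seed)
    cv <- compute_cv(atlas$matrix)
    cl <- hier_cluster(atlas$matrix, k = cfg$k_clusters)
    stress <- make_stress_data(seed = cfg$seed)
    screen <- stress_screen(stress$treated, stress$control,
                            scale = "log2")
    tsv(cv, "cv.tsv")
    tsv(cl$assignment, "clusters.tsv")
    tsv(screen, "stress.tsv")
    out$expression <- list(cv = cv, clusters = cl, stress = screen)
    message("expression: ", nrow(cv), " transcripts, ",
            sum(screen$responsive), " responsive calls")
  }
  if (any(c("association", "ld") %in% cfg$stages)) {
    sim <- make_panel(n_lines = cfg$n_lines, n_markers = cfg$n_markers,
                      causal = data.frame(marker = 10L,
                                          trait = "trait1",
                                          effect = 1),
                      seed = cfg$seed)
    panel <- filter_maf(sim$panel, cfg$maf_threshold)
    if ("association" %in% cfg$stages) {
      blup <- fit_blup(sim$phenotypes)
      pcs <- pca_covariates(panel, 3)
      assoc <- glm_assoc(panel, blup$blups, covariates = pcs,
                         alpha = cfg$alpha)
      tsv(assoc, "association.tsv")
      out$association <- assoc
      message("association: ", sum(assoc$significant),
              " significant marker-trait pairs of ", nrow(assoc))
    }
    if ("ld" %in% cfg$stages) {
      ld <- pairwise_r2(panel, cfg$maf_threshold)
      decay <- ld_decay(ld, cfg$ld_bin_width)
      tsv(ld, "ld_pairs.tsv")
      tsv(decay, "ld_decay.tsv")
      out$ld <- list(pairs = ld, decay = decay)
      message("ld: ", nrow(ld), " marker pairs")
    }
  }
  invisible(out)
}
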