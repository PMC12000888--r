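#' Default pipeline configuration
#'
#' Flat per-stage key namespace. Every random stage carries an explicit
#' seed. Unknown keys passed as overrides are rejected before any
#' computation.
#'
#' @param input_dir Directory holding the bundle layout written by
#'   [generate_study_like_bundle()] (`eems/`, `absorbance/`,
#'   `metadata.tsv`, `asv_table.tsv`, `taxonomy.tsv`, `tree.nwk`).
#' @param out_dir Output directory for all stage results.
#' @param overrides Named list of configuration overrides (flat keys as in
#'   the default).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, overrides = list()) {
  cfg <- list(
    input_dir = input_dir, out_dir = out_dir,
    seed = 1,
    trim_em_max = 600, trim_ex_min = 250,
    raman_ex_ref = 350, raman_em_band = c(371, 428),
    scatter_widths = list(rayleigh1 = 10, raman1 = 5, rayleigh2 = 10),
    parafac_k = 4, parafac_n_starts = 5, parafac_max_iter = 2500,
    parafac_tol = 1e-8,
    hix_variant = "zsolnay",
    shannon_base = 2,
    nmds_k = 2, nmds_n_starts = 20,
    bnti_n_null = 199, bnti_weighted = TRUE,
    ncm_conf = 0.95,
    network_rho_min = 0.6, network_q_max = 0.05,
    network_min_prevalence = 0.5,
    linkage_rank = "phylum", linkage_n_perm = 999,
    stages = c("preprocess", "parafac", "indices", "diversity", "assembly",
               "ncm", "network", "linkage"))
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    flk_error(paste("unknown config keys:", paste(unknown, collapse = ", ")),
              "fdomlink_config_error")
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Read a JSON pipeline configuration file
#'
#' @param path JSON file with `input_dir`, `out_dir` and any overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$input_dir) || is.null(raw$out_dir)) {
    flk_error("config must name input_dir and out_dir",
              "fdomlink_config_error")
  }
  ov <- raw[setdiff(names(raw), c("input_dir", "out_dir"))]
  pipeline_config(raw$input_dir, raw$out_dir, ov)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a bundle directory:
#' EEM preprocessing (blank subtraction, inner-filter correction, Raman
#' normalization, scatter excision, trimming, grid harmonization), PARAFAC
#' with component classification and percent composition, optical indices,
#' alpha/beta diversity with NMDS and group comparisons, betaNTI per matrix
#' type with stochastic/deterministic fractions, Sloan neutral-model fits
#' per matrix type, co-occurrence networks per group x matrix type, and
#' DOM-community linkage statistics. Outputs land under `cfg$out_dir`; a
#' `run_manifest.json` records the configuration, seed and package version.
#' Inputs are never mutated, and a rerun with the same config and seed
#' reproduces every numeric output byte-identically.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      flk_error(sprintf("stage '%s': %s", name, conditionMessage(e)),
                "fdomlink_stage_error")
    })
  }

  want <- function(s) s %in% cfg$stages
  need <- list(parafac = "preprocess", indices = "preprocess",
               network = "parafac", linkage = c("parafac", "assembly"))
  for (s in names(need)) {
    if (want(s) && !all(need[[s]] %in% cfg$stages)) {
      flk_error(sprintf("stage '%s' requires stage(s) %s", s,
                        paste(setdiff(need[[s]], cfg$stages), collapse = ", ")),
                "fdomlink_config_error")
    }
  }

  meta <- stage("load", load_metadata_tsv(file.path(cfg$input_dir,
                                                    "metadata.tsv")))
  blank <- stage("load", load_eem_csv(file.path(cfg$input_dir, "eems",
                                                "blank.csv"), "blank"))

  ds <- if (want("preprocess")) stage("preprocess", {
    eems <- lapply(meta$sample_id, function(sid) {
      e <- load_eem_csv(file.path(cfg$input_dir, "eems",
                                  paste0(sid, ".csv")), sid)
      a <- load_absorbance_csv(file.path(cfg$input_dir, "absorbance",
                                         paste0(sid, ".csv")), sid)
      e <- subtract_blank(e, blank)
      e <- inner_filter_correct(e, a)
      e <- raman_normalize(e, blank, cfg$raman_ex_ref, cfg$raman_em_band)$eem
      e <- excise_and_interpolate_scatter(e, cfg$scatter_widths)
      trim_wavelengths(e, cfg$trim_em_max, cfg$trim_ex_min)
    })
    harmonize_grid(eems, meta)
  })
  res$dataset <- ds

  fmax <- NULL
  if (want("parafac")) {
    model <- stage("parafac", fit_parafac(
      ds, cfg$parafac_k, n_starts = cfg$parafac_n_starts,
      max_iter = cfg$parafac_max_iter, tol = cfg$parafac_tol,
      seed = cfg$seed))
    write_parafac_model(model, file.path(out, "parafac"))
    fps <- classify_components(model)
    utils::write.csv(fps, file.path(out, "parafac", "components.csv"),
                     row.names = FALSE)
    fmax <- fmax_scores(model)
    pct <- percent_composition(fmax)
    utils::write.csv(data.frame(sample_id = rownames(pct), pct),
                     file.path(out, "parafac", "percent_composition.csv"),
                     row.names = FALSE)
    res$parafac <- model; res$components <- fps; res$fmax <- fmax
    res$percent_composition <- pct
  }

  if (want("indices")) {
    idx <- stage("indices", do.call(rbind, lapply(meta$sample_id,
                                                  function(sid) {
      a <- load_absorbance_csv(file.path(cfg$input_dir, "absorbance",
                                         paste0(sid, ".csv")), sid)
      optical_indices(ds$eems[[sid]], a,
                      meta$doc_mg_per_L[meta$sample_id == sid],
                      cfg$hix_variant)
    })))
    utils::write.csv(idx, file.path(out, "optical_indices.csv"),
                     row.names = FALSE)
    res$indices <- idx
  }

  table <- stage("load", read_feature_table(
    file.path(cfg$input_dir, "asv_table.tsv"),
    file.path(cfg$input_dir, "taxonomy.tsv")))
  tree <- stage("load", ape::read.tree(file.path(cfg$input_dir, "tree.nwk")))
  res$table <- table; res$tree <- tree

  div <- if (want("diversity")) stage("diversity", {
    alpha <- alpha_diversity(table, cfg$shannon_base)
    utils::write.csv(alpha, file.path(out, "alpha_diversity.csv"),
                     row.names = FALSE)
    per_mt <- lapply(split(meta$sample_id, meta$matrix_type), function(ids) {
      bc <- bray_curtis(table$counts[, ids, drop = FALSE])
      ord <- nmds(bc, k = cfg$nmds_k, n_starts = cfg$nmds_n_starts,
                  seed = cfg$seed)
      list(bray_curtis = bc, nmds = ord)
    })
    hl <- meta$group %in% c("HH", "LH")
    gc <- group_compare(alpha$shannon[match(meta$sample_id[hl],
                                            alpha$sample_id)],
                        meta$group[hl], "welch_t")
    list(alpha = alpha, per_matrix = per_mt, shannon_hh_vs_lh = gc)
  })
  res$diversity <- div

  by_mt <- split(seq_len(nrow(meta)), meta$matrix_type)
  res$assembly <- if (want("assembly")) stage("assembly", lapply(by_mt, function(rows) {
    ids <- meta$sample_id[rows]
    sub <- feature_table(table$counts[, ids, drop = FALSE], table$taxonomy)
    bn <- beta_nti(sub, tree, n_null = cfg$bnti_n_null,
                   weighted = cfg$bnti_weighted, seed = cfg$seed)
    write_beta_nti_csv(bn, file.path(
      out, paste0("bnti_", meta$matrix_type[rows[1]], ".csv")))
    list(bnti = bn, fractions = assembly_fractions(bn))
  }))

  res$ncm <- if (want("ncm")) stage("ncm", lapply(by_mt, function(rows) {
    ids <- meta$sample_id[rows]
    fit <- ncm_fit(feature_table(table$counts[, ids, drop = FALSE]),
                   conf = cfg$ncm_conf)
    write_ncm_fit(fit, file.path(out, paste0("ncm_",
                                             meta$matrix_type[rows[1]])))
    fit
  }))

  res$networks <- if (want("network")) stage("network", {
    nets <- list()
    for (mt in unique(meta$matrix_type)) for (gr in c("HH", "LH")) {
      ids <- meta$sample_id[meta$matrix_type == mt & meta$group == gr]
      if (length(ids) < 4L) next
      sub <- prevalence_filter(
        feature_table(table$counts[, ids, drop = FALSE], table$taxonomy),
        cfg$network_min_prevalence)
      taxa <- aggregate_taxa(sub, cfg$linkage_rank)
      domv <- t(fmax[ids, , drop = FALSE])
      env <- t(as.matrix(meta[match(ids, meta$sample_id),
                              c("doc_mg_per_L", "WT", "pH", "TN", "TP")]))
      colnames(env) <- ids
      feats <- rbind(taxa, domv, env)
      kinds <- c(rep("taxon", nrow(taxa)), rep("dom_component", nrow(domv)),
                 rep("environment", nrow(env)))
      net <- build_network(feats, kinds, cfg$network_rho_min,
                           cfg$network_q_max)
      write_network(net, file.path(out, paste0("network_", mt, "_", gr)))
      nets[[paste(mt, gr, sep = "_")]] <-
        list(network = net, metrics = network_metrics(net))
    }
    nets
  })

  res$linkage <- if (want("linkage")) stage("linkage", {
    taxa_all <- aggregate_taxa(table, cfg$linkage_rank)
    domm <- t(fmax)
    lk <- lapply(by_mt, function(rows) {
      ids <- meta$sample_id[rows]
      sm <- spearman_map(taxa_all[, ids, drop = FALSE],
                         domm[, ids, drop = FALSE])
      mt <- meta$matrix_type[rows[1]]
      utils::write.csv(sm, file.path(out, paste0("linkage_spearman_", mt,
                                                 ".csv")), row.names = FALSE)
      mr <- bnti_fdom_correlation(res$assembly[[mt]]$bnti,
                                  domm[, ids, drop = FALSE],
                                  n_perm = cfg$linkage_n_perm,
                                  seed = cfg$seed)
      utils::write.csv(mr, file.path(out, paste0("linkage_bnti_fdom_", mt,
                                                 ".csv")), row.names = FALSE)
      list(spearman = sm, mantel = mr)
    })
    lk
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fdomlink")),
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(cfg), c("stages"))],
    stages_run = cfg$stages)
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
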