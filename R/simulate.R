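#' Default fluorophore component shapes for the EEM generator
#'
#' Four Gaussian-loading components at literature-typical peak positions:
#' a terrestrial humic-like component with a dual excitation peak
#' (250 + 340 nm, em 460 nm), a microbial humic-like component
#' (ex 310, em 410), a tyrosine-like protein component (ex 275, em 304) and
#' a tryptophan-like protein component (ex 280, em 340). These are generator
#' conventions for building synthetic ground truth, not measured loadings.
#'
#' @return List of component specs (`label`, `ex_center` (may be length 2),
#'   `ex_width`, `em_center`, `em_width`).
#' @export
component_specs_default <- function() {
  list(
    list(label = "terrestrial humic-like", ex_center = c(250, 340),
         ex_width = c(15, 25), em_center = 460, em_width = 40),
    list(label = "microbial humic-like", ex_center = 310, ex_width = 20,
         em_center = 410, em_width = 35),
    list(label = "tyrosine-like", ex_center = 275, ex_width = 12,
         em_center = 304, em_width = 15),
    list(label = "tryptophan-like", ex_center = 280, ex_width = 14,
         em_center = 340, em_width = 20))
}

# unit-maximum Gaussian (or sum-of-Gaussians) loading on a wavelength grid
gaussian_loading <- function(wl, centers, widths) {
  y <- rowSums(vapply(seq_along(centers), function(i)
    exp(-0.5 * ((wl - centers[i]) / widths[i])^2), numeric(length(wl))))
  y / max(y)
}

component_loadings <- function(spec, ex_nm, em_nm) {
  list(ex = gaussian_loading(ex_nm, spec$ex_center, spec$ex_width),
       em = gaussian_loading(em_nm, spec$em_center, spec$em_width))
}

#' Generate a synthetic EEM dataset with known ground truth
#'
#' Each sample's surface is a nonnegative mixture of the component outer
#' products `em_loading %o% ex_loading` plus optional Rayleigh/Raman scatter
#' ridges and Gaussian noise scaled to a target signal-to-noise ratio
#' (`snr = RMS(signal) / noise_sd`; `Inf` for noiseless).
#'
#' @param n_samples Number of samples (default 40).
#' @param components List of component specs (default
#'   [component_specs_default()]).
#' @param weights Optional n_samples x K nonnegative mixing matrix;
#'   default: iid Gamma(shape 2, scale 1) draws.
#' @param snr Signal-to-noise ratio (default 50).
#' @param scatter Add first-order Rayleigh and Raman ridges (default
#'   `FALSE`).
#' @param ex_nm,em_nm Wavelength grids; defaults 240-450 nm and 300-600 nm
#'   at 2 nm, the instrument-style convention.
#' @param seed RNG seed; the dataset is a pure function of arguments + seed.
#' @param meta Optional metadata to attach.
#' @return List with `dataset` (an [eem_dataset()]) and `truth` (generator
#'   name, seed, true `ex_loadings`, `em_loadings`, `weights`, `noise_sd`,
#'   `labels`).
#' @export
generate_eem_dataset <- function(n_samples = 40,
                                 components = component_specs_default(),
                                 weights = NULL, snr = 50, scatter = FALSE,
                                 ex_nm = seq(240, 450, by = 2),
                                 em_nm = seq(300, 600, by = 2),
                                 seed = 1, meta = NULL) {
  set.seed(as.integer(seed))
  K <- length(components)
  loads <- lapply(components, component_loadings, ex_nm = ex_nm, em_nm = em_nm)
  exL <- vapply(loads, `[[`, numeric(length(ex_nm)), "ex")
  emL <- vapply(loads, `[[`, numeric(length(em_nm)), "em")
  if (is.null(weights)) {
    weights <- matrix(stats::rgamma(n_samples * K, shape = 2, scale = 1),
                      n_samples, K)
  }
  weights <- as.matrix(weights)
  if (any(weights < 0)) flk_error("weights must be nonnegative",
                                  "fdomlink_argument_error")
  surfaces <- lapply(seq_len(K), function(k) emL[, k] %o% exL[, k])
  eems <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    surf <- Reduce(`+`, Map(`*`, surfaces, weights[s, ]))
    if (scatter) surf <- surf + scatter_ridges(ex_nm, em_nm,
                                               amp = 2 * max(surf))
    if (is.finite(snr)) {
      rms <- sqrt(mean(surf^2))
      surf <- surf + stats::rnorm(length(surf), sd = rms / snr)
    }
    eems[[s]] <- eem(sprintf("syn%03d", s), ex_nm, em_nm, surf)
  }
  truth <- list(generator = "generate_eem_dataset", seed = seed,
                ex_loadings = exL, em_loadings = emL, weights = weights,
                snr = snr,
                labels = vapply(components, `[[`, "", "label"))
  list(dataset = eem_dataset(eems, meta), truth = truth)
}

# first-order Rayleigh + Raman ridges (Gaussian cross-sections along em)
scatter_ridges <- function(ex_nm, em_nm, amp, width = 4) {
  ridge <- matrix(0, length(em_nm), length(ex_nm))
  for (j in seq_along(ex_nm)) {
    ex <- ex_nm[j]
    raman_em <- 1 / (1 / ex - 0.00036)
    ridge[, j] <- amp * exp(-0.5 * ((em_nm - ex) / width)^2) +
      0.3 * amp * exp(-0.5 * ((em_nm - raman_em) / width)^2)
  }
  ridge
}

#' Generate absorbance spectra with known spectral slopes
#'
#' Piecewise double-exponential Napierian absorption: slope `slope_vis`
#' above the 320 nm breakpoint (anchored at `a_ref` m^-1 at 440 nm),
#' `slope_uv` below, continuous at the break; converted to decadic
#' absorbance for the stated path. The true slope ratio is
#' `slope_uv / slope_vis`. Multiplicative lognormal noise keeps spectra
#' positive.
#'
#' @param n Number of spectra.
#' @param slope_uv,slope_vis True slopes (nm^-1), defaults 0.03 / 0.015.
#' @param a_ref Napierian absorption at 440 nm (m^-1), default 1.2.
#' @param noise_sd Lognormal sigma (default 0 = noiseless).
#' @param wl_nm Grid, default 230-800 nm at 1 nm.
#' @param pathlength_cm Path length (default 1).
#' @param seed RNG seed.
#' @return List with `spectra` (list of [absorbance_spectrum()]) and
#'   `truth` (slopes, `sr`).
#' @export
generate_absorbance <- function(n = 16, slope_uv = 0.03, slope_vis = 0.015,
                                a_ref = 1.2, noise_sd = 0,
                                wl_nm = seq(230, 800, by = 1),
                                pathlength_cm = 1, seed = 1) {
  if (slope_uv <= 0 || slope_vis <= 0) {
    flk_error("slopes must be positive", "fdomlink_argument_error")
  }
  set.seed(as.integer(seed))
  brk <- 320
  a_brk <- a_ref * exp(slope_vis * (440 - brk))
  base_a <- ifelse(wl_nm >= brk,
                   a_ref * exp(slope_vis * (440 - wl_nm)),
                   a_brk * exp(slope_uv * (brk - wl_nm)))
  spectra <- lapply(seq_len(n), function(i) {
    a <- base_a
    if (noise_sd > 0) a <- a * exp(stats::rnorm(length(a), sd = noise_sd))
    A <- a * (pathlength_cm / 100) / 2.303
    absorbance_spectrum(sprintf("abs%03d", i), wl_nm, A, pathlength_cm)
  })
  list(spectra = spectra,
       truth = list(generator = "generate_absorbance", seed = seed,
                    slope_uv = slope_uv, slope_vis = slope_vis,
                    sr = slope_uv / slope_vis, a_ref = a_ref,
                    noise_sd = noise_sd))
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Forward simulation with unit speciation rate: starting from two lineages,
#' after each Exp(k) waiting time a uniformly chosen lineage splits, until
#' `n_tips` tips exist; pendant branches run to one further Exp(n) waiting
#' time so tips are contemporaneous. Tips are labelled `ASV_0001`, ...
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed RNG seed.
#' @return An `ape::phylo`.
#' @export
generate_phylogeny <- function(n_tips, seed = 1) {
  if (n_tips < 2L) flk_error("need >= 2 tips", "fdomlink_argument_error")
  set.seed(as.integer(seed))
  # Each lineage is one branch: born at its parent split event (0 = root),
  # terminated either by its own split event or by the present.
  lineage_event <- c(0L, 0L)    # spawning event per lineage (0 = root)
  terminated_by <- integer(0)   # event index -> lineage it terminated
  event_time <- numeric(0)
  t <- 0
  alive <- c(1L, 2L)
  next_id <- 3L
  while (length(alive) < n_tips) {
    t <- t + stats::rexp(1, rate = length(alive))
    pick <- alive[sample.int(length(alive), 1)]
    ev <- length(event_time) + 1L
    event_time[ev] <- t
    terminated_by[ev] <- pick
    alive <- c(alive[alive != pick], next_id, next_id + 1L)
    lineage_event[c(next_id, next_id + 1L)] <- ev
    next_id <- next_id + 2L
  }
  t_end <- t + stats::rexp(1, rate = length(alive))
  n_events <- length(event_time)
  n_lineages <- next_id - 1L
  # phylo node ids: tips 1..n, root n+1, event ev -> n+1+ev
  lineage_node <- integer(n_lineages)
  lineage_node[sort(alive)] <- seq_len(n_tips)
  lineage_end <- rep(t_end, n_lineages)
  for (ev in seq_len(n_events)) {
    lineage_node[terminated_by[ev]] <- n_tips + 1L + ev
    lineage_end[terminated_by[ev]] <- event_time[ev]
  }
  parent_ev <- lineage_event
  parent_node <- ifelse(parent_ev == 0L, n_tips + 1L, n_tips + 1L + parent_ev)
  start_time <- ifelse(parent_ev == 0L, 0, event_time[pmax(parent_ev, 1L)])
  tree <- list(edge = cbind(as.integer(parent_node),
                            as.integer(lineage_node)),
               edge.length = lineage_end - start_time,
               tip.label = sprintf("ASV_%04d", seq_len(n_tips)),
               Nnode = n_events + 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  check_tree(tree)
  tree
}

# Fisher log-series-style metacommunity relative abundances; default x keeps
# the dominance range comparable across pool sizes (x^n_taxa = e^-2.5)
logseries_metacommunity <- function(n_taxa, x = exp(-2.5 / n_taxa)) {
  p <- x^seq_len(n_taxa) / seq_len(n_taxa)
  p / sum(p)
}

#' Generate neutral communities from the Sloan stationary distribution
#'
#' Per sample, local relative abundances are drawn from a Dirichlet with
#' parameters `N * m * p` (whose marginals are the Sloan stationary
#' Beta(Nmp, Nm(1-p)) distribution), then `N` reads are drawn
#' multinomially. Sampling from the stationary marginal rather than forward
#' Hubbell dynamics makes parameter recovery a clean inverse problem.
#'
#' @param tree Optional `phylo`; its tips become the taxa. Otherwise give
#'   `n_taxa`.
#' @param n_taxa Number of taxa when no tree is supplied (default 500).
#' @param metacommunity Optional relative abundance vector (sums to 1);
#'   default a log-series shape randomly assigned to taxa, so that the
#'   metacommunity carries no phylogenetic structure.
#' @param N Reads per sample (default 5000).
#' @param m Migration probability (default 0.1).
#' @param n_samples Number of samples (default 50).
#' @param seed RNG seed.
#' @return List with `table` (a [feature_table()]) and `truth`
#'   (`m`, `N`, `p`).
#' @export
generate_neutral_communities <- function(tree = NULL, n_taxa = 500,
                                         metacommunity = NULL, N = 5000,
                                         m = 0.1, n_samples = 50, seed = 1) {
  if (m <= 0 || m > 1) flk_error("m must lie in (0, 1]",
                                 "fdomlink_argument_error")
  set.seed(as.integer(seed))
  taxa <- if (!is.null(tree)) tree$tip.label else sprintf("ASV_%04d",
                                                          seq_len(n_taxa))
  n_taxa <- length(taxa)
  p <- metacommunity %||% sample(logseries_metacommunity(n_taxa))
  p <- p / sum(p)
  names(p) <- taxa
  alpha <- N * m * p
  counts <- matrix(0L, n_taxa, n_samples,
                   dimnames = list(taxa, sprintf("S%03d", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    g <- stats::rgamma(n_taxa, shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(p)] <- 1
    counts[, s] <- stats::rmultinom(1, size = N, prob = g / sum(g))
  }
  list(table = feature_table(counts),
       truth = list(generator = "generate_neutral_communities", seed = seed,
                    m = m, N = N, Nm = N * m, p = p))
}

#' Generate niche-filtered communities with phylogenetically conserved
#' optima
#'
#' Per-taxon environmental optima evolve by Brownian motion along the tree
#' (so they are phylogenetically conserved); sample weights are
#' `exp(-selection_strength * (optimum - env)^2) * p` followed by a
#' multinomial read draw. `selection_strength = 0` reduces to neutral-like
#' multinomial sampling of the metacommunity. With `standardize = TRUE`
#' (default) the optima are rescaled to unit standard deviation before the
#' weight computation, so `env` and `selection_strength` are expressed in
#' trait-SD units and the filtering regime does not depend on tree height.
#'
#' @param tree A `phylo`; tips are the taxa.
#' @param env Per-sample environmental values (length `n_samples`), in
#'   trait-SD units when `standardize = TRUE`.
#' @param selection_strength Nonnegative filtering strength (default 4).
#' @param metacommunity Optional relative abundances; default log-series.
#' @param N Reads per sample (default 2000).
#' @param standardize Rescale optima to unit SD (default `TRUE`).
#' @param seed RNG seed.
#' @return List with `table` and `truth` (`optima` as used for the weights,
#'   `optima_raw`, `env`, `selection_strength`, `p`).
#' @export
generate_niche_communities <- function(tree, env, selection_strength = 4,
                                       metacommunity = NULL, N = 2000,
                                       standardize = TRUE, seed = 1) {
  if (selection_strength < 0) {
    flk_error("selection_strength must be >= 0", "fdomlink_argument_error")
  }
  check_tree(tree)
  set.seed(as.integer(seed))
  n_samples <- length(env)
  taxa <- tree$tip.label
  optima_raw <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  optima <- if (standardize) optima_raw / stats::sd(optima_raw) else optima_raw
  p <- metacommunity %||% sample(logseries_metacommunity(length(taxa)))
  p <- p / sum(p)
  names(p) <- taxa
  counts <- matrix(0L, length(taxa), n_samples,
                   dimnames = list(taxa, sprintf("S%03d", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    w <- exp(-selection_strength * (optima - env[s])^2) * p
    if (sum(w) == 0) w <- p
    counts[, s] <- stats::rmultinom(1, size = N, prob = w / sum(w))
  }
  list(table = feature_table(counts),
       truth = list(generator = "generate_niche_communities", seed = seed,
                    optima = optima, optima_raw = optima_raw, env = env,
                    selection_strength = selection_strength, p = p, N = N,
                    standardize = standardize))
}

#' Generate a complete study-like fixture bundle on disk
#'
#' Emulates the study layout: 16 sites (6 high-disturbance HH, 6
#' low-disturbance LH, 4 river R) sampled in both water and sediment.
#' Sediment EEMs are protein-dominated in HH and humic-dominated in LH;
#' water is humic-dominated throughout. Observed EEMs are built backwards
#' through the measurement chain (true mixture attenuated by the
#' inner-filter factor, plus blank pattern, scatter ridges and noise) so the
#' preprocessing stages have real work to do; a blank EEM with a water Raman
#' ridge is included. Water communities are neutral, sediment communities
#' niche-filtered along a disturbance gradient on a shared phylogeny.
#' Everything is written in the exact text formats the pipeline reads, plus
#' a machine-readable `ground_truth.json`.
#'
#' @param dir Output directory (created).
#' @param seed RNG seed; the bundle is bit-reproducible given it.
#' @param n_taxa Taxa on the shared phylogeny (default 150).
#' @param n_null Unused here; kept for config symmetry.
#' @return Invisibly, the manifest list (also serialized as JSON).
#' @export
generate_study_like_bundle <- function(dir, seed = 7, n_taxa = 150,
                                       n_null = NULL) {
  set.seed(as.integer(seed))
  dir.create(file.path(dir, "eems"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "absorbance"), showWarnings = FALSE)
  groups <- c(rep("HH", 6), rep("LH", 6), rep("R", 4))
  sites <- sprintf("site%02d", seq_along(groups))
  grid_ex <- seq(240, 450, by = 2); grid_em <- seq(300, 620, by = 2)
  comps <- component_specs_default()
  loads <- lapply(comps, component_loadings, ex_nm = grid_ex, em_nm = grid_em)
  surfaces <- lapply(loads, function(l) l$em %o% l$ex)
  # mean composition targets (C1 terrestrial humic, C2 microbial humic,
  # C3 tyrosine, C4 tryptophan); HH sediment protein-dominated ~69%,
  # LH sediment humic-dominated ~63%, water humic ~67%, river ~76%
  w_mean <- list(
    sediment = list(HH = c(0.18, 0.13, 0.42, 0.27),
                    LH = c(0.38, 0.25, 0.22, 0.15),
                    R  = c(0.45, 0.28, 0.12, 0.15)),
    water    = list(HH = c(0.40, 0.27, 0.18, 0.15),
                    LH = c(0.42, 0.27, 0.16, 0.15),
                    R  = c(0.50, 0.26, 0.10, 0.14)))
  blank <- scatter_ridges(grid_ex, grid_em, amp = 0.3) + 0.01
  blank_eem <- eem("blank", grid_ex, grid_em, blank)
  write_eem_csv(blank_eem, file.path(dir, "eems", "blank.csv"))
  absg <- generate_absorbance(n = 1, noise_sd = 0, seed = seed)
  meta_rows <- list(); truth_weights <- list(); truth_doc <- list()
  sample_ids <- character(0)
  for (mt in c("water", "sediment")) {
    for (i in seq_along(sites)) {
      sid <- paste0(sites[i], "_", substr(mt, 1, 1))
      sample_ids <- c(sample_ids, sid)
      wm <- w_mean[[mt]][[groups[i]]]
      w <- wm * stats::rgamma(4, shape = 25, rate = 25)  # ~10% CV jitter
      scale_tot <- stats::rlnorm(1, log(3), 0.2)         # overall RU scale
      w <- w / sum(w) * scale_tot
      clean <- Reduce(`+`, Map(`*`, surfaces, w))
      # absorbance: per-sample scaled reference spectrum
      a_scale <- stats::rlnorm(1, 0, 0.25)
      spec <- absg$spectra[[1]]
      spec$sample_id <- sid
      spec$absorbance <- spec$absorbance * a_scale
      utils::write.csv(data.frame(wl_nm = spec$wl_nm,
                                  absorbance = spec$absorbance),
                       file.path(dir, "absorbance", paste0(sid, ".csv")),
                       row.names = FALSE)
      a1 <- spec$absorbance / spec$pathlength_cm
      a_ex <- stats::approx(spec$wl_nm, a1, grid_ex, rule = 2)$y
      a_em <- stats::approx(spec$wl_nm, a1, grid_em, rule = 2)$y
      ife <- 10 ^ (-outer(a_em, a_ex, `+`) / 2)
      obs_int <- clean * ife + blank +
        scatter_ridges(grid_ex, grid_em, amp = 1.5 * max(clean)) +
        stats::rnorm(length(clean), sd = sqrt(mean(clean^2)) / 60)
      write_eem_csv(eem(sid, grid_ex, grid_em, obs_int),
                    file.path(dir, "eems", paste0(sid, ".csv")))
      doc <- stats::rlnorm(1, log(if (mt == "water") 6 else 12), 0.3)
      meta_rows[[sid]] <- data.frame(
        sample_id = sid, matrix_type = mt, group = groups[i],
        doc_mg_per_L = round(doc, 3),
        WT = round(stats::rnorm(1, 15, 2), 2),
        pH = round(stats::rnorm(1, 8, 0.3), 2),
        TN = round(stats::rlnorm(1, 0.5, 0.3), 3),
        TP = round(stats::rlnorm(1, -2, 0.3), 4),
        stringsAsFactors = FALSE)
      truth_weights[[sid]] <- w
      truth_doc[[sid]] <- doc
    }
  }
  meta <- do.call(rbind, meta_rows)
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  # shared phylogeny + communities
  tree <- generate_phylogeny(n_taxa, seed = seed + 1)
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  water_ids <- meta$sample_id[meta$matrix_type == "water"]
  sed_ids <- meta$sample_id[meta$matrix_type == "sediment"]
  neutral <- generate_neutral_communities(tree = tree, N = 5000, m = 0.1,
                                          n_samples = length(water_ids),
                                          seed = seed + 2)
  colnames(neutral$table$counts) <- water_ids
  disturbance <- ifelse(meta$group[meta$matrix_type == "sediment"] == "HH",
                        2, -2)
  niche <- generate_niche_communities(tree, env = disturbance,
                                      selection_strength = 2, N = 5000,
                                      seed = seed + 3)
  colnames(niche$table$counts) <- sed_ids
  counts <- cbind(neutral$table$counts, niche$table$counts)
  tab <- data.frame(asv_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(tab, file.path(dir, "asv_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  # simple taxonomy: clades of the tree mapped to synthetic phyla/genera
  phyla <- paste0("Phylum", cutree_clades(tree, 8))
  genera <- paste0("Genus", cutree_clades(tree, 30))
  tax <- data.frame(asv_id = tree$tip.label, phylum = phyla, genus = genera,
                    stringsAsFactors = FALSE)
  utils::write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    generator = "generate_study_like_bundle", seed = seed,
    protein_dominant_group = "HH", protein_components = c("C3", "C4"),
    groups = stats::setNames(as.list(groups), sites),
    weights = truth_weights, doc = truth_doc,
    component_labels = vapply(comps, `[[`, "", "label"),
    water = list(model = "neutral", m = 0.1, N = 5000),
    sediment = list(model = "niche", selection_strength = 2,
                    env = stats::setNames(as.list(disturbance), sed_ids)),
    absorbance_truth = absg$truth)
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# assign tips to clades by cutting the tree into k groups (on cophenetic
# distance; deterministic)
cutree_clades <- function(tree, k) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  stats::cutree(stats::hclust(d, method = "average"), k = k)[tree$tip.label]
}
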