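#' Tissue specification for the synthetic generator
#'
#' Describes one synthetic tissue: population sizes, per-TF detection
#' frequencies in the endothelial population, signed TF -> target regulatory
#' modules, indirect TF -> mediator -> target chains, background gene count
#' and the negative-binomial noise / dropout parameters.
#'
#' Planted edges act multiplicatively on the target's NB mean through a log
#' link of the standardized regulator expression:
#' mu(target) = baseline_mu * exp(sum over edges of effect * sign * z(TF)).
#' Chains route the same construction through a non-seed mediator with no
#' direct TF -> target term.
#'
#' @param name Tissue name.
#' @param n_cells_by_population Named integer vector, e.g.
#'   `c(endothelial = 150, other = 60)`; all sizes > 0.
#' @param tf_detect_freq Named fractions in \[0,1\] per seed TF: the
#'   probability that a TF is "on" (detected) in an endothelial cell.
#' @param tf_detect_freq_by_pop Optional named list of per-population
#'   frequency overrides; populations without an entry use
#'   `other_tf_freq` for every TF.
#' @param planted_edges data.frame with columns tf, target, sign (+1/-1),
#'   effect, population (or NULL for none).
#' @param indirect_chains data.frame with columns tf, mediator, target,
#'   effect, population (or NULL).
#' @param n_background_genes Independent NB noise genes.
#' @param nb_size NB size parameter (1/dispersion) shared by all genes.
#' @param dropout_rate Bernoulli zeroing probability for non-TF genes. Seed
#'   TF genes are exempt: `tf_detect_freq` is already the detection target.
#' @param tf_mu,baseline_mu,background_mu NB means for "on" TFs, module
#'   targets at baseline, and background genes.
#' @param other_tf_freq TF detection frequency in populations without an
#'   override (default 0.05).
#' @param n_housekeeping_genes,housekeeping_mu,housekeeping_size A block of
#'   high, stable "housekeeping" genes giving every cell a stable library
#'   mass, as in full-length protocols where a core of abundant transcripts
#'   dominates the total count.
#' @param max_log_fc Cap on the planted log fold-change of any regulated
#'   mean (keeps per-cell totals, and hence per-cell normalization factors,
#'   within a realistic range).
#' @param program_tfs Optional TF subset sharing a latent per-cell program
#'   activity in the endothelial population: each program TF's "on"
#'   expression mean is scaled by exp(lambda * a - lambda^2/2) for a common
#'   cell-level a ~ N(0,1). This correlates the expression *levels* of
#'   co-regulated TFs (the coordinated hemogenic program) while leaving
#'   their detection states independent Bernoulli draws.
#' @param program_lambda Loading of program TFs on the latent activity.
#' @param program_detect_loading Gaussian-copula loading of program-TF
#'   *detection* on the same latent activity: each program TF's on/off draw
#'   uses a uniform u = pnorm(loading * a + sqrt(1-loading^2) * noise), so
#'   the marginal detection frequency stays exactly `tf_detect_freq` while
#'   cells with high program activity tend to co-detect the whole panel —
#'   the coordinated co-expression signature of hemogenic endothelium.
#'   Non-program TFs keep fully independent detection.
#' @param n_rare_genes,rare_detect_freq,rare_mu A block of sparsely
#'   detected genes (independent noise) that pads the gene universe, as the
#'   long tail of rarely captured transcripts does in real data; they give
#'   per-cell rankings realistic depth while staying below the detection
#'   fraction that would make them network candidate targets.
#' @return A `tissue_spec` list.
#' @export
tissue_spec <- function(name, n_cells_by_population, tf_detect_freq,
                        tf_detect_freq_by_pop = NULL,
                        planted_edges = NULL, indirect_chains = NULL,
                        n_background_genes = 6L, nb_size = 6,
                        dropout_rate = 0.05, tf_mu = 8, baseline_mu = 6,
                        background_mu = 4, other_tf_freq = 0.05,
                        n_housekeeping_genes = 8L, housekeeping_mu = 300,
                        housekeeping_size = 100, max_log_fc = 2,
                        program_tfs = NULL, program_lambda = 0.8,
                        program_detect_loading = 0.75,
                        n_rare_genes = 100L, rare_detect_freq = 0.05,
                        rare_mu = 3) {
  panel_tfs <- seed_panel()$seed_tfs
  stopifnot(all(n_cells_by_population > 0),
            "endothelial" %in% names(n_cells_by_population),
            all(tf_detect_freq >= 0 & tf_detect_freq <= 1),
            all(names(tf_detect_freq) %in% panel_tfs),
            nb_size > 0, dropout_rate >= 0, dropout_rate < 1)
  if (!is.null(planted_edges)) {
    if (is.null(planted_edges$population))
      planted_edges$population <- "endothelial"
    stopifnot(all(planted_edges$tf %in% panel_tfs),
              !any(planted_edges$target %in% panel_tfs),
              all(planted_edges$sign %in% c(-1, 1)),
              all(is.finite(planted_edges$effect)))
  }
  if (!is.null(indirect_chains)) {
    if (is.null(indirect_chains$population))
      indirect_chains$population <- "endothelial"
    stopifnot(all(indirect_chains$tf %in% panel_tfs),
              !any(indirect_chains$mediator %in% panel_tfs),
              !any(indirect_chains$target %in% panel_tfs))
  }
  structure(list(name = name,
                 n_cells_by_population = n_cells_by_population,
                 tf_detect_freq = tf_detect_freq,
                 tf_detect_freq_by_pop = tf_detect_freq_by_pop,
                 planted_edges = planted_edges,
                 indirect_chains = indirect_chains,
                 n_background_genes = as.integer(n_background_genes),
                 nb_size = nb_size, dropout_rate = dropout_rate,
                 tf_mu = tf_mu, baseline_mu = baseline_mu,
                 background_mu = background_mu,
                 other_tf_freq = other_tf_freq,
                 n_housekeeping_genes = as.integer(n_housekeeping_genes),
                 housekeeping_mu = housekeeping_mu,
                 housekeeping_size = housekeeping_size,
                 max_log_fc = max_log_fc,
                 program_tfs = program_tfs,
                 program_lambda = program_lambda,
                 program_detect_loading = program_detect_loading,
                 n_rare_genes = as.integer(n_rare_genes),
                 rare_detect_freq = rare_detect_freq, rare_mu = rare_mu),
            class = "tissue_spec")
}

spec_module_genes <- function(spec) {
  unique(c(spec$planted_edges$target, spec$indirect_chains$mediator,
           spec$indirect_chains$target))
}

#' Generate one synthetic tissue
#'
#' Draws counts population by population. Seed-TF detection is Bernoulli at
#' the spec frequency; detected TFs draw a strictly positive count
#' 1 + NB(tf_mu - 1, size) so the planted frequency is exactly the detection
#' frequency. Planted targets and chain mediators/targets draw NB counts
#' whose log-mean shifts with the standardized expression of their
#' regulators; background genes (and module genes not planted in this
#' tissue) are independent NB noise. Dropout zeroes non-TF entries at the
#' spec rate. Deterministic given `seed`.
#'
#' @param spec A [tissue_spec()].
#' @param seed Integer seed.
#' @param all_genes Optional full gene universe (used by [generate_cohort()]
#'   so every tissue shares one gene axis); default is the spec's own genes.
#' @return List with `counts` (cells x genes sparse), `cell_meta`, and
#'   `tf_states` (cells x 11 logical matrix of planted TF on/off truth).
#' @export
generate_tissue <- function(spec, seed, all_genes = NULL) {
  set.seed(as.integer(seed))
  panel_tfs <- seed_panel()$seed_tfs
  if (is.null(all_genes)) {
    all_genes <- c(panel_tfs, spec_module_genes(spec),
                   sprintf("Bg%02d", seq_len(spec$n_background_genes)),
                   sprintf("Hk%02d", seq_len(spec$n_housekeeping_genes)),
                   sprintf("Rare%03d", seq_len(spec$n_rare_genes)))
  }
  stopifnot(all(panel_tfs %in% all_genes))
  pops <- names(spec$n_cells_by_population)
  blocks <- list(); metas <- list(); states <- list()
  for (pop in pops) {
    n <- spec$n_cells_by_population[[pop]]
    freqs <- setNames(rep(spec$other_tf_freq, length(panel_tfs)), panel_tfs)
    if (pop == "endothelial") {
      freqs[names(spec$tf_detect_freq)] <- spec$tf_detect_freq
    } else if (!is.null(spec$tf_detect_freq_by_pop[[pop]])) {
      ov <- spec$tf_detect_freq_by_pop[[pop]]
      freqs[names(ov)] <- ov
    }
    m <- matrix(0, nrow = n, ncol = length(all_genes),
                dimnames = list(NULL, all_genes))
    on <- matrix(FALSE, n, length(panel_tfs),
                 dimnames = list(NULL, panel_tfs))
    program <- if (pop == "endothelial" && length(spec$program_tfs))
      rnorm(n) else NULL
    ld <- spec$program_detect_loading
    for (tf in panel_tfs) {
      in_program <- !is.null(program) && tf %in% spec$program_tfs
      if (in_program) {
        # copula draw: marginal stays freqs[[tf]], detection co-varies
        # with program activity across the pool TFs
        u <- pnorm(ld * program + sqrt(1 - ld^2) * rnorm(n))
        on[, tf] <- u < freqs[[tf]]
      } else {
        on[, tf] <- runif(n) < freqs[[tf]]
      }
      k <- sum(on[, tf])
      if (k > 0) {
        mu_on <- rep(spec$tf_mu - 1, n)
        if (in_program)
          mu_on <- mu_on * exp(spec$program_lambda * program -
                               spec$program_lambda^2 / 2)
        m[on[, tf], tf] <- 1 + rnbinom(k, mu = mu_on[on[, tf]],
                                       size = spec$nb_size)
      }
    }
    zscore <- function(v) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) return(rep(0, length(v)))
      (v - mean(v)) / s
    }
    draw_regulated <- function(regulators, effects, signs) {
      lmu <- log(spec$baseline_mu) +
        Reduce(`+`, Map(function(r, e, s) e * s * zscore(m[, r]),
                        regulators, effects, signs))
      if (any(!is.finite(lmu)) || any(lmu > 700))
        stop("non-finite planted mean")
      mu <- exp(pmin(pmax(lmu, log(spec$baseline_mu) - spec$max_log_fc),
                     log(spec$baseline_mu) + spec$max_log_fc))
      rnbinom(n, mu = mu, size = spec$nb_size)
    }
    planted_here <- character(0)
    ch <- spec$indirect_chains
    if (!is.null(ch)) ch <- ch[ch$population == pop, , drop = FALSE]
    if (!is.null(ch) && nrow(ch)) {
      if (is.null(ch$effect)) ch$effect <- 0.9
      for (i in seq_len(nrow(ch))) {  # mediator first, then chained target
        m[, ch$mediator[i]] <- draw_regulated(ch$tf[i], ch$effect[i], 1)
        m[, ch$target[i]] <- draw_regulated(ch$mediator[i], ch$effect[i], 1)
        planted_here <- c(planted_here, ch$mediator[i], ch$target[i])
      }
    }
    pe <- spec$planted_edges
    if (!is.null(pe)) pe <- pe[pe$population == pop, , drop = FALSE]
    if (!is.null(pe) && nrow(pe)) {
      for (t in unique(pe$target)) {
        e <- pe[pe$target == t, , drop = FALSE]
        m[, t] <- draw_regulated(e$tf, e$effect, e$sign)
        planted_here <- c(planted_here, t)
      }
    }
    hk_genes <- grep("^Hk", all_genes, value = TRUE)
    rare_genes <- grep("^Rare", all_genes, value = TRUE)
    bg_genes <- setdiff(all_genes,
                        c(panel_tfs, planted_here, hk_genes, rare_genes))
    if (length(bg_genes))
      m[, bg_genes] <- rnbinom(n * length(bg_genes),
                               mu = spec$background_mu, size = spec$nb_size)
    if (length(hk_genes))
      m[, hk_genes] <- rnbinom(n * length(hk_genes),
                               mu = spec$housekeeping_mu,
                               size = spec$housekeeping_size)
    if (length(rare_genes)) {
      nr <- n * length(rare_genes)
      m[, rare_genes] <- (runif(nr) < spec$rare_detect_freq) *
        (1 + rnbinom(nr, mu = spec$rare_mu - 1, size = spec$nb_size))
    }
    if (spec$dropout_rate > 0) {
      non_tf <- setdiff(all_genes, panel_tfs)
      drop <- matrix(runif(n * length(non_tf)) < spec$dropout_rate,
                     nrow = n)
      m[, non_tf][drop] <- 0
    }
    blocks[[pop]] <- m
    metas[[pop]] <- data.frame(
      cell_id = sprintf("%s|%s|%04d", spec$name, pop, seq_len(n)),
      tissue = spec$name, population = pop, dataset = "synthetic",
      row.names = NULL)
    states[[pop]] <- on
  }
  counts <- Matrix::Matrix(do.call(rbind, blocks), sparse = TRUE)
  meta <- do.call(rbind, metas)
  rownames(counts) <- meta$cell_id
  tf_states <- do.call(rbind, states)
  rownames(tf_states) <- meta$cell_id
  list(counts = counts, cell_meta = meta, tf_states = tf_states)
}

#' Generate a multi-tissue synthetic cohort
#'
#' Concatenates per-tissue draws over a shared gene universe and returns the
#' bundle together with the ground truth needed to validate the pipeline:
#' the tissue specs, the true tissue order, and per-cell TF on/off states.
#' The true order is defined by the specs' construction: tissues sorted by
#' mean endothelial TF detection frequency times (1 + number of planted
#' endothelial edges), decreasing.
#'
#' @param specs List of [tissue_spec()] with distinct names; at least 2.
#' @param seed Integer seed; per-tissue seeds are derived from it.
#' @return List with `bundle` (an `expression_bundle`) and `truth`
#'   (class `synthetic_truth`).
#' @export
generate_cohort <- function(specs, seed) {
  stopifnot(length(specs) >= 2)
  tissue_names <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(tissue_names)) stop("duplicate tissue names")
  panel_tfs <- seed_panel()$seed_tfs
  module_genes <- sort(unique(unlist(lapply(specs, spec_module_genes))))
  n_bg <- max(vapply(specs, `[[`, 0L, "n_background_genes"))
  n_hk <- max(vapply(specs, `[[`, 0L, "n_housekeeping_genes"))
  n_rare <- max(vapply(specs, `[[`, 0L, "n_rare_genes"))
  all_genes <- c(panel_tfs, module_genes, sprintf("Bg%02d", seq_len(n_bg)),
                 sprintf("Hk%02d", seq_len(n_hk)),
                 sprintf("Rare%03d", seq_len(n_rare)))
  frags <- Map(function(sp, i) generate_tissue(sp, seed = seed + 1009L * i,
                                               all_genes = all_genes),
               specs, seq_along(specs))
  counts <- do.call(rbind, lapply(frags, `[[`, "counts"))
  meta <- do.call(rbind, c(lapply(frags, `[[`, "cell_meta"),
                           list(make.row.names = FALSE)))
  bundle <- expression_bundle(counts, all_genes, meta$cell_id, meta)
  order_score <- vapply(specs, function(sp) {
    n_edges <- if (is.null(sp$planted_edges)) 0L else
      sum(sp$planted_edges$population == "endothelial")
    mean(sp$tf_detect_freq) * (1 + n_edges)
  }, 0)
  truth <- structure(
    list(specs = setNames(specs, tissue_names),
         true_tissue_order = tissue_names[order(-order_score)],
         tf_states = do.call(rbind, lapply(frags, `[[`, "tf_states"))),
    class = "synthetic_truth")
  list(bundle = bundle, truth = truth)
}

#' Default six-tissue cohort
#'
#' The reference validation cohort: one embryo-like tissue in which all 11
#' seed TFs are detected in 95% of endothelial cells and the eight
#' co-expression-subset TFs jointly regulate a shared pool of 12 targets
#' (every pool TF drives every pool target, so target sets overlap fully);
#' four graded adult-like tissues with decreasing frequencies, shrinking
#' pools and a recurrent Runx1 module; and one null tissue with near-zero
#' frequencies, no Runx1-positive endothelial cells and no planted
#' endothelial edges, whose leukocyte population alone carries a shared
#' Fli1/Runx1 module (the white-blood-cell confound: a Fli1-Runx1 target
#' overlap present in the tissue but not in its endothelium).
#'
#' Pool TFs share the latent program activity (see [tissue_spec()]), which
#' keeps each TF marginally informative about the jointly regulated
#' targets; the per-edge effect is scaled as
#' sigma_target / sqrt(m + m(m-1) rho f) for a pool of m regulators at
#' detection frequency f, so the planted log-variance of every shared
#' target is about sigma_target^2 regardless of pool size. Private
#' targets, negative edges and the two indirect chains are attached to the
#' three non-program TFs (Cbfa2t3, Gata1, Ldb1), so their edges probe the
#' program-free regime and clique membership reflects the shared pool only.
#' The Runx1 module genes are planted in exactly four tissues (brain,
#' heart, kidney, liver), never in a tissue where Runx1 is part of the
#' program pool, keeping those edges free of program-mediated confounding.
#'
#' @param n_endothelial Endothelial cells per tissue (default 150).
#' @param n_other Cells in the non-endothelial "other" population.
#' @param n_leukocyte Leukocyte cells in the confound tissue.
#' @param sigma_target Planted log-scale standard deviation of shared-pool
#'   targets (sets the per-edge effects).
#' @param module_effect Effect size for private/module/chain edges.
#' @param program_rho Assumed expression correlation between program TFs
#'   used in the effect-size formula.
#' @return List of [tissue_spec()] (the default cohort, embryo first).
#' @export
default_cohort <- function(n_endothelial = 200L, n_other = 60L,
                           n_leukocyte = 120L, sigma_target = 1.2,
                           module_effect = 0.9, program_rho = 0.3) {
  tfs <- seed_panel()$seed_tfs
  clique8 <- seed_panel()$coexpr_subset
  nonclique <- setdiff(tfs, clique8)  # Cbfa2t3, Gata1, Ldb1
  runx1_mod <- sprintf("TgtRunx1_%02d", 1:6)
  priv <- setNames(sprintf("Tgt%s_priv", nonclique), nonclique)
  pool_effect <- function(m, f)
    sigma_target / sqrt(m + m * (m - 1) * program_rho * f)
  edges <- function(tf_list, targets, effect, sign = 1,
                    population = "endothelial") {
    do.call(rbind, lapply(tf_list, function(tf)
      data.frame(tf = tf, target = targets, sign = sign, effect = effect,
                 population = population)))
  }
  pool_edges <- function(pool_tfs, n_targets, f) {
    do.call(rbind, lapply(sprintf("TgtShared%02d", seq_len(n_targets)),
                          function(t)
      data.frame(tf = pool_tfs, target = t, sign = 1,
                 effect = pool_effect(length(pool_tfs), f),
                 population = "endothelial")))
  }
  freq_all <- function(moderate, low) {
    low_tfs <- c("Gata1", "Lyl1", "Runx1", "Tal1")
    setNames(ifelse(tfs %in% low_tfs, low, moderate), tfs)
  }
  ncells <- c(endothelial = as.integer(n_endothelial),
              other = as.integer(n_other))

  embryo <- tissue_spec(
    name = "embryo_AGM", n_cells_by_population = ncells,
    tf_detect_freq = setNames(rep(0.95, 11), tfs),
    program_tfs = clique8,
    planted_edges = rbind(
      pool_edges(clique8, 12, 0.95),
      do.call(rbind, lapply(nonclique, function(tf)
        data.frame(tf = tf, target = priv[[tf]], sign = 1,
                   effect = module_effect, population = "endothelial"))),
      data.frame(tf = c("Gata1", "Ldb1"),
                 target = c("TgtGata1_neg", "TgtLdb1_neg"),
                 sign = -1, effect = module_effect,
                 population = "endothelial")),
    indirect_chains = data.frame(
      tf = c("Cbfa2t3", "Ldb1"), mediator = c("MedCbfa2t3", "MedLdb1"),
      target = c("ChainCbfa2t3", "ChainLdb1"), effect = module_effect,
      population = "endothelial"))

  adult <- function(name, moderate, low, pool_tfs, n_targets, runx1_edges) {
    pe <- rbind(
      pool_edges(pool_tfs, n_targets, moderate),
      if (runx1_edges) edges("Runx1", runx1_mod, module_effect))
    tissue_spec(name = name, n_cells_by_population = ncells,
                tf_detect_freq = freq_all(moderate, low),
                program_tfs = pool_tfs,
                planted_edges = pe)
  }
  brain <- adult("brain", 0.60, 0.36, setdiff(clique8, c("Runx1", "Lyl1")),
                 10, runx1_edges = TRUE)
  heart <- adult("heart", 0.38, 0.23,
                 c("Cbfb", "Erg", "Fli1", "Gata2", "Lmo2"), 8,
                 runx1_edges = TRUE)
  kidney <- adult("kidney", 0.26, 0.15, c("Erg", "Fli1", "Lmo2"), 6,
                  runx1_edges = TRUE)
  liver <- adult("liver", 0.15, 0.09, c("Erg", "Fli1"), 6,
                 runx1_edges = TRUE)

  pancreas_freq <- setNames(rep(0.06, 11), tfs)
  pancreas_freq["Runx1"] <- 0
  pancreas <- tissue_spec(
    name = "pancreas",
    n_cells_by_population = c(ncells, leukocyte = as.integer(n_leukocyte)),
    tf_detect_freq = pancreas_freq,
    tf_detect_freq_by_pop = list(
      leukocyte = setNames(c(0.9, 0.9), c("Fli1", "Runx1"))),
    planted_edges = rbind(
      edges("Fli1", sprintf("LeukTgt%02d", 1:4), module_effect,
            population = "leukocyte"),
      edges("Runx1", sprintf("LeukTgt%02d", 1:4), module_effect,
            population = "leukocyte")))

  list(embryo, brain, heart, kidney, liver, pancreas)
}

#' Serialize / read synthetic ground truth
#'
#' The truth object is written as a single YAML file: tissue order, planted
#' edges and chains per tissue, and per-cell TF on/off states encoded as
#' 0/1 strings in panel order.
#'
#' @param truth A `synthetic_truth` from [generate_cohort()].
#' @param file Output path.
#' @export
write_truth <- function(truth, file) {
  enc <- list(
    true_tissue_order = truth$true_tissue_order,
    tf_order = colnames(truth$tf_states),
    cells = rownames(truth$tf_states),
    states = apply(truth$tf_states, 1, function(r)
      paste(as.integer(r), collapse = "")),
    tissues = lapply(truth$specs, function(sp) list(
      name = sp$name,
      tf_detect_freq = as.list(sp$tf_detect_freq),
      planted_edges = if (is.null(sp$planted_edges)) list() else
        unname(split(sp$planted_edges, seq_len(nrow(sp$planted_edges)))),
      indirect_chains = if (is.null(sp$indirect_chains)) list() else
        unname(split(sp$indirect_chains, seq_len(nrow(sp$indirect_chains)))))))
  enc$states <- unname(enc$states)
  yaml::write_yaml(enc, file)
  invisible(file)
}

#' @rdname write_truth
#' @return `read_truth()` returns a list with `true_tissue_order`,
#'   `tf_states` (logical matrix) and per-tissue `planted_edges` /
#'   `indirect_chains` data.frames.
#' @export
read_truth <- function(file) {
  enc <- yaml::read_yaml(file)
  states <- do.call(rbind, lapply(enc$states, function(s)
    as.integer(strsplit(s, "")[[1]]) == 1L))
  dimnames(states) <- list(unlist(enc$cells), unlist(enc$tf_order))
  tissues <- lapply(enc$tissues, function(ts) list(
    name = ts$name,
    tf_detect_freq = unlist(ts$tf_detect_freq),
    planted_edges = if (length(ts$planted_edges))
      do.call(rbind, lapply(ts$planted_edges, as.data.frame)) else NULL,
    indirect_chains = if (length(ts$indirect_chains))
      do.call(rbind, lapply(ts$indirect_chains, as.data.frame)) else NULL))
  names(tissues) <- vapply(tissues, `[[`, "", "name")
  list(true_tissue_order = unlist(enc$true_tissue_order),
       tf_states = states, tissues = tissues)
}

#' Simulate a seed-TF mediated chain
#'
#' Small validation bundle for the indirect-edge pruning logic: seed TF A
#' drives seed TF B (the mediator), and B drives a non-seed target, with no
#' direct A -> target term. Used to check that network inference prunes the
#' marginal A -> target edge by conditioning on B.
#'
#' @param n Cells.
#' @param seed Integer seed.
#' @param effect Chain effect size per link.
#' @param n_background Background noise genes.
#' @param tf_a,tf_b Seed TF names to use for the chain.
#' @return An `expression_bundle` (single tissue "chain_sim", population
#'   "endothelial") with a normalized layer.
#' @export
simulate_seed_chain <- function(n = 300L, seed = 1L, effect = 1.2,
                                n_background = 4L,
                                tf_a = "Gata2", tf_b = "Fli1") {
  set.seed(as.integer(seed))
  nb_size <- 20  # low dispersion: the chain must be strong enough to be
  mu_tf <- 16    # detected marginally yet smooth enough to be projectable
  panel_tfs <- seed_panel()$seed_tfs
  genes <- c(panel_tfs, "ChainTarget",
             sprintf("Bg%02d", seq_len(n_background)))
  m <- matrix(rnbinom(n * length(genes), mu = 4, size = nb_size), nrow = n,
              dimnames = list(NULL, genes))
  zscore <- function(v) if (sd(v) == 0) rep(0, length(v)) else
    pmin(pmax((v - mean(v)) / sd(v), -2), 2)
  m[, tf_a] <- 1 + rnbinom(n, mu = mu_tf, size = nb_size)
  m[, tf_b] <- rnbinom(n, mu = exp(log(mu_tf) + effect * zscore(m[, tf_a])),
                       size = nb_size)
  m[, "ChainTarget"] <- rnbinom(
    n, mu = exp(log(6) + effect * zscore(m[, tf_b])), size = nb_size)
  other <- setdiff(panel_tfs, c(tf_a, tf_b))
  m[, other] <- rbinom(n * length(other), 1, 0.5) *
    (1 + rnbinom(n * length(other), mu = mu_tf, size = nb_size))
  meta <- data.frame(cell_id = sprintf("chain|%04d", seq_len(n)),
                     tissue = "chain_sim", population = "endothelial",
                     dataset = "synthetic")
  b <- expression_bundle(m, genes, meta$cell_id, meta)
  lognormalize(b)
}
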