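# Synthetic atlas generator with planted ground truth.
#
# Emulates the structure of a dissected-ovary droplet experiment: several
# discrete non-ovarian cell types (compact isolated clusters), one
# continuous somatic lineage with a single branch point, cross-type
# doublets, cycling subpopulations driven by S/G2M programs, a
# mitochondrial gene subset, lognormal library sizes, NB counts, and an
# optional replicate with an additive (log-scale) batch effect.

#' Describe the continuous branched lineage of a simulation design
#'
#' The lineage is a population whose cells carry a latent time
#' `t ~ U(0, 1)` and, past the branch point `branch_time`, one of two
#' branch identities. Expression programs are smooth functions of `t`:
#' early genes decay (logistic), late genes rise (logistic), transient
#' genes follow Gaussian bumps, and branch-specific genes ramp up after
#' the branch point on one branch only.
#'
#' @param name population name (also its marker-panel cell type).
#' @param weight sampling weight relative to one discrete type.
#' @param n_marker_genes constitutive markers identifying the lineage.
#' @param marker_log2fc log2 fold change of those markers.
#' @param n_early,n_late,n_bump,n_branch gene counts per program class
#'   (`n_branch` applies to each branch).
#' @param program_log2fc peak log2 fold change of the time-varying
#'   programs (2 = 4-fold).
#' @param branch_time branch point `t_b` in (0, 1).
#' @return list of class `lineage_spec`.
#' @export
lineage_spec <- function(name = "somatic", weight = 2,
                         n_marker_genes = 10, marker_log2fc = 3,
                         n_early = 40, n_late = 40, n_bump = 20,
                         n_branch = 40, program_log2fc = 2,
                         branch_time = 0.5) {
  stopifnot(branch_time > 0, branch_time < 1, program_log2fc >= 0)
  structure(list(name = name, weight = weight,
                 n_marker_genes = n_marker_genes,
                 marker_log2fc = marker_log2fc,
                 n_early = n_early, n_late = n_late, n_bump = n_bump,
                 n_branch = n_branch, program_log2fc = program_log2fc,
                 branch_time = branch_time),
            class = "lineage_spec")
}

#' Default discrete cell types for the simulation
#'
#' @param n number of types (named after the non-ovarian populations a
#'   whole-ovary dissection captures; extra types are numbered).
#' @param n_marker_genes markers per type.
#' @param marker_log2fc marker log2 fold change in the owning type.
#' @return list of per-type lists (`name`, `n_marker_genes`,
#'   `marker_log2fc`).
#' @export
discrete_types <- function(n = 6, n_marker_genes = 10, marker_log2fc = 3) {
  base <- c("germline", "follicle", "muscle", "oviduct", "hemocyte",
            "fat_body", "trachea", "neuron")
  nm <- if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("type", seq_len(n - length(base))))
  lapply(nm, function(x) list(name = x, n_marker_genes = n_marker_genes,
                              marker_log2fc = marker_log2fc))
}

#' Build a simulation design
#'
#' Defaults define the package's reference simulation: 2,000 genes by
#' 3,000 cells, six well-separated discrete types (marker log2FC 3), a
#' 10% cross-type doublet rate, 20% cycling cells, ~0.3% mitochondrial
#' content, lognormal libraries around 7,000 UMIs, NB dispersion 0.25,
#' and planted out-of-range cells (debris, dying high-mito cells, and
#' over-loaded droplets) appended for QC validation.
#'
#' @param n_genes,n_cells matrix dimensions (planted QC-fail cells are
#'   appended on top of `n_cells`).
#' @param types list from [discrete_types()] (may be empty).
#' @param lineage a [lineage_spec()] or NULL.
#' @param doublet_rate per-cell doublet probability, in `[0, 0.5)`.
#' @param cycling_fraction fraction of cells in S or G2M (split evenly).
#' @param cc_log2fc log2 boost of the phase program in cycling cells.
#' @param n_cc_genes genes per cell-cycle program.
#' @param mito_mean_pct mean mitochondrial percentage (0-100 scale).
#' @param n_mito_genes number of `mt:` genes.
#' @param library_meanlog,library_sdlog lognormal library-size parameters.
#' @param nb_dispersion NB dispersion `alpha` (var = mu + alpha mu^2).
#' @param batch_shift_sd sd of the per-gene log2 batch effect applied to
#'   replicate 2 by [simulate_replicate_pair()].
#' @param qc_fail named counts of planted out-of-range cells
#'   (`low_gene`, `high_mito`, `high_umi`).
#' @param seed RNG seed; all randomness derives from it.
#' @return list of class `SimulationDesign`.
#' @export
simulation_design <- function(n_genes = 2000, n_cells = 3000,
                              types = discrete_types(6),
                              lineage = NULL,
                              doublet_rate = 0.1,
                              cycling_fraction = 0.2,
                              cc_log2fc = 2,
                              n_cc_genes = 40,
                              mito_mean_pct = 0.3,
                              n_mito_genes = 10,
                              library_meanlog = log(7000),
                              library_sdlog = 0.2,
                              nb_dispersion = 0.25,
                              batch_shift_sd = 0,
                              qc_fail = c(low_gene = 40, high_mito = 40,
                                          high_umi = 20),
                              seed = 1) {
  stopifnot(doublet_rate >= 0, doublet_rate < 0.5,
            cycling_fraction >= 0, cycling_fraction <= 1,
            nb_dispersion > 0, mito_mean_pct >= 0, mito_mean_pct < 100)
  qf <- c(low_gene = 0, high_mito = 0, high_umi = 0)
  qf[names(qc_fail)] <- qc_fail
  needed <- sum(vapply(types, function(x) x$n_marker_genes, 0)) +
    n_cc_genes * 2 + n_mito_genes +
    if (!is.null(lineage))
      lineage$n_marker_genes + lineage$n_early + lineage$n_late +
        lineage$n_bump + 2 * lineage$n_branch else 0
  if (needed > n_genes)
    stopf("infeasible design: %d program genes > %d genes", needed, n_genes)
  if (length(types) == 0 && is.null(lineage))
    stopf("design needs at least one population")
  structure(list(n_genes = n_genes, n_cells = n_cells, types = types,
                 lineage = lineage, doublet_rate = doublet_rate,
                 cycling_fraction = cycling_fraction,
                 cc_log2fc = cc_log2fc, n_cc_genes = n_cc_genes,
                 mito_mean_pct = mito_mean_pct,
                 n_mito_genes = n_mito_genes,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog,
                 nb_dispersion = nb_dispersion,
                 batch_shift_sd = batch_shift_sd,
                 qc_fail = qf, seed = seed),
            class = "SimulationDesign")
}

#' Reference branched-lineage design for trajectory validation
#'
#' A smaller, lineage-only design: 1,200 genes by 800 cells with a single
#' branch point at `t = 0.5`, 4-fold time-varying and branch-divergent
#' programs, no doublets, no cycling, no planted QC failures.
#'
#' @param n_genes,n_cells dimensions.
#' @param seed RNG seed.
#' @return A `SimulationDesign`.
#' @export
lineage_design <- function(n_genes = 1200, n_cells = 800, seed = 1) {
  simulation_design(
    n_genes = n_genes, n_cells = n_cells,
    types = list(), lineage = lineage_spec(weight = 1),
    doublet_rate = 0, cycling_fraction = 0,
    qc_fail = c(low_gene = 0, high_mito = 0, high_umi = 0),
    seed = seed)
}

# Deterministic model layer: gene roles, base abundances, program params.
build_sim_model <- function(design) {
  with_seed(design$seed + 104729L, {
    ng <- design$n_genes
    base <- stats::rgamma(ng, shape = 0.6, rate = 1)
    base <- pmax(base, 1e-4)
    role <- rep("background", ng)
    owner <- rep(NA_character_, ng)
    lfc <- rep(0, ng)
    center <- rep(NA_real_, ng)

    nxt <- 1L
    take <- function(k) {
      idx <- seq.int(nxt, length.out = k)
      nxt <<- nxt + k
      idx
    }
    # mitochondrial block: the few mt: transcripts are uniformly high,
    # so the block gets even shares summing to the target mito fraction
    mito_idx <- take(design$n_mito_genes)
    role[mito_idx] <- "mito"
    f <- design$mito_mean_pct / 100
    if (design$n_mito_genes > 0 && f > 0) {
      rest <- sum(base[-mito_idx])
      base[mito_idx] <- rest * (f / (1 - f)) / design$n_mito_genes
    }
    # cell-cycle programs: phase-restricted transcription (off outside
    # the phase, as for histones/cyclins), moderate on-state base
    s_idx <- take(design$n_cc_genes);  role[s_idx] <- "s_phase"
    g2m_idx <- take(design$n_cc_genes); role[g2m_idx] <- "g2m_phase"
    base[c(s_idx, g2m_idx)] <- stats::median(base) *
      stats::runif(2 * design$n_cc_genes, 0.8, 1.6)
    # discrete type markers: tissue-exclusive on/off expression around a
    # moderate base (boosted by log2fc in the owning type, suppressed by
    # log2fc elsewhere)
    for (ty in design$types) {
      idx <- take(ty$n_marker_genes)
      role[idx] <- "marker"
      owner[idx] <- ty$name
      lfc[idx] <- ty$marker_log2fc
      base[idx] <- stats::median(base) * stats::runif(length(idx), 0.3, 0.5)
    }
    lin <- design$lineage
    if (!is.null(lin)) {
      idx <- take(lin$n_marker_genes)
      role[idx] <- "marker"; owner[idx] <- lin$name
      lfc[idx] <- lin$marker_log2fc
      base[idx] <- stats::median(base) * stats::runif(length(idx), 0.3, 0.5)
      prog <- function(k, what, centers) {
        idx <- take(k)
        role[idx] <<- what; owner[idx] <<- lin$name
        lfc[idx] <<- lin$program_log2fc
        center[idx] <<- centers
        base[idx] <<- stats::median(base) * stats::runif(k, 0.8, 1.6)
      }
      prog(lin$n_early, "lineage_early",
           stats::runif(lin$n_early, 0.15, 0.5))
      prog(lin$n_late, "lineage_late", stats::runif(lin$n_late, 0.5, 0.9))
      prog(lin$n_bump, "lineage_bump", stats::runif(lin$n_bump, 0.2, 0.85))
      prog(lin$n_branch, "branch_a", NA)
      prog(lin$n_branch, "branch_b", NA)
    }
    symbols <- sprintf("gene%04d", seq_len(ng))
    symbols[mito_idx] <- sprintf("mt:gene%02d", seq_along(mito_idx))
    gene_info <- data.frame(
      gene_id = sprintf("SIMG%06d", seq_len(ng)),
      symbol = symbols, role = role, owner = owner, log2fc = lfc,
      center = center, base = base, stringsAsFactors = FALSE)
    pops <- c(vapply(design$types, `[[`, "", "name"),
              if (!is.null(lin)) lin$name)
    wts <- c(rep(1, length(design$types)), if (!is.null(lin)) lin$weight)
    shift <- if (design$batch_shift_sd > 0)
      stats::rnorm(ng, 0, design$batch_shift_sd) else rep(0, ng)
    list(gene_info = gene_info, populations = pops,
         pop_weights = wts / sum(wts), batch_shift = shift)
  })
}

# Relative expression profile (sums to 1) for one cell state.
cell_profile <- function(model, design, type, t = NA, branch = NA,
                         phase = "G1", mito_scale = 1, batch = FALSE) {
  gi <- model$gene_info
  l2 <- numeric(nrow(gi))
  # markers are on/off: boosted in the owning type, suppressed elsewhere
  mk_all <- gi$role == "marker"
  l2[mk_all] <- -gi$log2fc[mk_all]
  mk <- mk_all & !is.na(gi$owner) & gi$owner == type
  l2[mk] <- gi$log2fc[mk]
  if (!is.na(t)) {
    r <- gi$role
    i <- r == "lineage_early"
    l2[i] <- gi$log2fc[i] * (1 - stats::plogis((t - gi$center[i]) / 0.08))
    i <- r == "lineage_late"
    l2[i] <- gi$log2fc[i] * stats::plogis((t - gi$center[i]) / 0.08)
    i <- r == "lineage_bump"
    l2[i] <- gi$log2fc[i] * exp(-(t - gi$center[i])^2 / (2 * 0.1^2))
    # fate commitment: branch programs switch on logistically over a
    # short window after the branch point
    t_b <- design$lineage$branch_time
    ramp <- if (t > t_b)
      stats::plogis((t - t_b - 0.1) / 0.04) else 0
    if (!is.na(branch) && ramp > 0) {
      if (branch == "A") {
        i <- r == "branch_a"; l2[i] <- gi$log2fc[i] * ramp
      } else if (branch == "B") {
        i <- r == "branch_b"; l2[i] <- gi$log2fc[i] * ramp
      }
    }
  }
  # phase-restricted: each program is boosted in its phase and
  # suppressed (off state) in every other phase
  l2[gi$role == "s_phase"] <-
    if (phase == "S") design$cc_log2fc else -design$cc_log2fc
  l2[gi$role == "g2m_phase"] <-
    if (phase == "G2M") design$cc_log2fc else -design$cc_log2fc
  p <- gi$base * 2^l2
  if (mito_scale != 1) p[gi$role == "mito"] <- p[gi$role == "mito"] * mito_scale
  if (batch) p <- p * 2^model$batch_shift
  p / sum(p)
}

#' Expected (noiseless) lineage expression profile
#'
#' Relative gene abundances at latent time `t` on a branch — the mean of
#' the generative model before library-size scaling and NB sampling.
#' Useful to verify that planted pseudotime is recoverable in principle.
#'
#' @param sim result of [simulate_atlas()] on a design with a lineage.
#' @param t latent times in `[0, 1]`.
#' @param branch `"A"` or `"B"` (relevant past the branch point).
#' @return matrix (length(t) x genes) of relative abundances.
#' @export
expected_lineage_profile <- function(sim, t, branch = "A") {
  stopifnot(inherits(sim, "AtlasSimulation"), !is.null(sim$design$lineage))
  model <- list(gene_info = sim$gene_info, batch_shift = 0)
  out <- t(vapply(t, function(tt)
    cell_profile(model, sim$design, sim$design$lineage$name, tt, branch),
    numeric(nrow(sim$gene_info))))
  colnames(out) <- sim$gene_info$gene_id
  out
}

draw_nb_counts <- function(p_mat, libs, alpha) {
  # p_mat: cells x genes relative profiles; returns sparse counts
  n <- nrow(p_mat); g <- ncol(p_mat)
  mu <- p_mat * libs
  counts <- matrix(stats::rnbinom(n * g, size = 1 / alpha, mu = mu), n, g)
  methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
}

#' Simulate a synthetic atlas with full ground truth
#'
#' Draws singlet cells from the design's populations (NB counts over
#' smooth per-state expression programs), forms cross-type doublets by
#' summing two parents' counts and multinomially downsampling to a typical
#' library size, and appends planted out-of-range cells for QC
#' validation. Deterministic under the design seed.
#'
#' @param design a [simulation_design()].
#' @return list of class `AtlasSimulation`:
#'   `counts` ([count_matrix()]), `truth` (per-cell data.frame: barcode,
#'   true_type, t, branch, phase, is_doublet, parent1/parent2,
#'   parent_types, batch, qc_fail, qc_reason), `panel`
#'   ([marker_panel()] of the planted type markers with cross-type
#'   conflict groups), `gene_info`, `s_genes`, `g2m_genes`, `design`.
#' @export
simulate_atlas <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  model <- build_sim_model(design)
  sim_draw(model, design, design$n_cells, seed = design$seed,
           batch = FALSE, label = "REPL1")
}

sim_draw <- function(model, design, n_cells, seed, batch = FALSE,
                     pop_weights = NULL, label = "REPL1") {
  gi <- model$gene_info
  if (is.null(pop_weights)) pop_weights <- model$pop_weights
  lin <- design$lineage
  with_seed(seed, {
    n_doub <- stats::rbinom(1, n_cells, design$doublet_rate)
    n_sing <- n_cells - n_doub
    if (n_doub > 0 && length(model$populations) < 2)
      stopf("doublets require at least two populations")

    type <- sample(model$populations, n_sing, replace = TRUE,
                   prob = pop_weights)
    tvec <- rep(NA_real_, n_sing)
    branch <- rep(NA_character_, n_sing)
    if (!is.null(lin)) {
      is_lin <- type == lin$name
      tvec[is_lin] <- stats::runif(sum(is_lin))
      branch[is_lin] <- ifelse(tvec[is_lin] < lin$branch_time, "pre",
                               sample(c("A", "B"), sum(is_lin),
                                      replace = TRUE))
    }
    phase <- rep("G1", n_sing)
    cyc <- stats::runif(n_sing) < design$cycling_fraction
    phase[cyc] <- sample(c("S", "G2M"), sum(cyc), replace = TRUE)

    # cells without a latent time share a profile per (type, phase)
    prof <- matrix(0, n_sing, design$n_genes)
    static <- is.na(tvec)
    if (any(static)) {
      key <- paste(type[static], phase[static])
      for (kk in unique(key)) {
        rows <- which(static)[key == kk]
        prof[rows, ] <- rep(
          cell_profile(model, design, type[rows[1]],
                       phase = phase[rows[1]], batch = batch),
          each = length(rows))
      }
    }
    for (i in which(!static)) {
      prof[i, ] <- cell_profile(model, design, type[i], tvec[i], branch[i],
                                phase[i], batch = batch)
    }
    libs <- stats::rlnorm(n_sing, design$library_meanlog,
                          design$library_sdlog)
    counts <- draw_nb_counts(prof, libs, design$nb_dispersion)

    # doublets: two parents of differing types, summed then downsampled
    parent1 <- parent2 <- rep(NA_integer_, n_sing)
    if (n_doub > 0) {
      dmat <- matrix(0, n_doub, design$n_genes)
      parent1 <- parent2 <- integer(n_doub)
      for (d in seq_len(n_doub)) {
        repeat {
          pp <- sample.int(n_sing, 2)
          if (type[pp[1]] != type[pp[2]]) break
        }
        parent1[d] <- pp[1]; parent2[d] <- pp[2]
        tot <- counts[pp[1], ] + counts[pp[2], ]
        target <- round(stats::rlnorm(1, design$library_meanlog,
                                      design$library_sdlog))
        tot <- as.numeric(tot)
        if (sum(tot) > target)
          tot <- as.numeric(stats::rmultinom(1, target, prob = tot))
        dmat[d, ] <- tot
      }
      counts <- rbind(counts,
                      methods::as(Matrix::Matrix(dmat, sparse = TRUE),
                                  "generalMatrix"))
    }

    # planted out-of-range cells
    qf <- design$qc_fail
    n_qf <- sum(qf)
    qf_reason <- rep(c("low_gene", "high_mito", "high_umi"), qf)
    if (n_qf > 0) {
      qtype <- sample(model$populations, n_qf, replace = TRUE,
                      prob = pop_weights)
      qprof <- matrix(0, n_qf, design$n_genes)
      qlibs <- numeric(n_qf)
      for (i in seq_len(n_qf)) {
        ms <- if (qf_reason[i] == "high_mito") {
          # dying cell: mitochondrial share ~5%, far above the 1% gate
          f <- design$mito_mean_pct / 100
          (0.05 / (1 - 0.05)) / (f / (1 - f))
        } else 1
        qprof[i, ] <- cell_profile(model, design, qtype[i],
                                   phase = "G1", mito_scale = ms,
                                   batch = batch)
        qlibs[i] <- switch(qf_reason[i],
          low_gene = stats::rlnorm(1, log(300), 0.2),
          high_umi = stats::rlnorm(1, log(30000), 0.08),
          stats::rlnorm(1, design$library_meanlog, design$library_sdlog))
      }
      counts <- rbind(counts, draw_nb_counts(qprof, qlibs,
                                             design$nb_dispersion))
    }

    n_tot <- n_sing + n_doub + n_qf
    barcodes <- sprintf("%s-CELL%05d", label, seq_len(n_tot))
    truth <- data.frame(
      barcode = barcodes,
      true_type = c(type, rep(NA_character_, n_doub),
                    if (n_qf) qtype else character(0)),
      t = c(tvec, rep(NA_real_, n_doub + n_qf)),
      branch = c(branch, rep(NA_character_, n_doub + n_qf)),
      phase = c(phase, rep(NA_character_, n_doub),
                rep("G1", n_qf)),
      is_doublet = rep(c(FALSE, TRUE, FALSE), c(n_sing, n_doub, n_qf)),
      parent1 = c(rep(NA_integer_, n_sing),
                  if (n_doub) parent1[seq_len(n_doub)] else integer(0),
                  rep(NA_integer_, n_qf)),
      parent2 = c(rep(NA_integer_, n_sing),
                  if (n_doub) parent2[seq_len(n_doub)] else integer(0),
                  rep(NA_integer_, n_qf)),
      batch = label,
      qc_fail = rep(c(FALSE, FALSE, TRUE), c(n_sing, n_doub, n_qf)),
      qc_reason = c(rep(NA_character_, n_sing + n_doub), qf_reason),
      stringsAsFactors = FALSE)
    truth$parent_types <- NA_character_
    if (any(truth$is_doublet)) {
      di <- which(truth$is_doublet)
      truth$parent_types[di] <- paste(type[truth$parent1[di]],
                                      type[truth$parent2[di]], sep = "+")
    }

    cm <- count_matrix(counts, barcodes, gi$gene_id, gi$symbol)
    mk <- gi$role == "marker"
    panel_df <- data.frame(gene = gi$gene_id[mk],
                           cell_type = gi$owner[mk],
                           conflict_group = gi$owner[mk],
                           stringsAsFactors = FALSE)
    panel <- if (nrow(panel_df)) marker_panel(panel_df) else NULL
    structure(list(counts = cm, truth = truth, panel = panel,
                   gene_info = gi,
                   s_genes = gi$gene_id[gi$role == "s_phase"],
                   g2m_genes = gi$gene_id[gi$role == "g2m_phase"],
                   design = design),
              class = "AtlasSimulation")
  })
}

#' @export
print.AtlasSimulation <- function(x, ...) {
  cat(sprintf(
    "AtlasSimulation: %d cells x %d genes; %d doublets, %d planted QC fails\n",
    nrow(x$counts$counts), ncol(x$counts$counts),
    sum(x$truth$is_doublet), sum(x$truth$qc_fail)))
  invisible(x)
}

#' Simulate a replicate pair sharing one biological model
#'
#' Both replicates are drawn from the same generative model (same gene
#' roles, base abundances and programs); replicate 2 cells are drawn with
#' an independent seed, its gene means multiplied by `2^shift_g` where
#' `shift_g ~ N(0, batch_shift_sd)`, and its population composition
#' optionally thinned (emulating reduced sampling of rarer cell types).
#'
#' @param design a [simulation_design()].
#' @param n_cells2 replicate-2 cell count (default: half of replicate 1).
#' @param subsample named numeric vector of per-population weight
#'   multipliers for replicate 2 (0 removes a population).
#' @return list with `rep1` and `rep2` (each an `AtlasSimulation`) and
#'   `batch_shift` (the per-gene log2 shift applied to replicate 2).
#' @export
simulate_replicate_pair <- function(design, n_cells2 = NULL,
                                    subsample = NULL) {
  stopifnot(inherits(design, "SimulationDesign"))
  model <- build_sim_model(design)
  if (is.null(n_cells2)) n_cells2 <- ceiling(design$n_cells / 2)
  w2 <- model$pop_weights
  if (!is.null(subsample)) {
    idx <- match(names(subsample), model$populations)
    if (anyNA(idx)) stopf("subsample names unknown population")
    w2[idx] <- w2[idx] * subsample
    if (all(w2 == 0)) stopf("subsample removed every population")
    w2 <- w2 / sum(w2)
  }
  rep1 <- sim_draw(model, design, design$n_cells, seed = design$seed + 1L,
                   batch = FALSE, label = "REPL1")
  rep2 <- sim_draw(model, design, n_cells2, seed = design$seed + 2L,
                   batch = TRUE, pop_weights = w2, label = "REPL2")
  list(rep1 = rep1, rep2 = rep2, batch_shift = model$batch_shift)
}
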