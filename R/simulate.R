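# Synthetic-data generators: disease-stage cohorts with MMSE and NFT scores,
# expression matrices with planted stage-specific correlated genes,
# scale-free PPI networks, and overlapping process gene sets.

#' Simulation configuration
#'
#' Default values mirror a small hippocampal microarray cohort: 22 disease
#' samples in three stage groups (7 early, 8 medium, 7 late) plus 9
#' controls; MMSE approximately normal within each group and decreasing with
#' severity; NFT burden whose square root is approximately normal and
#' increasing with severity.  Power-oriented tests typically raise the
#' per-stage sample sizes, since n of about 7 per stage has little power by
#' construction.
#'
#' @param seed integer seed (optional); all generators are deterministic
#'   given the seed.
#' @param n_control,n_early,n_medium,n_late samples per group.
#' @param mmse_mean,mmse_sd named numeric vectors (control/early/medium/late)
#'   of MMSE means and standard deviations; draws are truncated to
#'   \[0, 30\] and rounded to integers.
#' @param sqrt_nft_mean,sqrt_nft_sd group means / sds of the square root of
#'   the NFT score; draws are truncated at 0 and squared to give NFT.
#' @param n_genes number of genes in the expression matrix.
#' @param n_planted number of planted correlated genes (spread round-robin
#'   over the six stage x score cells).
#' @param target_r2 population squared correlation of each planted gene with
#'   its score within its stage.
#' @param noise_sd expression noise standard deviation (log2 units).
#' @param call_absent_frac,call_marginal_frac per-cell probabilities of `A`
#'   and `M` detection calls.
#' @param ppi_nodes,ppi_edges_per_node scale-free network size and edges
#'   added per new node.
#' @param n_process_sets,set_size_range,overlap_fraction gene-set collection
#'   shape: number of sets, uniform size range, and fraction of each set
#'   drawn from a shared core pool (0 gives pairwise-disjoint sets).
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = NULL,
                              n_control = 9, n_early = 7, n_medium = 8,
                              n_late = 7,
                              mmse_mean = c(control = 28.5, early = 23.5,
                                            medium = 18, late = 10),
                              mmse_sd = c(control = 1.5, early = 3,
                                          medium = 3.5, late = 4),
                              sqrt_nft_mean = c(control = 0.8, early = 1.8,
                                                medium = 2.6, late = 3.4),
                              sqrt_nft_sd = c(control = 0.5, early = 0.6,
                                              medium = 0.6, late = 0.6),
                              n_genes = 2000, n_planted = 0,
                              target_r2 = 0.6, noise_sd = 1,
                              call_absent_frac = 0.1,
                              call_marginal_frac = 0.05,
                              ppi_nodes = 2000, ppi_edges_per_node = 6,
                              n_process_sets = 20,
                              set_size_range = c(15, 60),
                              overlap_fraction = 0.1) {
  cfg <- list(seed = seed, n_control = n_control, n_early = n_early,
              n_medium = n_medium, n_late = n_late,
              mmse_mean = mmse_mean, mmse_sd = mmse_sd,
              sqrt_nft_mean = sqrt_nft_mean, sqrt_nft_sd = sqrt_nft_sd,
              n_genes = n_genes, n_planted = n_planted,
              target_r2 = target_r2, noise_sd = noise_sd,
              call_absent_frac = call_absent_frac,
              call_marginal_frac = call_marginal_frac,
              ppi_nodes = ppi_nodes,
              ppi_edges_per_node = ppi_edges_per_node,
              n_process_sets = n_process_sets,
              set_size_range = set_size_range,
              overlap_fraction = overlap_fraction)
  with(cfg, {
    stopifnot(n_control > 0, n_early > 0, n_medium > 0, n_late > 0,
              n_genes > 0, n_planted >= 0,
              target_r2 > 0, target_r2 < 1, noise_sd > 0,
              call_absent_frac >= 0, call_marginal_frac >= 0,
              call_absent_frac + call_marginal_frac < 1,
              overlap_fraction >= 0, overlap_fraction < 1,
              length(set_size_range) == 2,
              set_size_range[1] <= set_size_range[2])
  })
  stopifnot(all(GROUP_LABELS %in% names(cfg$mmse_mean)),
            all(GROUP_LABELS %in% names(cfg$sqrt_nft_mean)))
  structure(cfg, class = "simulation_config")
}

# truncated-normal draws by rejection; errors out if the feasible mass is
# negligible (mean far outside the bounds)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mass <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  if (mass < 1e-6)
    stop("infeasible truncation: N(", mean, ", ", sd, ") has essentially no ",
         "mass in [", lower, ", ", upper, "]", call. = FALSE)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(ceiling((n - length(out)) / mass * 1.2) + 8, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a disease-stage cohort
#'
#' Draws per-group MMSE scores (truncated normal on \[0, 30\], rounded to
#' integers, decreasing with severity) and NFT scores (square root drawn
#' truncated-normal at 0 and then squared, increasing with severity).
#'
#' @param cfg a [simulation_config()].
#' @return a sample metadata data frame (`sample_id`, `group`, `mmse`,
#'   `nft`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ns <- c(control = cfg$n_control, early = cfg$n_early,
          medium = cfg$n_medium, late = cfg$n_late)
  rows <- lapply(GROUP_LABELS, function(g) {
    n <- ns[[g]]
    mmse <- round(rnorm_trunc(n, cfg$mmse_mean[[g]], cfg$mmse_sd[[g]],
                              0, 30))
    snft <- rnorm_trunc(n, cfg$sqrt_nft_mean[[g]], cfg$sqrt_nft_sd[[g]],
                        lower = 0)
    data.frame(group = g, mmse = as.integer(mmse), nft = snft^2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(out))), out)
  validate_sample_metadata(out)
}

#' Simulate an expression matrix with planted correlated genes
#'
#' Null genes are independent Gaussian noise.  Each planted gene is tied to
#' one (stage, score) cell: over that stage's samples its expression is a
#' linear function of the (standardized) score plus noise, with the slope
#' and noise scaled so the population squared correlation equals
#' `cfg$target_r2` given the realized scores; all other samples are pure
#' noise.  Planted direction alternates up/down, with `down` meaning the
#' clinical convention (positive correlation with MMSE, negative with
#' sqrt(NFT)).  A detection-call matrix is drawn with the configured
#' absent/marginal fractions.
#'
#' @param cohort a cohort data frame from [simulate_cohort()].
#' @param cfg a [simulation_config()].
#' @return a list of class `synthetic_cohort`: `dataset` (an
#'   [expression_dataset], log2 scale), `samples` (the cohort), and `truth`
#'   (data frame `gene_id`, `stage`, `score_type`, `direction`,
#'   `target_r2`; empty when nothing is planted).
#' @export
simulate_expression <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$target_r2 >= 1 || cfg$target_r2 <= 0)
    stop("target_r2 must lie strictly between 0 and 1", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  n_s <- nrow(cohort)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  vals <- matrix(rnorm(cfg$n_genes * n_s, 0, cfg$noise_sd),
                 nrow = cfg$n_genes,
                 dimnames = list(gene_ids, cohort$sample_id))

  truth <- data.frame(gene_id = character(0), stage = character(0),
                      score_type = character(0), direction = character(0),
                      target_r2 = numeric(0), stringsAsFactors = FALSE)
  if (cfg$n_planted > 0) {
    if (cfg$n_planted > cfg$n_genes)
      stop("cannot plant more genes than exist", call. = FALSE)
    cells <- expand.grid(stage = STAGE_LABELS, score_type = SCORE_TYPES,
                         stringsAsFactors = FALSE)
    pick <- cells[rep(seq_len(nrow(cells)),
                      length.out = cfg$n_planted), , drop = FALSE]
    planted_ids <- gene_ids[seq_len(cfg$n_planted)]
    direction <- rep(c("up", "down"), length.out = cfg$n_planted)
    r2 <- cfg$target_r2
    for (i in seq_len(cfg$n_planted)) {
      st <- pick$stage[i]; sc <- pick$score_type[i]
      idx <- which(cohort$group == st)
      v <- if (sc == "MMSE") cohort$mmse[idx] else sqrt(cohort$nft[idx])
      vz <- (v - mean(v)) / sd(v)
      # clinical direction: down <=> positive r with MMSE / negative with NFT
      sgn <- if (direction[i] == "down") 1 else -1
      if (sc == "sqrtNFT") sgn <- -sgn
      vals[planted_ids[i], idx] <-
        cfg$noise_sd * (sgn * sqrt(r2) * vz +
                          sqrt(1 - r2) * rnorm(length(idx)))
    }
    truth <- data.frame(gene_id = planted_ids, stage = pick$stage,
                        score_type = pick$score_type, direction = direction,
                        target_r2 = r2, stringsAsFactors = FALSE)
  }
  pp <- 1 - cfg$call_absent_frac - cfg$call_marginal_frac
  calls <- matrix(sample(c("P", "M", "A"), cfg$n_genes * n_s, replace = TRUE,
                         prob = c(pp, cfg$call_marginal_frac,
                                  cfg$call_absent_frac)),
                  nrow = cfg$n_genes)
  ds <- expression_dataset(vals, calls = calls, log2_scale = TRUE)
  structure(list(dataset = ds, samples = cohort, truth = truth),
            class = "synthetic_cohort")
}

#' Simulate a scale-free PPI network
#'
#' Preferential-attachment (Barabasi-Albert) growth: each new node attaches
#' to `ppi_edges_per_node` existing nodes with probability proportional to
#' degree, yielding a connected hub-dominated graph.  Node labels are drawn
#' from the simulated gene universe.
#'
#' @param cfg a [simulation_config()].
#' @return an edge-list data frame (`from`, `to`).
#' @export
simulate_ppi_network <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$ppi_nodes < 10)
    stop("need at least 10 network nodes", call. = FALSE)
  if (cfg$ppi_edges_per_node >= cfg$ppi_nodes)
    stop("edges per node must be smaller than the node count", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2L)
  g <- igraph::sample_pa(cfg$ppi_nodes, m = cfg$ppi_edges_per_node,
                         directed = FALSE)
  labels <- sprintf("G%05d", seq_len(cfg$ppi_nodes))
  el <- igraph::as_edgelist(g, names = FALSE)
  data.frame(from = labels[el[, 1]], to = labels[el[, 2]],
             stringsAsFactors = FALSE)
}

#' Simulate overlapping process gene sets
#'
#' Each set draws `overlap_fraction` of its members from a shared core pool
#' (producing pairwise overlap) and the rest from the remaining universe
#' without replacement across sets, so `overlap_fraction = 0` yields
#' pairwise-disjoint sets.  Optionally, planted genes are concentrated into
#' the first set(s) to create genuine enrichment.
#'
#' @param cfg a [simulation_config()].
#' @param gene_ids gene universe; defaults to the configured expression
#'   genes.
#' @param enrich_with optional character vector of genes (e.g. planted AD
#'   genes) packed into the first set.
#' @return a `gene_set_collection`.
#' @export
simulate_gene_sets <- function(cfg, gene_ids = NULL, enrich_with = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 3L)
  gene_ids <- gene_ids %||% sprintf("G%05d", seq_len(cfg$n_genes))
  sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                  cfg$n_process_sets, replace = TRUE)
  core_sizes <- round(sizes * cfg$overlap_fraction)
  n_core <- max(core_sizes) * 2 + 1
  n_private <- sum(sizes - core_sizes)
  if (n_core + n_private > length(gene_ids))
    stop("gene universe too small for the requested sets and overlap",
         call. = FALSE)
  pool <- sample(gene_ids)
  core_pool <- pool[seq_len(n_core)]
  private_pool <- pool[-seq_len(n_core)]
  sets <- vector("list", cfg$n_process_sets)
  off <- 0
  for (i in seq_len(cfg$n_process_sets)) {
    priv <- private_pool[off + seq_len(sizes[i] - core_sizes[i])]
    off <- off + sizes[i] - core_sizes[i]
    core <- if (core_sizes[i] > 0) sample(core_pool, core_sizes[i])
            else character(0)
    sets[[i]] <- unique(c(core, priv))
  }
  names(sets) <- sprintf("process_%02d", seq_len(cfg$n_process_sets))
  if (!is.null(enrich_with) && length(enrich_with)) {
    s1 <- sets[[1]]
    take <- min(length(enrich_with), length(s1))
    sets[[1]] <- unique(c(enrich_with[seq_len(take)],
                          s1[seq_len(length(s1) - take)]))
  }
  structure(sets,
            descriptions = stats::setNames(rep("simulated", length(sets)),
                                           names(sets)),
            class = "gene_set_collection")
}
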