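#' Synthetic benchmark configuration
#'
#' Describes a synthetic study emulating a literature-curated benchmark of
#' mutant trios: ~300 gene pairs with a roughly 190:110
#' redundant:nonredundant balance, mixed-type gene features in the six
#' standard categories, planted class-associated effects, and ordinal
#' phenotype emission. Defaults:
#'
#' * `n_pairs = 300`, `prevalence = 190/300` (latent redundancy rate);
#' * 30 base features: 16 continuous (11 expression/evolution-like on a
#'   log-normal scale, 5 percent-methylation-like on 0-100), 10 binary
#'   (duplication-mechanism, epigenetic and protein-modification flags,
#'   Bernoulli 0.3), 4 categorical (three annotation token sets and one
#'   coexpression-cluster id);
#' * planted effects: +1.5 SD shifts on `expr_breadth`, `expr_root` and
#'   `cpg_root`, -1.5 SD on `ks_rate` and `stress_down_breadth` (redundant
#'   pairs are younger, broadly expressed, less stress-responsive);
#'   log-odds +2 on the `wgd_flag` and `alpha_wgd_flag` duplication flags;
#'   coexpression co-membership probability 0.6 (redundant) vs 0.1
#'   (nonredundant);
#' * `emission_noise = 0.05`: the probability that a pair's phenotype trio
#'   is drawn from the other latent class's emission table (phenotype
#'   misclassification); with `emission_noise = 0` the inclusive
#'   redundancy label recovers the latent state exactly;
#' * `reuse_rate = 0.05`: small probability that a pair re-uses a gene
#'   from an earlier pair of the same latent state (paralog sets share
#'   genes); set `share_genes = FALSE` for fully independent pairs.
#'
#' @param n_pairs number of mutant trios.
#' @param prevalence latent redundancy probability.
#' @param continuous_effects named vector of standardized mean shifts.
#' @param binary_effects named vector of log-odds shifts.
#' @param cluster_effect length-2 vector: co-membership probability for
#'   redundant and nonredundant pairs.
#' @param emission_noise phenotype-emission flip probability.
#' @param share_genes,reuse_rate gene sharing across pairs.
#' @param phenotype_tables list with `redundant` and `nonredundant`
#'   data.frames (`sm_a`, `sm_b`, `dm`, `prob`).
#' @return object of class `syn_config`.
#' @export
syn_config <- function(n_pairs = 300,
                       prevalence = 190 / 300,
                       continuous_effects = c(expr_breadth = 1.5, expr_root = 1.5,
                                              cpg_root = 1.5, ks_rate = -1.5,
                                              stress_down_breadth = -1.5),
                       binary_effects = c(wgd_flag = 2, alpha_wgd_flag = 2),
                       cluster_effect = c(redundant = 0.6, nonredundant = 0.1),
                       emission_noise = 0.05,
                       share_genes = TRUE, reuse_rate = 0.05,
                       phenotype_tables = default_phenotype_tables()) {
  stopifnot(prevalence > 0, prevalence < 1, n_pairs >= 1,
            all(is.finite(continuous_effects)), all(is.finite(binary_effects)),
            emission_noise >= 0, emission_noise <= 1)
  for (tab in phenotype_tables) {
    stopifnot(abs(sum(tab$prob) - 1) < 1e-8, all(tab$prob >= 0))
  }
  features <- data.frame(
    name = c(
      # log-normal-scale continuous: expression levels/breadths, rates
      "expr_root", "expr_leaf", "expr_devstage", "expr_hormone",
      "expr_circadian", "expr_breadth", "stress_down_breadth",
      "stress_up_breadth", "ks_rate", "ka_rate", "gene_family_size",
      # percent-scale continuous: methylation levels, retention
      "cpg_root", "cpg_sperm", "chg_body", "chh_leaf", "retention_pct",
      # binary flags: duplication mechanism, epigenetic/protein marks
      "wgd_flag", "alpha_wgd_flag", "beta_wgd_flag", "tandem_flag",
      "proximal_flag", "reciprocal_best", "dnase_peak", "h3k4me3",
      "myristoylation", "acetylation",
      # categorical: annotation token sets, coexpression cluster id
      "go_slim", "pfam_domains", "aracyc_pathways", "coexpr_cluster"),
    data_type = c(rep("continuous", 16), rep("binary", 10),
                  rep("categorical", 4)),
    category = c(rep("expression", 8), rep("evolutionary property", 3),
                 rep("epigenetic", 4), "evolutionary property",
                 rep("evolutionary property", 6), "epigenetic", "epigenetic",
                 "protein property", "protein property",
                 rep("functional annotation", 3), "network"),
    kind = c(rep("lognormal", 11), rep("percent", 5), rep("bernoulli", 10),
             rep("tokens", 3), "cluster")
  )
  stopifnot(all(names(continuous_effects) %in%
                  features$name[features$data_type == "continuous"]),
            all(names(binary_effects) %in%
                  features$name[features$data_type == "binary"]))
  structure(
    list(n_pairs = n_pairs, prevalence = prevalence,
         continuous_effects = continuous_effects,
         binary_effects = binary_effects, cluster_effect = cluster_effect,
         emission_noise = emission_noise, share_genes = share_genes,
         reuse_rate = reuse_rate, phenotype_tables = phenotype_tables,
         features = features),
    class = "syn_config"
  )
}

#' Default phenotype-emission tables
#'
#' Conditional distributions over `(sm_a, sm_b, dm)` class triples given
#' the latent redundancy state. The redundant table weights
#' severe-double-mutant trios (class 0/0 single mutants with a lethal
#' double mutant) heavily enough that the extreme-redundancy subset is
#' well populated at n = 300, while still exercising the subtle
#' definitions (at least one abnormal single mutant); the nonredundant
#' table covers trios where a single mutant matches or exceeds the double
#' mutant.
#'
#' @return list with data.frames `redundant` and `nonredundant`.
#' @export
default_phenotype_tables <- function() {
  list(
    redundant = data.frame(
      sm_a = c("0", "0", "0", "0", "1A", "1A", "1B", "1A"),
      sm_b = c("0", "0", "0", "0", "0", "1A", "0", "0"),
      dm = c("2", "1C", "1B", "1A", "1C", "2", "2", "1B"),
      prob = c(0.35, 0.20, 0.08, 0.05, 0.10, 0.07, 0.07, 0.08)
    ),
    nonredundant = data.frame(
      sm_a = c("1C", "1A", "1B", "1C", "2", "1B", "1C", "2"),
      sm_b = c("0", "0", "1B", "1C", "1A", "0", "0", "0"),
      dm = c("1C", "0", "1B", "1A", "1A", "1A", "0", "2"),
      prob = c(0.15, 0.12, 0.12, 0.10, 0.10, 0.13, 0.13, 0.15)
    )
  )
}

#' Scale all planted effect sizes
#'
#' Multiplies the continuous and binary effects by `factor` and moves the
#' redundant-class cluster co-membership probability proportionally toward
#' the nonredundant baseline. `scale_effects(config, 0)` is the null
#' configuration (no signal).
#'
#' @param config a `syn_config`.
#' @param factor nonnegative multiplier.
#' @return modified `syn_config`.
#' @export
scale_effects <- function(config, factor) {
  stopifnot(inherits(config, "syn_config"), factor >= 0)
  config$continuous_effects <- config$continuous_effects * factor
  config$binary_effects <- config$binary_effects * factor
  base <- config$cluster_effect[["nonredundant"]]
  config$cluster_effect[["redundant"]] <-
    base + (config$cluster_effect[["redundant"]] - base) * factor
  config
}

# internal: token pools for categorical annotation features
token_pool <- function(feat) {
  switch(feat,
         go_slim = sprintf("GO:%04d", 1:40),
         pfam_domains = sprintf("PF%05d", 1:30),
         aracyc_pathways = sprintf("PWY-%03d", 1:25),
         stop("no token pool for feature ", feat))
}

# internal: one gene's feature values conditional on the latent state
draw_gene_values <- function(config, r, n_clusters = 20) {
  f <- config$features
  vals <- list()
  for (k in seq_len(nrow(f))) {
    nm <- f$name[k]
    vals[[nm]] <- switch(
      f$kind[k],
      lognormal = {
        shift <- if (nm %in% names(config$continuous_effects))
          r * config$continuous_effects[[nm]] else 0
        round(exp(stats::rnorm(1, mean = 1 + shift, sd = 1)), 4)
      },
      percent = {
        shift <- if (nm %in% names(config$continuous_effects))
          r * config$continuous_effects[[nm]] * 15 else 0
        round(min(100, max(0, stats::rnorm(1, mean = 50 + shift, sd = 15))), 2)
      },
      bernoulli = {
        lo <- stats::qlogis(0.3) +
          if (nm %in% names(config$binary_effects)) r * config$binary_effects[[nm]] else 0
        stats::rbinom(1, 1, stats::plogis(lo))
      },
      tokens = {
        pool <- token_pool(nm)
        paste(sort(sample(pool, sample(3:8, 1))), collapse = ";")
      },
      cluster = NA  # assigned at the pair level
    )
  }
  vals
}

#' Generate a gene-level attribute table
#'
#' Draws `n_genes` genes from the baseline (nonredundant-state) feature
#' distributions of a synthetic configuration: log-normal expression-like
#' values, uniform-ish percent-methylation values in `[0, 100]`, Bernoulli
#' binary flags, annotation token sets, and coexpression cluster ids.
#' Deterministic under `seed`.
#'
#' @param config a `syn_config`.
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return list with `genes` (data.frame, column `gene` plus one column
#'   per feature) and `schema`.
#' @export
generate_gene_table <- function(config = syn_config(), n_genes = 100, seed = 1) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_genes), function(i) {
      v <- draw_gene_values(config, r = 0)
      v$coexpr_cluster <- paste0("cl", sample(20, 1))
      c(list(gene = sprintf("G%05d", i)), v)
    })
    genes <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  })
  list(genes = genes,
       schema = config$features[, c("name", "data_type", "category")])
}

#' Generate a synthetic mutant-trio benchmark with planted signal
#'
#' For each of `n_pairs` gene pairs a latent redundancy state is drawn
#' (`Bernoulli(prevalence)`); the two genes' feature values are drawn with
#' the configured effects applied under the redundant state (mean shifts
#' on planted continuous features, log-odds shifts on planted binary
#' flags, elevated coexpression co-membership); and a phenotype trio is
#' emitted from the latent state's conditional class table, flipped to the
#' other class's table with probability `emission_noise`. With zero
#' emission noise the inclusive-redundancy label equals the latent state
#' for every pair. The latent truth is returned separately and must not be
#' given to the pipeline.
#'
#' @param config a `syn_config`.
#' @param seed integer seed; identical seeds give identical benchmarks.
#' @return list with `trios`, `genes`, `schema`, `pairs`, `truth`
#'   (pair_id, latent `redundant` state, `emitted_consistent`), `planted`
#'   (names of base features carrying planted effects), and the `config`.
#' @export
generate_benchmark <- function(config = syn_config(), seed = 1) {
  n <- config$n_pairs
  n_clusters <- 20
  with_seed(seed, {
    r <- stats::rbinom(n, 1, config$prevalence)
    gene_bank <- list()  # per latent state: indices of reusable genes
    genes <- list()
    pair_rows <- list()
    trio_rows <- list()
    consistent <- logical(n)
    gene_counter <- 0

    for (i in seq_len(n)) {
      ri <- r[i]
      # gene A: optionally re-use an earlier gene of the same latent state
      reuse <- config$share_genes && length(gene_bank[[as.character(ri)]]) > 0 &&
        stats::runif(1) < config$reuse_rate
      if (reuse) {
        ga_idx <- sample(gene_bank[[as.character(ri)]], 1)
      } else {
        gene_counter <- gene_counter + 1
        ga_idx <- gene_counter
        genes[[ga_idx]] <- c(list(gene = sprintf("G%05d", ga_idx)),
                             draw_gene_values(config, ri))
      }
      gene_counter <- gene_counter + 1
      gb_idx <- gene_counter
      genes[[gb_idx]] <- c(list(gene = sprintf("G%05d", gb_idx)),
                           draw_gene_values(config, ri))
      gene_bank[[as.character(ri)]] <- c(gene_bank[[as.character(ri)]], ga_idx, gb_idx)

      # coexpression cluster: co-membership probability depends on state
      p_same <- config$cluster_effect[[if (ri == 1) "redundant" else "nonredundant"]]
      cl_a <- sample(n_clusters, 1)
      cl_b <- if (stats::runif(1) < p_same) cl_a else
        sample(setdiff(seq_len(n_clusters), cl_a), 1)
      if (is.na(genes[[ga_idx]]$coexpr_cluster)) {
        genes[[ga_idx]]$coexpr_cluster <- paste0("cl", cl_a)
      }
      genes[[gb_idx]]$coexpr_cluster <- paste0("cl", cl_b)

      # phenotype emission
      flip <- stats::runif(1) < config$emission_noise
      state <- if ((ri == 1) != flip) "redundant" else "nonredundant"
      tab <- config$phenotype_tables[[state]]
      row <- tab[sample(nrow(tab), 1, prob = tab$prob), ]
      consistent[i] <- !flip
      pid <- sprintf("pair%04d", i)
      pair_rows[[i]] <- data.frame(pair_id = pid,
                                   gene_a = genes[[ga_idx]]$gene,
                                   gene_b = genes[[gb_idx]]$gene)
      trio_rows[[i]] <- data.frame(pair_id = pid,
                                   gene_a = genes[[ga_idx]]$gene,
                                   gene_b = genes[[gb_idx]]$gene,
                                   sm_a_class = row$sm_a, sm_b_class = row$sm_b,
                                   dm_class = row$dm)
    }
    genes_df <- do.call(rbind, lapply(genes, as.data.frame))
  })
  list(
    trios = do.call(rbind, trio_rows),
    genes = genes_df,
    schema = config$features[, c("name", "data_type", "category")],
    pairs = do.call(rbind, pair_rows),
    truth = data.frame(pair_id = vapply(pair_rows, `[[`, character(1), "pair_id"),
                       redundant = as.logical(r),
                       emitted_consistent = consistent),
    planted = c(names(config$continuous_effects), names(config$binary_effects),
                "coexpr_cluster"),
    config = config
  )
}

#' Write a synthetic benchmark to a directory of TSV files
#'
#' Writes `genes.tsv`, `schema.tsv`, `trios.tsv` and `pairs.tsv` (the
#' pipeline inputs) plus `truth.tsv` (the withheld latent states, for
#' evaluation only).
#'
#' @param bench a benchmark from [generate_benchmark()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(bench$genes, "genes.tsv")
  w(data.frame(name = bench$schema$name, data_type = bench$schema$data_type,
               category = bench$schema$category), "schema.tsv")
  w(bench$trios, "trios.tsv")
  w(bench$pairs, "pairs.tsv")
  w(bench$truth, "truth.tsv")
  invisible(dir)
}
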