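# Shared fixtures and independent oracles, built in code.

# exhaustive-enumeration oracle for the tuple count (independent of the DP)
enum_count_leq <- function(k, n, x) {
  grid <- expand.grid(rep(list(seq_len(n)), k))
  as.numeric(sum(apply(grid, 1, prod) <= x))
}

# all products achievable by k ranks in 1..n
achievable_products <- function(k, n) {
  grid <- expand.grid(rep(list(seq_len(n)), k))
  sort(unique(apply(grid, 1, prod)))
}

toy_de <- function() {
  de_table(
    data.frame(
      gene_id = c("gA", "gB", "gC", "gD"),
      log2fc = c(2.0, -1.5, 0.2, 1.2),
      p_adj = c(0.01, 0.04, 0.01, 0.20),
      stringsAsFactors = FALSE
    ),
    contrast_label = "toy"
  )
}

toy_map <- function(pairs) {
  ortholog_map(data.frame(
    source_gene = vapply(pairs, `[[`, character(1), 1),
    target_gene = vapply(pairs, `[[`, character(1), 2),
    stringsAsFactors = FALSE
  ))
}

# a small ranked profile over genes g001.. with a fixed seed
random_ranked_profile <- function(n, seed) {
  set.seed(seed)
  stats::setNames(sample.int(n), sprintf("g%03d", seq_len(n)))
}

random_signature <- function(universe, k_up, k_down, seed, name = "sig") {
  set.seed(seed)
  genes <- sample(universe, k_up + k_down)
  signature(name,
            up = if (k_up) genes[seq_len(k_up)] else character(0),
            down = if (k_down) genes[k_up + seq_len(k_down)] else character(0))
}

# in-memory synthetic pipeline run (no files): planted or null
run_synthetic_pipeline <- function(seed, n_genes = 2000, n_compounds = 100,
                                   n_timepoints = 3, n_signature_genes = 60,
                                   planted = NULL, translate = FALSE) {
  de <- simulate_timecourse_de(n_genes = n_genes, n_timepoints = n_timepoints,
                               n_signature_genes = n_signature_genes,
                               seed = seed)
  panel <- signature_panel(lapply(de, extract_signature))
  map <- NULL
  if (translate) {
    map <- simulate_ortholog_map(sprintf("zfg%05d", seq_len(n_genes)),
                                 seed = seed)
    panel <- signature_panel(lapply(panel, translate_signature, map = map,
                                    policy = "expand"))
  }
  cfg <- sim_config(n_genes = n_genes, n_compounds = n_compounds,
                    instances_per_compound = 2, planted = planted, seed = seed)
  pm <- simulate_profile_matrix(cfg, panel)
  run_repositioning(panel, pm, translate = FALSE)
}
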