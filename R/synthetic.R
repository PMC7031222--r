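# Synthetic fixtures for every pipeline stage: time-course DE tables,
# ortholog maps, and CMap-like profile matrices with planted connectivity,
# so the whole method is testable without any external download.
#
# Planting happens directly in rank space (the scoring consumes ranks, so
# the effect size delta is interpretable there): a planted positive
# instance redraws the rank of a fraction phi of the signature's up genes
# as ceiling(u * (1 - delta) * n) (pushed towards 1, with u ~ U(0,1)) and
# mirrors the down genes towards n; remaining genes fill the remaining
# ranks in random order, so every column stays a permutation.
#
# A single global seed fans out to per-component streams by stable hashing
# of (seed, component name): adding one component never shifts another's
# draws.

#' Derive a component seed from a global seed
#'
#' Stable polynomial string hash of `(seed, component)`, reduced to a
#' 31-bit integer suitable for [set.seed()].
#'
#' @param seed Global integer seed.
#' @param component Component name (e.g. `"de_tables"`).
#' @return An integer seed.
#' @export
fan_seed <- function(seed, component) {
  key <- paste0(seed, "/", component)
  h <- 17
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% 2147483629
  }
  as.integer(h)
}

#' Simulation configuration for a planted profile matrix
#'
#' @param n_genes Gene universe size.
#' @param n_compounds Number of compounds m.
#' @param instances_per_compound Treatment instances per compound.
#' @param cell_lines Cell-line labels cycled across instances.
#' @param planted Data frame with columns `compound_id`, `direction`
#'   (`"positive"`/`"negative"`), `delta` (effect size in \[0, 1\]) and
#'   `phi` (fraction of signature genes affected, in (0, 1\]); may have
#'   zero rows for a null configuration.
#' @param seed Global seed fanned out to all components.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_compounds = 100,
                       instances_per_compound = 2,
                       cell_lines = c("CL1", "CL2"),
                       planted = NULL, seed = 1) {
  stopifnot(n_genes >= 10, n_compounds >= 2, instances_per_compound >= 1)
  compounds <- sprintf("cmpd%04d", seq_len(n_compounds))
  if (is.null(planted)) {
    planted <- data.frame(compound_id = character(0), direction = character(0),
                          delta = numeric(0), phi = numeric(0),
                          stringsAsFactors = FALSE)
  }
  planted <- as.data.frame(planted, stringsAsFactors = FALSE)
  if (nrow(planted)) {
    stopifnot(all(c("compound_id", "direction", "delta", "phi") %in%
                    names(planted)),
              all(planted$direction %in% c("positive", "negative")),
              all(planted$delta >= 0 & planted$delta <= 1),
              all(planted$phi > 0 & planted$phi <= 1))
    bad <- setdiff(planted$compound_id, compounds)
    if (length(bad)) {
      stop("planted compound ids not in the compound set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_genes = n_genes, n_compounds = n_compounds,
         instances_per_compound = instances_per_compound,
         cell_lines = cell_lines, compounds = compounds,
         planted = planted, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a time-course of differential-expression tables
#'
#' Emulates a multi-timepoint injury/regeneration contrast series: at each
#' timepoint a random subset of `n_signature_genes` genes receives a strong
#' fold change (|log2fc| >= `lfc_effect`, adjusted p < 0.05) while
#' background genes get small noise fold changes and uniform p-values.
#'
#' @param n_genes Total genes (ids `zfg00001`, ...).
#' @param n_timepoints Number of timepoints (contrasts).
#' @param n_signature_genes Differentially expressed genes per timepoint.
#' @param lfc_effect Minimum absolute log2 fold change of affected genes.
#' @param seed Seed (fanned out per component).
#' @return A list of [de_table()]s labelled `tp1_vs_ref`, `tp2_vs_ref`, ...
#' @export
simulate_timecourse_de <- function(n_genes = 2000, n_timepoints = 3,
                                   n_signature_genes = 60, lfc_effect = 2,
                                   seed = 1) {
  stopifnot(n_signature_genes <= n_genes, n_timepoints >= 1)
  genes <- sprintf("zfg%05d", seq_len(n_genes))
  lapply(seq_len(n_timepoints), function(t) {
    set.seed(fan_seed(seed, paste0("de_tables/", t)))
    lfc <- rnorm(n_genes, 0, 0.3)
    p <- runif(n_genes)
    if (n_signature_genes > 0) {
      hit <- sample.int(n_genes, n_signature_genes)
      sign_hit <- sample(c(-1, 1), n_signature_genes, replace = TRUE)
      lfc[hit] <- sign_hit * (lfc_effect + rexp(n_signature_genes, rate = 2))
      p[hit] <- runif(n_signature_genes, 0, 0.049)
    }
    de_table(
      data.frame(gene_id = genes, log2fc = lfc, p_adj = p,
                 stringsAsFactors = FALSE),
      contrast_label = paste0("tp", t, "_vs_ref")
    )
  })
}

#' Simulate an ortholog map
#'
#' Assigns each source gene a fate: unmapped, one-to-one, or one-to-many
#' (two targets), with counts matching the requested fractions within
#' rounding.
#'
#' @param source_genes Character vector of source gene ids.
#' @param target_prefix Prefix for generated target ids.
#' @param frac_one_to_many Fraction of source genes mapping to two targets.
#' @param frac_unmapped Fraction of source genes with no target.
#' @param seed Seed.
#' @return An [ortholog_map()].
#' @export
simulate_ortholog_map <- function(source_genes, target_prefix = "hsg",
                                  frac_one_to_many = 0.1,
                                  frac_unmapped = 0.05, seed = 1) {
  stopifnot(frac_one_to_many >= 0, frac_unmapped >= 0)
  if (frac_one_to_many + frac_unmapped > 1) {
    stop("frac_one_to_many + frac_unmapped must be <= 1", call. = FALSE)
  }
  set.seed(fan_seed(seed, "ortholog_map"))
  n <- length(source_genes)
  n_un <- round(frac_unmapped * n)
  n_many <- round(frac_one_to_many * n)
  fate <- sample(rep(c("unmapped", "many", "one"),
                     c(n_un, n_many, n - n_un - n_many)))
  tid <- 0L
  next_target <- function() {
    tid <<- tid + 1L
    sprintf("%s%05d", target_prefix, tid)
  }
  rows <- lapply(seq_len(n), function(i) {
    switch(fate[[i]],
      unmapped = NULL,
      one = data.frame(source_gene = source_genes[[i]],
                       target_gene = next_target(),
                       stringsAsFactors = FALSE),
      many = data.frame(source_gene = source_genes[[i]],
                        target_gene = c(next_target(), next_target()),
                        stringsAsFactors = FALSE)
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(ortholog_map(data.frame(source_gene = character(0),
                                   target_gene = character(0),
                                   stringsAsFactors = FALSE)))
  }
  ortholog_map(do.call(rbind, rows))
}

# place `desired` target ranks (possibly with duplicates) as distinct ranks
# in 1..n: sort, bump collisions upward, then sweep back from n
place_desired_ranks <- function(desired, n) {
  k <- length(desired)
  stopifnot(k <= n)
  ord <- order(desired)
  pos <- desired[ord]
  for (i in seq_len(k)[-1]) {
    if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1
  }
  if (pos[k] > n) pos[k] <- n
  for (i in rev(seq_len(max(k - 1, 0)))) {
    if (pos[i] >= pos[i + 1]) pos[i] <- pos[i + 1] - 1
  }
  out <- integer(k)
  out[ord] <- pos
  out
}

#' Simulate a CMap-like profile matrix with planted connectivity
#'
#' Every non-planted instance is an independent uniform random permutation
#' of `1..n_genes`.  Instances of planted compounds are perturbed towards
#' the panel: the union of the panel's up genes is pushed towards rank 1
#' and the union of the down genes towards rank n (swapped for negative
#' planting), at effect size `delta` on a fraction `phi` of the genes.
#' Genes appearing in both directions across the panel are left untouched.
#'
#' @param cfg A [sim_config()].
#' @param panel A [signature_panel()] in the profile's gene space; all
#'   panel genes must be inside the generated universe.
#' @param universe Optional explicit gene universe; defaults to the panel
#'   genes padded with background ids (`bg00001`, ...) up to `n_genes`.
#' @return A `profile_matrix` of ranks with instance annotations and a
#'   `truth` attribute (the planted table).
#' @export
simulate_profile_matrix <- function(cfg, panel, universe = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "signature_panel"))
  n <- cfg$n_genes
  up_all <- sort(unique(unlist(lapply(panel, `[[`, "up"))))
  down_all <- sort(unique(unlist(lapply(panel, `[[`, "down"))))
  both <- intersect(up_all, down_all)
  up_all <- setdiff(up_all, both)
  down_all <- setdiff(down_all, both)
  panel_genes <- sort(unique(c(up_all, down_all, both)))
  if (is.null(universe)) {
    if (length(panel_genes) > n) {
      stop("panel has more genes than n_genes", call. = FALSE)
    }
    universe <- c(panel_genes,
                  sprintf("bg%05d", seq_len(n - length(panel_genes))))
  } else {
    if (length(universe) != n || anyDuplicated(universe)) {
      stop("universe must hold n_genes unique ids", call. = FALSE)
    }
    if (!all(panel_genes %in% universe)) {
      stop("panel genes must be contained in the universe", call. = FALSE)
    }
  }
  up_idx <- match(up_all, universe)
  down_idx <- match(down_all, universe)

  inst_ids <- character(0)
  ann <- NULL
  cols <- list()
  planted <- cfg$planted
  for (ci in seq_along(cfg$compounds)) {
    cmpd <- cfg$compounds[[ci]]
    plant <- planted[planted$compound_id == cmpd, , drop = FALSE]
    for (ii in seq_len(cfg$instances_per_compound)) {
      inst <- sprintf("%s_i%02d", cmpd, ii)
      set.seed(fan_seed(cfg$seed, paste0("profile/", inst)))
      ranks <- sample.int(n)
      if (nrow(plant)) {
        ranks <- plant_instance(ranks, n, up_idx, down_idx,
                                direction = plant$direction[[1]],
                                delta = plant$delta[[1]], phi = plant$phi[[1]])
      }
      inst_ids <- c(inst_ids, inst)
      cols[[inst]] <- ranks
      ann <- rbind(ann, data.frame(
        instance_id = inst, compound_id = cmpd,
        cell_line = cfg$cell_lines[[(ii - 1L) %% length(cfg$cell_lines) + 1L]],
        stringsAsFactors = FALSE
      ))
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- universe
  pm <- profile_matrix(mat, values = "ranks", annotations = ann)
  attr(pm, "truth") <- planted
  pm
}

# perturb one instance's rank permutation towards (or away from) the
# planted direction; returns a valid permutation of 1..n
plant_instance <- function(ranks, n, up_idx, down_idx, direction, delta, phi) {
  pick <- function(idx) {
    if (!length(idx)) return(integer(0))
    k <- round(phi * length(idx))
    if (k < 1) {
      warning("phi * k < 1: no genes moved for this direction",
              call. = FALSE)
      return(integer(0))
    }
    idx[sample.int(length(idx), k)]
  }
  top_idx <- pick(up_idx)      # pushed towards 1 for positive planting
  bottom_idx <- pick(down_idx) # pushed towards n for positive planting
  if (direction == "negative") {
    tmp <- top_idx
    top_idx <- bottom_idx
    bottom_idx <- tmp
  }
  moved <- c(top_idx, bottom_idx)
  if (!length(moved)) return(ranks)
  d_top <- pmax(1L, as.integer(ceiling(runif(length(top_idx)) * (1 - delta) * n)))
  d_bottom <- n + 1L -
    pmax(1L, as.integer(ceiling(runif(length(bottom_idx)) * (1 - delta) * n)))
  assigned <- place_desired_ranks(c(d_top, d_bottom), n)
  remaining <- setdiff(seq_len(n), assigned)
  ranks[-moved] <- sample(remaining)
  ranks[moved] <- assigned
  ranks
}

#' Write a complete synthetic fixture set to a directory
#'
#' Generates the full chain — time-course DE tables, extracted signatures,
#' ortholog map, translated panel, planted profile matrix — and writes
#' every artifact (DE TSVs, source and translated GMT, ortholog TSV, GCT
#' matrix, annotation TSV, truth table) for use as pipeline inputs.
#'
#' @param dir Output directory (created).
#' @param cfg A [sim_config()].
#' @param n_timepoints,n_signature_genes,lfc_effect Passed to
#'   [simulate_timecourse_de()].
#' @param frac_one_to_many,frac_unmapped Passed to
#'   [simulate_ortholog_map()].
#' @return Invisibly, a list with the in-memory objects (`de_tables`,
#'   `panel`, `map`, `panel_hs`, `pm`, `paths`).
#' @export
simulate_fixture <- function(dir, cfg, n_timepoints = 3,
                             n_signature_genes = 60, lfc_effect = 2,
                             frac_one_to_many = 0.1, frac_unmapped = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  de_tables <- simulate_timecourse_de(
    n_genes = cfg$n_genes, n_timepoints = n_timepoints,
    n_signature_genes = n_signature_genes, lfc_effect = lfc_effect,
    seed = cfg$seed
  )
  panel <- signature_panel(lapply(de_tables, extract_signature))
  map <- simulate_ortholog_map(
    sprintf("zfg%05d", seq_len(cfg$n_genes)),
    frac_one_to_many = frac_one_to_many, frac_unmapped = frac_unmapped,
    seed = cfg$seed
  )
  panel_hs <- signature_panel(lapply(panel, translate_signature, map = map,
                                     policy = "expand"))
  pm <- simulate_profile_matrix(cfg, panel_hs)

  paths <- list(
    de = file.path(dir, sprintf("de_%s.tsv",
                                vapply(de_tables, attr, character(1),
                                       "contrast_label"))),
    panel = file.path(dir, "signatures_source.gmt"),
    panel_hs = file.path(dir, "signatures_translated.gmt"),
    map = file.path(dir, "ortholog_map.tsv"),
    matrix = file.path(dir, "profiles.gct"),
    annotations = file.path(dir, "instances.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  for (i in seq_along(de_tables)) write_de_table(de_tables[[i]], paths$de[[i]])
  write_gmt(panel_to_gmt(panel), paths$panel)
  write_gmt(panel_to_gmt(panel_hs), paths$panel_hs)
  write_ortholog_map(map, paths$map)
  write_profile_matrix(pm, paths$matrix)
  write_instance_annotations(pm$annotations, paths$annotations)
  write.table(cfg$planted, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(de_tables = de_tables, panel = panel, map = map,
                 panel_hs = panel_hs, pm = pm, paths = paths))
}
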